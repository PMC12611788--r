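#' Multi-channel image stack with physical voxel sizes
#'
#' @param channels Named list of 3-D numeric arrays, all with the same
#'   dimensions, indexed `[x, y, z]`; intensities in arbitrary units >= 0.
#' @param voxel_size Numeric length-3 vector `(x, y, z)` in micrometres.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), length(voxel_size) == 3L,
            all(voxel_size > 0))
  dims <- dim(channels[[1L]])
  for (ch in channels) {
    stopifnot(length(dim(ch)) == 3L, all(dim(ch) == dims), all(ch >= 0))
  }
  structure(list(channels = channels,
                 voxel_size = stats::setNames(as.numeric(voxel_size),
                                              c("x", "y", "z")),
                 dim = dims),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %s voxels @ %s um; channels: %s\n",
              paste(x$dim, collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract a channel
#' @param stack An [image_stack()].
#' @param name Channel name.
#' @export
get_channel <- function(stack, name) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- stack$channels[[name]]
  if (is.null(ch)) stop(sprintf("channel '%s' not present", name))
  ch
}

#' Maximum-intensity projection along z
#' @param vol 3-D array `[x, y, z]`.
#' @param slices Optional z-slice indices (default all).
#' @export
mip <- function(vol, slices = NULL) {
  stopifnot(length(dim(vol)) == 3L)
  if (is.null(slices)) slices <- seq_len(dim(vol)[3L])
  apply(vol[, , slices, drop = FALSE], c(1L, 2L), max)
}

# 3-D connected-component labelling, 26-connectivity: EBImage's bwlabel is
# 2-D, so label slices independently and merge labels across neighbouring
# slices with a union-find over the 9 inter-slice pixel offsets.
.label3d <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (z in seq_len(d[3L])) {
    sl <- EBImage::bwlabel(mask[, , z])
    nlab <- max(0L, as.integer(max(sl)))
    pos <- sl > 0
    sl[pos] <- sl[pos] + offset
    labs[, , z] <- sl
    offset <- offset + nlab
  }
  if (offset == 0L) return(labs)
  parent <- seq_len(offset)
  findp <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  unite <- function(a, b) {
    ra <- findp(a); rb <- findp(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  shifts <- expand.grid(dx = -1:1, dy = -1:1)
  for (z in seq_len(d[3L] - 1L)) {
    a <- labs[, , z]; b <- labs[, , z + 1L]
    for (s in seq_len(nrow(shifts))) {
      dx <- shifts$dx[s]; dy <- shifts$dy[s]
      xa <- max(1L, 1L + dx):min(d[1L], d[1L] + dx)
      xb <- xa - dx
      ya <- max(1L, 1L + dy):min(d[2L], d[2L] + dy)
      yb <- ya - dy
      aa <- a[xa, ya]; bb <- b[xb, yb]
      both <- aa > 0L & bb > 0L
      if (any(both)) {
        pairs <- unique(cbind(aa[both], bb[both]))
        for (k in seq_len(nrow(pairs))) unite(pairs[k, 1L], pairs[k, 2L])
      }
    }
  }
  roots <- vapply(seq_len(offset), findp, integer(1))
  relab <- integer(offset)
  relab[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- labs > 0L
  labs[pos] <- relab[roots[labs[pos]]]
  labs
}
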