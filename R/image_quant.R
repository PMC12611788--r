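# Microscopy quantifications: nuclear segmentation and morphology,
# perinuclear/cytoplasmic ring enrichment, damage-foci calling, and area
# coverage. Standard morphology (Otsu, 2-D labelling, dilation, watershed,
# blurring) is delegated to EBImage; geometry is reported in micrometres.

# principal-axis lengths of a solid region from its coordinate covariance:
# a solid ellipse has variance a^2/4 along a semi-axis a, a solid ellipsoid
# a^2/5, so the full axis is 4*sqrt(var) (2-D) or 2*sqrt(5*var) (3-D)
.region_axes <- function(coords_um) {
  n <- nrow(coords_um)
  if (n < 3L) return(list(len = rep(0, ncol(coords_um)), vec = NULL))
  cv <- stats::cov(coords_um) * (n - 1) / n
  eg <- eigen(cv, symmetric = TRUE)
  fac <- if (ncol(coords_um) == 2L) 4 else 2 * sqrt(5)
  list(len = fac * sqrt(pmax(eg$values, 0)), vec = eg$vectors)
}

#' Segment nuclei from the DNA channel
#'
#' Global Otsu threshold, connected components and a minimum-size filter,
#' either on the 2-D maximum-intensity projection or in full 3-D
#' (26-connectivity). Morphology (length, width, aspect ratio, area or
#' volume, centroid) is reported in physical units from the component's
#' principal axes.
#'
#' @param stack An [image_stack()].
#' @param channel DNA channel name (default `"dna"`).
#' @param mode `"MIP"` (2-D projection) or `"3D"`.
#' @param min_size Minimum object size; defaults 20 um^2 (2-D) / 50 um^3
#'   (3-D), rejecting debris.
#' @return List with `labels` (2-D or 3-D label array), `records`
#'   (data.frame, one row per nucleus), `mask`, `mode`, `voxel_size`.
#' @export
segment_nuclei <- function(stack, channel = "dna", mode = c("MIP", "3D"),
                           min_size = NULL) {
  mode <- match.arg(mode)
  img <- get_channel(stack, channel)
  vs <- stack$voxel_size
  if (diff(range(img)) < .Machine$double.eps) {
    warning("degenerate threshold: empty or constant image, no nuclei")
    labs <- if (mode == "MIP") matrix(0L, dim(img)[1], dim(img)[2])
            else array(0L, dim(img))
    return(list(labels = labs, records = data.frame(), mask = labs > 0,
                mode = mode, voxel_size = vs))
  }
  if (mode == "MIP") {
    pr <- mip(img)
    thr <- EBImage::otsu(EBImage::Image(pr / max(pr))) * max(pr)
    mask <- pr > thr
    labs <- EBImage::bwlabel(mask)
    px_area <- vs[1] * vs[2]
    if (is.null(min_size)) min_size <- 20
    recs <- lapply(seq_len(max(labs)), function(l) {
      pix <- which(labs == l, arr.ind = TRUE)
      area <- nrow(pix) * px_area
      if (area < min_size) return(NULL)
      um <- cbind((pix[, 1] - 0.5) * vs[1], (pix[, 2] - 0.5) * vs[2])
      ax <- .region_axes(um)
      data.frame(label = l, area = area,
                 length = ax$len[1], width = ax$len[2],
                 aspect_ratio = ax$len[1] / ax$len[2],
                 centroid_x = mean(um[, 1]), centroid_y = mean(um[, 2]),
                 centroid_z = NA_real_)
    })
  } else {
    # flatten to 2-D so Otsu uses one global histogram, not one per slice
    thr <- EBImage::otsu(EBImage::Image(matrix(img / max(img)))) * max(img)
    mask <- img > thr
    labs <- .label3d(mask)
    vox_vol <- prod(vs)
    if (is.null(min_size)) min_size <- 50
    recs <- lapply(seq_len(max(labs)), function(l) {
      pix <- which(labs == l, arr.ind = TRUE)
      vol <- nrow(pix) * vox_vol
      if (vol < min_size) return(NULL)
      um <- sweep(sweep(pix, 2L, c(0.5, 0.5, 0.5)), 2L, vs, `*`)
      ax <- .region_axes(um)
      data.frame(label = l, volume = vol,
                 length = ax$len[1], width = ax$len[2],
                 aspect_ratio = ax$len[1] / ax$len[2],
                 centroid_x = mean(um[, 1]), centroid_y = mean(um[, 2]),
                 centroid_z = mean(um[, 3]))
    })
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  kept <- if (length(recs)) vapply(recs, `[[`, numeric(1), "label") else integer(0)
  labs[!(labs %in% kept)] <- 0L
  list(labels = labs, records = if (length(recs)) do.call(rbind, recs)
       else data.frame(),
       mask = labs > 0L, mode = mode, voxel_size = vs)
}

#' Mid-plane maximum-intensity projection around a nucleus
#'
#' Projects `n_slices` z-slices centred on the nucleus centroid.
#'
#' @param stack An [image_stack()].
#' @param channel Channel to project.
#' @param centroid_z Nucleus centroid z in micrometres.
#' @param n_slices Number of slices (default 3).
#' @export
midplane_mip <- function(stack, channel, centroid_z, n_slices = 3L) {
  img <- get_channel(stack, channel)
  nz <- dim(img)[3L]
  if (nz < n_slices) stop("stack thinner than n_slices")
  zc <- max(1L, min(nz, round(centroid_z / stack$voxel_size[3] + 0.5)))
  half <- (n_slices - 1L) %/% 2L
  z0 <- max(1L, min(zc - half, nz - n_slices + 1L))
  mip(img, slices = z0:(z0 + n_slices - 1L))
}

#' Perinuclear and cytoplasmic ring masks
#'
#' The perinuclear ring is a `pn_width` (default 0.5 um) morphological
#' dilation of the nucleus minus the nucleus; the cytoplasmic ring is a
#' further `cyt_width` (default 3 um) dilation minus both. Widths are
#' converted to pixels through the voxel size.
#'
#' @param nucleus_mask Logical 2-D matrix.
#' @param voxel_size Pixel size (um); first two components used.
#' @param pn_width,cyt_width Ring widths, um.
#' @return List with `perinuclear`, `cytoplasmic` (logical masks, disjoint
#'   from each other and the nucleus) and `border` (TRUE when the nucleus
#'   touches the image border, flagging an incomplete ring).
#' @export
ring_masks <- function(nucleus_mask, voxel_size, pn_width = 0.5,
                       cyt_width = 3) {
  px <- voxel_size[1]
  r_pn <- round(pn_width / px)
  r_cy <- round(cyt_width / px)
  if (r_pn < 1 || r_cy < 1) stop("ring width below one pixel")
  nuc <- nucleus_mask
  dil <- function(m, r) {
    EBImage::dilate(EBImage::Image(m * 1), EBImage::makeBrush(2L * r + 1L,
                                                              "disc")) > 0
  }
  pn <- dil(nuc, r_pn) & !nuc
  cyt <- dil(nuc, r_pn + r_cy) & !nuc & !pn
  d <- dim(nuc)
  border <- any(nuc[1, ]) || any(nuc[d[1], ]) || any(nuc[, 1]) || any(nuc[, d[2]])
  list(perinuclear = pn, cytoplasmic = cyt, border = border)
}

#' Perinuclear-to-cytoplasmic enrichment ratio
#'
#' Ratio of mean channel intensity in the perinuclear ring to the mean in
#' the cytoplasmic ring; both means are also returned.
#'
#' @param img 2-D intensity image.
#' @param masks A [ring_masks()] result.
#' @return List with `ratio`, `pn_mean`, `cyt_mean`, `valid` (FALSE with NA
#'   ratio when either mask is empty).
#' @export
enrichment_ratio <- function(img, masks) {
  if (!any(masks$perinuclear) || !any(masks$cytoplasmic)) {
    warning("empty ring mask: enrichment undefined")
    return(list(ratio = NA_real_, pn_mean = NA_real_, cyt_mean = NA_real_,
                valid = FALSE))
  }
  pn <- mean(img[masks$perinuclear])
  cy <- mean(img[masks$cytoplasmic])
  list(ratio = pn / cy, pn_mean = pn, cyt_mean = cy, valid = TRUE)
}

#' Pole enrichment at the long and short nuclear poles
#'
#' Automated stand-in for manually traced pole objects: caps of diameter
#' `pole_width` (default 2 um) centred where the principal axes meet the
#' nucleus boundary, excluding the nucleus itself; mean cap intensity is
#' normalized to the cytoplasmic ring mean. Flagged approximate in the
#' output (`automated = TRUE`), and flagged degenerate when the aspect
#' ratio is ~1 (axes tie-broken to the image axes).
#'
#' @param img 2-D intensity image.
#' @param nucleus_mask Logical 2-D matrix.
#' @param voxel_size Pixel size, um.
#' @param pole_width Cap diameter, um.
#' @return List with `long_pole_ratio`, `short_pole_ratio`, `degenerate`,
#'   `automated`.
#' @export
pole_enrichment <- function(img, nucleus_mask, voxel_size, pole_width = 2) {
  px <- voxel_size[1]
  pix <- which(nucleus_mask, arr.ind = TRUE)
  if (nrow(pix) < 10L) stop("nucleus mask too small for pole axes")
  um <- cbind((pix[, 1] - 0.5) * px, (pix[, 2] - 0.5) * voxel_size[2])
  ax <- .region_axes(um)
  degenerate <- ax$len[1] / ax$len[2] < 1.05
  vec <- if (degenerate) diag(2) else ax$vec
  cen <- colMeans(um)
  rings <- ring_masks(nucleus_mask, voxel_size)
  cyt_mean <- mean(img[rings$cytoplasmic])

  cap_mean <- function(dir, semi) {
    vals <- c()
    for (s in c(-1, 1)) {
      p0 <- cen + s * semi * dir
      xg <- ((seq_len(dim(img)[1]) - 0.5) * px - p0[1])^2
      yg <- ((seq_len(dim(img)[2]) - 0.5) * voxel_size[2] - p0[2])^2
      cap <- outer(xg, yg, `+`) <= (pole_width / 2)^2
      cap <- cap & !nucleus_mask
      if (any(cap)) vals <- c(vals, img[cap])
    }
    if (!length(vals)) NA_real_ else mean(vals)
  }
  list(long_pole_ratio = cap_mean(vec[, 1], ax$len[1] / 2) / cyt_mean,
       short_pole_ratio = cap_mean(vec[, 2], ax$len[2] / 2) / cyt_mean,
       degenerate = degenerate, automated = TRUE)
}

#' Detect nuclear-envelope-rupture reporter foci (2-D)
#'
#' Connected components of the reporter channel above a fixed intensity
#' threshold, kept when larger than `min_area`, touching the nucleus mask
#' (8-connected adjacency) and overlapping the perinuclear ring of width
#' `ring_width`.
#'
#' @param img 2-D reporter image (MIP).
#' @param nuclei A [segment_nuclei()] result (MIP mode).
#' @param voxel_size Pixel size, um.
#' @param intensity_thr Intensity threshold, a.u. (600 for the WT reporter
#'   line, 200 for the mutant line).
#' @param min_area Minimum focus area, um^2 (default 0.8).
#' @param ring_width Perinuclear ring width, um (default 1).
#' @return List with `foci` (data.frame: id, nucleus, area, mean/max
#'   intensity, touches_nucleus, in_ring) and `per_nucleus` counts.
#' @export
detect_cgas_foci <- function(img, nuclei, voxel_size, intensity_thr = 600,
                             min_area = 0.8, ring_width = 1) {
  px_area <- voxel_size[1] * voxel_size[2]
  nuc_mask <- nuclei$labels > 0
  ring <- ring_masks(nuc_mask, voxel_size, pn_width = ring_width)$perinuclear
  mask <- img > intensity_thr
  labs <- EBImage::bwlabel(mask)
  brush <- EBImage::makeBrush(3L, "box")
  out <- list()
  for (l in seq_len(max(labs))) {
    comp <- labs == l
    area <- sum(comp) * px_area
    if (area <= min_area) next
    grown <- EBImage::dilate(EBImage::Image(comp * 1), brush) > 0
    touches <- any(grown & nuc_mask)
    in_ring <- any(comp & ring)
    if (!(touches && in_ring)) next
    nl <- nuclei$labels[grown & nuc_mask]
    nl <- if (length(nl)) as.integer(names(which.max(table(nl[nl > 0]))))
          else NA_integer_
    out[[length(out) + 1L]] <- data.frame(
      id = l, nucleus = nl, area = area,
      mean_intensity = mean(img[comp]), max_intensity = max(img[comp]),
      touches_nucleus = touches, in_ring = in_ring)
  }
  foci <- if (length(out)) do.call(rbind, out) else
    data.frame(id = integer(0), nucleus = integer(0), area = numeric(0),
               mean_intensity = numeric(0), max_intensity = numeric(0),
               touches_nucleus = logical(0), in_ring = logical(0))
  labels_present <- if (nrow(nuclei$records)) nuclei$records$label else integer(0)
  per <- data.frame(nucleus = labels_present,
                    n_foci = vapply(labels_present,
                                    function(l) sum(foci$nucleus == l,
                                                    na.rm = TRUE), numeric(1)))
  list(foci = foci, per_nucleus = per)
}

#' Detect DNA damage foci in 3-D
#'
#' Intranuclear connected components (26-connectivity) of the marker
#' channel above a fixed intensity threshold, with a volume gate, plus
#' per-nucleus summaries: focus count, mean focus volume (integrated
#' volume / count) and the focus fraction of nuclear volume.
#'
#' @param stack An [image_stack()].
#' @param nuclei A [segment_nuclei()] result (3D mode).
#' @param channel Marker channel name (default `"gh2ax"`).
#' @param intensity_thr Intensity threshold, a.u. (default 2000).
#' @param vol_range Focus volume gate, um^3 (default 0.02 to 1000).
#' @return List with `foci` (per focus: id, nucleus, volume, mean/max
#'   intensity) and `per_nucleus` (count, mean_volume, fraction).
#' @export
detect_gh2ax_foci <- function(stack, nuclei, channel = "gh2ax",
                              intensity_thr = 2000,
                              vol_range = c(0.02, 1000)) {
  stopifnot(nuclei$mode == "3D")
  img <- get_channel(stack, channel)
  vox <- prod(stack$voxel_size)
  fg <- img > intensity_thr & nuclei$labels > 0L
  labs <- .label3d(fg)
  out <- list()
  for (l in seq_len(max(labs))) {
    sel <- labs == l
    vol <- sum(sel) * vox
    if (vol < vol_range[1] || vol > vol_range[2]) next
    nl <- nuclei$labels[sel]
    nl <- as.integer(names(which.max(table(nl[nl > 0]))))
    out[[length(out) + 1L]] <- data.frame(
      id = l, nucleus = nl, volume = vol,
      mean_intensity = mean(img[sel]), max_intensity = max(img[sel]))
  }
  foci <- if (length(out)) do.call(rbind, out) else
    data.frame(id = integer(0), nucleus = integer(0), volume = numeric(0),
               mean_intensity = numeric(0), max_intensity = numeric(0))
  per <- do.call(rbind, lapply(seq_len(nrow(nuclei$records)), function(i) {
    l <- nuclei$records$label[i]
    f <- foci[foci$nucleus == l, , drop = FALSE]
    tot <- sum(f$volume)
    data.frame(nucleus = l, count = nrow(f),
               mean_volume = if (nrow(f)) tot / nrow(f) else NA_real_,
               fraction = tot / nuclei$records$volume[i])
  }))
  if (is.null(per))
    per <- data.frame(nucleus = integer(0), count = numeric(0),
                      mean_volume = numeric(0), fraction = numeric(0))
  list(foci = foci, per_nucleus = per)
}

#' Outlier exclusion and control normalization of per-nucleus summaries
#'
#' Removes rows whose focus count or mean focus volume exceeds the
#' all-rows mean by more than 3 standard deviations (each criterion applied
#' independently), then divides the value columns by the control-group mean
#' (within each replicate when a replicate column is given).
#'
#' @param df Per-nucleus summary data.frame.
#' @param group_col,control_group Grouping column and the control level.
#' @param count_col,volume_col Columns screened for outliers.
#' @param value_cols Columns to normalize (default the two screened ones).
#' @param replicate_col Optional replicate column for per-replicate
#'   normalization.
#' @return The cleaned, normalized data.frame (attribute `n_excluded`).
#' @export
exclude_outliers_and_normalize <- function(df, group_col = "group",
                                           control_group,
                                           count_col = "count",
                                           volume_col = "mean_volume",
                                           value_cols = c(count_col, volume_col),
                                           replicate_col = NULL) {
  stopifnot(control_group %in% df[[group_col]])
  gate <- function(v) {
    ok <- !is.na(v)
    thr <- mean(v[ok]) + 3 * stats::sd(v[ok])
    if (is.na(thr)) rep(FALSE, length(v)) else !is.na(v) & v > thr
  }
  drop <- gate(df[[count_col]]) | gate(df[[volume_col]])
  out <- df[!drop, , drop = FALSE]
  reps <- if (is.null(replicate_col)) rep(1L, nrow(out)) else out[[replicate_col]]
  for (rp in unique(reps)) {
    sel <- reps == rp
    ctrl <- sel & out[[group_col]] == control_group
    for (vc in value_cols) {
      m <- mean(out[[vc]][ctrl], na.rm = TRUE)
      if (!is.finite(m) || m == 0)
        stop("control-group mean is zero or undefined; cannot normalize")
      out[[vc]][sel] <- out[[vc]][sel] / m
    }
  }
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Cardiomyocyte area coverage from the membrane (WGA) channel
#'
#' Maximum projection of `n_slices` central slices, Otsu threshold of the
#' membrane signal, and a distance-map watershed of the non-membrane space
#' into cell segments; coverage is the summed segment area over the image
#' area.
#'
#' @param stack An [image_stack()].
#' @param channel WGA channel name (default `"wga"`).
#' @param n_slices Slices in the projection (default 4).
#' @return List with `coverage` (fraction in 0..1) and `segments` (label
#'   matrix).
#' @export
cm_area_coverage <- function(stack, channel = "wga", n_slices = 4L) {
  img <- get_channel(stack, channel)
  nz <- dim(img)[3L]
  z0 <- max(1L, (nz - n_slices) %/% 2L + 1L)
  pr <- mip(img, slices = z0:min(nz, z0 + n_slices - 1L))
  if (diff(range(pr)) < .Machine$double.eps) {
    warning("no membrane signal found; coverage 0")
    return(list(coverage = 0, segments = matrix(0L, dim(pr)[1], dim(pr)[2])))
  }
  thr <- EBImage::otsu(EBImage::Image(pr / max(pr))) * max(pr)
  membrane <- pr > thr
  interior <- !membrane
  dm <- EBImage::distmap(EBImage::Image(interior * 1))
  seg <- EBImage::watershed(dm, tolerance = 1)
  seg <- as.integer(seg) |> array(dim(pr))
  seg[membrane] <- 0L
  list(coverage = sum(seg > 0L) / length(seg), segments = seg)
}

#' Percent area coverage of an immune marker
#'
#' Gaussian blur (sigma in physical units), maximum projection, fixed
#' threshold, percent of pixels above.
#'
#' @param stack An [image_stack()].
#' @param channel Marker channel.
#' @param threshold Intensity threshold, a.u.
#' @param sigma Blur sigma, um (default 0.3).
#' @return Percent area coverage (0..100).
#' @export
marker_coverage <- function(stack, channel, threshold, sigma = 0.3) {
  img <- get_channel(stack, channel)
  spx <- sigma / stack$voxel_size[1]
  blurred <- img
  for (z in seq_len(dim(img)[3L]))
    blurred[, , z] <- as.matrix(EBImage::gblur(EBImage::Image(img[, , z]),
                                               sigma = spx))
  pr <- mip(blurred)
  100 * mean(pr > threshold)
}
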