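#' Parameters for the synthetic microscopy-stack generator
#'
#' Describes a multi-channel 3-D field: ellipsoidal DNA-stained nuclei, a
#' perinuclear tubulin shell with configurable enrichment and pole boost,
#' planted reporter foci (spheres of stated size and intensity), an
#' optional membrane honeycomb, and detector noise. Intensities are on the
#' arbitrary-unit scale of the fixed thresholds used downstream (DNA ~500,
#' cytoplasmic tubulin ~100, rupture foci ~800 vs a 600 threshold, damage
#' foci ~3000 vs a 2000 threshold).
#'
#' @param field_size Field extent `(x, y, z)` in um.
#' @param voxel_size Voxel size `(x, y, z)` in um.
#' @param nuclei List of nuclei, each `list(center = c(x,y,z) um,
#'   semi = c(a,b,c) um, intensity = 500)`; semi-axis `a` lies along x.
#' @param shell `NULL` or `list(thickness = 0.6, enrichment = 1.9,
#'   pole_boost = 1, cyt_intensity = 100)`: tubulin shell around each
#'   nucleus at `enrichment` times the cytoplasmic level, with the long
#'   poles further multiplied by `pole_boost`.
#' @param foci `NULL` or a data.frame with columns `channel` (e.g. "cgas",
#'   "gh2ax"), `x`, `y`, `z` (um), `radius` (um), `intensity` (a.u.);
#'   rendered as uniform spheres added to their channel.
#' @param wga `NULL` or `list(pitch = 10, width = 0.5, intensity = 800)`:
#'   honeycomb (square-lattice) membrane grid in a `"wga"` channel.
#' @param background Background intensity added to every channel.
#' @param noise `list(gaussian_sd = 0, poisson = FALSE)` detector model.
#' @param seed Mandatory RNG seed.
#' @export
image_gen_params <- function(field_size = c(30, 25, 10),
                             voxel_size = c(0.2, 0.2, 0.5),
                             nuclei = list(list(center = c(15, 12.5, 5),
                                                semi = c(6, 3, 3),
                                                intensity = 500)),
                             shell = NULL, foci = NULL, wga = NULL,
                             background = 50,
                             noise = list(gaussian_sd = 0, poisson = FALSE),
                             seed) {
  if (missing(seed)) stop("seed is mandatory")
  for (nu in nuclei) {
    lo <- nu$center - nu$semi; hi <- nu$center + nu$semi
    if (any(lo < 0) || any(hi > field_size))
      stop("nucleus extends outside the field")
  }
  structure(as.list(environment()), class = "image_gen_params")
}

#' Generate a synthetic multi-channel stack with ground truth
#'
#' Renders the field described by [image_gen_params()] and returns the
#' stack together with machine-readable ground truth: exact nucleus masks
#' and morphology, shell masks, and the planted foci table.
#'
#' @param params An [image_gen_params()].
#' @return List with `stack` ([image_stack()]), `truth` (list:
#'   `nucleus_labels` 3-D array, `nuclei` data.frame, `foci` data.frame).
#' @export
gen_image_stack <- function(params) {
  stopifnot(inherits(params, "image_gen_params"))
  set.seed(params$seed)
  vs <- params$voxel_size
  d <- pmax(2L, round(params$field_size / vs))
  xs <- (seq_len(d[1]) - 0.5) * vs[1]
  ys <- (seq_len(d[2]) - 0.5) * vs[2]
  zs <- (seq_len(d[3]) - 0.5) * vs[3]

  blank <- array(0, d)
  dna <- blank
  tubulin <- NULL
  nuc_labels <- array(0L, d)

  # squared normalized ellipsoid distance field for one nucleus
  ell2 <- function(center, semi) {
    ex <- ((xs - center[1]) / semi[1])^2
    ey <- ((ys - center[2]) / semi[2])^2
    ez <- ((zs - center[3]) / semi[3])^2
    outer(outer(ex, ey, `+`), ez, `+`)
  }

  nuc_truth <- list()
  for (i in seq_along(params$nuclei)) {
    nu <- params$nuclei[[i]]
    q <- ell2(nu$center, nu$semi)
    inside <- q <= 1
    if (any(inside & nuc_labels > 0L)) stop("overlapping nuclei")
    nuc_labels[inside] <- i
    inten <- if (is.null(nu$intensity)) 500 else nu$intensity
    dna[inside] <- dna[inside] + inten
    nuc_truth[[i]] <- data.frame(
      label = i, volume = 4 / 3 * pi * prod(nu$semi),
      length = 2 * max(nu$semi), width = 2 * sort(nu$semi, TRUE)[2],
      aspect_ratio = max(nu$semi) / sort(nu$semi, TRUE)[2],
      centroid_x = nu$center[1], centroid_y = nu$center[2],
      centroid_z = nu$center[3])
  }

  if (!is.null(params$shell)) {
    sh <- params$shell
    cyt <- if (is.null(sh$cyt_intensity)) 100 else sh$cyt_intensity
    tubulin <- array(cyt, d)
    tubulin[nuc_labels > 0L] <- 0
    for (i in seq_along(params$nuclei)) {
      nu <- params$nuclei[[i]]
      q_in <- ell2(nu$center, nu$semi)
      q_out <- ell2(nu$center, nu$semi + sh$thickness)
      shell_vox <- q_out <= 1 & q_in > 1
      val <- cyt * sh$enrichment
      tubulin[shell_vox] <- val
      boost <- if (is.null(sh$pole_boost)) 1 else sh$pole_boost
      if (boost != 1) {
        # long poles: shell voxels beyond 70% of the long semi-axis in x
        ax <- abs(outer(outer(xs - nu$center[1], ys * 0, `+`), zs * 0, `+`))
        pole <- shell_vox & ax > 0.7 * nu$semi[1]
        tubulin[pole] <- val * boost
      }
    }
  }

  channels <- list(dna = dna + params$background)
  if (!is.null(tubulin)) channels$tubulin <- tubulin + params$background

  if (!is.null(params$foci)) {
    for (ch in unique(params$foci$channel)) {
      img <- array(0, d)
      rows <- params$foci[params$foci$channel == ch, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        fo <- rows[k, ]
        q <- ell2(c(fo$x, fo$y, fo$z), rep(fo$radius, 3L))
        img[q <= 1] <- fo$intensity
      }
      channels[[ch]] <- img + params$background
    }
  }

  if (!is.null(params$wga)) {
    wg <- params$wga
    half_w <- wg$width / 2
    on_line <- function(v) (v %% wg$pitch) < half_w |
      (v %% wg$pitch) > (wg$pitch - half_w)
    memb2d <- outer(on_line(xs), rep(TRUE, d[2]), `&`) |
              outer(rep(TRUE, d[1]), on_line(ys), `&`)
    img <- array(rep(memb2d * wg$intensity, d[3]), d)
    channels$wga <- img + params$background
  }

  if (params$noise$poisson)
    channels <- lapply(channels, function(ch)
      array(stats::rpois(length(ch), lambda = ch), d))
  if (params$noise$gaussian_sd > 0)
    channels <- lapply(channels, function(ch)
      pmax(ch + array(stats::rnorm(length(ch), 0, params$noise$gaussian_sd), d), 0))

  list(stack = image_stack(channels, vs),
       truth = list(nucleus_labels = nuc_labels,
                    nuclei = do.call(rbind, nuc_truth),
                    foci = params$foci))
}
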