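#' LOESS smoothing of an aspect-ratio vs. enrichment scatter
#'
#' Locally weighted linear regression (tricube weights) evaluated on a
#' uniform grid spanning the observed x-range. Used to visualize the pooled
#' biphasic relation between nuclear aspect ratio and perinuclear
#' microtubule enrichment before fitting the piecewise model.
#'
#' @param x,y Numeric vectors (enrichment ratio, aspect ratio), n >= 10.
#' @param span LOESS span (fraction of points per local fit), default 0.6.
#' @param n_grid Number of grid points for the smoothed curve.
#' @return data.frame with columns `x`, `y` (the smoothed curve).
#' @export
loess_smooth <- function(x, y, span = 0.6, n_grid = 100L) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) stop("loess_smooth: need at least 10 points")
  if (span * length(x) < 4) stop("loess_smooth: span too small for local fits")
  fit <- stats::loess(y ~ x, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = n_grid)
  data.frame(x = grid, y = stats::predict(fit, newdata = data.frame(x = grid)))
}

#' Deflection point of a smoothed curve
#'
#' Locates the interior grid point with the largest absolute change in local
#' slope (second difference). A curve whose maximal curvature is
#' indistinguishable from flat is reported as having no deflection.
#'
#' @param curve data.frame with `x`, `y` from [loess_smooth()] (>= 20 points).
#' @param flat_tol Minimum slope change (per unit x, relative to the overall
#'   slope scale) counted as a deflection.
#' @return List with `x_star` (NA if none) and `deflection` (logical).
#' @export
find_deflection <- function(curve, flat_tol = 0.05) {
  stopifnot(all(c("x", "y") %in% names(curve)))
  if (nrow(curve) < 20L) stop("find_deflection: need >= 20 grid points")
  x <- curve$x; y <- curve$y
  # slopes over a window of fixed physical width (15 % of the x-range), so
  # the estimate does not degrade as the evaluation grid is refined
  k <- max(2L, round(0.15 * (length(x) - 1L)))
  idx <- seq_len(length(x) - 2L * k)
  sl_lo <- (y[idx + k] - y[idx]) / (x[idx + k] - x[idx])
  sl_hi <- (y[idx + 2L * k] - y[idx + k]) / (x[idx + 2L * k] - x[idx + k])
  d2 <- abs(sl_hi - sl_lo)                  # slope change at x[idx + k]
  scale <- max(abs(c(sl_lo, sl_hi)), .Machine$double.eps)
  if (max(d2) < flat_tol * scale)
    return(list(x_star = NA_real_, deflection = FALSE))
  i <- which.max(d2) + k                    # interior grid index
  list(x_star = x[i], deflection = TRUE)
}

#' Continuity-constrained piecewise linear (hinge) regression
#'
#' Fits y = a + b_low * x + (b_high - b_low) * max(x - c, 0): two straight
#' segments joined continuously at a breakpoint c. The breakpoint is chosen
#' by profiling the residual sum of squares over a grid spanning the central
#' 80 % of x (one refinement pass around the coarse optimum), unless a fixed
#' breakpoint is supplied. Slope standard errors and two-sided p-values for
#' each segment slope (null: slope = 0) come from the conditional linear
#' model at the selected breakpoint, under homoscedastic normal errors.
#'
#' @param x,y Numeric vectors; x > 0, y >= 1 for aspect-ratio data (not
#'   enforced; any biphasic scatter is accepted). n >= 10.
#' @param breakpoint Optional fixed breakpoint (e.g. a LOESS deflection).
#' @param n_grid Breakpoint profile grid size (default 100).
#' @param min_side Minimum points required on each side of a candidate
#'   breakpoint (default 5).
#' @return Object of class `piecewise_fit`: breakpoint, slopes, intercept,
#'   standard errors, p-values, SSE of the hinge and of the single-line fit,
#'   and an `identifiable` flag (FALSE when the hinge does not improve on a
#'   single line).
#' @export
piecewise_fit <- function(x, y, breakpoint = NULL, n_grid = 100L,
                          min_side = 5L) {
  stopifnot(length(x) == length(y), length(x) >= 10L)
  ord <- order(x); x <- x[ord]; y <- y[ord]

  fit_at <- function(bp) {
    if (sum(x < bp) < min_side || sum(x > bp) < min_side) return(NULL)
    h <- pmax(x - bp, 0)
    fit <- stats::lm(y ~ x + h)
    list(bp = bp, fit = fit, sse = sum(stats::resid(fit)^2))
  }
  profile_grid <- function(grid) {
    fits <- lapply(grid, fit_at)
    fits <- fits[!vapply(fits, is.null, logical(1))]
    if (!length(fits)) stop("piecewise_fit: no candidate breakpoint leaves ",
                            min_side, " points on each side")
    sse <- vapply(fits, `[[`, numeric(1), "sse")
    bps <- vapply(fits, `[[`, numeric(1), "bp")
    # tie-break: smallest SSE then smallest breakpoint
    fits[[order(sse, bps)[1L]]]
  }

  if (is.null(breakpoint)) {
    lo <- stats::quantile(x, 0.10); hi <- stats::quantile(x, 0.90)
    coarse <- profile_grid(seq(lo, hi, length.out = n_grid))
    step <- (hi - lo) / (n_grid - 1)
    best <- profile_grid(seq(coarse$bp - step, coarse$bp + step,
                             length.out = 21L))
    # continuous polish inside the bracketing interval (SSE is piecewise
    # smooth in the breakpoint, so 1-D minimization closes the grid gap)
    opt <- stats::optimize(function(b) {
      f <- fit_at(b); if (is.null(f)) Inf else f$sse
    }, interval = c(best$bp - step / 10, best$bp + step / 10))
    polished <- fit_at(opt$minimum)
    if (!is.null(polished) && polished$sse <= best$sse) best <- polished
  } else {
    best <- fit_at(breakpoint)
    if (is.null(best)) stop("piecewise_fit: fixed breakpoint leaves fewer than ",
                            min_side, " points on one side")
  }

  cf <- stats::coef(best$fit)
  V <- stats::vcov(best$fit)
  slope_low <- unname(cf["x"])
  slope_high <- unname(cf["x"] + cf["h"])
  se_low <- sqrt(V["x", "x"])
  se_high <- sqrt(V["x", "x"] + V["h", "h"] + 2 * V["x", "h"])
  df <- stats::df.residual(best$fit)
  p_low <- 2 * stats::pt(abs(slope_low / se_low), df, lower.tail = FALSE)
  p_high <- 2 * stats::pt(abs(slope_high / se_high), df, lower.tail = FALSE)

  line <- stats::lm(y ~ x)
  sse_line <- sum(stats::resid(line)^2)
  structure(list(
    breakpoint = best$bp,
    slope_low = slope_low, slope_high = slope_high,
    intercept = unname(cf["(Intercept)"]),
    se = c(slope_low = se_low, slope_high = se_high),
    p_slope_low = p_low, p_slope_high = p_high,
    sse = best$sse, sse_line = sse_line,
    identifiable = (sse_line - best$sse) >
      1e-6 * max(sum((y - mean(y))^2), .Machine$double.eps),
    n = length(x), df = df), class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(paste0("<piecewise_fit> breakpoint %.3f; slope below %.3f",
                     " (p=%.3g), above %.3f (p=%.3g)%s\n"),
              x$breakpoint, x$slope_low, x$p_slope_low,
              x$slope_high, x$p_slope_high,
              if (x$identifiable) "" else " [breakpoint unidentifiable]"))
  invisible(x)
}

#' Evaluate a hinge function
#'
#' @param x Points to evaluate at.
#' @param breakpoint,slope_low,slope_high,intercept_at_breakpoint Hinge
#'   parameters; `intercept_at_breakpoint` is the y-value at the breakpoint.
#' @export
hinge <- function(x, breakpoint, slope_low, slope_high,
                  intercept_at_breakpoint) {
  ifelse(x < breakpoint,
         intercept_at_breakpoint + slope_low * (x - breakpoint),
         intercept_at_breakpoint + slope_high * (x - breakpoint))
}

#' Generate a synthetic biphasic scatter
#'
#' Draws x uniformly over `x_range` and sets y to a hinge (continuous
#' two-segment line) plus Gaussian noise. Defaults are calibrated to the
#' pooled aspect-ratio vs. enrichment relation: deflection at 1.9, slope
#' -2.1 below, flat above, aspect ratio 2 at the deflection.
#'
#' @param n Number of points (default 300, >= 20).
#' @param breakpoint,slope_low,slope_high,intercept_at_breakpoint Hinge
#'   parameters (see [hinge()]).
#' @param x_range Range of enrichment values (must contain the breakpoint).
#' @param noise_sd Gaussian noise s.d. on y (aspect-ratio units).
#' @param seed Mandatory RNG seed.
#' @return List with `data` (data.frame x, y) and `truth` (the parameters).
#' @export
gen_biphasic_scatter <- function(n = 300L, breakpoint = 1.9,
                                 slope_low = -2.1, slope_high = 0,
                                 intercept_at_breakpoint = 2.0,
                                 x_range = c(0.8, 3.5), noise_sd = 0.3,
                                 seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n >= 20L, x_range[1] < breakpoint, breakpoint < x_range[2])
  set.seed(seed)
  x <- stats::runif(n, x_range[1], x_range[2])
  y <- hinge(x, breakpoint, slope_low, slope_high, intercept_at_breakpoint) +
    stats::rnorm(n, 0, noise_sd)
  list(data = data.frame(x = x, y = y),
       truth = list(breakpoint = breakpoint, slope_low = slope_low,
                    slope_high = slope_high,
                    intercept_at_breakpoint = intercept_at_breakpoint,
                    noise_sd = noise_sd, n = n, seed = seed))
}
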