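#' Raw length trace
#'
#' Container for a single-channel length recording from a stimulated
#' cardiomyocyte: sarcomere length (from the optical Fourier transform
#' readout) or nuclear length/width (from segmented fluorescence frames).
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   on a uniform grid.
#' @param value Numeric vector of lengths in micrometres, positive.
#' @param sampling_rate Sampling rate in Hz. If `NULL`, inferred from `time`.
#' @param stim_times Numeric vector of field-stimulation times (seconds),
#'   each within the recorded interval.
#' @param channel One of `"sarcomere_length"`, `"nuclear_length"`,
#'   `"nuclear_width"`.
#' @return An object of class `raw_trace`.
#' @export
raw_trace <- function(time, value, sampling_rate = NULL,
                      stim_times = numeric(0),
                      channel = c("sarcomere_length", "nuclear_length",
                                  "nuclear_width")) {
  channel <- match.arg(channel)
  stopifnot(is.numeric(time), is.numeric(value), length(time) == length(value))
  if (length(time) < 1L || anyNA(time) || anyNA(value))
    stop("trace must be non-empty and finite")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(value <= 0)) stop("lengths must be positive")
  if (is.null(sampling_rate)) {
    sampling_rate <- if (length(time) > 1L) 1 / stats::median(diff(time)) else NA_real_
  }
  if (!is.na(sampling_rate) && sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (length(stim_times) &&
      (min(stim_times) < time[1L] - 1e-9 || max(stim_times) > time[length(time)] + 1e-9))
    stop("stim_times must lie within the recorded interval")
  structure(
    list(time = as.numeric(time), value = as.numeric(value),
         sampling_rate = sampling_rate,
         stim_times = sort(as.numeric(stim_times)), channel = channel),
    class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %s: %d samples @ %.1f Hz, %d stimuli\n",
              x$channel, length(x$time), x$sampling_rate,
              length(x$stim_times)))
  invisible(x)
}

#' Cell-level quality-control filter
#'
#' Inclusion gate applied to each recorded cell: baseline sarcomere length
#' must exceed 1.7 um and peak sarcomere length strain must exceed 10 %.
#' Cells failing either gate are excluded and the failing criterion is named.
#'
#' @param baseline_sarcomere_length Baseline (diastolic) sarcomere length, um.
#' @param peak_sarcomere_strain Peak sarcomere strain (signed or magnitude).
#' @param min_baseline,min_strain The gates (defaults 1.7 um and 0.10).
#' @return List with `include` (logical) and `reason` (`NA` if included,
#'   otherwise `"baseline"` or `"strain"`; both gates failing gives
#'   `"baseline+strain"`).
#' @export
qc_filter <- function(baseline_sarcomere_length, peak_sarcomere_strain,
                      min_baseline = 1.7, min_strain = 0.10) {
  if (!is.finite(baseline_sarcomere_length) || !is.finite(peak_sarcomere_strain))
    stop("qc_filter: inputs must be finite")
  fail <- character(0)
  if (!(baseline_sarcomere_length > min_baseline)) fail <- c(fail, "baseline")
  if (!(abs(peak_sarcomere_strain) > min_strain)) fail <- c(fail, "strain")
  list(include = length(fail) == 0L,
       reason = if (length(fail)) paste(fail, collapse = "+") else NA_character_)
}

#' Beat-average a trace
#'
#' Cuts the recording into equal-length beats anchored at the stimulation
#' timestamps and returns their pointwise mean as a single averaged beat.
#' The beat window is the median inter-stimulus interval; time in the
#' returned trace restarts at 0 (stimulus onset).
#'
#' @param trace A [raw_trace()].
#' @param n_beats Number of beats to average (uses the first `n_beats`
#'   stimuli that leave a full window inside the recording).
#' @param spacing_tol Relative tolerance on inter-stimulus spacing.
#' @return A `raw_trace` holding one averaged beat, with a single stimulus
#'   at time 0.
#' @export
beat_average <- function(trace, n_beats = 5L, spacing_tol = 0.05) {
  stopifnot(inherits(trace, "raw_trace"))
  st <- trace$stim_times
  if (length(st) < n_beats)
    stop(sprintf("beat_average: %d beats requested but only %d stimuli present",
                 n_beats, length(st)))
  isi <- diff(st)
  period <- if (length(isi)) stats::median(isi) else NA_real_
  if (is.na(period)) {
    # single stimulus: window runs to the end of the recording
    period <- trace$time[length(trace$time)] - st[1L]
  }
  if (length(isi) && any(abs(isi - period) > spacing_tol * period)) {
    bad <- which(abs(isi - period) > spacing_tol * period)[1L]
    stop(sprintf("beat_average: irregular stimulus spacing at beat %d", bad))
  }
  dt <- 1 / trace$sampling_rate
  n_win <- max(2L, floor(period / dt + 1e-9))
  segs <- vector("list", n_beats)
  used <- 0L
  for (k in seq_along(st)) {
    i0 <- which.min(abs(trace$time - st[k]))
    if (i0 + n_win - 1L > length(trace$value)) next
    used <- used + 1L
    segs[[used]] <- trace$value[i0:(i0 + n_win - 1L)]
    if (used == n_beats) break
  }
  if (used < n_beats)
    stop(sprintf("beat_average: only %d complete beats available at beat window %.3f s",
                 used, period))
  avg <- Reduce(`+`, segs[seq_len(used)]) / used
  raw_trace(time = (seq_len(n_win) - 1L) * dt, value = avg,
            sampling_rate = trace$sampling_rate, stim_times = 0,
            channel = trace$channel)
}

#' Resample a trace by linear interpolation
#'
#' Interpolates onto a uniform grid at `target_rate` spanning the original
#' interval (endpoints preserved). Used to place the sarcomere trace on the
#' 91 Hz grid of the nuclear imaging.
#'
#' @param trace A [raw_trace()].
#' @param target_rate Target sampling rate, Hz (default 91).
#' @return A resampled `raw_trace`.
#' @export
resample_to <- function(trace, target_rate = 91) {
  stopifnot(inherits(trace, "raw_trace"))
  if (target_rate <= 0) stop("target_rate must be positive")
  if (length(trace$time) < 2L) stop("resample_to: need at least 2 samples")
  t0 <- trace$time[1L]; t1 <- trace$time[length(trace$time)]
  n <- floor((t1 - t0) * target_rate) + 1L
  tt <- t0 + (seq_len(n) - 1L) / target_rate
  tt[n] <- min(tt[n], t1)
  vv <- stats::approx(trace$time, trace$value, xout = tt)$y
  raw_trace(time = tt, value = vv, sampling_rate = target_rate,
            stim_times = trace$stim_times, channel = trace$channel)
}

#' Strain from a length trace
#'
#' eps(t) = (L(t) - L0) / L0 with L0 the mean length over a baseline window
#' that ends at the first stimulus. Compression is negative; "peak
#' compression" reported elsewhere is `|min eps|`.
#'
#' @param trace A [raw_trace()].
#' @param baseline_window Window length in seconds ending at the first
#'   stimulus (default 0.2 s) used to estimate the baseline length.
#' @param L0 Optional externally supplied baseline length (um); when given,
#'   `baseline_window` is ignored. Used when strains for an averaged beat are
#'   normalized by the pre-stimulation baseline of the parent recording.
#' @return List with `time`, `strain`, `L0`, `peak_compression`.
#' @export
compute_strain <- function(trace, baseline_window = 0.2, L0 = NULL) {
  stopifnot(inherits(trace, "raw_trace"))
  if (is.null(L0)) {
    if (!length(trace$stim_times))
      stop("compute_strain: no stimulus to anchor the baseline window")
    s0 <- trace$stim_times[1L]
    sel <- trace$time >= (s0 - baseline_window) & trace$time < s0
    if (!any(sel))
      stop("compute_strain: baseline window empty or overlapping stimulation")
    L0 <- mean(trace$value[sel])
  }
  if (!is.finite(L0) || L0 <= 0) stop("compute_strain: invalid baseline")
  eps <- (trace$value - L0) / L0
  list(time = trace$time, strain = eps, L0 = L0,
       peak_compression = abs(min(eps)))
}

#' Paired strain series on a common grid
#'
#' Aligns sarcomere and nuclear strain series (already beat-averaged and
#' resampled to the same rate) on a shared time grid, truncating to the
#' common length.
#'
#' @param t Time grid (seconds).
#' @param eps_s Sarcomere strain.
#' @param eps_nL Nuclear length strain.
#' @param eps_nW Optional nuclear width strain.
#' @param baselines Named numeric vector of baseline lengths (um).
#' @return Object of class `paired_strain_series`.
#' @export
paired_strain_series <- function(t, eps_s, eps_nL, eps_nW = NULL,
                                 baselines = c(L0_s = NA, L0_nL = NA, L0_nW = NA)) {
  n <- min(length(t), length(eps_s), length(eps_nL),
           if (is.null(eps_nW)) Inf else length(eps_nW))
  structure(list(t = t[seq_len(n)], eps_s = eps_s[seq_len(n)],
                 eps_nL = eps_nL[seq_len(n)],
                 eps_nW = if (is.null(eps_nW)) NULL else eps_nW[seq_len(n)],
                 baselines = baselines),
            class = "paired_strain_series")
}

#' Sarcomere-nuclear coupling curve
#'
#' Orders the (sarcomere strain, nuclear strain) pairs in time and splits
#' them into a systolic branch (up to and including the sample of maximum
#' sarcomere compression, the earliest such sample on ties) and a diastolic
#' branch (after it).
#'
#' @param series A [paired_strain_series()].
#' @param nuclear_axis `"length"` (default) or `"width"`.
#' @return Object of class `coupling_curve` with `eps_s`, `eps_n`, `phase`
#'   and `peak_index`.
#' @export
build_coupling_curve <- function(series, nuclear_axis = c("length", "width")) {
  stopifnot(inherits(series, "paired_strain_series"))
  nuclear_axis <- match.arg(nuclear_axis)
  eps_n <- if (nuclear_axis == "length") series$eps_nL else series$eps_nW
  if (is.null(eps_n)) stop("requested nuclear axis not present")
  x <- series$eps_s
  if (length(x) < 3L || diff(range(x)) < .Machine$double.eps^0.5)
    stop("build_coupling_curve: flat trace, no extremum found")
  peak <- which.max(abs(x))[1L]
  phase <- rep("diastolic", length(x))
  phase[seq_len(peak)] <- "systolic"
  structure(list(eps_s = x, eps_n = eps_n, phase = phase, peak_index = peak),
            class = "coupling_curve")
}

# Path integral of (f(x) - y) dx along the branch in time order, trapezoidal.
# x, y are compression magnitudes; f is the reference line.
.branch_area <- function(x, y, ref) {
  if (length(x) < 2L) return(0)
  gap <- ref(x) - y
  sum((gap[-1L] + gap[-length(gap)]) / 2 * diff(x))
}

#' Systolic dampening area
#'
#' Area in the compression-magnitude strain plane between the lossless 1:1
#' line and the observed nuclear compression over the systolic branch,
#' integrated against sarcomere compression (trapezoidal). Zero for identity
#' coupling; positive when the nuclear strain is dampened.
#'
#' @param curve A [build_coupling_curve()] result.
#' @param monotone_tol Relative tolerance on backtracking of |eps_s| within
#'   the branch before a warning is issued.
#' @return `D_sys` in strain^2.
#' @export
systolic_dampening <- function(curve, monotone_tol = 0.05) {
  stopifnot(inherits(curve, "coupling_curve"))
  sel <- curve$phase == "systolic"
  x <- abs(curve$eps_s[sel]); y <- abs(curve$eps_n[sel])
  if (length(x) < 2L) stop("systolic_dampening: no systolic branch")
  bt <- -min(0, min(diff(x)))
  if (bt > monotone_tol * max(x))
    warning("systolic branch not monotone in |eps_s|; integrating in time order")
  # path integral of (x - y) dx from rest to peak systole
  .branch_area(x, y, ref = function(z) z)
}

#' Diastolic dampening area
#'
#' Area between the observed nuclear re-lengthening path and a unit-slope
#' reference line anchored at the end-systolic point, integrated against
#' sarcomere compression along the diastolic branch (trapezoidal, in time
#' order so that a nucleus loitering above the line accrues positive area).
#' Zero when relaxation retraces the reference line exactly.
#'
#' @inheritParams systolic_dampening
#' @return `D_dia` in strain^2.
#' @export
diastolic_dampening <- function(curve, monotone_tol = 0.05) {
  stopifnot(inherits(curve, "coupling_curve"))
  peak <- curve$peak_index
  if (peak >= length(curve$eps_s)) stop("diastolic_dampening: no diastolic branch")
  idx <- peak:length(curve$eps_s)
  x <- abs(curve$eps_s[idx]); y <- abs(curve$eps_n[idx])
  bt <- max(0, max(diff(x)))
  if (bt > monotone_tol * max(x))
    warning("diastolic branch not monotone in |eps_s|; integrating in time order")
  x_es <- x[1L]; y_es <- y[1L]
  ref <- function(z) z - (x_es - y_es)
  # time order runs x from x_es down to ~0, so (ref - y) dx accrues positive
  # area when y sits above the reference line
  .branch_area(x, y, ref)
}

#' Integrated nuclear strain over a cycle
#'
#' Time integral of the absolute nuclear length strain over the contractile
#' cycle (trapezoidal), in strain-seconds.
#'
#' @param series A [paired_strain_series()].
#' @return `S_int` (strain * s), non-negative.
#' @export
integrated_nuclear_strain <- function(series) {
  stopifnot(inherits(series, "paired_strain_series"))
  y <- abs(series$eps_nL); t <- series$t
  sum((y[-1L] + y[-length(y)]) / 2 * diff(t))
}

#' Full per-cell strain-coupling analysis
#'
#' Convenience pipeline: QC, beat-averaging, resampling to the nuclear
#' imaging rate, strain normalization by the pre-stimulation baseline, and
#' the coupling metrics.
#'
#' @param sarc,nucL [raw_trace()] recordings of sarcomere length and nuclear
#'   length; `nucW` optional nuclear width.
#' @param n_beats Beats to average (default 5).
#' @param rate Common grid rate, Hz (default 91).
#' @param baseline_window Baseline window before the first stimulus, s.
#' @return List with the paired series, coupling curve and a one-row
#'   data.frame of metrics (`D_sys`, `D_dia`, `S_int`, peak compressions,
#'   `included`, `qc_reason`).
#' @export
analyze_cell <- function(sarc, nucL, nucW = NULL, n_beats = 5L, rate = 91,
                         baseline_window = 0.2) {
  base <- function(tr) {
    s0 <- tr$stim_times[1L]
    mean(tr$value[tr$time >= s0 - baseline_window & tr$time < s0])
  }
  L0_s <- base(sarc); L0_nL <- base(nucL)
  L0_nW <- if (!is.null(nucW)) base(nucW) else NA_real_

  avg_s <- resample_to(beat_average(sarc, n_beats), rate)
  avg_nL <- resample_to(beat_average(nucL, n_beats), rate)
  eps_s <- compute_strain(avg_s, L0 = L0_s)
  eps_nL <- compute_strain(avg_nL, L0 = L0_nL)
  eps_nW <- if (!is.null(nucW))
    compute_strain(resample_to(beat_average(nucW, n_beats), rate), L0 = L0_nW)
  qc <- qc_filter(L0_s, eps_s$peak_compression)

  series <- paired_strain_series(
    eps_s$time, eps_s$strain, eps_nL$strain,
    eps_nW = if (is.null(eps_nW)) NULL else eps_nW$strain,
    baselines = c(L0_s = L0_s, L0_nL = L0_nL, L0_nW = L0_nW))
  curve <- build_coupling_curve(series)
  metrics <- data.frame(
    D_sys = systolic_dampening(curve),
    D_dia = diastolic_dampening(curve),
    S_int = integrated_nuclear_strain(series),
    peak_eps_s = eps_s$peak_compression,
    peak_eps_nL = eps_nL$peak_compression,
    peak_eps_nW = if (is.null(eps_nW)) NA_real_ else eps_nW$peak_compression,
    included = qc$include, qc_reason = qc$reason,
    stringsAsFactors = FALSE)
  list(series = series, curve = curve, metrics = metrics)
}
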