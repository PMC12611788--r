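# Strain-coupling assay: QC gates, beat averaging, resampling, strain
# normalization, dampening areas and integrated strain.

test_that("QC gates follow the inclusion criteria and name the failure", {
  cases <- list(
    list(L0 = 1.65, eps = 0.12, include = FALSE, reason = "baseline"),
    list(L0 = 1.80, eps = 0.12, include = TRUE, reason = NA_character_),
    list(L0 = 1.80, eps = 0.08, include = FALSE, reason = "strain"),
    list(L0 = 1.60, eps = 0.05, include = FALSE, reason = "baseline+strain"))
  for (cs in cases) {
    got <- qc_filter(cs$L0, cs$eps)
    expect_identical(got$include, cs$include)
    expect_identical(got$reason, cs$reason)
  }
  expect_error(qc_filter(NaN, 0.12), "finite")
})

test_that("beat averaging returns one cycle and reduces noise ~ sqrt(n)", {
  dt <- 1 / 250
  tt <- seq(0, 5.999, by = dt)
  stims <- 0.5 + 0:4
  beat <- function(tb) 1.85 * (1 - 0.1 * sin(pi * pmin(tb, 1))^2)
  clean <- rep(1.85, length(tt))
  for (s in stims) {
    sel <- tt >= s & tt < s + 1
    clean[sel] <- beat(tt[sel] - s)
  }
  tr <- raw_trace(tt, clean, stim_times = stims, channel = "sarcomere_length")
  avg <- beat_average(tr, 5)
  expect_equal(length(avg$time), 250)
  expect_equal(avg$value, beat(avg$time), tolerance = 1e-12)

  # Monte-Carlo: residual s.d. of the 5-beat average vs a single beat
  set.seed(42)
  ratios <- replicate(20, {
    noisy <- raw_trace(tt, clean + rnorm(length(tt), 0, 0.01),
                       stim_times = stims, channel = "sarcomere_length")
    avg_n <- beat_average(noisy, 5)
    sd(avg_n$value - beat(avg_n$time)) / 0.01
  })
  expect_equal(mean(ratios), 1 / sqrt(5), tolerance = 0.1)

  expect_error(beat_average(raw_trace(tt, clean, stim_times = stims[1:2],
                                      channel = "sarcomere_length"), 3),
               "3 beats requested")
  irr <- raw_trace(tt, clean, stim_times = c(0.5, 1.5, 2.2, 3.5, 4.5),
                   channel = "sarcomere_length")
  expect_error(beat_average(irr, 5), "irregular")
})

test_that("resampling is linear interpolation with endpoints preserved", {
  t0 <- seq(0, 1, by = 1 / 91)
  tr <- raw_trace(t0, 1 + t0, channel = "nuclear_length")
  expect_equal(resample_to(tr, 91)$value, tr$value, tolerance = 1e-12)

  tr2 <- raw_trace(seq(0, 1, by = 1 / 250), 1 + 2 * seq(0, 1, by = 1 / 250),
                   channel = "sarcomere_length")
  rs <- resample_to(tr2, 91)
  expect_equal(rs$value, 1 + 2 * rs$time, tolerance = 1e-12)

  ts <- seq(0, 2, by = 1e-3)
  sine <- raw_trace(ts, 2 + 0.5 * sin(2 * pi * ts), channel = "nuclear_length")
  rs2 <- resample_to(sine, 91)
  expect_lt(max(abs(rs2$value - (2 + 0.5 * sin(2 * pi * rs2$time)))) / 2.5,
            1e-3)
  expect_error(resample_to(sine, -1), "positive")
})

test_that("strain is normalized by the pre-stimulation baseline", {
  tt <- seq(0, 2, by = 0.01)
  tr <- raw_trace(tt, rep(1.8, length(tt)), stim_times = 1,
                  channel = "sarcomere_length")
  cs <- compute_strain(tr, baseline_window = 0.2)
  expect_equal(cs$strain, rep(0, length(tt)))
  expect_equal(cs$L0, 1.8)

  v <- rep(1.80, length(tt)); v[tt > 1.2 & tt < 1.3] <- 1.60
  tr2 <- raw_trace(tt, v, stim_times = 1, channel = "sarcomere_length")
  cs2 <- compute_strain(tr2)
  expect_equal(min(cs2$strain), -0.2 / 1.8, tolerance = 1e-12)
  expect_equal(cs2$peak_compression, 0.1111, tolerance = 1e-3)

  expect_error(compute_strain(raw_trace(tt, v, stim_times = 0,
                                        channel = "sarcomere_length")),
               "baseline")
  # strain is invariant to um <-> nm rescaling of the lengths
  tr_nm <- raw_trace(tt, v * 1000, stim_times = 1,
                     channel = "sarcomere_length")
  expect_equal(compute_strain(tr_nm)$strain, cs2$strain, tolerance = 1e-12)
})

test_that("coupling curve splits phases at peak sarcomere compression", {
  s <- fix_hinge_series(gain = 1)
  cc <- build_coupling_curve(s)
  expect_equal(cc$eps_n, cc$eps_s)            # identity coupling on 1:1 line
  expect_equal(cc$peak_index, which.max(abs(s$eps_s)))
  expect_identical(unique(cc$phase[seq_len(cc$peak_index)]), "systolic")
  expect_identical(unique(cc$phase[-seq_len(cc$peak_index)]), "diastolic")
  flat <- paired_strain_series(1:10 / 10, rep(0, 10), rep(0, 10))
  expect_error(build_coupling_curve(flat), "flat")
})

test_that("dampening areas match closed-form oracles", {
  # identity coupling: both areas vanish
  cc1 <- build_coupling_curve(fix_hinge_series(gain = 1))
  expect_equal(systolic_dampening(cc1), 0, tolerance = 1e-12)
  expect_equal(diastolic_dampening(cc1), 0, tolerance = 1e-12)

  # rigid nucleus: triangle area 1/2 * 0.1 * 0.1
  cc0 <- build_coupling_curve(fix_hinge_series(gain = 0))
  expect_equal(systolic_dampening(cc0), 0.0050, tolerance = 1e-9)

  # proportional dampening 0.5: half the triangle
  cch <- build_coupling_curve(fix_hinge_series(gain = 0.5))
  expect_equal(systolic_dampening(cch), 0.0025, tolerance = 1e-9)

  # nucleus frozen at end-systole while the sarcomere relaxes fully:
  # area between the unit-slope line and the horizontal path
  n <- 200
  x_sys <- seq(0, 0.10, length.out = n)
  x_dia <- seq(0.10, 0, length.out = n)
  eps_s <- -c(x_sys, x_dia[-1])
  eps_n <- -c(0.66 * x_sys, rep(0.066, n - 1))
  s2 <- paired_strain_series(seq_along(eps_s) / 91, eps_s, eps_n)
  expect_equal(diastolic_dampening(build_coupling_curve(s2)), 0.0050,
               tolerance = 1e-9)
})

test_that("dampening grows monotonically as coupling gain drops", {
  gains <- c(1, 0.8, 0.6, 0.4, 0.2, 0)
  d <- vapply(gains, function(g)
    systolic_dampening(build_coupling_curve(fix_hinge_series(g))), numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("integrated nuclear strain: triangle oracle, additivity, scaling", {
  n <- 401
  tt <- seq(0, 1, length.out = n)
  tri <- numeric(n)
  up <- tt <= 0.2; down <- tt > 0.2 & tt <= 0.4
  tri[up] <- tt[up] / 0.2; tri[down] <- (0.4 - tt[down]) / 0.2
  s <- paired_strain_series(tt, -tri * 0.1, -tri * 0.066)
  expect_equal(integrated_nuclear_strain(s), 0.5 * 0.4 * 0.066,
               tolerance = 1e-6)

  z <- paired_strain_series(tt, -tri * 0.1, rep(0, n))
  expect_equal(integrated_nuclear_strain(z), 0)

  # linear in a global scaling of the nuclear strain
  s2 <- paired_strain_series(tt, s$eps_s, 3 * s$eps_nL)
  expect_equal(integrated_nuclear_strain(s2),
               3 * integrated_nuclear_strain(s), tolerance = 1e-12)

  # additive over concatenated cycles
  s_cat <- paired_strain_series(c(tt, 1 + tt[-1]),
                                c(s$eps_s, s$eps_s[-1]),
                                c(s$eps_nL, s$eps_nL[-1]))
  expect_equal(integrated_nuclear_strain(s_cat),
               2 * integrated_nuclear_strain(s), tolerance = 1e-6)
})

test_that("pipeline recovers generator peaks on noise-free traces", {
  g <- gen_traces(trace_preset("WT", seed = 5, n_cells = 3, noise_sd = 0,
                               peak_sarc_sd = 0, gain_sd = 0))
  m <- analyze_cohort(g)
  expect_lt(max(abs(m$peak_eps_s - 0.114) / 0.114), 0.005)
  expect_lt(max(abs(m$peak_eps_nL - 0.066) / 0.066), 0.005)
  expect_true(all(m$included))
})
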