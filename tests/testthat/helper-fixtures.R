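# Shared fixtures, built in code. FE solutions are cached per session
# because a solve takes a few seconds and several tests inspect the same
# physiological state.

.fix_env <- new.env(parent = emptyenv())

fix_wt_solution <- function() {
  if (is.null(.fix_env$wt)) {
    m <- build_model()
    .fix_env$wt_model <- m
    .fix_env$wt <- solve_prestress(m)
  }
  list(model = .fix_env$wt_model, sol = .fix_env$wt)
}

fix_condition_table <- function() {
  if (is.null(.fix_env$cond)) .fix_env$cond <- compare_conditions()
  .fix_env$cond
}

# one clean single-beat strain pair: raised-cosine sarcomere transient with
# a known analytic form, used for oracle checks of the dampening areas
fix_hinge_series <- function(gain = 1, n = 401, peak = 0.10) {
  t <- seq(0, 1, length.out = n)
  w <- ifelse(t < 0.2, 0.5 * (1 - cos(pi * t / 0.2)),
              exp(-(t - 0.2) / 0.15))
  paired_strain_series(t, -peak * w, -gain * peak * w)
}

# small noise-free nucleus stack reused by several image tests
fix_nucleus_stack <- function() {
  if (is.null(.fix_env$nuc_stack)) {
    p <- image_gen_params(field_size = c(24, 18, 8),
                          voxel_size = c(0.1, 0.1, 0.5),
                          nuclei = list(list(center = c(12, 9, 4),
                                             semi = c(6, 3, 3),
                                             intensity = 500)),
                          shell = list(thickness = 0.55, enrichment = 1.9,
                                       pole_boost = 1, cyt_intensity = 100),
                          background = 0, seed = 11)
    .fix_env$nuc_stack <- gen_image_stack(p)
  }
  .fix_env$nuc_stack
}
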