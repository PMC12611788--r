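# Shape, stress-location and sweep post-processing for the axisymmetric
# pre-stress solutions.

#' Deformed nuclear shape metrics
#'
#' Length and width are twice the maximal deformed z- and r-extent of the
#' nucleus (nucleoplasm plus envelope); the aspect ratio is reported >= 1.
#' Volume is computed two ways: a revolution integral over the deformed
#' outer envelope boundary (primary) and a sum over deformed elements
#' (`volume_mesh`, used as an independent quadrature check).
#'
#' @param sol A [solve_prestress()] solution.
#' @return List with `length`, `width`, `aspect_ratio`, `volume`,
#'   `volume_mesh` (um / um^3).
#' @export
nuclear_shape <- function(sol) {
  m <- sol$model
  path <- m$ne_outer
  rd <- m$nodes[path, 1L] + sol$u[path, 1L]
  zd <- m$nodes[path, 2L] + sol$u[path, 2L]
  if (any(!is.finite(rd)) || any(rd < -1e-6))
    stop("non-simple deformed boundary")
  len <- 2 * max(zd); wid <- 2 * max(rd)
  # revolution of the quarter region: V = 2 * 2*pi * closed-integral of
  # (r^2/2) dz; the axis (r = 0) and midplane (dz = 0) legs contribute 0,
  # so only the envelope arc matters, traversed equator -> pole
  rr <- rev(rd); zz <- rev(zd)
  V_arc <- 4 * pi * sum((rr[-1L]^2 + rr[-length(rr)]^2) / 4 * diff(zz))

  # independent quadrature: element sum on the deformed mesh
  quad <- .tri_quad()
  nuc_el <- which(m$sub %in% c(1L, 2L))
  def_nodes <- m$nodes + sol$u
  V_mesh <- 0
  for (e in nuc_el) {
    conn <- m$t6[e, ]
    qps <- tryCatch(.elem_qp(def_nodes, conn, quad),
                    error = function(e) NULL)
    if (is.null(qps)) stop("non-simple deformed boundary (inverted element)")
    V_mesh <- V_mesh + sum(vapply(qps, `[[`, numeric(1), "w"))
  }
  V_mesh <- 2 * V_mesh
  ar <- len / wid
  list(length = len, width = wid,
       aspect_ratio = max(ar, 1 / ar),
       volume = V_arc, volume_mesh = V_mesh)
}

#' Location of the maximum principal envelope stress
#'
#' Finds the maximum principal (most tensile) stress over the nuclear
#' envelope and classifies its location as `"mid"` or `"tip"`. The tip
#' region is the envelope arc beyond `tip_frac` of the deformed nuclear
#' half-length (deformed element centroids); ties go to the larger stress.
#'
#' @param sol A solution.
#' @param tip_frac Axial fraction defining the tip region (default 0.7).
#' @return List with `location` (`"mid"`, `"tip"` or `"undefined"` for an
#'   all-zero field), `value` (kPa), `z_frac` (axial position of the
#'   maximum, as a fraction of the deformed half-length), and the per-element
#'   envelope table.
#' @export
principal_stress_location <- function(sol, tip_frac = 0.7) {
  m <- sol$model
  nee <- which(m$sub == 2L)
  p1 <- sol$principal[nee, "p1"]
  if (all(abs(p1) < 1e-12) && all(abs(sol$u) < 1e-12))
    return(list(location = "undefined", value = 0, z_frac = NA_real_,
                table = NULL))
  half_len <- max(m$nodes[m$ne_outer, 2L] + sol$u[m$ne_outer, 2L])
  zf <- sol$centroid_def[nee, 2L] / half_len
  i <- which.max(p1)
  tab <- data.frame(z_frac = zf, p1 = p1,
                    r = sol$centroid_def[nee, 1L],
                    z = sol$centroid_def[nee, 2L])
  list(location = if (zf[i] > tip_frac) "tip" else "mid",
       value = p1[i], z_frac = zf[i], table = tab)
}

#' Relative nuclear volume change between two solutions
#'
#' @param sol_a,sol_b Solutions (a is the reference).
#' @return Percent change `100 |V_b - V_a| / V_a`.
#' @export
volume_change <- function(sol_a, sol_b) {
  Va <- nuclear_shape(sol_a)$volume
  Vb <- nuclear_shape(sol_b)$volume
  100 * abs(Vb - Va) / Va
}

#' Solve the model for a named condition
#'
#' @param condition A [condition_spec()] or condition name.
#' @param geometry,cyto,cage Base parameter sets.
#' @param mesh_density Mesh density factor.
#' @return A solution with the condition recorded.
#' @export
solve_condition <- function(condition = "WT", geometry = fe_geometry(),
                            cyto = cytoplasm_params(), cage = cage_params(),
                            mesh_density = 1) {
  if (is.character(condition)) condition <- condition_spec(condition)
  stopifnot(inherits(condition, "condition_spec"))
  model <- build_model(geometry, cyto, nucleus_params(E_ne = condition$E_ne),
                       cage, mesh_density = mesh_density)
  sol <- solve_prestress(model,
                         cage_stress_scale = condition$cage_stress_scale,
                         cage_stiffness_scale = condition$cage_stiffness_scale)
  sol$condition <- condition$name
  sol
}

#' Compare nuclear shape across conditions
#'
#' Solves each condition on the same mesh density and tabulates the
#' deformed nuclear shape.
#'
#' @param conditions Character vector or list of [condition_spec()]s.
#' @param ... Passed to [solve_condition()].
#' @return data.frame with one row per condition (aspect ratio, length,
#'   width, volume, stress location class).
#' @export
compare_conditions <- function(conditions = c("WT", "LMNA", "LINC",
                                              "LMNA_LINC"), ...) {
  rows <- lapply(conditions, function(cn) {
    sol <- solve_condition(cn, ...)
    sh <- nuclear_shape(sol)
    loc <- principal_stress_location(sol)
    data.frame(condition = if (is.character(cn)) cn else cn$name,
               aspect_ratio = sh$aspect_ratio, length = sh$length,
               width = sh$width, volume = sh$volume,
               stress_location = loc$location,
               max_principal = loc$value)
  })
  do.call(rbind, rows)
}

#' Critical cage stress for the tip instability
#'
#' Scans a monotone grid of cage compressive stresses, classifying each
#' converged solution by the location of the maximum principal envelope
#' stress, and refines the mid-to-tip switch by bisection. A failure to
#' converge at full load is itself recorded as a detection signal.
#'
#' @param model A [build_model()] (envelope stiffness of interest baked in).
#' @param cage_stress_grid Monotone increasing sigma_MT grid, kPa.
#' @param tol Bisection tolerance on sigma_MT, kPa.
#' @return List with `critical` (kPa, or NA), `detected` (logical), `mode`
#'   (`"stress_shift"`, `"non_convergence"` or `"none in range"`), and the
#'   per-grid-point classification table.
#' @export
detect_instability <- function(model, cage_stress_grid = seq(0.5, 10, by = 0.5),
                               tol = 0.01) {
  stopifnot(all(diff(cage_stress_grid) > 0))
  asm <- .assemble(model, cage_scale = 1)
  free <- setdiff(seq_len(asm$ndof), asm$fixed)
  asm$Kff <- asm$K[free, free, drop = FALSE]
  asm$Kff_lu <- Matrix::lu(asm$Kff)     # one factorization for all grid points
  classify <- function(sig) {
    sol <- tryCatch(
      .solve_with_asm(model, asm, rho_target = model$cyto$rhobar0,
                      sig_target = sig),
      error = function(e) NULL)
    if (is.null(sol)) return("non_convergence")
    principal_stress_location(sol)$location
  }
  cls <- vapply(cage_stress_grid, classify, character(1))
  tab <- data.frame(sigma_MT = cage_stress_grid, location = cls)
  bad <- which(cls %in% c("tip", "non_convergence"))
  if (!length(bad))
    return(list(critical = NA_real_, detected = FALSE,
                mode = "none in range", table = tab))
  i <- bad[1L]
  mode <- if (cls[i] == "tip") "stress_shift" else "non_convergence"
  lo <- if (i > 1L) cage_stress_grid[i - 1L] else 0
  hi <- cage_stress_grid[i]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (classify(mid) %in% c("tip", "non_convergence")) hi <- mid else lo <- mid
  }
  list(critical = (lo + hi) / 2, detected = TRUE, mode = mode, table = tab)
}

#' Aspect ratio as a function of microtubule-cage enrichment
#'
#' Maps each enrichment value to a cage scale (see
#' [enrichment_to_cage_scale()]), solves the model, and tabulates the
#' deformed aspect ratio and stress-location class. The output feeds the
#' piecewise (biphasic) regression.
#'
#' @param enrichment_grid Enrichment ratios to sweep.
#' @param geometry,cyto,cage,mesh_density Model setup.
#' @param E_ne Envelope modulus for the sweep (15 = WT, 10 = lamin mutant).
#' @param e_phys Enrichment mapped to cage_scale 1.
#' @return data.frame (enrichment, cage_scale, aspect_ratio, location,
#'   converged).
#' @export
sweep_enrichment <- function(enrichment_grid = seq(0, 3, by = 0.25),
                             geometry = fe_geometry(),
                             cyto = cytoplasm_params(), cage = cage_params(),
                             E_ne = 15, e_phys = 2.0, mesh_density = 1) {
  model <- build_model(geometry, cyto, nucleus_params(E_ne = E_ne), cage,
                       mesh_density = mesh_density)
  rows <- lapply(enrichment_grid, function(e) {
    cs <- enrichment_to_cage_scale(e, e_phys)
    sol <- tryCatch(solve_prestress(model, cage_scale = cs),
                    error = function(err) NULL)
    if (is.null(sol))
      return(data.frame(enrichment = e, cage_scale = cs,
                        aspect_ratio = NA_real_, location = NA_character_,
                        converged = FALSE))
    sh <- nuclear_shape(sol)
    data.frame(enrichment = e, cage_scale = cs,
               aspect_ratio = sh$aspect_ratio,
               location = principal_stress_location(sol)$location,
               converged = TRUE)
  })
  do.call(rbind, rows)
}
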