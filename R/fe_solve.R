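# Quadratic-triangle axisymmetric assembly. Voigt strain order is
# (e_rr, e_zz, e_tt, gamma_rz); the hoop strain e_tt = u_r / r gives the
# axisymmetric coupling, and all integrals carry the 2*pi*r measure.

# 6-point (degree-4) quadrature on the reference triangle
.tri_quad <- function() {
  a <- 0.445948490915965; b <- 0.091576213509771
  wa <- 0.223381589678011; wb <- 0.109951743655322
  list(xi = c(a, 1 - 2 * a, a, b, 1 - 2 * b, b),
       eta = c(a, a, 1 - 2 * a, b, b, 1 - 2 * b),
       w = c(wa, wa, wa, wb, wb, wb) / 2)
}

# T6 shape functions and reference-space gradients at (xi, eta)
.t6_shape <- function(xi, eta) {
  L1 <- 1 - xi - eta; L2 <- xi; L3 <- eta
  N <- c(L1 * (2 * L1 - 1), L2 * (2 * L2 - 1), L3 * (2 * L3 - 1),
         4 * L1 * L2, 4 * L2 * L3, 4 * L3 * L1)
  dxi <- c(-(4 * L1 - 1), 4 * L2 - 1, 0,
           4 * (L1 - L2), 4 * L3, -4 * L3)
  deta <- c(-(4 * L1 - 1), 0, 4 * L3 - 1,
            -4 * L2, 4 * L2, 4 * (L1 - L3))
  list(N = N, dxi = dxi, deta = deta)
}

# isotropic D matrix in Voigt (rr, zz, tt, rz) with engineering shear
.dmat <- function(K, mu) {
  m <- c(1, 1, 1, 0)
  K * (m %o% m) + 2 * mu * (diag(c(1, 1, 1, 0.5)) - (m %o% m) / 3)
}

# per-element quadrature data: B (4 x 12), N, r and weight at each qp
.elem_qp <- function(nodes, conn, quad) {
  xe <- nodes[conn, 1L]; ze <- nodes[conn, 2L]
  out <- vector("list", length(quad$w))
  for (q in seq_along(quad$w)) {
    sh <- .t6_shape(quad$xi[q], quad$eta[q])
    J11 <- sum(sh$dxi * xe); J12 <- sum(sh$dxi * ze)
    J21 <- sum(sh$deta * xe); J22 <- sum(sh$deta * ze)
    detJ <- J11 * J22 - J12 * J21
    if (detJ <= 0) stop("mesh generation failure: non-positive Jacobian")
    dNr <- ( J22 * sh$dxi - J12 * sh$deta) / detJ
    dNz <- (-J21 * sh$dxi + J11 * sh$deta) / detJ
    r <- sum(sh$N * xe)
    B <- matrix(0, 4L, 12L)
    ir <- seq(1L, 12L, by = 2L); iz <- ir + 1L
    B[1L, ir] <- dNr
    B[2L, iz] <- dNz
    B[3L, ir] <- sh$N / r
    B[4L, ir] <- dNz; B[4L, iz] <- dNr
    out[[q]] <- list(B = B, N = sh$N, r = r, w = quad$w[q] * detJ * 2 * pi * r)
  }
  out
}

# assemble stiffness, the two unit-load eigenstress vectors and the pressure
# blocks; returns everything needed for repeated solves under load scaling
.assemble <- function(model, cage_scale = 1) {
  nn <- model$n_nodes
  quad <- .tri_quad()
  ne_elems <- which(model$sub == 2L)
  pnode <- sort(unique(as.vector(model$t6[ne_elems, 1:3])))
  pdof <- integer(nn); pdof[pnode] <- seq_along(pnode)
  np <- length(pnode)
  ndof <- 2L * nn + np

  mu_ne <- model$nuc$mu_ne
  kappa <- 1000 * model$nuc$E_ne       # penalty regularization of p
  Dmats <- list(
    .dmat(model$nuc$E_chromatin / (3 * (1 - 2 * model$nuc$nu_chromatin)),
          model$nuc$E_chromatin / (2 * (1 + model$nuc$nu_chromatin))),
    .dmat(0, mu_ne),                   # NE: deviatoric only, p carries K
    .dmat(model$cage$K_MT * cage_scale, model$cage$mu_MT * cage_scale),
    .dmat(model$cyto$Kbar, model$cyto$mubar))

  est <- model$n_elem * 180L
  ti <- integer(est * 2L); tj <- integer(est * 2L); tv <- numeric(est * 2L)
  ptr <- 0L
  add <- function(ii, jj, vv) {
    n <- length(vv)
    if (ptr + n > length(tv)) {
      ti <<- c(ti, integer(n + est)); tj <<- c(tj, integer(n + est))
      tv <<- c(tv, numeric(n + est))
    }
    ti[ptr + seq_len(n)] <<- ii; tj[ptr + seq_len(n)] <<- jj
    tv[ptr + seq_len(n)] <<- vv
    ptr <<- ptr + n
  }

  f_rho <- numeric(ndof); f_sig <- numeric(ndof)
  m4 <- c(1, 1, 1, 0)
  qp_cache <- vector("list", model$n_elem)

  for (e in seq_len(model$n_elem)) {
    conn <- model$t6[e, ]
    qps <- .elem_qp(model$nodes, conn, quad)
    qp_cache[[e]] <- qps
    sd <- model$sub[e]
    D <- Dmats[[sd]]
    edof <- as.vector(rbind(2L * conn - 1L, 2L * conn))
    Ke <- matrix(0, 12L, 12L)
    fe_r <- numeric(12L); fe_s <- numeric(12L)
    is_ne <- sd == 2L
    if (is_ne) {
      pn <- conn[1:3]
      pd <- 2L * nn + pdof[pn]
      Bp <- matrix(0, 12L, 3L)
      Cp <- matrix(0, 3L, 3L)
    }
    for (q in seq_along(qps)) {
      qp <- qps[[q]]
      Ke <- Ke + crossprod(qp$B, D %*% qp$B) * qp$w
      if (sd == 4L)
        fe_r <- fe_r - crossprod(qp$B, m4) * qp$w   # rho_bar0 eigenstress (unit)
      if (sd == 3L)
        fe_s <- fe_s + crossprod(qp$B, m4) * qp$w   # -sigma_MT eigenstress (unit)
      if (is_ne) {
        # P1 pressure: corner area coordinates
        Np <- c(1 - quad$xi[q] - quad$eta[q], quad$xi[q], quad$eta[q])
        Bp <- Bp + (crossprod(qp$B, m4) %o% Np)[, 1, ] * qp$w
        Cp <- Cp - (Np %o% Np) / kappa * qp$w
      }
    }
    add(rep(edof, times = 12L), rep(edof, each = 12L), as.vector(Ke))
    f_rho[edof] <- f_rho[edof] + fe_r
    f_sig[edof] <- f_sig[edof] + fe_s
    if (is_ne) {
      add(rep(edof, times = 3L), rep(pd, each = 12L), as.vector(Bp))
      add(rep(pd, times = 12L), rep(edof, each = 3L), as.vector(t(Bp)))
      add(rep(pd, times = 3L), rep(pd, each = 3L), as.vector(Cp))
    }
  }
  K <- Matrix::sparseMatrix(i = ti[seq_len(ptr)], j = tj[seq_len(ptr)],
                            x = tv[seq_len(ptr)], dims = c(ndof, ndof))

  fixed <- sort(unique(c(2L * model$bc$axis - 1L,
                         2L * model$bc$sym, 2L * model$bc$end)))
  list(K = K, f_rho = f_rho, f_sig = f_sig, fixed = fixed,
       ndof = ndof, nn = nn, np = np, pnode = pnode, pdof = pdof,
       qp_cache = qp_cache, Dmats = Dmats, cage_scale = cage_scale,
       kappa = kappa)
}

#' Solve the cytoskeletal pre-stress problem
#'
#' Ramps the diastolic contractility (`rho0`) and the cage compressive
#' stress (`sigma_MT`) from zero to their targets and solves the
#' quasi-static equilibrium at each step. The constitutive laws are linear
#' in the kinematic variables with the active terms entering as isotropic
#' eigenstresses, so each ramp step converges in a single correction; the
#' relative residual is still checked against `tol` at every step.
#'
#' @param model A [build_model()].
#' @param ramp Data frame with columns `f_rho`, `f_sig` (monotone fractions
#'   ending at 1), or `NULL` for a proportional 5-step ramp.
#' @param cage_scale Scale factor applied to both cage stress and stiffness
#'   (used by enrichment sweeps); overridden by the two explicit scales.
#' @param cage_stress_scale,cage_stiffness_scale Separate scale factors on
#'   `sigma_MT` and on (`K_MT`, `mu_MT`) for condition perturbations.
#' @param tol Relative residual tolerance (default 1e-8).
#' @return Object of class `fe_solution`: nodal displacements `u` (n x 2),
#'   NE pressures, per-element centroid fields (stress, strain,
#'   contractility tensor, principal stresses), reaction bookkeeping, and
#'   the model.
#' @export
solve_prestress <- function(model, ramp = NULL, cage_scale = 1,
                            cage_stress_scale = NULL,
                            cage_stiffness_scale = NULL, tol = 1e-8) {
  stopifnot(inherits(model, "fe_model"))
  if (is.null(cage_stress_scale)) cage_stress_scale <- cage_scale
  if (is.null(cage_stiffness_scale)) cage_stiffness_scale <- cage_scale
  if (is.null(ramp)) {
    fr <- seq(0.2, 1, by = 0.2)
    ramp <- data.frame(f_rho = fr, f_sig = fr)
  }
  stopifnot(all(diff(ramp$f_rho) >= 0), all(diff(ramp$f_sig) >= 0))
  asm <- .assemble(model, cage_scale = cage_stiffness_scale)
  .solve_with_asm(model, asm,
                  rho_target = model$cyto$rhobar0,
                  sig_target = model$cage$sigma_MT * cage_stress_scale,
                  ramp = ramp, tol = tol)
}

# solve for given load targets on an existing assembly (the stiffness does
# not depend on the loads, so instability/sigma sweeps reuse it)
.solve_with_asm <- function(model, asm, rho_target, sig_target,
                            ramp = data.frame(f_rho = 1, f_sig = 1),
                            tol = 1e-8) {
  free <- setdiff(seq_len(asm$ndof), asm$fixed)
  if (is.null(asm$Kff_lu)) {
    asm$Kff <- asm$K[free, free, drop = FALSE]
    asm$Kff_lu <- Matrix::lu(asm$Kff)
  }
  sol_u <- numeric(asm$ndof)
  for (s in seq_len(nrow(ramp))) {
    f <- asm$f_rho * (rho_target * ramp$f_rho[s]) +
         asm$f_sig * (sig_target * ramp$f_sig[s])
    rhs <- f[free]
    u_free <- as.numeric(Matrix::solve(asm$Kff_lu, rhs))
    res <- sqrt(sum((as.numeric(asm$Kff %*% u_free) - rhs)^2))
    scale <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
    if (scale > .Machine$double.eps && res / scale > tol)
      stop(sprintf("solver failed to converge at ramp fraction %.2f",
                   ramp$f_rho[s]))
    sol_u[free] <- u_free
  }
  last <- nrow(ramp)
  .postprocess(model, asm, sol_u,
               rho_scale = rho_target * ramp$f_rho[last],
               sig_scale = sig_target * ramp$f_sig[last])
}

# element-centroid fields and reaction bookkeeping
.postprocess <- function(model, asm, sol_u, rho_scale, sig_scale) {
  nn <- asm$nn
  u <- cbind(sol_u[2L * seq_len(nn) - 1L], sol_u[2L * seq_len(nn)])
  p <- sol_u[2L * nn + seq_len(asm$np)]
  quad <- .tri_quad()
  ne_centroid_sh <- .t6_shape(1 / 3, 1 / 3)

  nel <- model$n_elem
  stress <- matrix(0, nel, 4L,
                   dimnames = list(NULL, c("s_rr", "s_zz", "s_tt", "s_rz")))
  strain <- matrix(0, nel, 4L,
                   dimnames = list(NULL, c("e_rr", "e_zz", "e_tt", "g_rz")))
  rho_t <- matrix(NA_real_, nel, 2L, dimnames = list(NULL, c("rho_rr", "rho_zz")))
  cen <- matrix(0, nel, 2L); cen_def <- matrix(0, nel, 2L)
  m4 <- c(1, 1, 1, 0)
  cy <- model$cyto
  for (e in seq_len(nel)) {
    conn <- model$t6[e, ]
    edof <- as.vector(rbind(2L * conn - 1L, 2L * conn))
    ue <- sol_u[edof]
    # centroid B: average of qp B's weighted is fine; evaluate at centroid
    xe <- model$nodes[conn, , drop = FALSE]
    sh <- ne_centroid_sh
    J11 <- sum(sh$dxi * xe[, 1]); J12 <- sum(sh$dxi * xe[, 2])
    J21 <- sum(sh$deta * xe[, 1]); J22 <- sum(sh$deta * xe[, 2])
    detJ <- J11 * J22 - J12 * J21
    dNr <- ( J22 * sh$dxi - J12 * sh$deta) / detJ
    dNz <- (-J21 * sh$dxi + J11 * sh$deta) / detJ
    r <- sum(sh$N * xe[, 1])
    B <- matrix(0, 4L, 12L)
    ir <- seq(1L, 12L, by = 2L); iz <- ir + 1L
    B[1L, ir] <- dNr; B[2L, iz] <- dNz
    B[3L, ir] <- sh$N / r
    B[4L, ir] <- dNz; B[4L, iz] <- dNr
    eps <- as.numeric(B %*% ue)
    sd <- model$sub[e]
    sg <- as.numeric(asm$Dmats[[sd]] %*% eps)
    if (sd == 4L) {
      sg <- sg + rho_scale * m4
      ekk <- sum(eps[1:3])
      dev_rr <- eps[1] - ekk / 3; dev_zz <- eps[2] - ekk / 3
      rho_t[e, ] <- c(rho_scale + 3 * cy$Kbar_rho * ekk / 3 + 2 * cy$mubar_rho * dev_rr,
                      rho_scale + 3 * cy$Kbar_rho * ekk / 3 + 2 * cy$mubar_rho * dev_zz)
    } else if (sd == 3L) {
      sg <- sg - sig_scale * m4
    } else if (sd == 2L) {
      pc <- mean(p[asm$pdof[conn[1:3]]])
      sg <- sg + pc * m4
    }
    stress[e, ] <- sg
    strain[e, ] <- eps
    cen[e, ] <- c(r, sum(sh$N * xe[, 2]))
    cen_def[e, ] <- cen[e, ] + c(sum(sh$N * u[conn, 1]), sum(sh$N * u[conn, 2]))
  }

  # principal stresses: in-plane eigenvalues plus the hoop component
  tr2 <- (stress[, "s_rr"] + stress[, "s_zz"]) / 2
  dd <- sqrt(((stress[, "s_rr"] - stress[, "s_zz"]) / 2)^2 + stress[, "s_rz"]^2)
  princ <- cbind(p1 = pmax(tr2 + dd, stress[, "s_tt"]),
                 p3 = pmin(tr2 - dd, stress[, "s_tt"]))

  # reactions: residual of the full system at constrained dofs
  f_full <- asm$f_rho * rho_scale + asm$f_sig * sig_scale
  resid <- as.numeric(asm$K %*% sol_u) - f_full
  structure(list(
    model = model, u = u, pressure = p,
    stress = stress, strain = strain, principal = princ,
    contractility = rho_t,
    centroid = cen, centroid_def = cen_def,
    reactions = resid, fixed = asm$fixed,
    rho_scale = rho_scale, sig_scale = sig_scale,
    cage_scale = asm$cage_scale,
    load = c(rho0_bar = rho_scale, sigma_MT = sig_scale)),
    class = "fe_solution")
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf(paste0("<fe_solution> rho0_bar=%.3f kPa, sigma_MT=%.3f kPa; ",
                     "max |u| = %.2f um\n"),
              x$rho_scale, x$sig_scale, max(abs(x$u))))
  invisible(x)
}

#' Closed-form far-field solution for a homogeneous active cylinder
#'
#' For a cell with no nucleus or cage (cytoplasm everywhere), ends held at
#' fixed length and a traction-free lateral surface, the exact solution is a
#' uniform radial contraction: with sigma_rr = sigma_tt = 0 and e_zz = 0,
#' the radial strain is \eqn{e = -\bar\rho_0 / (2\bar K + 2\bar\mu/3)} and
#' the axial stress \eqn{\sigma_{zz} = (2\bar K - 4\bar\mu/3) e + \bar\rho_0}.
#'
#' @param cyto A [cytoplasm_params()].
#' @return List with `e_rr` and `s_zz` (kPa).
#' @export
homogeneous_oracle <- function(cyto = cytoplasm_params()) {
  e <- -cyto$rhobar0 / (2 * cyto$Kbar + 2 * cyto$mubar / 3)
  s_zz <- (2 * cyto$Kbar - 4 * cyto$mubar / 3) * e + cyto$rhobar0
  list(e_rr = e, s_zz = s_zz)
}

#' Axial force-balance residual
#'
#' The net axial reaction on the constrained cell end must balance the net
#' axial reaction transmitted through the mid-cell symmetry plane (the
#' discrete counterpart of integrating sigma_zz over the cross-section).
#' Returns the imbalance normalized by the larger of the two magnitudes.
#'
#' @param sol A [solve_prestress()] solution.
#' @export
force_balance_residual <- function(sol) {
  nn <- sol$model$n_nodes
  zdof <- function(nodes) 2L * nodes
  R_end <- sum(sol$reactions[zdof(sol$model$bc$end)])
  R_sym <- sum(sol$reactions[zdof(sol$model$bc$sym)])
  abs(R_end + R_sym) / max(abs(R_end), abs(R_sym), .Machine$double.eps)
}

#' Sample the stress field at a point
#'
#' Returns the element-centroid stress of the element containing the
#' (undeformed) point.
#'
#' @param sol A solution.
#' @param r,z Point coordinates, um.
#' @export
sample_stress <- function(sol, r, z) {
  m <- sol$model
  for (e in seq_len(m$n_elem)) {
    v <- m$t6[e, 1:3]
    x <- m$nodes[v, 1L]; y <- m$nodes[v, 2L]
    d <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
    l1 <- ((y[2] - y[3]) * (r - x[3]) + (x[3] - x[2]) * (z - y[3])) / d
    l2 <- ((y[3] - y[1]) * (r - x[3]) + (x[1] - x[3]) * (z - y[3])) / d
    l3 <- 1 - l1 - l2
    if (l1 >= -1e-9 && l2 >= -1e-9 && l3 >= -1e-9)
      return(c(sol$stress[e, ], subdomain = m$sub[e]))
  }
  stop("point outside mesh")
}
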