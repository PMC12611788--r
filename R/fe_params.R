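#' Cardiomyocyte model geometry
#'
#' Axisymmetric quarter-domain geometry of the resting cardiomyocyte: a
#' cylinder of radius `cell_radius` and length `cell_length` containing a
#' central round nucleus (nucleoplasm of radius `nuclear_radius` wrapped in
#' an envelope-plus-lamina layer of thickness `ne_thickness`) surrounded by
#' an ellipsoidal perinuclear microtubule cage with semi-axes
#' `cage_semi_axis_z` (axial) and `cage_semi_axis_r` (radial). All lengths
#' in micrometres.
#'
#' @param cell_radius,cell_length,nuclear_radius,ne_thickness Dimensions, um.
#' @param cage_semi_axis_z,cage_semi_axis_r Cage ellipse semi-axes, um. The
#'   stated cage axis lengths (8 and 4.4 um) are read as semi-axes: full
#'   lengths would place the cage boundary inside the 4.2-um nuclear surface
#'   along z, leaving no pole-enriched shell.
#' @return List of class `fe_geometry`.
#' @export
fe_geometry <- function(cell_radius = 35, cell_length = 100,
                        nuclear_radius = 4, ne_thickness = 0.2,
                        cage_semi_axis_z = 8, cage_semi_axis_r = 4.4) {
  g <- as.list(environment())
  if (nuclear_radius <= 0) stop("degenerate geometry: nuclear_radius must be > 0")
  if (nuclear_radius + ne_thickness >= cell_radius)
    stop("nucleus does not fit inside the cell radius")
  if (cage_semi_axis_r <= nuclear_radius + ne_thickness ||
      cage_semi_axis_z <= nuclear_radius + ne_thickness)
    stop("cage boundary must enclose the nuclear envelope in this mesher")
  structure(g, class = "fe_geometry")
}

#' Effective chemo-mechanical moduli
#'
#' The active cytoplasm (myofibril) constitutive law couples passive
#' elasticity to a stress-dependent contractility field. Eliminating the
#' contractility gives an effective linear law with barred moduli and an
#' isotropic active eigenstress:
#' \deqn{3\bar K = (3K\beta - 1)/(\beta - \alpha_v),\quad
#'       2\bar\mu = (2\mu\beta - 1)/(\beta - \alpha_v),\quad
#'       \bar\rho_0 = \beta\rho_0/(\beta - \alpha_v)}
#' with the corresponding contractility-tensor moduli
#' \eqn{3\bar K_\rho = (3K\alpha_v - 1)/(\beta - \alpha_v)} and
#' \eqn{2\bar\mu_\rho = (2\mu\alpha_v - 1)/(\beta - \alpha_v)}.
#' \eqn{K = E/(3(1-2\nu))} and \eqn{\mu = E/(2(1+\nu))}.
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson's ratio.
#' @param beta Chemical stiffness, 1/kPa (default 2.77).
#' @param alpha_v Volumetric chemo-mechanical feedback, 1/kPa (default 2.3).
#' @param rho0 Initial contractility, kPa (default 1.2 at full load).
#' @return List with `K`, `mu`, `Kbar`, `mubar`, `rhobar0`, `Kbar_rho`,
#'   `mubar_rho` (all kPa).
#' @export
effective_moduli <- function(E = 1.2, nu = 0.3, beta = 2.77, alpha_v = 2.3,
                             rho0 = 1.2) {
  if (E <= 0 || beta <= 0) stop("E and beta must be positive")
  if (beta <= alpha_v)
    stop("singular parameters: beta must exceed alpha_v")
  K <- E / (3 * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  d <- beta - alpha_v
  list(K = K, mu = mu,
       Kbar = (3 * K * beta - 1) / (3 * d),
       mubar = (2 * mu * beta - 1) / (2 * d),
       rhobar0 = beta * rho0 / d,
       Kbar_rho = (3 * K * alpha_v - 1) / (3 * d),
       mubar_rho = (2 * mu * alpha_v - 1) / (2 * d))
}

#' Cytoplasm (myofibril) material parameters
#'
#' @inheritParams effective_moduli
#' @return List of class `cytoplasm_params` (includes the barred moduli).
#' @export
cytoplasm_params <- function(E = 1.2, nu = 0.3, beta = 2.77, alpha_v = 2.3,
                             rho0 = 1.2) {
  p <- c(list(E = E, nu = nu, beta = beta, alpha_v = alpha_v, rho0 = rho0),
         effective_moduli(E, nu, beta, alpha_v, rho0))
  structure(p, class = "cytoplasm_params")
}

#' Nucleus material parameters
#'
#' Chromatin (nucleoplasm) is linear elastic and nearly incompressible;
#' the nuclear envelope plus lamina is an incompressible layer handled with
#' a mixed displacement-pressure formulation.
#'
#' @param E_chromatin Nucleoplasm Young's modulus, kPa (default 0.15, i.e.
#'   150 Pa).
#' @param nu_chromatin Nucleoplasm Poisson's ratio (default 0.49).
#' @param E_ne Envelope+lamina modulus, kPa (default 15).
#' @return List of class `nucleus_params`.
#' @export
nucleus_params <- function(E_chromatin = 0.15, nu_chromatin = 0.49,
                           E_ne = 15) {
  structure(list(E_chromatin = E_chromatin, nu_chromatin = nu_chromatin,
                 E_ne = E_ne, nu_ne = 0.5, mu_ne = E_ne / 3),
            class = "nucleus_params")
}

#' Microtubule-cage material parameters
#'
#' The cage is an active linear elastic ellipsoidal shell carrying an
#' isotropic compressive eigenstress `sigma_MT` (0.5 kPa at the
#' physiological state) on top of passive moduli that default to the
#' cytoplasm values (E = 1.2 kPa, nu = 0.3).
#'
#' @param E,nu Passive elasticity of the cage.
#' @param sigma_MT Active isotropic compressive stress, kPa (>= 0).
#' @return List of class `cage_params` with `K_MT`, `mu_MT`, `sigma_MT`.
#' @export
cage_params <- function(E = 1.2, nu = 0.3, sigma_MT = 0.5) {
  if (sigma_MT < 0) stop("sigma_MT must be >= 0")
  structure(list(E = E, nu = nu,
                 K_MT = E / (3 * (1 - 2 * nu)),
                 mu_MT = E / (2 * (1 + nu)),
                 sigma_MT = sigma_MT),
            class = "cage_params")
}

#' Condition presets for the finite-element model
#'
#' \describe{
#'   \item{WT}{envelope modulus 15 kPa, cage at full stress and stiffness.}
#'   \item{LMNA}{lamin-mutant envelope softened to 10 kPa.}
#'   \item{LINC}{LINC-complex disruption: cage compressive stress scaled by
#'     0.1 and cage stiffness by 0.5. The stress reduction dominates the
#'     phenotype (thinner, longer nucleus at conserved volume); collapsing
#'     the passive stiffness by the same factor would instead let the
#'     surrounding contraction arch around the soft cage pocket and fatten
#'     the nucleus, so stress and stiffness are scaled separately.}
#'   \item{LMNA_LINC}{both perturbations combined.}
#' }
#'
#' @param name Condition name.
#' @param E_ne Envelope modulus override, kPa.
#' @param cage_stress_scale Factor multiplying `sigma_MT`.
#' @param cage_stiffness_scale Factor multiplying `K_MT` and `mu_MT`.
#' @return List of class `condition_spec`.
#' @export
condition_spec <- function(name = c("WT", "LMNA", "LINC", "LMNA_LINC"),
                           E_ne = NULL, cage_stress_scale = NULL,
                           cage_stiffness_scale = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    WT = list(E_ne = 15, s = 1, k = 1),
    LMNA = list(E_ne = 10, s = 1, k = 1),
    LINC = list(E_ne = 15, s = 0.1, k = 0.5),
    LMNA_LINC = list(E_ne = 10, s = 0.1, k = 0.5))
  structure(list(name = name,
                 E_ne = if (is.null(E_ne)) defaults$E_ne else E_ne,
                 cage_stress_scale = if (is.null(cage_stress_scale))
                   defaults$s else cage_stress_scale,
                 cage_stiffness_scale = if (is.null(cage_stiffness_scale))
                   defaults$k else cage_stiffness_scale),
            class = "condition_spec")
}

#' Map imaging enrichment to a cage scale factor
#'
#' The quantitative map between the perinuclear enrichment ratio measured by
#' imaging and the cage stress/stiffness is not known; this linear stand-in
#' scales both by `enrichment / e_phys`, with `e_phys = 2` taken as the
#' physiological enrichment corresponding to the WT cage.
#'
#' @param enrichment Perinuclear/cytoplasmic enrichment ratio (>= 0).
#' @param e_phys Enrichment mapped to cage_scale 1.
#' @export
enrichment_to_cage_scale <- function(enrichment, e_phys = 2.0) {
  stopifnot(all(enrichment >= 0), e_phys > 0)
  enrichment / e_phys
}

#' Euler buckling force of a microtubule
#'
#' Critical compressive force for a rod of flexural rigidity `EI` buckling
#' with wavelength `lambda` (a pinned Euler column buckles in a half sine
#' wave, so the buckle wavelength is twice the column length):
#' \eqn{F = 4\pi^2 EI/\lambda^2}. With the rigidity of a single microtubule
#' (2.2e-23 N m^2) and the observed 2-3 um buckle wavelengths this gives
#' forces of order 100 pN and above.
#'
#' @param EI Flexural rigidity, N m^2 (default 2.2e-23).
#' @param wavelength Buckle wavelength, metres (default 2.5e-6).
#' @return Critical force in piconewtons.
#' @export
mt_buckling_force <- function(EI = 2.2e-23, wavelength = 2.5e-6) {
  stopifnot(EI > 0, wavelength > 0)
  4 * pi^2 * EI / wavelength^2 * 1e12
}
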