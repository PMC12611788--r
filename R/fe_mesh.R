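# Axisymmetric quarter-domain mesh: polar rays from the cell centre sweep
# phi in [0, pi/2] (phi = 0 along +z); radial stations are laid out in four
# bands (nucleoplasm, NE, cage, cytoplasm) so that every material interface
# coincides with element edges. Quadratic (6-node) triangles.

# radius of the cage ellipse boundary along direction phi
.cage_radius <- function(phi, b_r, c_z) {
  1 / sqrt((sin(phi) / b_r)^2 + (cos(phi) / c_z)^2)
}

# radius of the outer rectangle boundary along direction phi
.outer_radius <- function(phi, R, H) {
  rr <- ifelse(sin(phi) > 1e-12, R / sin(phi), Inf)
  zz <- ifelse(cos(phi) > 1e-12, H / cos(phi), Inf)
  pmin(rr, zz)
}

#' Build the axisymmetric finite-element model
#'
#' Meshes the quarter domain (r in [0, cell_radius], z in [0, cell_length/2])
#' with quadratic triangles in four subdomains (nucleoplasm, nuclear
#' envelope, microtubule cage, cytoplasm) and attaches materials and
#' boundary conditions: u_r = 0 on the symmetry axis, u_z = 0 on the
#' mid-cell symmetry plane (z = 0) and on the constrained cell end
#' (z = cell_length/2).
#'
#' @param geometry A [fe_geometry()].
#' @param cyto A [cytoplasm_params()].
#' @param nuc A [nucleus_params()].
#' @param cage A [cage_params()].
#' @param mesh_density Scaling factor on element counts (default 1; 2 halves
#'   the element size).
#' @return Object of class `fe_model`: mesh (nodes, T6 connectivity,
#'   subdomain ids), materials, and boundary dof sets.
#' @export
build_model <- function(geometry = fe_geometry(), cyto = cytoplasm_params(),
                        nuc = nucleus_params(), cage = cage_params(),
                        mesh_density = 1) {
  stopifnot(inherits(geometry, "fe_geometry"))
  R <- geometry$cell_radius; H <- geometry$cell_length / 2
  r_n <- geometry$nuclear_radius
  r_ne <- r_n + geometry$ne_thickness
  b_r <- geometry$cage_semi_axis_r; c_z <- geometry$cage_semi_axis_z

  n_phi <- max(8L, round(36 * mesh_density))
  n1 <- max(3L, round(5 * mesh_density))   # nucleoplasm layers
  n2 <- max(2L, round(2 * mesh_density))   # NE layers across 0.2 um
  n3 <- max(3L, round(5 * mesh_density))   # cage layers
  n4 <- max(6L, round(14 * mesh_density))  # cytoplasm layers (graded)

  phi <- seq(0, pi / 2, length.out = n_phi + 1L)
  phi_c <- atan2(R, H)                     # ray through the domain corner
  phi[which.min(abs(phi - phi_c))] <- phi_c

  # radial stations per ray (excluding the origin)
  grade <- 1.35                            # geometric grading in the cytoplasm
  w4 <- grade^(seq_len(n4) - 1L); w4 <- cumsum(w4) / sum(w4)
  stations <- function(ph) {
    rc <- .cage_radius(ph, b_r, c_z)
    ro <- .outer_radius(ph, R, H)
    c(r_n * seq_len(n1) / n1,
      r_n + geometry$ne_thickness * seq_len(n2) / n2,
      r_ne + (rc - r_ne) * seq_len(n3) / n3,
      rc + (ro - rc) * w4)
  }
  M <- n1 + n2 + n3 + n4

  # nodes: origin + (n_phi+1) x M lattice
  nodes <- matrix(0, nrow = 1L + (n_phi + 1L) * M, ncol = 2L)
  idx <- function(j, i) 1L + (j - 1L) * M + i       # ray j (1-based), station i
  for (j in seq_len(n_phi + 1L)) {
    st <- stations(phi[j])
    d <- c(sin(phi[j]), cos(phi[j]))
    nodes[idx(j, seq_len(M)), ] <- cbind(st * d[1L], st * d[2L])
  }

  tri <- list(); sub <- integer(0)
  classify <- function(cen) {
    rho <- sqrt(sum(cen^2))
    if (rho <= r_n + 1e-9) return(1L)                        # nucleoplasm
    if (rho <= r_ne + 1e-9) return(2L)                       # NE
    if ((cen[1L] / b_r)^2 + (cen[2L] / c_z)^2 <= 1 + 1e-9) return(3L)  # cage
    4L                                                       # cytoplasm
  }
  push <- function(a, b, c) {
    # enforce counter-clockwise orientation
    det <- (nodes[b, 1] - nodes[a, 1]) * (nodes[c, 2] - nodes[a, 2]) -
           (nodes[c, 1] - nodes[a, 1]) * (nodes[b, 2] - nodes[a, 2])
    if (det < 0) { tmp <- b; b <- c; c <- tmp }
    tri[[length(tri) + 1L]] <<- c(a, b, c)
    cen <- colMeans(nodes[c(a, b, c), , drop = FALSE])
    sub[length(sub) + 1L] <<- classify(cen)
  }
  for (j in seq_len(n_phi)) {
    push(1L, idx(j, 1L), idx(j + 1L, 1L))           # centre fan
    for (i in seq_len(M - 1L)) {
      a <- idx(j, i); b <- idx(j + 1L, i)
      cc <- idx(j + 1L, i + 1L); d <- idx(j, i + 1L)
      if ((i + j) %% 2L == 0L) { push(a, b, cc); push(a, cc, d) }
      else { push(a, b, d); push(b, cc, d) }
    }
  }
  tri <- do.call(rbind, tri)

  # quadratic nodes on edge midpoints
  nn <- nrow(nodes)
  edge_key <- new.env(hash = TRUE, parent = emptyenv())
  mids <- list()
  t6 <- matrix(0L, nrow(tri), 6L)
  for (e in seq_len(nrow(tri))) {
    v <- tri[e, ]
    m <- integer(3L)
    pairs <- rbind(v[c(1L, 2L)], v[c(2L, 3L)], v[c(3L, 1L)])
    for (k in 1:3) {
      key <- paste(sort(pairs[k, ]), collapse = "_")
      got <- edge_key[[key]]
      if (is.null(got)) {
        mids[[length(mids) + 1L]] <- (nodes[pairs[k, 1L], ] +
                                      nodes[pairs[k, 2L], ]) / 2
        got <- nn + length(mids)
        edge_key[[key]] <- got
      }
      m[k] <- got
    }
    t6[e, ] <- c(v, m)
  }
  nodes <- rbind(nodes, do.call(rbind, mids))

  # ordered node path (pole -> equator) along the outer NE interface,
  # corner and mid-edge nodes interleaved; used for revolution integrals
  i_ne <- n1 + n2
  ne_outer <- integer(0)
  for (j in seq_len(n_phi)) {
    a <- idx(j, i_ne); b <- idx(j + 1L, i_ne)
    mid <- edge_key[[paste(sort(c(a, b)), collapse = "_")]]
    ne_outer <- c(ne_outer, a, mid)
  }
  ne_outer <- c(ne_outer, idx(n_phi + 1L, i_ne))

  # clamp tiny negative coordinates from rounding
  nodes[abs(nodes) < 1e-12] <- 0

  tol <- 1e-8
  on_axis <- which(nodes[, 1L] < tol)
  on_sym <- which(nodes[, 2L] < tol)
  on_end <- which(nodes[, 2L] > H - tol)

  structure(list(
    nodes = nodes, t6 = t6, sub = sub,
    subdomain_names = c("nucleoplasm", "ne", "cage", "cytoplasm"),
    geometry = geometry, cyto = cyto, nuc = nuc, cage = cage,
    bc = list(axis = on_axis, sym = on_sym, end = on_end),
    ne_outer = ne_outer,
    mesh_density = mesh_density,
    n_nodes = nrow(nodes), n_elem = nrow(t6)), class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model> %d nodes, %d T6 elements; subdomain elements: %s\n",
              x$n_nodes, x$n_elem,
              paste(sprintf("%s=%d", x$subdomain_names,
                            tabulate(x$sub, 4L)), collapse = ", ")))
  invisible(x)
}

#' Subdomain areas of the meshed cross-section
#'
#' Plane (r-z) areas of the four subdomains, for mesh-quality checks against
#' the analytic circle/ellipse areas.
#'
#' @param model A [build_model()] result.
#' @return Named numeric vector of areas (um^2).
#' @export
subdomain_areas <- function(model) {
  a <- numeric(4L)
  for (e in seq_len(model$n_elem)) {
    v <- model$t6[e, 1:3]
    x <- model$nodes[v, 1L]; y <- model$nodes[v, 2L]
    area <- abs((x[2] - x[1]) * (y[3] - y[1]) -
                (x[3] - x[1]) * (y[2] - y[1])) / 2
    a[model$sub[e]] <- a[model$sub[e]] + area
  }
  stats::setNames(a, model$subdomain_names)
}
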