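# Finite-element model: parameters, mesh, oracles, invariants, conditions.

test_that("effective moduli follow the chemo-mechanical closure", {
  em <- effective_moduli()
  expect_equal(em$K, 1, tolerance = 1e-12)
  expect_equal(em$mu, 1.2 / 2.6, tolerance = 1e-12)
  expect_equal(em$rhobar0, 2.77 * 1.2 / 0.47, tolerance = 1e-12)
  expect_equal(3 * em$Kbar, (3 * 1 * 2.77 - 1) / 0.47, tolerance = 1e-12)
  expect_equal(2 * em$mubar, (2 * (1.2 / 2.6) * 2.77 - 1) / 0.47,
               tolerance = 1e-12)

  # alpha_v = 0, beta large: barred moduli approach the passive ones
  em2 <- effective_moduli(beta = 1e6, alpha_v = 0)
  expect_equal(em2$Kbar, em2$K, tolerance = 1e-5)
  expect_equal(em2$mubar, em2$mu, tolerance = 1e-5)
  expect_equal(em2$rhobar0, 1.2, tolerance = 1e-6)

  expect_equal(effective_moduli(rho0 = 0)$rhobar0, 0)
  expect_error(effective_moduli(beta = 2, alpha_v = 2.3), "singular")
})

test_that("microtubule buckling force is of order 100 pN", {
  expect_gte(mt_buckling_force(), 100)
  # quadratic in 1/wavelength
  expect_equal(mt_buckling_force(wavelength = 5e-6),
               mt_buckling_force() / 4, tolerance = 1e-12)
})

test_that("mesh has resolved subdomains matching analytic areas", {
  m <- build_model()
  expect_equal(sort(unique(m$sub)), 1:4)
  a <- subdomain_areas(m)
  expect_equal(unname(a["nucleoplasm"]), pi * 4^2 / 4, tolerance = 2e-3)
  expect_equal(unname(a["ne"]), pi * (4.2^2 - 4^2) / 4, tolerance = 2e-3)
  expect_equal(unname(a["cage"]), pi * (4.4 * 8 - 4.2^2) / 4,
               tolerance = 3e-3)
  expect_equal(sum(a), 35 * 50, tolerance = 1e-9)

  # refinement conserves subdomain areas to < 0.1 %
  a2 <- subdomain_areas(build_model(mesh_density = 2))
  expect_lt(max(abs(a2 - a) / a), 1e-3)

  expect_error(fe_geometry(nuclear_radius = 0), "degenerate")
  expect_error(fe_geometry(nuclear_radius = 34.9), "fit inside")
})

test_that("zero load gives zero displacement and stress", {
  wt <- fix_wt_solution()
  s0 <- solve_prestress(wt$model, ramp = data.frame(f_rho = 0, f_sig = 0))
  expect_equal(max(abs(s0$u)), 0)
  expect_equal(max(abs(s0$stress)), 0)
  expect_identical(principal_stress_location(s0)$location, "undefined")
  sh <- nuclear_shape(s0)
  expect_equal(sh$aspect_ratio, 1, tolerance = 1e-9)
  expect_equal(sh$volume, 4 / 3 * pi * 4.2^3, tolerance = 2e-3)
})

test_that("homogeneous cytoplasm matches the closed-form far field to <1%", {
  m <- build_model()
  m$sub[] <- 4L                      # cytoplasm everywhere, no cage stress
  sol <- solve_prestress(m, cage_stress_scale = 0)
  orc <- homogeneous_oracle()
  s <- sample_stress(sol, 20, 25)
  expect_lt(abs(s[["s_zz"]] - orc$s_zz) / abs(orc$s_zz), 0.01)
  expect_lt(abs(s[["s_rr"]]) / abs(orc$s_zz), 0.01)
  expect_lt(max(abs(sol$strain[, "e_rr"] - orc$e_rr)) / abs(orc$e_rr), 0.01)
})

test_that("global axial force balance holds to 1e-6", {
  wt <- fix_wt_solution()
  expect_lt(force_balance_residual(wt$sol), 1e-6)
})

test_that("incompressible envelope conserves element volumes to <0.5%", {
  wt <- fix_wt_solution()
  nee <- which(wt$model$sub == 2L)
  # element-average volumetric strain (the constraint is enforced against
  # the P1 pressure space, not pointwise)
  ekk <- rowSums(wt$sol$strain[nee, 1:3])
  expect_lt(mean(abs(ekk)), 5e-3)
  expect_lt(stats::quantile(abs(ekk), 0.9), 5e-3)
})

test_that("nuclear volume agrees between independent quadratures", {
  wt <- fix_wt_solution()
  sh <- nuclear_shape(wt$sol)
  expect_lt(abs(sh$volume - sh$volume_mesh) / sh$volume, 0.005)
  expect_gt(sh$aspect_ratio, 1)      # elongated along the contractile axis
})

test_that("aspect ratio is mesh converged to <1% under refinement", {
  wt <- fix_wt_solution()
  ar1 <- nuclear_shape(wt$sol)$aspect_ratio
  sol2 <- solve_prestress(build_model(mesh_density = 2))
  ar2 <- nuclear_shape(sol2)$aspect_ratio
  expect_lt(abs(ar2 - ar1) / ar1, 0.01)
})

test_that("WT fields: far-field tension, cage compression at the tips", {
  wt <- fix_wt_solution()
  far <- sample_stress(wt$sol, 20, 25)
  expect_identical(unname(far["subdomain"]), 4)
  expect_gt(far[["s_zz"]], 2); expect_lt(far[["s_zz"]], 3)

  cage <- which(wt$model$sub == 3L)
  szz <- wt$sol$stress[cage, "s_zz"]
  expect_true(all(szz < 0))          # the whole cage is axially compressed
  cen <- wt$sol$centroid[cage, ]
  ang <- atan2(cen[, 1], cen[, 2])   # 0 = long tip, pi/2 = short side
  expect_gt(mean(abs(szz[ang < 0.3])), mean(abs(szz[ang > 1.27])))
})

test_that("aspect ratio responds monotonically to cage stress and envelope
           stiffness", {
  wt <- fix_wt_solution()
  # higher sigma_MT compresses the poles: AR non-increasing in sigma_MT
  ars <- vapply(c(0.5, 1, 2), function(s) {
    nuclear_shape(solve_prestress(wt$model, cage_stress_scale = s / 0.5))$
      aspect_ratio
  }, numeric(1))
  expect_true(all(diff(ars) < 0))
  # softer envelope elongates more
  tab <- fix_condition_table()
  expect_gt(tab$aspect_ratio[tab$condition == "LMNA"],
            tab$aspect_ratio[tab$condition == "WT"])
})

test_that("condition ordering and volume conservation match observations", {
  tab <- fix_condition_table()
  ar <- stats::setNames(tab$aspect_ratio, tab$condition)
  expect_true(ar["WT"] < ar["LMNA"] &&
              ar["LMNA"] < ar["LINC"] &&
              ar["LINC"] < ar["LMNA_LINC"])
  dv <- 100 * abs(tab$volume - tab$volume[tab$condition == "WT"]) /
    tab$volume[tab$condition == "WT"]
  expect_lt(max(dv), 10)
  # determinism: identical specs give identical results
  s1 <- solve_condition("LMNA")
  s2 <- solve_condition("LMNA")
  expect_identical(nuclear_shape(s1)$aspect_ratio,
                   nuclear_shape(s2)$aspect_ratio)
})

test_that("volume change is a scale-invariant percentage", {
  wt <- fix_wt_solution()
  expect_equal(volume_change(wt$sol, wt$sol), 0)
})

test_that("instability detection brackets the mid-to-tip switch", {
  wt <- fix_wt_solution()
  # grid entirely below the switch: nothing detected
  low <- detect_instability(wt$model, cage_stress_grid = c(0.2, 0.4, 0.6),
                            tol = 0.05)
  expect_false(low$detected)
  expect_identical(low$mode, "none in range")

  d1 <- detect_instability(wt$model, cage_stress_grid = seq(0.5, 2.5, 0.5),
                           tol = 0.02)
  expect_true(d1$detected)
  expect_gt(d1$critical, 0.5)        # the physiological WT state is "mid"
  # grid-independence of the bisection result
  d2 <- detect_instability(wt$model, cage_stress_grid = seq(0.4, 2.6, 0.2),
                           tol = 0.02)
  expect_lt(abs(d1$critical - d2$critical), 0.2)
})

test_that("enrichment sweep declines with enrichment above the arch regime", {
  tab <- sweep_enrichment(enrichment_grid = c(1, 1.5, 2, 2.5, 3))
  expect_true(all(tab$converged))
  expect_true(all(diff(tab$aspect_ratio) < 0))
  # lamin-mutant sweep sits above WT at matched enrichment
  tab10 <- sweep_enrichment(enrichment_grid = c(1, 2), E_ne = 10)
  expect_true(all(tab10$aspect_ratio >
                  tab$aspect_ratio[tab$enrichment %in% c(1, 2)]))
})
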