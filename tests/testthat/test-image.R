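# Microscopy quantification against planted ground truth.

test_that("3-D segmentation recovers planted ellipsoid morphology", {
  g <- fix_nucleus_stack()
  seg <- segment_nuclei(g$stack, mode = "3D")
  expect_equal(nrow(seg$records), 1L)
  expect_equal(seg$records$aspect_ratio, 2, tolerance = 0.025)
  expect_equal(seg$records$volume, g$truth$nuclei$volume, tolerance = 0.05)
  expect_equal(seg$records$length, 12, tolerance = 0.05)
  # segmentation overlap with the exact planted mask
  inter <- sum(seg$labels > 0 & g$truth$nucleus_labels > 0)
  uni <- sum(seg$labels > 0 | g$truth$nucleus_labels > 0)
  expect_gt(inter / uni, 0.95)
})

test_that("blank images yield no nuclei, with a warning", {
  blank <- image_stack(list(dna = array(0, c(20, 20, 3))),
                       c(0.2, 0.2, 0.5))
  expect_warning(seg <- segment_nuclei(blank), "degenerate")
  expect_equal(nrow(seg$records), 0L)
})

test_that("two separated ellipsoids are recovered individually", {
  p <- image_gen_params(field_size = c(30, 14, 8),
                        voxel_size = c(0.2, 0.2, 0.5),
                        nuclei = list(
                          list(center = c(7, 7, 4), semi = c(5, 2.5, 2.5)),
                          list(center = c(22, 7, 4), semi = c(5, 2.5, 2.5))),
                        background = 20, seed = 12)
  g <- gen_image_stack(p)
  seg <- segment_nuclei(g$stack, mode = "3D")
  expect_equal(nrow(seg$records), 2L)
  expect_equal(seg$records$volume, g$truth$nuclei$volume, tolerance = 0.05)
})

test_that("ring masks match the analytic annulus and stay disjoint", {
  px <- 0.1
  d <- c(160, 160)
  cx <- (seq_len(d[1]) - 0.5) * px; cy <- (seq_len(d[2]) - 0.5) * px
  circ <- outer((cx - 8)^2, (cy - 8)^2, `+`) <= 25   # r = 5 um
  masks <- ring_masks(circ, c(px, px))
  a_pn <- sum(masks$perinuclear) * px^2
  expect_equal(a_pn, pi * (5.5^2 - 5^2), tolerance = 0.08)
  a_cy <- sum(masks$cytoplasmic) * px^2
  expect_equal(a_cy, pi * (8.5^2 - 5.5^2), tolerance = 0.08)
  expect_false(any(masks$perinuclear & circ))
  expect_false(any(masks$cytoplasmic & (circ | masks$perinuclear)))
  expect_false(masks$border)
  expect_error(ring_masks(circ, c(px, px), pn_width = 0.01), "below one pixel")
})

test_that("enrichment ratio is exact on constructed masks and scale
           invariant", {
  img <- matrix(100, 50, 50)
  pn <- matrix(FALSE, 50, 50); pn[20:30, 20:30] <- TRUE
  cyt <- matrix(FALSE, 50, 50); cyt[1:10, 1:10] <- TRUE
  img[pn] <- 190
  masks <- list(perinuclear = pn, cytoplasmic = cyt)
  expect_equal(enrichment_ratio(img, masks)$ratio, 1.9)
  expect_equal(enrichment_ratio(img * 7.3, masks)$ratio, 1.9)
  expect_equal(enrichment_ratio(matrix(5, 50, 50), masks)$ratio, 1)
  empty <- list(perinuclear = pn & FALSE, cytoplasmic = cyt)
  expect_warning(bad <- enrichment_ratio(img, empty), "empty")
  expect_false(bad$valid)
})

test_that("planted 1.9x shell is recovered through the ring pipeline", {
  g <- fix_nucleus_stack()
  nmask <- g$truth$nucleus_labels[, , 8] > 0     # mid-plane slice (z = 4 um)
  tub <- get_channel(g$stack, "tubulin")[, , 8]
  er <- enrichment_ratio(tub, ring_masks(nmask, g$stack$voxel_size))
  expect_equal(er$ratio, 1.9, tolerance = 0.05 / 1.9)
  expect_equal(er$cyt_mean, 100, tolerance = 0.02)
})

test_that("pole enrichment picks up tip-enriched shells and is rotation
           invariant", {
  p <- image_gen_params(field_size = c(24, 18, 8),
                        voxel_size = c(0.1, 0.1, 0.5),
                        nuclei = list(list(center = c(12, 9, 4),
                                           semi = c(6, 3, 3))),
                        shell = list(thickness = 0.55, enrichment = 1.5,
                                     pole_boost = 2, cyt_intensity = 100),
                        background = 0, seed = 13)
  g <- gen_image_stack(p)
  nmask <- g$truth$nucleus_labels[, , 8] > 0
  tub <- get_channel(g$stack, "tubulin")[, , 8]
  pe <- pole_enrichment(tub, nmask, g$stack$voxel_size)
  expect_gt(pe$long_pole_ratio, pe$short_pole_ratio)
  expect_true(pe$automated)

  # 90-degree rotation swaps long/short axes but not the ratios
  rot <- function(m) t(m[nrow(m):1, ])
  pe_r <- pole_enrichment(rot(tub), rot(nmask), g$stack$voxel_size)
  expect_equal(pe_r$long_pole_ratio, pe$long_pole_ratio, tolerance = 1e-9)
  expect_equal(pe_r$short_pole_ratio, pe$short_pole_ratio, tolerance = 1e-9)

  # uniform image: both poles at the cytoplasmic level
  un <- pole_enrichment(matrix(80, 240, 180), nmask, g$stack$voxel_size)
  expect_equal(un$long_pole_ratio, 1)
  expect_equal(un$short_pole_ratio, 1)
})

test_that("rupture foci calling applies intensity, size and ring gates", {
  foci <- data.frame(channel = "cgas",
                     x = c(18.2, 5.8, 12, 12, 2),
                     y = c(9, 9, 12.2, 5.8, 2),
                     z = 4,
                     radius = c(0.62, 0.62, 0.62, 0.4, 0.62),
                     intensity = c(800, 800, 800, 800, 800))
  p <- image_gen_params(field_size = c(24, 18, 8),
                        voxel_size = c(0.1, 0.1, 0.5),
                        nuclei = list(list(center = c(12, 9, 4),
                                           semi = c(6, 3, 3))),
                        foci = foci, background = 50, seed = 14)
  g <- gen_image_stack(p)
  seg <- segment_nuclei(g$stack, mode = "MIP")
  cg <- mip(get_channel(g$stack, "cgas"))
  det <- detect_cgas_foci(cg, seg, g$stack$voxel_size)
  # 3 tip foci kept; the 0.5-um2 focus fails the size gate and the distant
  # focus fails the nucleus-contact/ring gates
  expect_equal(nrow(det$foci), 3L)
  expect_true(all(det$foci$area > 0.8))
  expect_true(all(det$foci$touches_nucleus & det$foci$in_ring))
  expect_equal(det$per_nucleus$n_foci, 3)

  # no supra-threshold pixels: empty table
  none <- detect_cgas_foci(cg * 0, seg, g$stack$voxel_size)
  expect_equal(nrow(none$foci), 0L)
})

test_that("3-D damage foci respect the volume gate and summarize per
           nucleus", {
  pg <- image_gen_params(field_size = c(16, 12, 11),
                         voxel_size = c(0.1, 0.1, 0.25),
                         nuclei = list(list(center = c(8, 6, 5.5),
                                            semi = c(6.2, 4.4, 4.4))),
                         foci = data.frame(channel = "gh2ax",
                                           x = c(6, 8, 10, 7, 9, 8),
                                           y = c(5, 6, 7, 6.5, 5.5, 7.5),
                                           z = c(5, 5.5, 6, 4.5, 6.5, 5),
                                           radius = c(rep(0.288, 5), 0.134),
                                           intensity = 3000),
                         background = 50, seed = 15)
  g <- gen_image_stack(pg)
  seg <- segment_nuclei(g$stack, mode = "3D")
  det <- detect_gh2ax_foci(g$stack, seg)
  expect_equal(det$per_nucleus$count, 5)      # the 0.01-um3 punctum is gated
  expect_true(all(det$foci$volume >= 0.02))
  # fraction ~ 5 x 0.1 um3 in a ~500 um3 nucleus
  expect_equal(det$per_nucleus$fraction, 0.001, tolerance = 0.25)
  expect_equal(det$per_nucleus$mean_volume,
               sum(det$foci$volume) / 5, tolerance = 1e-12)

  # zero supra-threshold voxels
  stack0 <- g$stack
  stack0$channels$gh2ax[] <- 50
  det0 <- detect_gh2ax_foci(stack0, seg)
  expect_equal(det0$per_nucleus$count, 0)
  expect_equal(det0$per_nucleus$fraction, 0)
})

test_that("outlier exclusion and control normalization follow the 3-sd
           rule", {
  df <- data.frame(group = rep(c("ctrl", "treat"), each = 10),
                   count = c(rep(4, 10), rep(8, 10)),
                   mean_volume = 0.1)
  out <- exclude_outliers_and_normalize(df, control_group = "ctrl")
  expect_equal(attr(out, "n_excluded"), 0L)
  expect_equal(out$count[out$group == "ctrl"], rep(1, 10))
  expect_equal(out$count[out$group == "treat"], rep(2, 10))
  expect_equal(out$mean_volume, rep(1, 20))

  # a value far beyond mean + 3 sd on either criterion is excluded
  df2 <- df
  df2$count[20] <- 30
  out2 <- exclude_outliers_and_normalize(df2, control_group = "ctrl")
  expect_equal(attr(out2, "n_excluded"), 1L)
  df3 <- df
  df3$mean_volume <- seq(0.1, 0.2, length.out = 20)
  df3$mean_volume[1] <- 10
  out3 <- exclude_outliers_and_normalize(df3, control_group = "ctrl")
  expect_equal(attr(out3, "n_excluded"), 1L)

  dfz <- df; dfz$count[dfz$group == "ctrl"] <- 0
  expect_error(exclude_outliers_and_normalize(dfz, control_group = "ctrl"),
               "zero")
})

test_that("membrane watershed coverage matches the honeycomb ground
           truth", {
  p <- image_gen_params(field_size = c(50, 50, 4), voxel_size = c(0.2, 0.2, 1),
                        nuclei = list(),
                        wga = list(pitch = 10, width = 0.5, intensity = 800),
                        background = 20, seed = 16)
  g <- gen_image_stack(p)
  memb_frac <- mean(mip(get_channel(g$stack, "wga")) > 400)
  cv <- cm_area_coverage(g$stack)
  expect_equal(cv$coverage, 1 - memb_frac, tolerance = 0.02)
  expect_gt(max(cv$segments), 15)    # individual cells separated
  expect_lte(cv$coverage, 1)

  blank <- image_stack(list(wga = array(3, c(30, 30, 4))), c(0.2, 0.2, 1))
  expect_warning(cv0 <- cm_area_coverage(blank), "no membrane")
  expect_equal(cv0$coverage, 0)
})

test_that("marker coverage recovers planted blob area percentages", {
  p <- image_gen_params(field_size = c(246, 246, 2),
                        voxel_size = c(0.2, 0.2, 1), nuclei = list(),
                        foci = data.frame(channel = "cd45", x = 123, y = 123,
                                          z = 1, radius = 2.821,
                                          intensity = 5000),
                        background = 10, seed = 17)
  g <- gen_image_stack(p)
  pct <- marker_coverage(g$stack, "cd45", threshold = 2500)
  expect_equal(pct, 100 * 25 / 246^2, tolerance = 0.15)

  blank <- image_stack(list(cd45 = array(1, c(100, 100, 2))), c(0.2, 0.2, 1))
  expect_equal(marker_coverage(blank, "cd45", threshold = 100), 0)
  # threshold at half the plateau: the blur crossing sits on the boundary
  half <- array(1, c(100, 100, 2)); half[1:50, , ] <- 1e4
  hs <- image_stack(list(cd45 = half), c(0.2, 0.2, 1))
  expect_equal(marker_coverage(hs, "cd45", threshold = 5000), 50,
               tolerance = 0.03)
})
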