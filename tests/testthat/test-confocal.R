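# Segmentation, object metrics, noise filter, mass model, concentrations
# and organ extrapolation.

test_that("uniform stacks segment to zero foreground", {
  g <- small_grid(32, 32, 8)
  stk <- generate_stack(g, empty_scene())
  lab <- segment_stack(stk, "absolute", threshold = 10)
  expect_equal(attr(lab, "n_labels"), 0)
  flat <- stk
  flat$data[] <- 2
  expect_equal(attr(segment_stack(flat, "otsu"), "n_labels"), 0)
  bad <- stk
  bad$data[1] <- NA
  expect_error(segment_stack(bad, "otsu"), "NA")
})

test_that("well-separated spheres give one label each; close pairs merge", {
  g <- small_grid(64, 64, 24)
  # separation 3 um >> PSF support
  sc2 <- placed_scene(g, c(2.5, 5.5), c(3.8, 3.8), c(3.6, 3.6),
                      diameter = 0.6)
  stk2 <- generate_stack(g, sc2)
  expect_equal(attr(segment_stack(stk2, "otsu"), "n_labels"), 2)
  # separation 0.15 um < 0.2 um lateral resolution: detected as one larger
  # object
  scm <- placed_scene(g, c(3.7, 3.85), c(3.8, 3.8), c(3.6, 3.6),
                      diameter = 0.3)
  stkm <- generate_stack(g, scm)
  labm <- segment_stack(stkm, "otsu")
  expect_equal(attr(labm, "n_labels"), 1)
  obj <- extract_objects(labm, stkm)
  expect_gt(obj$volume_um3, sphere_volume(0.3))
})

test_that("object metrics follow the voxel geometry closed forms", {
  g <- small_grid(16, 16, 8)
  stk <- generate_stack(g, empty_scene())
  lab <- array(0L, dim(stk$data))
  lab[5, 5, 3] <- 1L                 # 1 voxel
  lab[10:12, 10, 4] <- 2L            # 3 voxels
  lab[2:4, 2:3, 5] <- 3L             # 6 voxels
  objs <- extract_objects(lab, stk)
  expect_equal(objs$volume_um3, c(0.00432, 3 * 0.00432, 0.02592))
  expect_equal(objs$eq_diameter_um[1], (6 * 0.00432 / pi)^(1 / 3))
  expect_equal(objs$eq_diameter_um[3], 0.367, tolerance = 1e-3)
  expect_equal(objs$deepest_z_um, (c(3, 4, 5) - 0.5) * 0.3)
  expect_false(any(objs$touches_edge))
})

test_that("objects touching any stack face are flagged and excluded", {
  g <- small_grid(16, 16, 8)
  stk <- generate_stack(g, empty_scene())
  lab <- array(0L, dim(stk$data))
  lab[1, 8, 4] <- 1L     # x = 0 face
  lab[8, 8, 8] <- 2L     # z = top face
  lab[8, 8, 4] <- 3L     # interior
  objs <- extract_objects(lab, stk)
  expect_equal(objs$touches_edge, c(TRUE, TRUE, FALSE))
  scan <- tissue_concentration(objs, 1e6, polymer_spec("PS", 1.05))
  expect_equal(scan$n_objects, 1)
})

test_that("noise filter removes <= 5-voxel objects, keeps 6, idempotent", {
  objs <- data.frame(label = 1:3, voxels = c(5L, 6L, 1L),
                     volume_um3 = c(5, 6, 1) * 0.00432,
                     eq_diameter_um = 1, mean_intensity = 1,
                     deepest_z_um = 1, touches_edge = FALSE)
  kept <- filter_noise(objs)
  expect_equal(kept$voxels, 6L)
  expect_equal(filter_noise(kept), kept)
  expect_equal(nrow(filter_noise(objs[0, ])), 0)
})

test_that("packing-density mass model gives the closed-form masses", {
  ps <- polymer_spec("PS", 1.05, 0.64)
  expect_equal(object_mass(sphere_volume(1.0), ps),
               pi / 6 * 0.64 * 1.05 * 1e-12)
  expect_equal(object_mass(4e-4, ps), 2.688e-16)
  expect_equal(eq_sphere_diameter(4e-4), 0.0914, tolerance = 1e-3)
  expect_equal(object_mass(1, polymer_spec("unit", 1, packing = 1)), 1e-12)
  expect_error(object_mass(1), "polymer_spec")
  expect_error(polymer_spec("x", 1.05, packing = 1.2), "packing")
})

test_that("tissue concentrations scale with scanned volume", {
  ps <- polymer_spec("PS", 1.05, 0.64)
  objs <- data.frame(volume_um3 = c(0.3, 0.2), touches_edge = FALSE)
  objs$volume_um3 <- objs$volume_um3 /
    (ps$packing * ps$density_g_cm3)  # total mass exactly 0.5 pg
  scan <- tissue_concentration(objs, 1e6, ps)
  expect_equal(scan$mass_ng_per_100um3, 0.5e-3)
  expect_equal(scan$number_per_100um3, 2)
  scan2 <- tissue_concentration(objs, 2e6, ps)
  expect_equal(scan2$mass_ng_per_100um3, scan$mass_ng_per_100um3 / 2)
  expect_equal(scan2$number_per_100um3, 1)
  empty <- tissue_concentration(objs[0, ], 1e6, ps)
  expect_equal(empty$mass_ng_per_100um3, 0)
  expect_error(tissue_concentration(objs, 0, ps), "scanned volume")
})

test_that("organ burden extrapolation matches the published arithmetic", {
  b <- organ_burden(0.42, organ_volume_ml = 10, organ_weight_g = 1.63)
  expect_equal(b$total_mass_mg, 4.2)
  expect_equal(b$mass_per_g_mg, 2.58, tolerance = 0.002)
  ln <- organ_burden(0.48, organ_volume_ml = 0.03, organ = "LN")
  expect_equal(ln$total_mass_ug, 14.4)
  expect_error(organ_burden(0.42, -1), "organ volume")
})

test_that("scanned volume can truncate at the deepest detected object", {
  g <- small_grid(100, 100, 40)  # 12 x 12 x 12 um
  expect_equal(scanned_volume(g), 12 * 12 * 12)
  objs <- data.frame(deepest_z_um = c(2.85, 5.25))
  expect_equal(scanned_volume(g, objs, truncate_at_deepest = TRUE),
               12 * 12 * (5.25 + 0.15))
  expect_error(scanned_volume(g, NULL, truncate_at_deepest = TRUE),
               "objects")
})

test_that("size histogram is normalised and recovers the generator mode", {
  one <- data.frame(eq_diameter_um = 0.8)
  h1 <- size_histogram(one, breaks = seq(0, 2, 0.5))
  expect_equal(sum(h1$frequency), 1)
  expect_equal(h1$frequency[h1$bin_lo == 0.5], 1)
  set.seed(5)
  objs <- data.frame(eq_diameter_um = rlnorm(2000, log(0.7), 0.25))
  h <- size_histogram(objs, breaks = seq(0, 10, 0.25))
  expect_equal(sum(h$frequency), 1)
  expect_true(all(h$frequency >= 0))
  mode_bin <- h$mid[which.max(h$frequency)]
  expect_lte(abs(mode_bin - 0.7), 0.25 + 0.125)
  expect_equal(nrow(size_histogram(objs[0, , drop = FALSE])), 0)
})

test_that("lower thresholds never decrease the raw object count", {
  stk <- recovery_stack(n = 12, seed = 13)
  counts <- vapply(c(60, 30, 10, 4), function(thr) {
    lab <- segment_stack(stk, "absolute", threshold = thr)
    nrow(extract_objects(lab, stk))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
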