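test_that("an empty scene yields a background-only stack with no objects", {
  g <- small_grid()
  stk <- generate_stack(g, empty_scene(background = 3))
  expect_equal(mean(stk$data), 3, tolerance = 0.01)
  lab <- segment_stack(stk, "absolute", threshold = 3 + 6 * 0.25)
  objs <- filter_noise(extract_objects(lab, stk))
  expect_equal(nrow(objs), 0)
})

test_that("voxelisation conserves integrated emitter signal before noise", {
  g <- small_grid()
  for (d in c(0.4, 1.0, 2.5)) {
    sc <- placed_scene(g, g$field_x / 2, g$field_y / 2, g$depth / 2, d)
    stk <- generate_stack(g, sc)
    # emitter intensity is per fully occupied voxel, so integrated signal
    # is intensity * volume / voxel volume
    expected <- 100 * sphere_volume(d) / g$voxel_volume
    expect_equal(sum(stk$clean - 1), expected, tolerance = 0.01)
  }
})

test_that("stacks are bit-reproducible under the same seed", {
  g <- small_grid(96, 96, 24)
  sc1 <- random_scene(g, 5, margin = 1.5, seed = 9)
  sc2 <- random_scene(g, 5, margin = 1.5, seed = 9)
  expect_identical(generate_stack(g, sc1)$data, generate_stack(g, sc2)$data)
  sc3 <- random_scene(g, 5, margin = 1.5, seed = 10)
  expect_false(identical(generate_stack(g, sc1)$data,
                         generate_stack(g, sc3)$data))
})

test_that("depth fade attenuates deep objects as exp(-z/L)", {
  g <- small_grid(48, 48, 80)  # 24 um deep
  L <- 53 / log(4)
  sc <- placed_scene(g, rep(g$field_x / 2, 2), rep(g$field_y / 2, 2),
                     c(3, 21), diameter = 1, fade_length = L)
  stk <- generate_stack(g, sc)
  top <- max(stk$clean[, , 1:30]) - 1
  deep <- max(stk$clean[, , 51:80]) - 1
  expect_equal(deep / top, exp(-(21 - 3) / L), tolerance = 0.05)
})

test_that("a sub-resolution emitter appears as at least 6 voxels at high SNR", {
  g <- small_grid(48, 48, 24)
  sc <- placed_scene(g, g$field_x / 2, g$field_y / 2, g$depth / 2,
                     diameter = 0.089, intensity = 5000,
                     shot_scale = 0.05, read_noise_sd = 0.3)
  stk <- generate_stack(g, sc)
  lab <- segment_stack(stk, "absolute", threshold = 1 + 5)
  objs <- extract_objects(lab, stk)
  expect_equal(nrow(objs), 1)
  expect_gte(objs$voxels, 6)
  # the apparent size exceeds the true size
  expect_gt(objs$eq_diameter_um, 0.089)
})

test_that("generator rejects invalid scenes", {
  g <- small_grid(32, 32, 8)
  expect_error(placed_scene(g, 1, 1, 1, diameter = -1), "diameters")
  expect_error(
    ground_truth_scene(data.frame(x = 1, y = 1, z = 1, diameter = 1,
                                  intensity = 1),
                       shot_scale = -0.1, seed = 1),
    "noise")
  expect_error(ground_truth_scene(data.frame(x = 1, y = 1, z = 1,
                                             diameter = 1, intensity = 1)),
               "seed")
  big <- placed_scene(g, 1, 1, 1, diameter = 50)
  expect_error(generate_stack(g, big), "exceeds")
  outside <- placed_scene(g, -5, 1, 1, diameter = 0.5)
  expect_warning(generate_stack(g, outside), "outside")
})
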