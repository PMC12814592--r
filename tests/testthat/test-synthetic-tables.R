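# Generators for burden time courses, pyrolysis runs and impactor runs.

test_that("burden generator reproduces the closed-form curve at CV = 0", {
  spec <- burden_timecourse_spec(4.2, data.frame(end_day = Inf,
                                                 half_time = 46),
                                 cv = 0, sampling_days = 46,
                                 n_animals = 4, seed = 1)
  tc <- generate_burden_timecourse(spec)
  expect_equal(tc$burden_mg, rep(2.1, 4))

  # biphasic closed form: 3.8 mg, 68 d to day 35 then 226 d, at day 91
  expected <- 3.8 * exp(-35 * log(2) / 68) * exp(-56 * log(2) / 226)
  spec2 <- burden_timecourse_spec(3.8, biphasic_phases(), cv = 0,
                                  sampling_days = 91, n_animals = 2,
                                  seed = 1)
  expect_equal(generate_burden_timecourse(spec2)$burden_mg,
               rep(expected, 2))
  expect_equal(expected, 2.2400, tolerance = 1e-4)
})

test_that("lognormal animal factors have unit mean", {
  spec <- burden_timecourse_spec(10, data.frame(end_day = Inf,
                                                half_time = 50),
                                 cv = 0.3, sampling_days = 0,
                                 n_animals = 1000, seed = 3)
  tc <- generate_burden_timecourse(spec)
  se <- 10 * 0.3 / sqrt(1000)
  expect_lt(abs(mean(tc$burden_mg) - 10), 3 * se)
})

test_that("burden generator rejects days beyond the last phase", {
  expect_error(
    burden_timecourse_spec(1, data.frame(end_day = c(35, 91),
                                         half_time = c(68, 226)),
                           cv = 0, sampling_days = 120, seed = 1),
    "beyond")
})

test_that("pyrolysis run is linear and reproducible", {
  run <- generate_pyro_run(50, slope = 2, intercept = 0, noise_sd = 0,
                           seed = 1)
  expect_equal(run$peak_area, 100)
  # exact slope recovery over the lung calibration range at zero noise
  masses <- seq(37, 3700, length.out = 8)
  run2 <- generate_pyro_run(masses, slope = 2, intercept = 5,
                            noise_sd = 0, seed = 1)
  cv <- fit_calibration(run2$true_mass_ng, run2$peak_area)
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 5)
  r1 <- generate_pyro_run(masses, 2, 5, noise_sd = 3, seed = 4)
  expect_identical(r1, generate_pyro_run(masses, 2, 5, noise_sd = 3,
                                         seed = 4))
  expect_error(generate_pyro_run(50, slope = -1, seed = 1), "slope")
  expect_error(generate_pyro_run(-5, slope = 1, seed = 1), "masses")
})

test_that("noisy replicates at the lowest mass give finite limits", {
  masses <- rep(c(20, 100, 500, 1140), each = 6)
  run <- generate_pyro_run(masses, slope = 2, intercept = 0, noise_sd = 4,
                           seed = 8)
  cv <- fit_calibration(run$true_mass_ng, run$peak_area)
  dl <- detection_limits(cv, 75, k = 3)
  expect_true(is.finite(dl$lod_ug) && dl$lod_ug >= 0)
  expect_lte(dl$lod_ug, dl$loq_ug)
})

test_that("impactor stage masses conserve total mass and round-trip", {
  run <- generate_impactor_run(1.51, 2.04, total_mass_mg = 12.5)
  expect_equal(sum(run$mass_mg), 12.5)
  f <- fit_mmad_gsd(run)
  expect_equal(f$mmad_um, 1.51, tolerance = 1e-9)
  expect_equal(f$gsd, 2.04, tolerance = 1e-9)
  expect_error(generate_impactor_run(1.5, gsd = 1, total_mass_mg = 1),
               "gsd")
  expect_error(generate_impactor_run(1.5, 2, 1, cutoffs_um = c(1, 2, 3)),
               "decreasing")
})

test_that("noisy impactor runs recover the MMAD within 10% in the median", {
  fits <- vapply(1:50, function(s) {
    run <- generate_impactor_run(1.32, 2.11, 10, noise_cv = 0.05, seed = s)
    fit_mmad_gsd(run)$mmad_um
  }, numeric(1))
  expect_lt(abs(median(fits) - 1.32) / 1.32, 0.10)
})
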