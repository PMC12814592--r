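# Dosimetry equations and clearance fits.

test_that("ventilation rate and applied mass reproduce the worked values", {
  expect_equal(ventilation_rate(0.270), 0.216)
  expect_equal(ventilation_rate(0.200), 0.16)
  expect_warning(r0 <- ventilation_rate(0.2, 0), "degenerate")
  expect_equal(r0, 0)
  ps <- exposure_scenario(50, 360, 20, 0.270)
  pa <- exposure_scenario(50, 360, 20, 0.200)
  expect_equal(total_applied_mass(ps), 77.76)   # printed as 77.8
  expect_equal(total_applied_mass(pa), 57.6)
  zero <- exposure_scenario(50, 360, 0, 0.270)
  expect_equal(total_applied_mass(zero), 0)
})

test_that("deposition fraction matches and is scale-invariant", {
  expect_equal(round(deposition_fraction(4.2, 77.76), 1), 5.4)
  expect_equal(round(deposition_fraction(3.8, 57.6), 1), 6.6)
  expect_equal(deposition_fraction(0, 57.6), 0)
  expect_equal(deposition_fraction(4.2 * 7, 77.76 * 7),
               deposition_fraction(4.2, 77.76))
  expect_error(deposition_fraction(1, 0), "applied")
})

test_that("two-point clearance is the closed form; halving gives t1/2", {
  cf <- clearance_fit(data.frame(day = c(0, 46), burden = c(4.2, 2.1)))
  expect_equal(cf$phases$half_time_days, 46)
  expect_equal(cf$n0, 4.2)
  # published group means: 0.42 -> 0.26 ng/(100 um)^3 over 35 days
  cf2 <- clearance_fit(data.frame(day = c(0, 35), burden = c(0.42, 0.26)))
  expect_equal(cf2$phases$half_time_days, 35 * log(2) / log(0.42 / 0.26))
  expect_equal(cf2$phases$half_time_days, 50.59, tolerance = 1e-3)
})

test_that("biphasic fits recover generator half-times exactly at zero noise", {
  days <- c(0, 35, 91)
  burden <- clearance_curve(3.8, biphasic_phases(), days)
  cf <- clearance_fit(data.frame(day = days, burden = burden),
                      phase_boundaries = 35)
  expect_equal(cf$phases$half_time_days, c(68, 226))
  expect_equal(cf$phases$start_day, c(0, 35))
  # continuity at the boundary: both phases share the boundary observation
  expect_equal(cf$phases$end_day[1], cf$phases$start_day[2])
})

test_that("t1/2 * lambda = ln 2 for every fitted phase", {
  set.seed(21)
  for (i in 1:20) {
    n0 <- runif(1, 1, 10)
    t12 <- runif(2, 20, 300)
    days <- sort(c(0, 35, sample(40:120, 1)))
    ph <- data.frame(end_day = c(35, Inf), half_time = t12)
    obs <- data.frame(day = days,
                      burden = clearance_curve(n0, ph, days) *
                        exp(rnorm(3, 0, 0.05)))
    cf <- suppressWarnings(clearance_fit(obs, phase_boundaries = 35))
    expect_equal(cf$phases$half_time_days * cf$phases$lambda_per_day,
                 rep(log(2), 2))
  }
})

test_that("log-linear regression is used with more than two points", {
  ph <- data.frame(end_day = Inf, half_time = 68)
  days <- c(0, 7, 14, 28, 35)
  obs <- data.frame(day = days, burden = clearance_curve(3.8, ph, days))
  cf <- clearance_fit(obs)
  expect_equal(cf$phases$half_time_days, 68, tolerance = 1e-9)
})

test_that("increasing burdens warn of growth rather than clearance", {
  expect_warning(cf <- clearance_fit(data.frame(day = c(0, 35),
                                                burden = c(2.95, 126.29))),
                 "growth")
  expect_lt(cf$phases$lambda_per_day, 0)
  expect_error(clearance_fit(data.frame(day = 0, burden = 1)), "2 timepoints")
  expect_error(clearance_fit(data.frame(day = c(0, 1), burden = c(1, -1))),
               "> 0")
})

test_that("noisy per-animal time courses recover both half-times", {
  # 5 animals per timepoint, CV 0.3; median fitted half-times over 200
  # seeds within 15% of truth
  fit_one <- function(s) {
    spec <- burden_timecourse_spec(3.8, biphasic_phases(), cv = 0.3,
                                   sampling_days = c(0, 35, 91),
                                   n_animals = 5, seed = s)
    tc <- generate_burden_timecourse(spec)
    means <- aggregate(burden_mg ~ day, tc, mean)
    names(means)[2] <- "burden"
    suppressWarnings(
      clearance_fit(means, phase_boundaries = 35))$phases$half_time_days
  }
  # individual slow-phase fits can have negative clearance constants at
  # this noise level, so the median is taken on lambda and converted
  fits <- vapply(1:200, fit_one, numeric(2))
  med <- log(2) / apply(log(2) / fits, 1, median)
  expect_lt(abs(med[1] - 68) / 68, 0.15)
  expect_lt(abs(med[2] - 226) / 226, 0.15)
})

test_that("overload check uses a strict 1 mg/g threshold", {
  expect_true(overload_check(4.2, 1.63)$overload)    # 2.58 mg/g
  expect_equal(overload_check(4.2, 1.63)$ratio_mg_g, 4.2 / 1.63)
  expect_false(overload_check(0.26, 0.91)$overload)  # 0.29 mg/g
  expect_false(overload_check(1.0, 1.0)$overload)    # boundary
  expect_error(overload_check(1, 0), "weight")
})
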