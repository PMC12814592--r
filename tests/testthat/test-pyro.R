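# Calibration, organ back-calculation, detection limits, spike recovery.

test_that("calibration fits an exact line exactly", {
  cv <- fit_calibration(c(10, 50, 100, 500), 2 * c(10, 50, 100, 500))
  expect_equal(cv$slope, 2)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$residual_sd, 0, tolerance = 1e-10)
  expect_error(fit_calibration(c(10, 10, 10), c(1, 2, 3)), "distinct")
})

test_that("the stock dilution series reproduces the printed standards", {
  # 62 mg / 25 mL stock, 50 uL into 10 mL, 3-300 uL pipetted (lung series)
  expect_equal(dilution_series_mass(62, 25, 50, 10, 3), 37.2)
  expect_equal(dilution_series_mass(62, 25, 50, 10, 300), 3720)
  # 49 mg stock, 2-115 uL (lymph-node series)
  expect_equal(dilution_series_mass(49, 25, 50, 10, 2), 19.6)
  expect_equal(dilution_series_mass(49, 25, 50, 10, 115), 1127)
})

test_that("organ back-calculation applies the dilution factor", {
  cv <- fit_calibration(c(37, 370, 3700), 2 * c(37, 370, 3700))
  # crucible mass 190 ng, 20 uL of 20 mL -> factor 1000 -> 190 ug/organ
  q <- quantify_organ(2 * 190, cv, aliquot_ul = 20, extract_ml = 20)
  expect_equal(q$dilution_factor, 1000)
  expect_equal(q$organ_mass_ug, 190)
  # per-gram values as printed: 3.8 mg / 1.05 g and 0.26 mg / 0.91 g
  q2 <- quantify_organ(2 * 3800, cv, 20, 20, organ_weight_g = 1.05)
  expect_equal(q2$organ_mass_mg, 3.8)
  expect_equal(round(q2$mass_per_g_mg, 1), 3.6)
  q3 <- quantify_organ(2 * 260, cv, 20, 20, organ_weight_g = 0.91)
  expect_equal(round(q3$mass_per_g_mg, 1), 0.3)
  # doubling the extract volume doubles the organ mass
  q4 <- quantify_organ(2 * 190, cv, 20, 40)
  expect_equal(q4$organ_mass_ug, 2 * q$organ_mass_ug)
  # areas below the intercept report 0, flagged
  cvb <- fit_calibration(c(37, 370, 3700), 10 + 2 * c(37, 370, 3700))
  qb <- quantify_organ(5, cvb, 20, 20)
  expect_true(qb$below_range)
  expect_equal(qb$organ_mass_ug, 0)
  expect_error(quantify_organ(100, cv, 0, 20), "aliquot")
})

test_that("detection limits reproduce the lymph-node values", {
  masses <- c(20, 100, 500, 1140)
  cv <- fit_calibration(masses, 3 * masses)
  dl <- detection_limits(cv, dilution_factor = 75)
  expect_equal(dl$loq_ug, 1.5)
  expect_equal(dl$lod_ug, 1.2)   # 20% subtraction at the lowest mass
  expect_lte(dl$lod_ug, dl$loq_ug)
  # zero replicate SD collapses LOD onto LOQ
  cv0 <- fit_calibration(rep(masses, each = 3), 3 * rep(masses, each = 3))
  expect_warning(dl0 <- detection_limits(cv0, 75, k = 3), "SD")
  expect_equal(dl0$lod_ug, dl0$loq_ug)
})

test_that("LOD <= LOQ across random noisy calibrations", {
  for (s in 1:20) {
    run <- generate_pyro_run(rep(c(20, 100, 500, 1140), each = 4),
                             slope = 2, intercept = 1, noise_sd = 5,
                             seed = s)
    cv <- fit_calibration(run$true_mass_ng, run$peak_area)
    dl <- detection_limits(cv, 75, k = 3)
    expect_lte(dl$lod_ug, dl$loq_ug)
  }
})

test_that("spike recovery arithmetic", {
  expect_equal(spike_recovery(100, 100), 100)
  expect_equal(spike_recovery(163, 100, endogenous_ug = 100), 63)
  expect_error(spike_recovery(100, 0), "spiked")
})

test_that("calibration round trip: bias vanishes with noise", {
  masses <- seq(37, 3700, length.out = 8)
  truth <- c(150, 900, 2500)
  bias_at <- function(noise_sd) {
    rel <- replicate(30, {
      s <- sample.int(1e6, 1)
      cal <- generate_pyro_run(masses, 2.2, 8, noise_sd, seed = s)
      cv <- fit_calibration(cal$true_mass_ng, cal$peak_area)
      smp <- generate_pyro_run(truth, 2.2, 8, noise_sd, seed = s + 1)
      est <- (smp$peak_area - cv$intercept) / cv$slope
      mean((est - truth) / truth)
    })
    abs(mean(rel))
  }
  set.seed(99)
  b_hi <- bias_at(40)
  b_lo <- bias_at(4)
  expect_lt(b_lo, 0.01)
  expect_lt(b_lo, b_hi + 0.01)
})

test_that("censored burdens are reported as <LOD, not zero", {
  cz <- censor_below_lod(c(0.5, 2, 3), lod_ug = 1.2)
  expect_equal(cz$censored, c(TRUE, FALSE, FALSE))
  expect_equal(cz$display[1], "<LOD")
  expect_equal(cz$mean_ug, mean(c(0.6, 2, 3)))
  ce <- censor_below_lod(c(0.5, 2, 3), 1.2, substitute = "exclude")
  expect_equal(ce$mean_ug, 2.5)
})
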