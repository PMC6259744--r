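test_that("noiseless calibration standards lie exactly on the detector line", {
  std <- simulate_calibration(levels = 5, conc_range = c(1, 5), slope = 10,
                              intercept = 0, noise_sd_frac = 0)
  expect_equal(std$concentration, 1:5)
  expect_equal(std$peak_area, c(10, 20, 30, 40, 50))
})

test_that("default calibration grid follows the published dilution ratios", {
  std <- simulate_calibration(noise_sd_frac = 0)
  expect_equal(nrow(std), 5L)
  expect_equal(std$concentration / std$concentration[1], c(1, 4, 7, 10, 13),
               tolerance = 1e-12)
  # 0.1 mL of the 8 mg / 5 mL FA stock into 10 mL
  expect_equal(std$concentration[1], 8 / 452.20105 / 5 * 1e6 * 0.1 / 10,
               tolerance = 1e-12)
})

test_that("seeded generators are reproducible and respect differing seeds", {
  a <- simulate_calibration(seed = 11)
  b <- simulate_calibration(seed = 11)
  c <- simulate_calibration(seed = 12)
  expect_identical(a$peak_area, b$peak_area)
  expect_false(identical(a$peak_area, c$peak_area))

  cal <- exact_curve()
  es <- fa_esters()[["FA-21-Ac"]]
  t1 <- simulate_time_course(es, calibration = cal, seed = 7)
  t2 <- simulate_time_course(es, calibration = cal, seed = 7)
  expect_identical(t1$fa_peak_area, t2$fa_peak_area)

  a1 <- simulate_activity(c(0.01, 0.05), c(3, 4), seed = 3)
  a2 <- simulate_activity(c(0.01, 0.05), c(3, 4), seed = 3)
  expect_identical(a1$edema_reduction, a2$edema_reduction)

  # the caller's RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_calibration(seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("invalid simulation designs are rejected with classed errors", {
  expect_error(simulate_calibration(levels = 1), class = "esterkin_design_error")
  expect_error(simulate_calibration(slope = 0), class = "esterkin_design_error")
  expect_error(simulate_calibration(noise_sd_frac = -0.1),
               class = "esterkin_validation_error")
  cal <- exact_curve()
  no_k <- ester_record("X", molar_mass = 500, initial_mass = 10, volume = 100)
  expect_error(simulate_time_course(no_k, calibration = cal),
               class = "esterkin_configuration_error")
  es <- fa_esters()[["FA-21-Ac"]]
  expect_error(simulate_time_course(es, calibration = NULL),
               class = "esterkin_configuration_error")
  expect_error(simulate_time_course(es, times = c(2, 4), calibration = cal),
               class = "esterkin_validation_error")
  expect_error(simulate_time_course(es, times = c(0, 4, 4), calibration = cal),
               class = "esterkin_validation_error")
  expect_error(simulate_activity(c(0.1, 0.2), 3),
               class = "esterkin_dimension_error")
})

test_that("noiseless time courses keep molar mass balance and monotone FA", {
  cal <- exact_curve(slope = 17.3, intercept = 4.2)
  for (es in fa_esters()) {
    tc <- simulate_time_course(es, calibration = cal, noise_sd_frac = 0)
    truth <- attr(tc, "truth")
    c0 <- attr(tc, "c0")
    expect_equal(truth$c_ester + truth$c_fa, rep(c0, length(tc$time_h)),
                 tolerance = 1e-14)
    expect_true(all(diff(tc$fa_peak_area) >= 0))
  }
  # no decay: areas stay at the zero-concentration response
  frozen <- ester_record("frozen", molar_mass = 500, initial_mass = 10,
                         volume = 100, true_K = 0)
  tc0 <- simulate_time_course(frozen, calibration = cal, noise_sd_frac = 0)
  expect_equal(tc0$fa_peak_area, rep(cal$intercept, 6), tolerance = 1e-12)
})

test_that("24 h conversion matches the closed-form exponential for the fastest ester", {
  es <- fa_esters()[["FA-21-Ac"]]
  expect_equal(es$true_K, 0.0615)
  cal <- exact_curve()
  tc <- simulate_time_course(es, calibration = cal, noise_sd_frac = 0)
  frac <- attr(tc, "truth")$c_fa / attr(tc, "c0")
  expect_equal(frac[length(frac)], 1 - exp(-0.0615 * 24), tolerance = 1e-12)
})

test_that("initial concentration follows from the weighed mass", {
  es <- fa_esters()[["FA-21-Ac"]]
  expect_equal(es$initial_mass, 16)  # mg into 100 mL
  expect_equal(initial_concentration(es), 16 / 494.21162 / 100 * 1e6,
               tolerance = 1e-12)
  expect_error(ester_record("bad", molar_mass = 400, fa_molar_mass = 452.2,
                            initial_mass = 16, volume = 100),
               class = "esterkin_validation_error")
})

test_that("activity generator: arithmetic, clipping, determinism of the mean", {
  one <- simulate_activity(0.01, 3, coeffs = c(10, 300, 5), noise_sd = 0)
  expect_equal(one$edema_reduction, 28)
  high <- simulate_activity(0.1, 20, coeffs = c(10, 300, 5), noise_sd = 0)
  expect_equal(high$edema_reduction, 100)  # 140 clipped to the bound
  low <- simulate_activity(0, 0, coeffs = c(-5, 0, 0), noise_sd = 0)
  expect_equal(low$edema_reduction, 0)
})
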