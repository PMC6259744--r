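# Shared fixtures built in code.

study_times <- c(0, 2, 4, 6, 8, 24)

# A concentration series on the exact first-order law, bypassing detector noise.
noiseless_series <- function(K, c0 = 300, times = study_times) {
  c_ester <- c0 * exp(-K * times)
  suppressWarnings(ester_concentration(c_fa = c0 - c_ester, c0 = c0,
                                       times = times))
}

# Simulate one ester end to end (areas -> quantitation -> mass balance).
simulated_series <- function(ester, curve, noise_sd_frac, seed,
                             times = study_times) {
  tc <- simulate_time_course(ester, times = times, calibration = curve,
                             noise_sd_frac = noise_sd_frac, seed = seed)
  suppressWarnings(ester_concentration(
    quantify_fa(tc$fa_peak_area, curve),
    c0 = initial_concentration(ester), times = tc$time_h))
}

exact_curve <- function(slope = 25, intercept = 0)
  fit_calibration(simulate_calibration(slope = slope, intercept = intercept,
                                       noise_sd_frac = 0))
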