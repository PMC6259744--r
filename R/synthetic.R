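# Synthetic-data generators emulating the solvolysis protocol: HPLC
# calibration standards, first-order FA-release time courses read out as
# peak areas, and a linear anti-inflammatory activity generator.

# Evaluate code under a temporary RNG state so seeded simulations are
# reproducible without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    ek_stop("'seed' must be a single integer or NULL",
            "esterkin_validation_error")
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# FA calibration stock: 8 mg FA in 5 mL ethanol, in umol/L.
fa_stock_conc <- function() 8 / 452.20105 / 5 * 1e6

#' Simulate HPLC calibration standards
#'
#' Generates fluocinolone acetonide calibration standards with peak areas on
#' a straight detector line plus multiplicative Gaussian noise
#' (`sd = noise_sd_frac * signal`). The default concentration grid follows
#' the published dilution scheme — aliquots of 0.1, 0.4, 0.7, 1 and 1.3 mL
#' of an 8 mg / 5 mL FA stock made up to 10 mL — so five default levels sit
#' at the printed 0.1 : 0.4 : 0.7 : 1 : 1.3 ratios.
#'
#' @param levels number of standards (>= 2).
#' @param conc_range length-2 concentration interval (µmol/L) spanned
#'   evenly by the standards; defaults to the dilution scheme above.
#' @param slope true detector response (area units per µmol/L, > 0).
#' @param intercept true detector offset (area units).
#' @param noise_sd_frac noise standard deviation as a fraction of the
#'   noise-free signal; 0 gives an exact line.
#' @param seed integer seed for reproducibility, or `NULL` to use the
#'   current RNG stream.
#' @return A `data.frame` of class `calibration_standards` with columns
#'   `concentration` (µmol/L) and `peak_area`.
#' @seealso [fit_calibration()]
#' @export
#' @examples
#' std <- simulate_calibration(noise_sd_frac = 0, slope = 10, intercept = 0)
#' fit_calibration(std)
simulate_calibration <- function(levels = 5, conc_range = NULL, slope = 25,
                                 intercept = 0, noise_sd_frac = 0.01,
                                 seed = NULL) {
  if (!is.numeric(levels) || length(levels) != 1L || levels < 2)
    ek_stop("'levels' must be >= 2", "esterkin_design_error")
  stopifnot_scalar_number(slope, "slope")
  if (slope <= 0)
    ek_stop("'slope' must be > 0 (detector response)", "esterkin_design_error")
  stopifnot_scalar_number(intercept, "intercept")
  stopifnot_scalar_number(noise_sd_frac, "noise_sd_frac", nonnegative = TRUE)
  if (is.null(conc_range))
    conc_range <- fa_stock_conc() * c(0.1, 1.3) / 10
  if (!is.numeric(conc_range) || length(conc_range) != 2L ||
      conc_range[1] < 0 || conc_range[2] <= conc_range[1])
    ek_stop("'conc_range' must be an increasing non-negative interval",
            "esterkin_design_error")
  conc <- seq(conc_range[1], conc_range[2], length.out = levels)
  mu <- slope * conc + intercept
  area <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd_frac * abs(mu)))
  out <- data.frame(concentration = conc, peak_area = area)
  class(out) <- c("calibration_standards", "data.frame")
  attr(out, "generator") <- list(slope = slope, intercept = intercept,
                                 noise_sd_frac = noise_sd_frac, seed = seed)
  out
}

#' Simulate a solvolysis time course read out as FA peak areas
#'
#' The ester decays first-order, `c_ester(t) = c0 * exp(-true_K * t)`, with
#' c0 computed from the weighed mass, molar mass and volume; the liberated
#' FA concentration is `c0 - c_ester(t)` (exact molar mass balance). FA is
#' converted to a detector peak area through the calibration line and
#' perturbed by multiplicative Gaussian noise.
#'
#' @param ester an [ester_record()] with `true_K` set.
#' @param times sampling times in hours; strictly increasing, starting at 0.
#'   Defaults to the published schedule 0, 2, 4, 6, 8, 24 h.
#' @param calibration a [fit_calibration()] curve, or any list with `slope`
#'   and `intercept`, defining the area/concentration line.
#' @param noise_sd_frac multiplicative noise fraction on peak areas.
#' @param seed integer seed, or `NULL`.
#' @return A `data.frame` of class `time_course` with columns `time_h` and
#'   `fa_peak_area`; attributes `ester`, `c0` (µmol/L) and `truth` (the
#'   noise-free molar series, used by recovery tests).
#' @export
#' @examples
#' cal <- fit_calibration(simulate_calibration(noise_sd_frac = 0))
#' ac <- fa_esters()[["FA-21-Ac"]]
#' simulate_time_course(ac, calibration = cal, noise_sd_frac = 0)
simulate_time_course <- function(ester, times = c(0, 2, 4, 6, 8, 24),
                                 calibration, noise_sd_frac = 0.01,
                                 seed = NULL) {
  if (!inherits(ester, "ester_record"))
    ek_stop("'ester' must be an ester_record", "esterkin_validation_error")
  if (is.na(ester$true_K))
    ek_stop(sprintf("ester '%s' has no true_K; set one to simulate", ester$name),
            "esterkin_configuration_error")
  if (missing(calibration) || is.null(calibration))
    ek_stop("a calibration curve is required to convert FA concentration to peak area",
            "esterkin_configuration_error")
  if (!is.numeric(calibration$slope) || !is.numeric(calibration$intercept))
    ek_stop("'calibration' must carry numeric 'slope' and 'intercept'",
            "esterkin_configuration_error")
  validate_times(times)
  stopifnot_scalar_number(noise_sd_frac, "noise_sd_frac", nonnegative = TRUE)

  c0 <- initial_concentration(ester)
  c_ester <- c0 * exp(-ester$true_K * times)
  c_fa <- c0 - c_ester
  mu <- calibration$slope * c_fa + calibration$intercept
  area <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd_frac * abs(mu)))
  out <- data.frame(time_h = times, fa_peak_area = area)
  class(out) <- c("time_course", "data.frame")
  attr(out, "ester") <- ester
  attr(out, "c0") <- c0
  attr(out, "truth") <- list(c_ester = c_ester, c_fa = c_fa)
  attr(out, "noise_sd_frac") <- noise_sd_frac
  out
}

validate_times <- function(times) {
  if (!is.numeric(times) || length(times) < 2L || anyNA(times))
    ek_stop("'times' must be a numeric vector of length >= 2",
            "esterkin_validation_error")
  if (times[1] != 0)
    ek_stop("'times' must start at 0 (the freshly prepared mixture)",
            "esterkin_validation_error")
  if (any(diff(times) <= 0))
    ek_stop("'times' must be strictly increasing", "esterkin_validation_error")
  invisible(times)
}

#' Simulate anti-inflammatory activity from rate constant and lipophilicity
#'
#' Generates percent edema reduction on the linear model
#' `activity = b0 + b1 * K + b2 * cLogP + noise`, clipped to `[0, 100]`.
#' The linear structure mirrors the activity-versus-(K, cLogP) multiple
#' regression of the study; the coefficients themselves are generator
#' settings, since the underlying animal-assay activities are published
#' elsewhere and are not part of this package.
#'
#' @param K per-hour solvolytic rate constants.
#' @param clogp cLogP values, same length as `K`.
#' @param coeffs generator coefficients `c(b0, b_K, b_cLogP)`.
#' @param noise_sd Gaussian noise standard deviation, in percent units.
#' @param seed integer seed, or `NULL`.
#' @param esters optional ester names for the output.
#' @return A `data.frame` of class `activity_records` with columns `ester`,
#'   `K`, `cLogP` and `edema_reduction` (percent, in `[0, 100]`).
#' @seealso [fit_mlr()]
#' @export
#' @examples
#' t1 <- load_table1()
#' simulate_activity(t1$K, t1$esters$cLogP, noise_sd = 0)
simulate_activity <- function(K, clogp, coeffs = c(30, 350, 5), noise_sd = 5,
                              seed = NULL, esters = names(K)) {
  if (length(K) != length(clogp))
    ek_stop(sprintf("'K' (length %d) and 'clogp' (length %d) must have equal length",
                    length(K), length(clogp)), "esterkin_dimension_error")
  if (!is.numeric(coeffs) || length(coeffs) != 3L)
    ek_stop("'coeffs' must be c(b0, b_K, b_cLogP)", "esterkin_validation_error")
  stopifnot_scalar_number(noise_sd, "noise_sd", nonnegative = TRUE)
  mu <- coeffs[1] + coeffs[2] * K + coeffs[3] * clogp
  act <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  act <- pmin(pmax(act, 0), 100)
  if (is.null(esters)) esters <- paste0("ester", seq_along(K))
  out <- data.frame(ester = esters, K = as.numeric(K),
                    cLogP = as.numeric(clogp), edema_reduction = act)
  class(out) <- c("activity_records", "data.frame")
  attr(out, "generator") <- list(coeffs = coeffs, noise_sd = noise_sd,
                                 seed = seed)
  out
}
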