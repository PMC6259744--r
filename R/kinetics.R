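# Kinetics stage: calibration, FA quantitation, the ester mass-balance
# c(t) = c(0) - c_FA(t), and the pseudo-first-order fit of ln c versus t.

# Straight-line OLS from first principles. Returns every statistic the QSPR
# stage reports; with n = 2 the error statistics are NaN (0 residual df).
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  dx <- x - mx; dy <- y - my
  sxx <- sum(dx * dx)
  if (sxx == 0)
    ek_stop("predictor is constant: straight-line fit is singular",
            "esterkin_singular_error")
  slope <- sum(dx * dy) / sxx
  intercept <- my - slope * mx
  fitted <- intercept + slope * x
  res <- y - fitted
  sse <- sum(res * res)
  ssr <- slope^2 * sxx
  mse <- if (n > 2) sse / (n - 2) else NaN
  syy <- sum(dy * dy)
  r <- if (syy == 0) NA_real_ else sum(dx * dy) / sqrt(sxx * syy)
  list(slope = slope, intercept = intercept,
       se_slope = sqrt(mse / sxx),
       se_intercept = sqrt(mse * (1 / n + mx^2 / sxx)),
       se_est = sqrt(mse),
       r = r, F = ssr / mse, df = c(1L, n - 2L), n = n,
       fitted = fitted, residuals = res)
}

#' Fit an HPLC calibration line
#'
#' Ordinary least squares of peak area on FA concentration, with a free
#' intercept. Two standards define the line exactly; the correlation of the
#' fit is reported alongside.
#'
#' @param standards a `data.frame` with columns `concentration` (µmol/L)
#'   and `peak_area`, e.g. from [simulate_calibration()].
#' @return An object of class `calibration_curve`: `slope` (area per
#'   µmol/L), `intercept` (area), `r`, `n`.
#' @seealso [quantify_fa()] for the inverse use of the curve.
#' @export
#' @examples
#' fit_calibration(data.frame(concentration = 1:3, peak_area = c(10, 20, 30)))
fit_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("concentration", "peak_area") %in% names(standards)))
    ek_stop("'standards' needs columns 'concentration' and 'peak_area'",
            "esterkin_schema_error")
  x <- as.numeric(standards$concentration)
  y <- as.numeric(standards$peak_area)
  if (length(unique(x)) < 2L)
    ek_stop("need >= 2 standards with distinct concentrations",
            "esterkin_singular_error")
  fit <- ols_line(x, y)
  structure(list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
                 n = fit$n),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> area = %.6g * conc + %.6g  (r = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Convert FA peak areas to concentrations
#'
#' Inverts the calibration line: `concentration = (area - intercept) /
#' slope`. Negative results (possible under noise near zero concentration)
#' are floored at 0 with a warning.
#'
#' @param peak_areas numeric vector of detector peak areas.
#' @param curve a [fit_calibration()] curve.
#' @return FA concentrations (µmol/L).
#' @export
quantify_fa <- function(peak_areas, curve) {
  if (!is.numeric(curve$slope) || curve$slope == 0)
    ek_stop("calibration slope must be non-zero", "esterkin_singular_error")
  conc <- (as.numeric(peak_areas) - curve$intercept) / curve$slope
  neg <- conc < 0
  if (any(neg)) {
    ek_warn(sprintf("%d negative FA concentration(s) floored at 0", sum(neg)),
            "esterkin_clip_warning")
    conc[neg] <- 0
  }
  conc
}

#' Ester concentration by mass balance
#'
#' Applies the mass balance `c_ester(t) = c0 - c_FA(t)` in molar units. FA
#' concentrations above c0 (possible under noise at late times) are clipped
#' to c0, so the ester concentration never goes negative; ester
#' concentrations below a small positive floor are set to the floor and
#' flagged, since they cannot enter a log fit. Both clips warn.
#'
#' @param c_fa liberated FA concentrations (µmol/L).
#' @param c0 initial ester concentration (µmol/L, > 0).
#' @param times optional sampling times (hours) carried along for the rate
#'   fit; validated if given.
#' @param floor_frac the floor as a fraction of c0 (default 1e-9).
#' @return An object of class `concentration_series`: `times`, `c_ester`,
#'   `c_fa`, `c0`, `floored` (logical, points at the floor).
#' @seealso [fit_rate_constant()], [solvolysis_percentage()]
#' @export
#' @examples
#' ester_concentration(c_fa = c(0, 3), c0 = 10, times = c(0, 2))$c_ester
ester_concentration <- function(c_fa, c0, times = NULL, floor_frac = 1e-9) {
  stopifnot_scalar_number(c0, "c0", positive = TRUE)
  stopifnot_scalar_number(floor_frac, "floor_frac", positive = TRUE)
  c_fa <- as.numeric(c_fa)
  if (!is.null(times)) {
    if (length(times) != length(c_fa))
      ek_stop("'times' and 'c_fa' must have equal length",
              "esterkin_dimension_error")
    if (any(diff(times) <= 0))
      ek_stop("'times' must be strictly increasing", "esterkin_validation_error")
  }
  over <- c_fa > c0
  if (any(over)) {
    ek_warn(sprintf("%d FA concentration(s) above c0 clipped to c0", sum(over)),
            "esterkin_clip_warning")
    c_fa[over] <- c0
  }
  c_ester <- c0 - c_fa
  floor <- floor_frac * c0
  floored <- c_ester < floor
  if (any(floored)) {
    ek_warn(sprintf("%d ester concentration(s) below the floor (%.3g) excluded from log fits",
                    sum(floored), floor), "esterkin_clip_warning")
    c_ester[floored] <- floor
  }
  structure(list(times = times, c_ester = c_ester, c_fa = c_fa, c0 = c0,
                 floor = floor, floored = floored),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  cat(sprintf("<concentration_series> c0 = %.4g umol/L, %d points (%d at floor)\n",
              x$c0, length(x$c_ester), sum(x$floored)))
  if (!is.null(x$times))
    print(data.frame(time_h = x$times, c_ester = x$c_ester, c_fa = x$c_fa))
  invisible(x)
}

#' Fit a pseudo-first-order solvolytic rate constant
#'
#' Ordinary least squares of `ln(c_ester)` on time; the rate constant is
#' the negative slope. Points clipped to the concentration floor are
#' excluded (the log is not meaningful there) and counted; at least three
#' usable points are required. On noiseless first-order data the fit is
#' exact and `|r| = 1`.
#'
#' @param series a [ester_concentration()] series with `times` set.
#' @return An object of class `rate_fit`: `K` (1/h), `ln_intercept`, `r`
#'   (of ln c versus t), `n_points`, `n_excluded`, `residuals`, `fitted`
#'   (on the log scale) and the underlying times/log-concentrations.
#' @export
#' @examples
#' tt <- c(0, 2, 4, 6, 8, 24)
#' ce <- 300 * exp(-0.0615 * tt)
#' s <- ester_concentration(c_fa = 300 - ce, c0 = 300, times = tt)
#' fit_rate_constant(s)
fit_rate_constant <- function(series) {
  if (!inherits(series, "concentration_series"))
    ek_stop("'series' must come from ester_concentration()",
            "esterkin_validation_error")
  if (is.null(series$times))
    ek_stop("'series' carries no sampling times", "esterkin_validation_error")
  use <- !series$floored & series$c_ester > 0
  if (sum(use) < 3L)
    ek_stop(sprintf("only %d usable point(s); need >= 3 for a rate fit",
                    sum(use)), "esterkin_insufficient_data_error")
  t_use <- series$times[use]
  lnc <- log(series$c_ester[use])
  fit <- ols_line(t_use, lnc)
  K <- -fit$slope
  if (K < 0 && abs(K) < 1e-12) K <- 0
  structure(list(K = K, ln_intercept = fit$intercept, r = fit$r,
                 n_points = fit$n, n_excluded = sum(!use),
                 residuals = fit$residuals, fitted = fit$fitted,
                 times = t_use, ln_c = lnc, c0 = series$c0),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<rate_fit> K = %.*g 1/h  (r = %.4f, n = %d%s)\n",
              digits, x$K, x$r, x$n_points,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' @export
summary.rate_fit <- function(object, ...) {
  cat("Pseudo-first-order solvolysis fit (ln c vs t)\n")
  print(object)
  cat(sprintf("  ln c(0) = %.4f (c0 used: %.4g umol/L)\n",
              object$ln_intercept, object$c0))
  cat(sprintf("  half-life = %.3g h\n", log(2) / object$K))
  invisible(object)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(K = object$K, ln_intercept = object$ln_intercept)
}

#' @export
residuals.rate_fit <- function(object, ...) object$residuals

#' Predicted ester concentration from a rate fit
#'
#' @param object a [fit_rate_constant()] fit.
#' @param times hours at which to predict; defaults to the fitted times.
#' @param ... unused.
#' @return Ester concentrations `exp(ln_intercept - K * t)` (µmol/L).
#' @export
predict.rate_fit <- function(object, times = object$times, ...) {
  exp(object$ln_intercept - object$K * times)
}

#' @export
plot.rate_fit <- function(x, ...) {
  graphics::plot(x$times, x$ln_c, xlab = "time (h)",
                 ylab = "ln c(ester)", pch = 19, ...)
  graphics::abline(a = x$ln_intercept, b = -x$K)
  invisible(x)
}

#' Percentage of ester solvolysed
#'
#' `100 * (c0 - c_ester(t)) / c0` for each point of a concentration series.
#'
#' @param series a [ester_concentration()] series.
#' @return Percent solvolysed per time point.
#' @export
solvolysis_percentage <- function(series) {
  if (!inherits(series, "concentration_series"))
    ek_stop("'series' must come from ester_concentration()",
            "esterkin_validation_error")
  100 * (series$c0 - series$c_ester) / series$c0
}
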