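# QSPR stage: Pearson screen of every descriptor against the rate
# constants, the single-descriptor OLS line with its full statistics, and
# the activity-versus-(K, cLogP) multiple regression. The OLS internals are
# written out from the normal equations so that every reported statistic
# (slopes, their standard errors, SE of estimate, F) is explicit.

#' Pearson product-moment correlation
#'
#' Computed directly from the covariance definition,
#' `sum((x - mean(x)) * (y - mean(y))) / sqrt(Sxx * Syy)`.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' pearson_r(1:6, c(2, 4, 5, 4, 5, 7))
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    ek_stop("'x' and 'y' must be numeric vectors of equal length",
            "esterkin_dimension_error")
  if (length(x) < 3L)
    ek_stop("need at least 3 observations", "esterkin_insufficient_data_error")
  if (anyNA(x) || anyNA(y))
    ek_stop("missing values not allowed", "esterkin_validation_error")
  dx <- x - mean(x); dy <- y - mean(y)
  sxx <- sum(dx * dx); syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0)
    ek_stop("correlation undefined for a constant vector",
            "esterkin_correlation_error")
  sum(dx * dy) / sqrt(sxx * syy)
}

#' Correlation-screen descriptors against rate constants
#'
#' Computes the Pearson correlation of every descriptor row of the table
#' with the rate-constant vector and ranks descriptors by `|r|` (ties
#' broken by label, for determinism). Rows flagged in the table (derived
#' from annotated typo cells) are kept in the report but marked, and a
#' warning notes their presence.
#'
#' @param table a [build_descriptor_table()] table.
#' @param k named or unnamed per-ester rate constants (1/h), in the
#'   table's ester order; if named, names must match the table's esters.
#' @return A `data.frame` of class `descriptor_screen` with columns
#'   `descriptor`, `level`, `quantity`, `r`, `n`, `flagged`, `rank`,
#'   ordered by decreasing `|r|`.
#' @export
#' @examples
#' t1 <- load_table1()
#' d <- build_descriptor_table(t1$charges, t1$geometry,
#'                             steric = t1$esters$steric_hindrance,
#'                             clogp = t1$esters$cLogP)
#' head(screen_descriptors(d, t1$K))
screen_descriptors <- function(table, k) {
  if (!inherits(table, "descriptor_table"))
    ek_stop("'table' must come from build_descriptor_table()",
            "esterkin_validation_error")
  esters <- attr(table, "esters")
  if (length(k) != length(esters))
    ek_stop(sprintf("'k' has length %d but the table covers %d esters",
                    length(k), length(esters)), "esterkin_alignment_error")
  if (!is.null(names(k)) && !identical(names(k), esters))
    ek_stop(paste0("'k' names do not match the table's ester order: ",
                   paste(esters, collapse = ", ")),
            "esterkin_alignment_error")
  vals <- as.matrix(as.data.frame(table)[, esters, drop = FALSE])
  r <- apply(vals, 1L, pearson_r, y = as.numeric(k))
  out <- data.frame(
    descriptor = ifelse(table$level == "global", table$quantity,
                        paste(table$level, table$quantity)),
    level = table$level, quantity = table$quantity,
    r = r, n = length(esters), flagged = table$flagged,
    stringsAsFactors = FALSE
  )
  out <- out[order(-abs(out$r), out$descriptor), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (any(out$flagged))
    ek_warn(sprintf("%d screened descriptor row(s) derive from typo-flagged cells",
                    sum(out$flagged)), "esterkin_flagged_cell_warning")
  class(out) <- c("descriptor_screen", "data.frame")
  out
}

#' @export
print.descriptor_screen <- function(x, n = 10, ...) {
  cat(sprintf("<descriptor_screen> %d descriptors vs K (n = %d); top %d by |r|:\n",
              nrow(x), x$n[1], min(n, nrow(x))))
  shown <- utils::head(as.data.frame(x)[, c("rank", "descriptor", "r", "flagged")], n)
  shown$r <- round(shown$r, 4)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Single linear regression with full OLS statistics
#'
#' Fits `y = intercept + slope * x` by ordinary least squares and reports
#' the statistics of the classical straight-line analysis: standard errors
#' of both coefficients (`se_slope = sqrt(MSE/Sxx)`, `se_intercept =
#' sqrt(MSE * (1/n + mean(x)^2/Sxx))`), the correlation `r`, the standard
#' error of the estimate `sqrt(SSE/(n-2))` and the regression F statistic
#' `MSR/MSE` on (1, n-2) degrees of freedom.
#'
#' @param x predictor vector (non-constant, length >= 3).
#' @param y response vector, same length.
#' @param xname,yname labels used by the print method.
#' @return An object of class `slr_fit`.
#' @seealso [fit_mlr()]; [fit_rate_constant()] uses the same line fit on
#'   the log scale.
#' @export
#' @examples
#' t1 <- load_table1()
#' p <- as.numeric(t1$printed[t1$printed$level == "B3LYP/STO-3G COSMO ethanol" &
#'                            t1$printed$quantity == "P_C-O2",
#'                            names(t1$K)])
#' fit_slr(p, t1$K, xname = "P_C-O2", yname = "K")
fit_slr <- function(x, y, xname = deparse1(substitute(x)),
                    yname = deparse1(substitute(y))) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    ek_stop("'x' and 'y' must be numeric vectors of equal length",
            "esterkin_dimension_error")
  if (length(x) < 3L)
    ek_stop("need at least 3 observations for regression statistics",
            "esterkin_insufficient_data_error")
  fit <- ols_line(x, as.numeric(y))
  structure(c(fit, list(x = x, y = as.numeric(y), xname = xname,
                        yname = yname)),
            class = "slr_fit")
}

#' @export
print.slr_fit <- function(x, digits = 4, ...) {
  b <- x$intercept
  cat(sprintf("%s = (%.*f±%.*f) × %s %s (%.*f±%.*f)\n",
              x$yname, digits, x$slope, digits, x$se_slope, x$xname,
              if (b < 0) "−" else "+", digits, abs(b), digits,
              x$se_intercept))
  cat(sprintf("R = %.*f, SE = %.*f, F = %.3f  (df = %d, %d; n = %d)\n",
              digits, x$r, digits, x$se_est, x$F, x$df[1], x$df[2], x$n))
  invisible(x)
}

#' @export
summary.slr_fit <- function(object, ...) {
  print(object)
  tab <- data.frame(
    estimate = c(object$intercept, object$slope),
    std_error = c(object$se_intercept, object$se_slope),
    row.names = c("(Intercept)", object$xname)
  )
  tab$t_value <- tab$estimate / tab$std_error
  tab$p_value <- 2 * stats::pt(-abs(tab$t_value), df = object$df[2])
  print(tab)
  invisible(object)
}

#' @export
coef.slr_fit <- function(object, ...) {
  stats::setNames(c(object$intercept, object$slope),
                  c("(Intercept)", object$xname))
}

#' @export
residuals.slr_fit <- function(object, ...) object$residuals

#' Predict from a single-descriptor QSPR line
#'
#' @param object a [fit_slr()] model.
#' @param newdata predictor values; defaults to the fitted ones.
#' @param ... unused.
#' @return Predicted responses; the residual scale `se_est` is attached as
#'   an attribute for banding.
#' @export
predict.slr_fit <- function(object, newdata = object$x, ...) {
  if (!is.numeric(newdata))
    ek_stop("'newdata' must be numeric for a single-predictor model",
            "esterkin_schema_error")
  out <- object$intercept + object$slope * newdata
  attr(out, "se_est") <- object$se_est
  out
}

#' @export
plot.slr_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xname, ylab = x$yname, pch = 19, ...)
  graphics::abline(a = x$intercept, b = x$slope)
  invisible(x)
}

#' Multiple linear regression (activity on K and cLogP)
#'
#' Ordinary least squares with an intercept, solved by QR decomposition of
#' the design matrix. The multiple correlation coefficient is the
#' correlation between fitted and observed responses, equivalently
#' `sqrt(1 - SSE/SST)`.
#'
#' @param predictors matrix or `data.frame` of predictors with named
#'   columns (e.g. `K`, `cLogP`).
#' @param y response vector (e.g. percent edema reduction).
#' @return An object of class `mlr_fit`: `coefficients` (intercept first),
#'   `multiple_r`, `n`, `df_residual`, `fitted`, `residuals`, `se_est`.
#'   A warning is raised when only one residual degree of freedom remains.
#' @export
#' @examples
#' t1 <- load_table1()
#' act <- simulate_activity(t1$K, t1$esters$cLogP, noise_sd = 0)
#' fit_mlr(act[c("K", "cLogP")], act$edema_reduction)
fit_mlr <- function(predictors, y) {
  X0 <- as.matrix(as.data.frame(predictors))
  if (!is.numeric(X0))
    ek_stop("'predictors' must be numeric", "esterkin_validation_error")
  if (is.null(colnames(X0)))
    colnames(X0) <- paste0("x", seq_len(ncol(X0)))
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(X0) != n)
    ek_stop("'predictors' and 'y' must have matching rows",
            "esterkin_dimension_error")
  p <- ncol(X0) + 1L
  if (n <= p)
    ek_stop(sprintf("n = %d observations cannot identify %d coefficients",
                    n, p), "esterkin_insufficient_data_error")
  X <- cbind(`(Intercept)` = 1, X0)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    ek_stop(paste0("design matrix is rank deficient; collinear column(s): ",
                   paste(dropped, collapse = ", ")),
            "esterkin_singular_error")
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  df_res <- n - p
  if (df_res <= 1L)
    ek_warn(sprintf("only %d residual degree(s) of freedom; statistics are fragile",
                    df_res), "esterkin_df_warning")
  multiple_r <- if (sst == 0) NA_real_ else sqrt(max(0, 1 - sse / sst))
  structure(list(coefficients = beta, multiple_r = multiple_r, n = n,
                 df_residual = df_res, fitted = fitted, residuals = res,
                 se_est = sqrt(sse / max(df_res, 1L)),
                 xnames = colnames(X0), y = y),
            class = "mlr_fit")
}

#' @export
print.mlr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<mlr_fit> n = %d, multiple R = %.*f\n", x$n, digits,
              x$multiple_r))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
summary.mlr_fit <- function(object, ...) {
  print(object)
  cat(sprintf("residual SE = %.4g on %d df\n", object$se_est,
              object$df_residual))
  invisible(object)
}

#' @export
coef.mlr_fit <- function(object, ...) object$coefficients

#' @export
residuals.mlr_fit <- function(object, ...) object$residuals

#' Predict from a multiple regression fit
#'
#' @param object a [fit_mlr()] model.
#' @param newdata `data.frame` or matrix containing every predictor column
#'   of the fit; missing columns raise a schema error. Defaults to the
#'   fitted values.
#' @param ... unused.
#' @return Predicted responses.
#' @export
predict.mlr_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$xnames, names(nd))
  if (length(miss))
    ek_stop(paste0("newdata lacks predictor column(s): ",
                   paste(miss, collapse = ", ")), "esterkin_schema_error")
  X <- cbind(1, as.matrix(nd[object$xnames]))
  drop(X %*% object$coefficients)
}
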