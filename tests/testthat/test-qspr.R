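test_that("pearson_r matches the covariance-definition oracle and stats::cor", {
  brute <- function(x, y) {
    n <- length(x)
    cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
    cxy / (stats::sd(x) * stats::sd(y))
  }
  set.seed(7)
  for (i in 1:50) {
    x <- stats::rnorm(6); y <- stats::rnorm(6)
    expect_equal(pearson_r(x, y), brute(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(x, y), stats::cor(x, y), tolerance = 1e-12)
    expect_equal(pearson_r(x, y), pearson_r(y, x))
  }
  x <- stats::rnorm(8)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(rep(1, 5), 1:5), class = "esterkin_correlation_error")
  expect_error(pearson_r(1:2, 1:2), class = "esterkin_insufficient_data_error")
})

test_that("screen reproduces the headline printed correlations and ranking", {
  t1 <- load_table1()
  sc <- suppressWarnings(screen_descriptors(table1_descriptors(), t1$K))
  r_of <- function(lv, q) sc$r[sc$level == lv & sc$quantity == q]
  expect_equal(r_of("global", "d_C_O2"), 0.9627, tolerance = 0.002)
  expect_equal(r_of("AM1", "P_C-O2"), 0.9247, tolerance = 0.002)
  expect_equal(r_of("HF/6-31G CPCM ethanol", "C"), 0.9101, tolerance = 0.002)
  expect_equal(r_of("global", "cLogP"), 0.0533, tolerance = 0.002)
  expect_equal(sc$descriptor[1], "B3LYP/STO-3G COSMO ethanol P_C-O2")

  expect_error(screen_descriptors(table1_descriptors(), t1$K[1:3]),
               class = "esterkin_alignment_error")
  expect_error(screen_descriptors(table1_descriptors(), rev(t1$K)),
               class = "esterkin_alignment_error")
})

test_that("single linear regression is exact on exact lines", {
  fit <- fit_slr(1:5, 2 * (1:5) + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r, 1)
  expect_equal(fit$se_est, 0)
  expect_error(fit_slr(rep(3, 5), 1:5), class = "esterkin_singular_error")
  expect_error(fit_slr(1:2, 1:2), class = "esterkin_insufficient_data_error")
})

test_that("QSPR line on the printed best descriptor matches the publication", {
  t1 <- load_table1()
  d <- table1_descriptors()
  p <- as.numeric(as.data.frame(d)[d$level == "B3LYP/STO-3G COSMO ethanol" &
                                     d$quantity == "P_C-O2",
                                   attr(d, "esters")])
  fit <- fit_slr(p, unname(t1$K), xname = "P_C-O2", yname = "K")
  expect_equal(fit$slope, 2.5808, tolerance = 0.01)
  expect_equal(fit$intercept, -1.4658, tolerance = 0.01)
  expect_equal(fit$r, 0.9924, tolerance = 1e-3)
  out <- capture.output(print(fit))
  expect_match(out[1], "K = \\(2\\.58.*P_C-O2")
})

test_that("SLR statistics agree with the stats::lm oracle to 1e-10", {
  set.seed(11)
  for (i in 1:20) {
    x <- stats::rnorm(6); y <- stats::rnorm(6)
    mine <- fit_slr(x, y)
    ref <- stats::lm(y ~ x)
    s <- summary(ref)
    expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-10)
    expect_equal(mine$se_intercept, s$coefficients[1, 2], tolerance = 1e-10)
    expect_equal(mine$se_slope, s$coefficients[2, 2], tolerance = 1e-10)
    expect_equal(mine$se_est, s$sigma, tolerance = 1e-10)
    expect_equal(mine$F, unname(s$fstatistic[1]), tolerance = 1e-10)
    expect_equal(mine$r, stats::cor(x, y), tolerance = 1e-12)
  }
})

test_that("F equals the r-squared identity and residuals are orthogonal", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    fit <- fit_slr(x, y)
    expect_equal(fit$F, fit$r^2 / (1 - fit$r^2) * (n - 2),
                 tolerance = 1e-9)
    expect_lt(abs(sum(fit$residuals)), 1e-9)
    expect_lt(abs(sum(fit$residuals * x)), 1e-9)
  }
})

test_that("MLR inverts the noiseless activity generator and matches lm", {
  t1 <- load_table1()
  act <- simulate_activity(t1$K, t1$esters$cLogP, coeffs = c(10, 300, 5),
                           noise_sd = 0)
  fit <- fit_mlr(act[c("K", "cLogP")], act$edema_reduction)
  expect_equal(unname(coef(fit)), c(10, 300, 5), tolerance = 1e-8)
  expect_equal(fit$multiple_r, 1, tolerance = 1e-8)

  set.seed(31)
  X <- cbind(a = stats::rnorm(8), b = stats::rnorm(8))
  y <- stats::rnorm(8)
  mine <- fit_mlr(X, y)
  ref <- stats::lm(y ~ a + b, data = as.data.frame(X))
  expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(mine$multiple_r, sqrt(summary(ref)$r.squared),
               tolerance = 1e-10)
  expect_equal(mine$fitted + mine$residuals, y, tolerance = 1e-12)
})

test_that("null responses, rank deficiency and thin designs are handled", {
  # response orthogonal to intercept and both predictors: multiple R ~ 0
  set.seed(13)
  X <- cbind(a = stats::rnorm(6), b = stats::rnorm(6))
  y <- unname(stats::residuals(stats::lm(stats::rnorm(6) ~ X)))
  fit <- fit_mlr(X, y)
  expect_lt(fit$multiple_r, 1e-7)

  err <- tryCatch(fit_mlr(cbind(K = 1:6, K2 = 2 * (1:6)), stats::rnorm(6)),
                  error = identity)
  expect_s3_class(err, "esterkin_singular_error")
  expect_match(conditionMessage(err), "K2")

  expect_warning(fit_mlr(cbind(a = c(1, 2, 4, 8), b = c(1, 3, 2, 5)),
                         c(0.5, 2, 1, 4)),
                 class = "esterkin_df_warning")
  expect_error(fit_mlr(cbind(a = 1:2), 1:2),
               class = "esterkin_insufficient_data_error")
})

test_that("prediction is the linear evaluation, through the mean point", {
  # published coefficients evaluated at the COSMO polarity of FA-21-Ac
  eq2 <- structure(list(intercept = -1.4658, slope = 2.5808, se_est = 0.0035,
                        x = 0.59, xname = "P", yname = "K"),
                   class = "slr_fit")
  expect_equal(round(as.numeric(predict(eq2, 0.5911)), 4), 0.0597)

  set.seed(5)
  x <- stats::rnorm(6); y <- stats::rnorm(6)
  fit <- fit_slr(x, y)
  expect_equal(as.numeric(predict(fit, mean(x))), mean(y), tolerance = 1e-12)
  ident <- fit_slr(1:5, 1:5)
  expect_equal(as.numeric(predict(ident, c(-2, 0.5))), c(-2, 0.5))

  X <- cbind(K = c(0.01, 0.03, 0.05, 0.02, 0.06, 0.04),
             cLogP = c(3, 4, 2, 5, 3.5, 4.5))
  m <- fit_mlr(X, 10 + 100 * X[, 1] + 2 * X[, 2])
  expect_equal(unname(predict(m, data.frame(K = 0.02, cLogP = 3))),
               10 + 2 + 6, tolerance = 1e-8)
  expect_error(predict(m, data.frame(K = 0.02)),
               class = "esterkin_schema_error")
})
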