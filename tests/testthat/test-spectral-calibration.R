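test_that("Savitzky-Golay first derivative is exact on polynomials and accurate on sines", {
  nb <- 200
  wavenumber <- seq(4000, 4000 - 2 * (nb - 1), by = -2)
  mk <- function(rows) structure(
    list(sample_id = sprintf("s%d", seq_len(nrow(rows))),
         wavenumber = wavenumber, absorbance = rows,
         is_reference = rep(TRUE, nrow(rows)), analytes = character()),
    class = "spectra_table")

  const <- mk(matrix(3, 2, nb))
  d <- sg_first_derivative(const)
  expect_equal(max(abs(d$absorbance)), 0)
  expect_equal(length(d$wavenumber), nb - 2)  # one band trimmed per edge

  lin <- mk(matrix(rep(0.01 * wavenumber + 2, 2), 2, nb, byrow = TRUE))
  d <- sg_first_derivative(lin)
  expect_equal(as.vector(d$absorbance), rep(0.01, 2 * (nb - 2)),
               tolerance = 1e-10)

  sine <- mk(matrix(sin(wavenumber / 50), 1, nb, byrow = TRUE))
  d <- sg_first_derivative(sine)
  truth <- cos(d$wavenumber / 50) / 50
  interior <- 10:(nb - 12)
  expect_lt(max(abs(d$absorbance[1, interior] - truth[interior]) /
                  max(abs(truth))), 0.01)

  expect_error(sg_first_derivative(const, window = 4), "odd")
  expect_error(sg_first_derivative(const, window = 2001), "smaller")
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(21)
  n <- 20; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
  fit <- pfsdiag:::pls1_fit(X, y, ncomp = p)
  ols <- lm(y ~ X)
  expect_equal(drop(X %*% fit$coef + fit$intercept),
               unname(fitted(ols)), tolerance = 1e-8)
})

test_that("noiseless mixtures are recovered almost perfectly; permuted labels are not", {
  fx <- mixing_spectra(n = 40, noise_sd = 0)
  values <- fx$conc[, 1]
  cv <- cross_validate(fx$spectra, values, ncomp = 3, n_folds = 10, seed = 2)
  expect_gte(cv$R2, 0.999)
  expect_lt(cv$RMSECV, 0.01 * sd(values))

  perm <- with_seed(8, sample(values))
  cvp <- cross_validate(fx$spectra, perm, ncomp = 3, n_folds = 10, seed = 2)
  expect_lte(cvp$R2, 0.1)
})

test_that("cross-validation statistics follow their definitions", {
  fx <- mixing_spectra(n = 30, noise_sd = 0.002)
  values <- fx$conc[, 2]
  cv <- cross_validate(fx$spectra, values, ncomp = 3, n_folds = 5, seed = 3)
  # recompute both statistics from the per-fold held-out predictions
  resid <- cv$predictions$predicted - cv$predictions$observed
  expect_equal(cv$RMSECV, sqrt(mean(resid^2)))
  expect_equal(cv$R2, 1 - sum(resid^2) /
                 sum((values - mean(values))^2))
  expect_equal(cv$n_pred, 30)

  # leave-one-out predictions do not depend on sample order
  loo1 <- cross_validate(fx$spectra, values, ncomp = 3, n_folds = 30)
  ord <- rev(seq_len(30))
  sp2 <- subset_spectra(fx$spectra, ord)
  loo2 <- cross_validate(sp2, values[ord], ncomp = 3, n_folds = 30)
  expect_equal(loo1$RMSECV, loo2$RMSECV, tolerance = 1e-10)
  expect_error(cross_validate(fx$spectra, values, ncomp = 3, n_folds = 31),
               "n_folds")
})

test_that("automatic component selection is parsimonious and calibration predicts", {
  fx <- mixing_spectra(n = 40, noise_sd = 0)
  values <- fx$conc[, 1]
  model <- fit_calibration(fx$spectra, values, ncomp = "auto", seed = 4)
  expect_lte(model$ncomp, 4)  # rank-3 mixing needs no more than ~3
  pred <- predict_nutrients(model, fx$spectra)
  expect_equal(unname(pred), values, tolerance = 1e-6)

  # log-transform back-transforms through exponentiation
  lmod <- fit_calibration(fx$spectra, exp(values), transform = "log",
                          ncomp = 3, seed = 4)
  lpred <- predict_nutrients(lmod, fx$spectra)
  expect_equal(unname(lpred), exp(values), tolerance = 1e-4)
  expect_error(fit_calibration(fx$spectra, values - 5, transform = "log"),
               "positive")

  # a zero-coefficient log model predicts exp(intercept) everywhere
  zmod <- lmod
  zmod$coefficients <- rep(0, length(zmod$coefficients))
  zmod$intercept <- 1.3
  zpred <- predict_nutrients(zmod, fx$spectra)
  expect_equal(unname(zpred), rep(exp(1.3), 40))
})

test_that("prediction demands a matching wavenumber grid", {
  fx <- mixing_spectra(n = 20)
  model <- fit_calibration(fx$spectra, fx$conc[, 1], ncomp = 3)
  other <- fx$spectra
  other$wavenumber <- other$wavenumber + 1
  expect_error(predict_nutrients(model, other), "grid")
})

test_that("calibration survives noise at realistic levels", {
  # signal amplitude ~ O(1); 5% noise still recovers the analyte
  fx <- mixing_spectra(n = 60, noise_sd = 0.05, seed = 13)
  values <- fx$conc[, 1]
  model <- fit_calibration(fx$spectra, values, ncomp = 3, seed = 5)
  pred <- predict_nutrients(model, fx$spectra)
  expect_gte(cor(pred, values), 0.95)
  # held-out skill persists (derivative preprocessing amplifies white noise,
  # so the held-out fit is noticeably weaker than the training correlation)
  cv <- cross_validate(fx$spectra, values, ncomp = 3, seed = 5)
  expect_gt(cv$R2, 0.3)
})

test_that("calibration models round-trip through JSON", {
  fx <- mixing_spectra(n = 20)
  model <- fit_calibration(fx$spectra, fx$conc[, 3], ncomp = 3,
                           analyte = "a3")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(model, path)
  back <- read_calibration_json(path)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_equal(back$intercept, model$intercept, tolerance = 1e-12)
  expect_identical(back$analyte, "a3")
  expect_equal(back$ncomp, model$ncomp, ignore_attr = TRUE)
  pred1 <- predict_nutrients(model, fx$spectra)
  pred2 <- predict_nutrients(back, fx$spectra)
  expect_equal(pred1, pred2, tolerance = 1e-10)
})
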