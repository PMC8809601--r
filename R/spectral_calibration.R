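#' Savitzky-Golay first-derivative preprocessing
#'
#' Applies a Savitzky-Golay first derivative (polynomial order 2, default
#' window of 3 points, which reduces to the central difference) along the
#' wavenumber axis of a spectra table. The derivative is taken with respect
#' to wavenumber, honouring the stored (descending) grid spacing, and the
#' edge bands that lack a full window are trimmed.
#'
#' @param spectra A `spectra_table`.
#' @param window Odd window length >= 3.
#' @return A `spectra_table` on the trimmed grid with derivative absorbance.
#' @export
sg_first_derivative <- function(spectra, window = 3) {
  stopifnot(inherits(spectra, "spectra_table"))
  nb <- length(spectra$wavenumber)
  if (window %% 2 != 1 || window < 3) stop_value("window must be odd and >= 3")
  if (window >= nb) stop_value("window must be smaller than the band count")
  steps <- diff(spectra$wavenumber)
  if (max(abs(steps - steps[1])) > 1e-8 * abs(steps[1]))
    stop_value("spectral grid must be uniform")
  dx <- steps[1]

  coefs <- signal::sgolay(p = 2, n = window, m = 1)
  centre <- coefs[(window + 1) / 2, ]  # derivative per sample step
  h <- (window - 1) / 2
  keep <- (h + 1):(nb - h)
  X <- spectra$absorbance
  D <- matrix(0, nrow(X), length(keep))
  for (k in seq_len(window)) {
    D <- D + centre[k] * X[, keep + (k - 1 - h), drop = FALSE]
  }
  D <- D / dx
  out <- spectra
  out$wavenumber <- spectra$wavenumber[keep]
  out$absorbance <- D
  out$loadings <- NULL
  attr(out, "preprocessing") <- list(derivative = 1, window = window, order = 2)
  out
}

# PLS1 via NIPALS on centred data. Returns regression coefficients on the
# original (uncentred) predictor scale plus the intercept.
pls1_fit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1, p)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) { ncomp <- a - 1; break }
    w <- w / nw
    t <- Xc %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xc, t) / tt
    qa <- sum(yc * t) / tt
    Xc <- Xc - t %*% t(pvec)
    yc <- yc - t * qa
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  if (ncomp == 0) {
    return(list(coef = rep(0, p), intercept = ym, ncomp = 0))
  }
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), q)
  list(coef = drop(B), intercept = ym - sum(xm * B), ncomp = ncomp)
}

prepare_xy <- function(spectra, values, transform, window) {
  d <- sg_first_derivative(spectra, window)
  y <- values
  if (transform == "log") {
    if (any(!is.finite(y)) || any(y <= 0))
      stop_value("values must be positive and finite under log transform")
    y <- log(y)
  }
  list(X = d$absorbance, y = y, grid = d$wavenumber)
}

#' Cross-validate a spectral calibration
#'
#' Seeded k-fold hold-out cross-validation of a PLS calibration: folds are
#' assigned at random, the model is refitted on each training portion and
#' the held-out samples are predicted once each. The coefficient of
#' determination is computed on the held-out pairs as
#' `R2 = 1 - SSE/TSS` (the regression-to-total sum-of-squares ratio) and
#' `RMSECV = sqrt(mean((yhat_cv - y)^2))`, both on the analysis
#' (possibly log) scale.
#'
#' @param spectra A `spectra_table` (rows to cross-validate).
#' @param values Reference values, one per spectra row.
#' @param transform `"none"` or `"log"` (natural log).
#' @param ncomp Number of PLS components.
#' @param n_folds Number of folds (2..n).
#' @param seed Integer seed for fold assignment.
#' @param window Savitzky-Golay window.
#' @return A `calibration_stats` list: `R2`, `RMSECV`, `n_pred`, and a
#'   `predictions` data frame (fold, observed, predicted on analysis scale).
#' @export
cross_validate <- function(spectra, values, transform = c("none", "log"),
                           ncomp = 3, n_folds = 10, seed = 1, window = 3) {
  transform <- match.arg(transform)
  n <- nrow(spectra$absorbance)
  if (length(values) != n) stop_value("values must match spectra rows")
  if (n_folds < 2 || n_folds > n)
    stop_value("n_folds must be between 2 and the number of samples")
  pr <- prepare_xy(spectra, values, transform, window)
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out = n)))
  pred <- numeric(n)
  for (f in seq_len(n_folds)) {
    test <- folds == f
    fit <- pls1_fit(pr$X[!test, , drop = FALSE], pr$y[!test], ncomp)
    pred[test] <- pr$X[test, , drop = FALSE] %*% fit$coef + fit$intercept
  }
  resid <- pred - pr$y
  tss <- sum((pr$y - mean(pr$y))^2)
  structure(list(
    R2 = 1 - sum(resid^2) / tss,
    RMSECV = sqrt(mean(resid^2)),
    n_pred = n,
    predictions = data.frame(fold = folds, observed = pr$y,
                             predicted = pred)),
    class = "calibration_stats")
}

#' @export
print.calibration_stats <- function(x, ...) {
  cat(sprintf("calibration_stats: R2 = %.3f, RMSECV = %.4g (n = %d)\n",
              x$R2, x$RMSECV, x$n_pred))
  invisible(x)
}

#' Fit a PLS spectral calibration on reference samples
#'
#' Fits partial least squares (PLS1, NIPALS) regression of wet-chemistry
#' reference values on Savitzky-Golay first-derivative spectra, optionally
#' on the natural-log scale. With `ncomp = "auto"` the number of latent
#' components minimises the cross-validated RMSECV with a parsimony rule:
#' the smallest component count whose RMSECV is within 2% of the minimum.
#'
#' @param spectra A `spectra_table` restricted to the reference rows.
#' @param values Reference analyte values, one per spectra row.
#' @param transform `"none"` or `"log"`.
#' @param ncomp Component count, or `"auto"`.
#' @param max_comp Largest component count tried under `"auto"`.
#' @param window Savitzky-Golay window (odd, >= 3).
#' @param n_folds,seed Cross-validation controls for `"auto"` selection.
#' @param analyte Analyte name recorded in the model.
#' @param smearing If `TRUE`, apply Duan's smearing factor when
#'   back-transforming log-scale predictions (default naive exponentiation).
#' @return A `calibration_model`: analyte, preprocessing spec, transform,
#'   `ncomp`, coefficients and intercept on the preprocessed scale, training
#'   ids, the training grid, and the cross-validation statistics of the
#'   selected model.
#' @export
fit_calibration <- function(spectra, values, transform = c("none", "log"),
                            ncomp = "auto", max_comp = 10, window = 3,
                            n_folds = 10, seed = 1, analyte = "analyte",
                            smearing = FALSE) {
  transform <- match.arg(transform)
  n <- nrow(spectra$absorbance)
  if (length(values) != n) stop_value("values must match spectra rows")
  if (n < 10) stop_value("at least 10 reference samples are required")
  pr <- prepare_xy(spectra, values, transform, window)
  kmax <- min(max_comp, n - ceiling(n / max(2, n_folds)) - 1, ncol(pr$X))

  if (identical(ncomp, "auto")) {
    rmse <- vapply(seq_len(kmax), function(k)
      cross_validate(spectra, values, transform, ncomp = k,
                     n_folds = n_folds, seed = seed, window = window)$RMSECV,
      numeric(1))
    ncomp <- which(rmse <= 1.02 * min(rmse))[1]
  }
  ncomp <- as.integer(ncomp)
  if (ncomp < 1) stop_value("ncomp must be >= 1")
  fit <- pls1_fit(pr$X, pr$y, ncomp)
  cv <- cross_validate(spectra, values, transform, ncomp = fit$ncomp,
                       n_folds = min(n_folds, n), seed = seed, window = window)
  smear_factor <- 1
  if (transform == "log") {
    fitted <- drop(pr$X %*% fit$coef + fit$intercept)
    smear_factor <- mean(exp(pr$y - fitted))
  }
  structure(list(
    analyte = analyte,
    preprocessing = list(derivative = 1, order = 2, window = window),
    transform = transform,
    ncomp = fit$ncomp,
    coefficients = fit$coef,
    intercept = fit$intercept,
    training_ids = spectra$sample_id,
    wavenumber = spectra$wavenumber,
    smearing = smearing,
    smear_factor = smear_factor,
    cv = cv),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "calibration_model [%s]: PLS %d comp, SG window %d, transform %s\n",
    x$analyte, x$ncomp, x$preprocessing$window, x$transform))
  cat(sprintf("  cross-validated R2 = %.3f, RMSECV = %.4g\n",
              x$cv$R2, x$cv$RMSECV))
  invisible(x)
}

#' Predict nutrient concentrations from spectra
#'
#' Applies the model's preprocessing to new spectra on the identical
#' wavenumber grid, evaluates the linear PLS predictor, and back-transforms
#' log-scale models by exponentiation (times Duan's smearing factor when the
#' model was fitted with `smearing = TRUE`).
#'
#' @param model A `calibration_model`.
#' @param spectra A `spectra_table` on the training grid.
#' @return Named numeric vector of predictions (names are sample ids).
#' @export
predict_nutrients <- function(model, spectra) {
  stopifnot(inherits(model, "calibration_model"),
            inherits(spectra, "spectra_table"))
  if (length(spectra$wavenumber) != length(model$wavenumber) ||
      max(abs(spectra$wavenumber - model$wavenumber)) > 1e-8)
    stop_value("spectra grid does not match the training grid")
  d <- sg_first_derivative(spectra, model$preprocessing$window)
  pred <- drop(d$absorbance %*% model$coefficients + model$intercept)
  if (model$transform == "log") {
    pred <- exp(pred)
    if (isTRUE(model$smearing)) pred <- pred * model$smear_factor
  }
  names(pred) <- spectra$sample_id
  pred
}

#' Subset a spectra table by row
#' @param spectra A `spectra_table`.
#' @param idx Logical or integer row index.
#' @return A `spectra_table` containing the selected samples.
#' @export
subset_spectra <- function(spectra, idx) {
  stopifnot(inherits(spectra, "spectra_table"))
  out <- spectra
  out$sample_id <- spectra$sample_id[idx]
  out$absorbance <- spectra$absorbance[idx, , drop = FALSE]
  out$is_reference <- spectra$is_reference[idx]
  out
}

#' Serialise a calibration model to JSON
#' @param model A `calibration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(model, path) {
  obj <- unclass(model)
  obj$cv <- list(R2 = model$cv$R2, RMSECV = model$cv$RMSECV,
                 n_pred = model$cv$n_pred)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model from JSON
#' @param path JSON file written by [write_calibration_json()].
#' @return A `calibration_model`.
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$cv <- structure(obj$cv, class = "calibration_stats")
  structure(obj, class = "calibration_model")
}
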