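# Shared fixture builders. Everything is generated in code at test time.

default_frame <- function(seed = 1) {
  frame <- partition_block(rect_m(0, 0, 10000, 10000), 16, 10)
  select_units(frame, 8, 32, seed = seed)
}

default_plots <- function(seed = 1) {
  survey_plots(default_frame(seed), fields_per_subtile = 2, seed = seed + 1)
}

default_survey <- function(seed = 1, ...) {
  simulate_survey(default_plots(seed), truth_params(seed = seed, ...))
}

# a noise-free truth: yield is an exact function of the soil surfaces
noiseless_truth <- function(seed = 1) {
  tp <- truth_params(seed = seed)
  tp$yield_noise_sd <- 0
  tp$missing_yield_fraction <- 0
  tp$outlier_fraction <- 0
  for (nm in c("N", "P", "K")) tp$uptake[[nm]]$noise_cv <- 0
  tp$biovolume$noise_sd <- 0
  tp
}

# tiny synthetic spectra with known rank-3 linear mixing
mixing_spectra <- function(n = 40, nb = 120, noise_sd = 0, seed = 11) {
  set.seed(seed)
  wavenumber <- seq(4000, 4000 - 2 * (nb - 1), by = -2)
  conc <- matrix(runif(n * 3, 0.5, 2), n, 3)
  loadings <- sapply(1:3, function(j) {
    centers <- runif(3, min(wavenumber), max(wavenumber))
    rowSums(sapply(centers, function(cc)
      exp(-(wavenumber - cc)^2 / (2 * 60^2))))
  })
  absorbance <- conc %*% t(loadings)
  if (noise_sd > 0)
    absorbance <- absorbance + matrix(rnorm(n * nb, 0, noise_sd), n, nb)
  list(spectra = structure(list(sample_id = sprintf("s%03d", 1:n),
                                wavenumber = wavenumber,
                                absorbance = absorbance,
                                is_reference = rep(TRUE, n),
                                analytes = c("a1", "a2", "a3")),
                           class = "spectra_table"),
       conc = conc)
}

# brute-force Cate-Nelson oracle: direct O(n^2) candidate scan with direct
# counting, implementing the declared canon (chance-corrected agreeing count,
# ties by raw count, then binary-split R2, then smaller cx, then smaller cy)
cate_nelson_oracle <- function(x, y) {
  n <- length(x)
  ux <- sort(unique(x)); uy <- sort(unique(y))
  cxs <- (ux[-1] + ux[-length(ux)]) / 2
  cys <- (uy[-1] + uy[-length(uy)]) / 2
  tss <- sum((y - mean(y))^2)
  best <- NULL
  for (cx in cxs) {
    for (cy in cys) {
      low <- x < cx; lowy <- y < cy
      agree <- sum(low & lowy) + sum(!low & !lowy)
      expected <- (sum(low) * sum(lowy) + sum(!low) * sum(!lowy)) / n
      excess <- agree - expected
      sse <- sum((y[low] - mean(y[low]))^2) +
        sum((y[!low] - mean(y[!low]))^2)
      r2 <- 1 - sse / tss
      cand <- list(excess = excess, agree = agree, r2 = r2, cx = cx, cy = cy)
      if (is.null(best) ||
          excess > best$excess + 1e-9 ||
          (abs(excess - best$excess) <= 1e-9 &&
           (agree > best$agree ||
            (agree == best$agree && r2 > best$r2 + 1e-12))))
        best <- cand
    }
  }
  best
}

# brute-force global Moran double sum
moran_oracle <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in 1:n) for (j in 1:n) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# brute-force local Moran, population-variance denominator
moran_local_oracle <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  delta <- mean(z^2)
  sapply(1:n, function(i) {
    s <- 0
    for (j in setdiff(1:n, i)) s <- s + W[i, j] * z[j]
    z[i] / delta * s
  })
}
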