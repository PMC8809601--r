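#' Ground-truth parameters for the survey generator
#'
#' Bundles every parameter the synthetic-data generator needs, with defaults
#' emulating the magnitudes of an unfertilized smallholder maize landscape:
#' soil total N around 0.15% with CV 25%, Mehlich-3 extractable P around
#' 21 mg kg^-1 with CV 61% (lognormal), exchangeable K around 4.2
#' cmol_c kg^-1 with CV 35% (lognormal), a saturating (linear-plateau) yield
#' response with known critical soil values, tissue-uptake links, about 7%
#' of yields missing (fields harvested before measurement), and a small
#' fraction of rare high tissue-N outliers.
#'
#' @param soil Named list of per-nutrient surface parameters; each entry has
#'   `mean`, `cv`, `marginal` ("normal"/"lognormal"), `critical` (true
#'   critical soil value), `curvature` (relative yield loss per unit of
#'   soil-test shortfall below critical).
#' @param uptake Named list of per-nutrient tissue-uptake parameters
#'   `t_max` (asymptotic tissue concentration, %) and `k_m` (soil value at
#'   half saturation), plus `noise_cv` multiplicative tissue noise.
#' @param range_m Spatial correlation range of the nutrient surfaces (m).
#' @param plateau Yield plateau (Mg ha^-1).
#' @param yield_noise_sd Additive yield noise SD (Mg ha^-1).
#' @param yield_combine `"multiplicative"` (default) combines per-nutrient
#'   response factors as a product; `"liebig"` takes the minimum factor.
#' @param missing_yield_fraction Fraction of plots with missing yield.
#' @param outlier_fraction Fraction of plots whose tissue N is multiplied by
#'   `outlier_magnitude` (default 11/256, emulating rare very high N records).
#' @param outlier_magnitude Multiplier for injected tissue-N outliers.
#' @param biovolume List `base`, `per_yield`, `noise_sd` linking target plant
#'   biovolume (cm^3) to expected yield, and `height_mean`, `height_sd` (cm)
#'   from which basal diameter is back-solved.
#' @param seed Integer root seed for the generator.
#' @return A validated list of class `truth_params`.
#' @export
truth_params <- function(
    soil = list(
      N = list(mean = 0.15, cv = 0.25, marginal = "normal",
               critical = 0.13, curvature = 5),
      P = list(mean = 21, cv = 0.61, marginal = "lognormal",
               critical = 18.3, curvature = 0.03),
      K = list(mean = 4.24, cv = 0.35, marginal = "lognormal",
               critical = 5.3, curvature = 0.12)),
    uptake = list(
      N = list(t_max = 4.0, k_m = 0.05, noise_cv = 0.08),
      P = list(t_max = 0.50, k_m = 20, noise_cv = 0.10),
      K = list(t_max = 3.2, k_m = 2.5, noise_cv = 0.10)),
    range_m = 2000,
    plateau = 4.5,
    yield_noise_sd = 0.45,
    yield_combine = c("multiplicative", "liebig"),
    missing_yield_fraction = 0.07,
    outlier_fraction = 11 / 256,
    outlier_magnitude = 3,
    biovolume = list(base = 60, per_yield = 30, noise_sd = 25,
                     height_mean = 180, height_sd = 15),
    seed = 42) {
  yield_combine <- match.arg(yield_combine)
  for (nm in c("N", "P", "K")) {
    s <- soil[[nm]]
    if (is.null(s)) stop_value("soil parameters missing for ", nm)
    if (s$mean <= 0) stop_value("soil mean must be > 0 for ", nm)
    if (s$cv < 0 || s$cv > 2) stop_value("soil cv must be in [0, 2] for ", nm)
  }
  if (missing_yield_fraction < 0 || missing_yield_fraction >= 1)
    stop_value("missing_yield_fraction must be in [0, 1)")
  if (plateau <= 0) stop_value("plateau must be > 0")
  structure(list(soil = soil, uptake = uptake, range_m = range_m,
                 plateau = plateau, yield_noise_sd = yield_noise_sd,
                 yield_combine = yield_combine,
                 missing_yield_fraction = missing_yield_fraction,
                 outlier_fraction = outlier_fraction,
                 outlier_magnitude = outlier_magnitude,
                 biovolume = biovolume, seed = as.integer(seed)),
            class = "truth_params")
}

#' Simulate a stationary spatially correlated nutrient surface
#'
#' Returns a deterministic, seeded function of location built as a
#' superposition of random cosine waves (the spectral method): the wave
#' vectors are drawn from the spectral density of a Gaussian correlation
#' function, so correlation decays as `exp(-(d/range_m)^2)`. The standard
#' Gaussian field is mapped to the requested mean and CV either linearly
#' (`marginal = "normal"`) or through a moment-matched lognormal
#' transformation, which keeps values positive.
#'
#' @param mean Target surface mean (must be > 0).
#' @param cv Target coefficient of variation as a fraction; `cv = 0` gives
#'   the constant surface equal to `mean`.
#' @param range_m Correlation range in metres (> 0).
#' @param seed Integer seed fixing the wave field.
#' @param marginal `"normal"` or `"lognormal"` marginal distribution.
#' @param n_waves Number of cosine components (default 96).
#' @return A function `f(x, y)` evaluable at arbitrary coordinate vectors.
#' @export
simulate_surface <- function(mean, cv, range_m, seed = 1,
                             marginal = c("normal", "lognormal"),
                             n_waves = 96) {
  marginal <- match.arg(marginal)
  if (mean <= 0) stop_value("mean must be > 0")
  if (cv < 0) stop_value("cv must be >= 0")
  if (range_m <= 0) stop_value("range_m must be > 0")
  if (cv == 0) {
    f <- function(x, y) rep(mean, length(x))
    return(f)
  }
  waves <- with_seed(seed, {
    sigma_omega <- sqrt(2) / range_m
    list(wx = rnorm(n_waves, 0, sigma_omega),
         wy = rnorm(n_waves, 0, sigma_omega),
         phase = runif(n_waves, 0, 2 * pi))
  })
  amp <- sqrt(2 / n_waves)
  s_log <- sqrt(log(1 + cv^2))
  function(x, y) {
    z <- amp * colSums(cos(outer(waves$wx, x) + outer(waves$wy, y) +
                             waves$phase))
    if (marginal == "normal") mean * (1 + cv * z)
    else mean * exp(s_log * z - s_log^2 / 2)
  }
}

#' Linear-plateau expected yield response
#'
#' Expected yield rises linearly with the soil-test value below the critical
#' value and is constant at the plateau above it; the response is continuous
#' at the critical value and floored at zero:
#' `plateau * max(0, 1 - curvature * max(0, critical - soil_value))`.
#'
#' @param soil_value Soil-test value(s).
#' @param critical Critical soil-test value.
#' @param plateau Plateau yield (> 0).
#' @param curvature Relative yield loss per unit shortfall below critical.
#' @return Expected yield, same length as `soil_value`.
#' @examples
#' yield_response(0.13, critical = 0.13, plateau = 4.5, curvature = 5) # 4.5
#' @export
yield_response <- function(soil_value, critical, plateau, curvature) {
  if (plateau <= 0) stop_value("plateau must be > 0")
  plateau * pmax(0, 1 - curvature * pmax(0, critical - soil_value))
}

#' Simulate a plot-level survey table with known ground truth
#'
#' Samples per-nutrient soil surfaces at the plot coordinates, links tissue
#' concentrations to soil values through saturating uptake curves with
#' multiplicative noise, combines per-nutrient linear-plateau response
#' factors into an expected yield (product by default, Liebig minimum
#' optionally), back-solves plant height and basal diameter from a
#' yield-linked target biovolume, and finally injects missing yields and
#' rare high tissue-N outliers. Fixed seeds give byte-identical tables.
#'
#' @param plots Plot table from [survey_plots()] (projected `x`, `y` needed).
#' @param truth A `truth_params` object.
#' @return A `survey_table` data frame: ids, lon/lat, `soil_N`, `soil_P`,
#'   `soil_K`, `tissue_N`, `tissue_P`, `tissue_K`, `grain_yield` (Mg ha^-1,
#'   possibly `NA`), `height_cm`, `basal_diameter_cm`, `biovolume_cm3`,
#'   `field_quality`, `outlier_injected`. The generating `truth` is attached
#'   as an attribute.
#' @export
simulate_survey <- function(plots, truth = truth_params()) {
  stopifnot(inherits(truth, "truth_params"))
  if (is.null(plots) || nrow(plots) == 0) stop_value("empty plot list")
  if (!all(c("x", "y") %in% names(plots)))
    stop_value("plots must carry projected x/y coordinates")
  n <- nrow(plots)
  nutrients <- c("N", "P", "K")

  soil <- matrix(NA_real_, n, 3, dimnames = list(NULL, nutrients))
  for (i in seq_along(nutrients)) {
    p <- truth$soil[[nutrients[i]]]
    f <- simulate_surface(p$mean, p$cv, truth$range_m,
                          seed = truth$seed + 100 + i, marginal = p$marginal)
    soil[, i] <- f(plots$x, plots$y)
  }
  soil[soil <= 0] <- min(soil[soil > 0]) / 2  # guard rare negative normals

  out <- with_seed(truth$seed + 200, {
    tissue <- sapply(seq_along(nutrients), function(i) {
      u <- truth$uptake[[nutrients[i]]]
      base <- u$t_max * soil[, i] / (soil[, i] + u$k_m)
      pmax(base * (1 + rnorm(n, 0, u$noise_cv)), 1e-6)
    })
    colnames(tissue) <- nutrients

    factors <- sapply(seq_along(nutrients), function(i) {
      p <- truth$soil[[nutrients[i]]]
      yield_response(soil[, i], p$critical, 1, p$curvature)
    })
    combined <- if (truth$yield_combine == "liebig")
      apply(factors, 1, min) else apply(factors, 1, prod)
    yield_exp <- truth$plateau * combined
    grain_yield <- pmax(0, yield_exp + rnorm(n, 0, truth$yield_noise_sd))

    bv <- truth$biovolume
    bv_target <- pmax(10, bv$base + bv$per_yield * yield_exp +
                        rnorm(n, 0, bv$noise_sd))
    height <- pmax(50, rnorm(n, bv$height_mean, bv$height_sd))
    basal <- 2 * sqrt(bv_target / (height * pi))

    miss <- runif(n) < truth$missing_yield_fraction
    grain_yield[miss] <- NA_real_

    n_out <- round(truth$outlier_fraction * n)
    out_idx <- if (n_out > 0) sample(n, n_out) else integer()
    tissue[out_idx, "N"] <- tissue[out_idx, "N"] * truth$outlier_magnitude

    list(tissue = tissue, grain_yield = grain_yield, yield_exp = yield_exp,
         height = height, basal = basal, out_idx = out_idx)
  })

  tab <- data.frame(
    plots[, intersect(c("block_id", "tile_id", "subtile_id", "field_id",
                        "plot_id", "plot_label", "role", "x", "y",
                        "lon", "lat"), names(plots))],
    soil_N = soil[, "N"], soil_P = soil[, "P"], soil_K = soil[, "K"],
    tissue_N = out$tissue[, "N"], tissue_P = out$tissue[, "P"],
    tissue_K = out$tissue[, "K"],
    grain_yield = out$grain_yield,
    height_cm = out$height, basal_diameter_cm = out$basal,
    stringsAsFactors = FALSE)
  tab$biovolume_cm3 <- biovolume(tab$height_cm, tab$basal_diameter_cm)
  tab$outlier_injected <- seq_len(n) %in% out$out_idx

  # purposive poor/good field labels from expected-yield quantiles
  if ("field_id" %in% names(tab)) {
    fy <- tapply(out$yield_exp, tab$field_id, mean)
    qs <- stats::quantile(fy, c(0.2, 0.8))
    lab <- ifelse(fy <= qs[[1]], "poor", ifelse(fy >= qs[[2]], "good",
                                                "typical"))
    tab$field_quality <- unname(lab[tab$field_id])
  } else {
    tab$field_quality <- "typical"
  }
  attr(tab, "truth") <- truth
  class(tab) <- c("survey_table", "data.frame")
  tab
}

#' Simulate mid-infrared spectra linked to survey analytes
#'
#' Each sample's spectrum is a linear mixture of fixed smooth analyte loading
#' curves (sums of Gaussian bands, drawn once from `loadings_seed`) weighted
#' by the sample's analyte values (scaled by the analyte means so each
#' contributes O(1) absorbance), plus a smooth low-order polynomial baseline
#' and white noise. A `reference_fraction` subset is flagged as the
#' wet-chemistry reference set used for calibration.
#'
#' @param survey A `survey_table`.
#' @param analytes Character vector of survey columns driving the spectra
#'   (default the three soil nutrients).
#' @param wn_max,wn_min,wn_step Wavenumber grid (cm^-1), stored descending
#'   from `wn_max` to `wn_min`.
#' @param loadings_seed Seed fixing loading curves, baselines and noise.
#' @param noise_sd White-noise SD in absorbance units.
#' @param reference_fraction Fraction of samples flagged as reference.
#' @return A `spectra_table`: list with `sample_id`, `wavenumber`
#'   (descending), `absorbance` (samples x bands), `is_reference`,
#'   `analytes`.
#' @export
simulate_spectra <- function(survey, analytes = c("soil_N", "soil_P", "soil_K"),
                             wn_max = 4000, wn_min = 600, wn_step = 2,
                             loadings_seed = 7, noise_sd = 0.003,
                             reference_fraction = 0.25) {
  stopifnot(all(analytes %in% names(survey)))
  wavenumber <- seq(wn_max, wn_min, by = -abs(wn_step))
  nb <- length(wavenumber)
  if (nb < 20) stop_value("spectral grid must have at least 20 bands")
  n <- nrow(survey)
  vals <- as.matrix(survey[, analytes, drop = FALSE])
  scaled <- sweep(vals, 2, colMeans(vals), "/")

  with_seed(loadings_seed, {
    loadings <- sapply(seq_along(analytes), function(a) {
      centers <- runif(5, wn_min, wn_max)
      widths <- runif(5, 40, 160)
      amps <- runif(5, 0.1, 0.5)
      rowSums(sapply(1:5, function(j)
        amps[j] * exp(-(wavenumber - centers[j])^2 / (2 * widths[j]^2))))
    })
    u <- (wavenumber - mean(wavenumber)) / (diff(range(wavenumber)) / 2)
    basis <- cbind(1, u, u^2)
    base_coef <- matrix(rnorm(n * 3, 0, c(0.05, 0.02, 0.02)), n, 3,
                        byrow = TRUE)
    absorbance <- scaled %*% t(loadings) + base_coef %*% t(basis)
    if (noise_sd > 0)
      absorbance <- absorbance + matrix(rnorm(n * nb, 0, noise_sd), n, nb)
    n_ref <- round(reference_fraction * n)
    is_reference <- seq_len(n) %in% sample(n, n_ref)
    structure(list(sample_id = survey$plot_id, wavenumber = wavenumber,
                   absorbance = absorbance, is_reference = is_reference,
                   analytes = analytes, loadings = loadings),
              class = "spectra_table")
  })
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("spectra_table: %d samples x %d bands (%g to %g cm^-1), %d reference\n",
              nrow(x$absorbance), length(x$wavenumber), x$wavenumber[1],
              x$wavenumber[length(x$wavenumber)], sum(x$is_reference)))
  invisible(x)
}

#' Write a survey table as CSV
#'
#' @param table A `survey_table` (or plain data frame with its columns).
#' @param path Output path. Missing values are written as empty fields.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a spectra table as wide CSV (sample_id + one column per wavenumber)
#' @param spectra A `spectra_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_table"))
  df <- data.frame(sample_id = spectra$sample_id,
                   is_reference = spectra$is_reference,
                   spectra$absorbance, check.names = FALSE)
  names(df)[-(1:2)] <- format(spectra$wavenumber, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
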