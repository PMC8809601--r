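#' Pipeline configuration with documented defaults
#'
#' Assembles every tunable of the four-step survey -> diagnose -> rank -> map
#' workflow into one nested list. Defaults: the LDSF design (100 km^2 block,
#' 16 tiles, 8 selected, 32 sub-tiles, 2 fields each, 12.2 m Y-frame radius,
#' 20 m boundary offset), established tissue criticals (N 3.00%, P 0.25%,
#' K 2.00%), baseline soil criticals (0.2% N, 10 mg kg^-1 P,
#' 3 cmol_c kg^-1 K), DRIS sensitivity k = 1000, inverse-distance weights
#' (power 1) with 599 Monte Carlo permutations, IDW power 2, and a 7%
#' missing-yield, 25% reference-fraction synthetic ground truth.
#'
#' @param seed Root seed; every stage derives its own stream from it.
#' @param input_csv Optional path to a survey CSV; `NULL` simulates.
#' @param truth A `truth_params` object for simulation.
#' @param ... Named overrides of individual blocks (`design`, `thresholds`,
#'   `calibration`, `dris`, `spatial`, `outliers`); supplied fields replace
#'   the corresponding defaults.
#' @return A `pfs_config` list.
#' @export
pfs_config <- function(seed = 42, input_csv = NULL,
                       truth = truth_params(seed = seed), ...) {
  cfg <- list(
    seed = as.integer(seed),
    input_csv = input_csv,
    truth = truth,
    design = list(block_km2 = 100, n_tiles = 16, n_subtiles_per_tile = 10,
                  n_tiles_sel = 8, n_subtiles_sel = 32,
                  fields_per_subtile = 2, radius_m = 12.2, offset_m = 20,
                  origin_lonlat = c(34.25, 0.07)),
    thresholds = list(
      tissue_critical = c(N = 3.00, P = 0.25, K = 2.00),
      soil_baseline = c(N = 0.2, P = 10, K = 3)),
    calibration = list(enabled = FALSE, window = 3, n_folds = 10,
                       ncomp = "auto", noise_sd = 0.003,
                       reference_fraction = 0.25),
    dris = list(k = 1000),
    spatial = list(weight_power = 1, idw_power = 2, n_perm = 599,
                   grid_n = 40),
    outliers = list(k_sd = 3))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pfs_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML document and merges it over the [pfs_config()] defaults;
#' any field present in the file replaces the default.
#'
#' @param path YAML file path.
#' @return A `pfs_config`.
#' @export
read_pfs_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 42
  truth_args <- y$truth
  truth <- if (is.null(truth_args)) truth_params(seed = seed)
  else do.call(truth_params, c(truth_args, list(seed = seed)))
  blocks <- y[setdiff(names(y), c("seed", "truth", "input_csv"))]
  # thresholds arrive as named lists from YAML; coerce numeric blocks
  if (!is.null(blocks$thresholds))
    blocks$thresholds <- lapply(blocks$thresholds, function(v) unlist(v))
  do.call(pfs_config,
          c(list(seed = seed, input_csv = y$input_csv, truth = truth),
            blocks))
}

SURVEY_COLUMNS <- c("field_id", "plot_id", "role", "lon", "lat",
                    "soil_N", "soil_P", "soil_K",
                    "tissue_N", "tissue_P", "tissue_K",
                    "grain_yield", "height_cm", "basal_diameter_cm",
                    "biovolume_cm3")

#' Read a survey table from CSV
#'
#' Parses a plot-level survey CSV against the documented schema. Mandatory
#' columns: `field_id`, `plot_id`, `role`, `lon`, `lat`, `soil_N`, `soil_P`,
#' `soil_K`, `tissue_N`, `tissue_P`, `tissue_K`, `grain_yield`, `height_cm`,
#' `basal_diameter_cm`, `biovolume_cm3`. Missing mandatory columns raise a
#' schema error naming them; unknown columns produce a warning and are
#' kept. Empty fields become `NA`.
#'
#' @param path CSV file path.
#' @return A `survey_table` data frame.
#' @export
read_survey_csv <- function(path) {
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE,
                                  na.strings = c("", "NA")),
                  error = function(e) stop_value("cannot parse ", path, ": ",
                                                 conditionMessage(e)))
  if (nrow(tab) == 0 || ncol(tab) <= 1)
    stop_value("schema error: ", path, " contains no survey records")
  missing_cols <- setdiff(SURVEY_COLUMNS, names(tab))
  if (length(missing_cols))
    stop_value("schema error: missing mandatory columns: ",
               paste(missing_cols, collapse = ", "))
  known <- c(SURVEY_COLUMNS, "block_id", "tile_id", "subtile_id",
             "plot_label", "x", "y", "field_quality", "outlier_injected")
  unknown <- setdiff(names(tab), known)
  if (length(unknown))
    warning("unknown survey columns kept as-is: ",
            paste(unknown, collapse = ", "))
  if (!"x" %in% names(tab)) {
    xy <- lonlat_to_xy(tab$lon, tab$lat)
    tab$x <- xy[, "x"]; tab$y <- xy[, "y"]
  }
  class(tab) <- c("survey_table", "data.frame")
  tab
}

#' Validate a survey table
#'
#' Structural and range checks that never mutate the table: mandatory
#' columns, finite non-missing numerics, positive soil and tissue values,
#' yield non-negative, plot multiplicity (one central + three satellites
#' per field). Returns a structured issue list; an empty data frame means a
#' clean table.
#'
#' @param table A `survey_table`.
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `row`, `column`, `message`.
#' @export
validate_survey <- function(table) {
  issues <- list()
  add <- function(severity, row, column, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, row = row, column = column, message = message,
      stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(SURVEY_COLUMNS, names(table))
  for (mc in missing_cols) add("error", NA, mc, "mandatory column missing")
  num_cols <- intersect(c("soil_N", "soil_P", "soil_K", "tissue_N",
                          "tissue_P", "tissue_K", "grain_yield",
                          "height_cm", "basal_diameter_cm",
                          "biovolume_cm3"), names(table))
  for (cc in num_cols) {
    v <- table[[cc]]
    bad <- which(!is.na(v) & !is.finite(v))
    for (b in bad) add("error", b, cc, "non-finite value")
    if (cc != "grain_yield") {
      neg <- which(!is.na(v) & v <= 0)
      for (b in neg) add("error", b, cc, "non-positive value")
    } else {
      neg <- which(!is.na(v) & v < 0)
      for (b in neg) add("error", b, cc, "negative yield")
    }
  }
  if (all(c("field_id", "role") %in% names(table))) {
    per_field <- table(table$field_id)
    wrong <- names(per_field)[per_field != 4]
    for (w in wrong)
      add("warning", NA, "field_id",
          sprintf("field %s has %d plots (expected 4)", w, per_field[[w]]))
    for (f in unique(table$field_id)) {
      roles <- table$role[table$field_id == f]
      if (sum(roles == "central") != 1)
        add("warning", NA, "role",
            sprintf("field %s lacks exactly one central plot", f))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(), row = integer(),
                  column = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Run the four-step population-based farm survey pipeline
#'
#' Step 1 simulates (or loads) the plot-level survey, optionally replacing
#' measured soil nutrients with spectral predictions calibrated on the
#' reference subset. Step 2 screens high tissue-N outliers, computes
#' descriptive statistics, baseline-threshold prevalences, Cate-Nelson
#' critical soil-test and yield values, and localized frequency-overlap
#' cut-offs (log scale for P and K). Step 3 splits the population at the
#' soil-N critical yield, derives DRIS norms from the sufficient
#' subpopulation, computes per-plot indices and ranks nutrient limitation.
#' Step 4 aggregates indices to field level, maps them by IDW and tests
#' spatial clustering with Moran's I and a Monte Carlo permutation test.
#'
#' All randomness derives from `config$seed`; rerunning with the same
#' configuration reproduces the report exactly. Every filtering step logs
#' (n_before, n_after) in the report's `filters` block.
#'
#' @param config A `pfs_config`.
#' @param out_dir Optional directory; when given, the survey CSV, per-plot
#'   index CSV, diagnostics CSV, GeoJSON point layer, ASCII-grid rasters and
#'   the JSON report are written there.
#' @return A `pfs_report` list with `design`, `survey`, `descriptives`,
#'   `diagnostics`, `dris`, `spatial`, `filters` and `provenance` blocks.
#' @export
run_pipeline <- function(config = pfs_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pfs_config"))
  seed <- config$seed
  filters <- list()
  note_filter <- function(stage, n_before, n_after) {
    filters[[stage]] <<- list(n_before = n_before, n_after = n_after,
                              n_dropped = n_before - n_after)
  }

  ## Step 1 — survey
  des <- config$design
  side <- sqrt(des$block_km2 * 1e6)
  frame <- partition_block(rect_m(0, 0, side, side), des$n_tiles,
                           des$n_subtiles_per_tile)
  frame <- select_units(frame, des$n_tiles_sel, des$n_subtiles_sel,
                        seed = seed + 1)
  plots <- survey_plots(frame, des$fields_per_subtile, seed = seed + 2,
                        radius_m = des$radius_m, offset_m = des$offset_m,
                        origin_lonlat = des$origin_lonlat)
  survey <- if (!is.null(config$input_csv)) read_survey_csv(config$input_csv)
  else simulate_survey(plots, config$truth)

  calibration_models <- NULL
  if (isTRUE(config$calibration$enabled)) {
    cal <- config$calibration
    spectra <- simulate_spectra(survey, loadings_seed = seed + 3,
                                noise_sd = cal$noise_sd,
                                reference_fraction = cal$reference_fraction)
    ref <- subset_spectra(spectra, spectra$is_reference)
    calibration_models <- list()
    for (nm in c("N", "P", "K")) {
      col <- paste0("soil_", nm)
      transform <- if (nm == "N") "none" else "log"
      model <- fit_calibration(ref, survey[[col]][spectra$is_reference],
                               transform = transform, ncomp = cal$ncomp,
                               window = cal$window, n_folds = cal$n_folds,
                               seed = seed + 4, analyte = col)
      survey[[col]] <- unname(predict_nutrients(model, spectra))
      calibration_models[[col]] <- model
    }
  }

  ## Step 2 — diagnostics
  out_flags <- remove_outliers(survey$tissue_N, config$outliers$k_sd)
  clean <- survey[!out_flags$flags, , drop = FALSE]
  note_filter("tissue_N_outliers", nrow(survey), nrow(clean))

  descriptives <- lapply(
    c(soil_N = "soil_N", soil_P = "soil_P", soil_K = "soil_K",
      tissue_N = "tissue_N", tissue_P = "tissue_P", tissue_K = "tissue_K",
      grain_yield = "grain_yield", biovolume_cm3 = "biovolume_cm3"),
    function(cc) describe_values(clean[[cc]]))

  yield_ok <- !is.na(clean$grain_yield)
  note_filter("missing_yield", nrow(clean), sum(yield_ok))

  diagnostics <- list()
  for (nm in c("N", "P", "K")) {
    col <- paste0("soil_", nm)
    baseline <- config$thresholds$soil_baseline[[nm]]
    base_cls <- classify_deficiency(clean[[col]], baseline)
    cn <- cate_nelson(clean[[col]][yield_ok], clean$grain_yield[yield_ok],
                      ids = clean$plot_id[yield_ok])
    split <- split_subpopulations(clean, cn$critical_y)
    cut <- derive_cutoff(split$deficient[[col]], split$sufficient[[col]],
                         ci_level = 0.90, log_scale = nm %in% c("P", "K"))
    local_cls <- classify_deficiency(clean[[col]], cut$cutoff)
    diagnostics[[nm]] <- list(
      baseline_threshold = baseline,
      prevalence_baseline = base_cls$prevalence,
      cate_nelson = cn,
      cutoff = cut,
      prevalence_localized = local_cls$prevalence,
      responsive_fraction = cn$separation_r2)
  }

  ## Step 3 — DRIS
  yield_split <- diagnostics$N$cate_nelson$critical_y
  split <- split_subpopulations(clean, yield_split)
  norms <- compute_norms(split$sufficient, split$deficient,
                         k = config$dris$k)
  indices <- compute_indices(clean, norms)
  note_filter("incomplete_tissue", nrow(clean), sum(indices$complete))
  ranking <- rank_limitations(indices)

  ## Step 4 — spatial
  sp <- config$spatial
  fields <- stats::aggregate(
    indices[indices$complete, c("index_N", "index_P", "index_K")],
    by = list(field_id = indices$field_id[indices$complete]), FUN = mean)
  fxy <- stats::aggregate(clean[, c("x", "y", "lon", "lat")],
                          by = list(field_id = clean$field_id), FUN = mean)
  fields <- merge(fields, fxy, by = "field_id")
  weights <- build_weights(fields[, c("x", "y")], power = sp$weight_power)
  spatial <- list(fields = fields)
  rasters <- list()
  for (nm in c("N", "P", "K")) {
    col <- paste0("index_", nm)
    mt <- permutation_test(fields[[col]], weights, n_perm = sp$n_perm,
                           seed = seed + 5)
    mt$perm_I <- NULL
    spatial[[paste0("moran_", nm)]] <- mt
    g <- raster_grid(c(frame$block[["xmin"]], frame$block[["ymin"]]),
                     side / sp$grid_n, sp$grid_n, sp$grid_n)
    rasters[[col]] <- idw_interpolate(fields[, c("x", "y")], fields[[col]],
                                      g, power = sp$idw_power)
  }

  report <- structure(list(
    design = list(n_tiles = des$n_tiles,
                  n_tiles_selected = length(frame$selected_tile_ids),
                  n_subtiles_selected = length(frame$selected_subtile_ids),
                  n_fields = length(unique(plots$field_id)),
                  n_plots = nrow(plots), radius_m = des$radius_m),
    survey = survey,
    calibration = calibration_models,
    descriptives = descriptives,
    diagnostics = diagnostics,
    dris = list(norms = norms, indices = indices, ranking = ranking,
                yield_split = yield_split,
                n_deficient = nrow(split$deficient),
                n_sufficient = nrow(split$sufficient)),
    spatial = spatial,
    rasters = rasters,
    filters = filters,
    provenance = list(seed = seed, package_version =
                        as.character(utils::packageVersion("pfsdiag")))),
    class = "pfs_report")

  if (!is.null(out_dir)) write_report(report, out_dir, frame = frame)
  report
}

#' @export
print.pfs_report <- function(x, ...) {
  cat(sprintf("PFS report: %d plots / %d fields (seed %d)\n",
              x$design$n_plots, x$design$n_fields, x$provenance$seed))
  for (nm in c("N", "P", "K")) {
    d <- x$diagnostics[[nm]]
    cat(sprintf(
      "  %s: baseline prevalence %.1f%%, critical_x %.4g, critical_y %.3g, cutoff %.4g, localized prevalence %.1f%%\n",
      nm, d$prevalence_baseline, d$cate_nelson$critical_x,
      d$cate_nelson$critical_y, d$cutoff$cutoff, d$prevalence_localized))
  }
  cat(sprintf("  DRIS ranking (most limiting first): %s\n",
              paste(x$dris$ranking$ranking, collapse = " > ")))
  for (nm in c("N", "P", "K")) {
    m <- x$spatial[[paste0("moran_", nm)]]
    cat(sprintf("  Moran I (%s) = %.3f, p = %.4g\n", nm, m$I, m$p_value))
  }
  invisible(x)
}

report_to_json_list <- function(report) {
  diag_list <- lapply(report$diagnostics, function(d) list(
    baseline_threshold = d$baseline_threshold,
    prevalence_baseline = d$prevalence_baseline,
    critical_x = d$cate_nelson$critical_x,
    critical_y = d$cate_nelson$critical_y,
    quadrant_counts = as.list(d$cate_nelson$counts),
    separation_r2 = d$cate_nelson$separation_r2,
    cutoff = d$cutoff$cutoff,
    cutoff_method = d$cutoff$method,
    prevalence_localized = d$prevalence_localized))
  moran_list <- lapply(c(N = "N", P = "P", K = "K"), function(nm) {
    m <- report$spatial[[paste0("moran_", nm)]]
    list(I = m$I, expected = m$expected, p_value = m$p_value,
         n_perm = m$n_perm, seed = m$seed)
  })
  list(design = report$design,
       descriptives = lapply(report$descriptives, as.list),
       diagnostics = diag_list,
       dris = list(norms = as.list(report$dris$norms$norms),
                   cv = as.list(report$dris$norms$cv),
                   k = report$dris$norms$k,
                   yield_split = report$dris$yield_split,
                   n_deficient = report$dris$n_deficient,
                   n_sufficient = report$dris$n_sufficient,
                   mean_indices = as.list(report$dris$ranking$mean_indices),
                   ranking = report$dris$ranking$ranking,
                   most_limiting_prevalence =
                     as.list(report$dris$ranking$most_limiting_prevalence)),
       moran = moran_list,
       filters = report$filters,
       provenance = report$provenance)
}

#' Write pipeline artifacts to a directory
#'
#' @param report A `pfs_report`.
#' @param out_dir Output directory, created if needed.
#' @param frame Optional `sampling_frame` for the GeoJSON frame layer.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, frame = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_survey_csv(report$survey, file.path(out_dir, "survey.csv"))
  utils::write.csv(as.data.frame(report$dris$indices),
                   file.path(out_dir, "dris_indices.csv"), row.names = FALSE)
  utils::write.csv(report$spatial$fields,
                   file.path(out_dir, "field_indices.csv"), row.names = FALSE)
  write_plots_geojson(report$spatial$fields,
                      file.path(out_dir, "fields.geojson"))
  for (nm in names(report$rasters))
    write_raster_ascii(report$rasters[[nm]],
                       file.path(out_dir, paste0("idw_", nm, ".asc")))
  if (!is.null(frame))
    write_frame_geojson(frame, file.path(out_dir, "frame.geojson"))
  jsonlite::write_json(report_to_json_list(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
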