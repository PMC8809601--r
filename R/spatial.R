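#' Inverse-distance spatial weights
#'
#' Builds the pairwise weight matrix `W_ij = 1 / d_ij^power` for distinct
#' sites, with a zero diagonal and optional row standardisation. Coincident
#' sites (zero distance) are handled by flooring their distance at half the
#' smallest nonzero distance; the number of floored pairs is recorded.
#'
#' @param coords Two-column matrix or data frame of projected coordinates (m).
#' @param power Distance decay exponent (default 1, plain inverse distance).
#' @param row_standardize Scale each row to sum to 1 (default `TRUE`).
#' @return A `spatial_weights` list: `W`, `coords`, `scheme`, `power`,
#'   `row_standardized`, `n_coincident_pairs`.
#' @export
build_weights <- function(coords, power = 1, row_standardize = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop_value("at least 3 sites are required")
  d <- as.matrix(stats::dist(coords))
  off <- d[upper.tri(d)]
  if (all(off == 0)) stop_value("all sites are coincident")
  floor_d <- min(off[off > 0]) / 2
  n_co <- sum(off == 0)
  d[d == 0] <- floor_d
  W <- 1 / d^power
  diag(W) <- 0
  dimnames(W) <- NULL
  if (row_standardize) W <- W / rowSums(W)
  structure(list(W = W, coords = coords, scheme = "inverse-distance",
                 power = power, row_standardized = row_standardize,
                 n_coincident_pairs = n_co),
            class = "spatial_weights")
}

#' Global Moran's I
#'
#' `I = (n / S0) * sum_ij W_ij (y_i - ybar)(y_j - ybar) / sum_i (y_i - ybar)^2`
#' with `S0` the sum of all weights. Positive values indicate spatial
#' clustering of like values, negative values dispersion; the expectation
#' under the randomisation null is `-1/(n-1)`.
#'
#' @param values Numeric vector, one value per site.
#' @param weights A `spatial_weights` object.
#' @return A `moran_result` list: `I`, `expected`, `n`, `S0`; `p_value`,
#'   `n_perm`, `seed` are `NA` until a permutation test fills them.
#' @export
morans_i_global <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  if (n != nrow(weights$W)) stop_value("values do not match the weight matrix")
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0) stop_value("values have zero variance")
  S0 <- sum(weights$W)
  I <- (n / S0) * drop(crossprod(z, weights$W %*% z)) / s2
  structure(list(I = I, expected = -1 / (n - 1), n = n, S0 = S0,
                 p_value = NA_real_, n_perm = NA_integer_,
                 seed = NA_integer_, tail = NA_character_),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, n = %d)", x$I, x$expected,
              x$n))
  if (!is.na(x$p_value))
    cat(sprintf("; permutation p = %.4g (%d permutations, %s tail)",
                x$p_value, x$n_perm, x$tail))
  cat("\n")
  invisible(x)
}

#' Local Moran's I
#'
#' `I_i = ((y_i - ybar) / delta) * sum_{j != i} W_ij (y_j - ybar)` with
#' `delta` the (population) variance of `y`. With row-standardised weights
#' the mean of the local values equals the global statistic.
#'
#' @param values Numeric vector, one value per site.
#' @param weights A `spatial_weights` object.
#' @return Numeric vector of per-site local I values.
#' @export
morans_i_local <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  n <- length(values)
  if (n != nrow(weights$W)) stop_value("values do not match the weight matrix")
  z <- values - mean(values)
  delta <- mean(z^2)
  if (delta == 0) stop_value("values have zero variance")
  drop(z / delta * (weights$W %*% z))
}

#' Monte Carlo permutation test for global Moran's I
#'
#' Randomly relabels the values across sites `n_perm` times and compares the
#' permuted statistics with the observed one. The positive-tail p-value is
#' `(1 + #{I_perm >= I_obs}) / (1 + n_perm)`; the two-sided variant compares
#' absolute deviations from the null expectation `-1/(n-1)`.
#'
#' @param values Numeric vector, one value per site.
#' @param weights A `spatial_weights` object.
#' @param n_perm Number of permutations (default 599, the conventional
#'   Monte Carlo count giving a minimum attainable p of 1/600).
#' @param seed Integer seed; the test is reproducible given the seed.
#' @param tail `"positive"` (clustering alternative, default) or
#'   `"two-sided"`.
#' @return A `moran_result` with `p_value`, `n_perm`, `seed`, `tail` filled
#'   and the permuted statistics attached as `perm_I`.
#' @export
permutation_test <- function(values, weights, n_perm = 599, seed = 1,
                             tail = c("positive", "two-sided")) {
  tail <- match.arg(tail)
  if (n_perm < 19) stop_value("n_perm must be at least 19")
  obs <- morans_i_global(values, weights)
  n <- obs$n
  z <- values - mean(values)
  s2 <- sum(z^2)
  Zp <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  })
  Ip <- (n / obs$S0) * colSums(Zp * (weights$W %*% Zp)) / s2
  p <- if (tail == "positive") {
    (1 + sum(Ip >= obs$I)) / (1 + n_perm)
  } else {
    (1 + sum(abs(Ip - obs$expected) >= abs(obs$I - obs$expected))) /
      (1 + n_perm)
  }
  obs$p_value <- p
  obs$n_perm <- as.integer(n_perm)
  obs$seed <- as.integer(seed)
  obs$tail <- tail
  obs$perm_I <- Ip
  obs
}

#' Regular raster grid specification
#'
#' @param origin `c(x, y)` of the lower-left corner (m).
#' @param cellsize Cell edge length (m).
#' @param n_rows,n_cols Grid dimensions; row 1 is the northernmost row.
#' @return A `raster_grid` with an all-`NA` values matrix.
#' @export
raster_grid <- function(origin, cellsize, n_rows, n_cols) {
  structure(list(origin = as.numeric(origin), cellsize = cellsize,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 values = matrix(NA_real_, n_rows, n_cols),
                 nodata = -9999),
            class = "raster_grid")
}

grid_centers <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$n_cols) - 0.5) * grid$cellsize
  ys <- grid$origin[2] + (grid$n_rows - seq_len(grid$n_rows) + 0.5) *
    grid$cellsize
  list(x = xs, y = ys)  # ys ordered north -> south to match row order
}

#' Inverse-distance-weighted interpolation onto a raster grid
#'
#' Each cell value is `sum(w_k v_k) / sum(w_k)` with `w_k = 1/d_k^power`
#' over the data points (or the `max_neighbors` nearest ones). A cell whose
#' centre coincides with a data point takes that point's value exactly, and
#' every interpolated value lies within the data range.
#'
#' @param points Two-column matrix/data frame of point coordinates (m).
#' @param values Numeric vector of point values.
#' @param grid A `raster_grid` covering the points.
#' @param power IDW decay exponent (default 2, the conventional choice).
#' @param max_neighbors Optional neighbour cap; default uses all points.
#' @return The `raster_grid` with its values matrix filled.
#' @export
idw_interpolate <- function(points, values, grid, power = 2,
                            max_neighbors = NULL) {
  stopifnot(inherits(grid, "raster_grid"))
  points <- as.matrix(points)
  if (nrow(points) < 1) stop_value("at least one data point is required")
  if (length(values) != nrow(points))
    stop_value("values must match the number of points")
  if (grid$n_rows < 1 || grid$n_cols < 1) stop_value("empty grid")
  ctr <- grid_centers(grid)
  cells <- cbind(x = rep(ctr$x, each = grid$n_rows),
                 y = rep(ctr$y, times = grid$n_cols))
  # distances: cells x points
  d2 <- outer(cells[, "x"], points[, 1], "-")^2 +
    outer(cells[, "y"], points[, 2], "-")^2
  d <- sqrt(d2)
  w <- 1 / d^power
  if (!is.null(max_neighbors) && max_neighbors < nrow(points)) {
    for (i in seq_len(nrow(w))) {
      keep <- order(d[i, ])[seq_len(max_neighbors)]
      w[i, -keep] <- 0
    }
  }
  exact <- d == 0
  vals <- as.vector((w %*% values) / rowSums(w))
  hit <- which(rowSums(exact) > 0)
  if (length(hit)) {
    vals[hit] <- values[apply(exact[hit, , drop = FALSE], 1, which.max)]
  }
  grid$values <- matrix(vals, grid$n_rows, grid$n_cols)
  grid
}

#' Bin DRIS index values into severity classes
#'
#' Presentation binning of nutrient-limitation intensity into
#' severe/moderate/low/optimum classes at configurable breaks (defaults
#' 0.5, 2 and 5 on the mapped proxy scale).
#'
#' @param values Numeric vector.
#' @param breaks Three increasing break points.
#' @param labels Four class labels, most severe first.
#' @return Factor of classes, levels ordered `labels`.
#' @export
classify_severity <- function(values, breaks = c(0.5, 2, 5),
                              labels = c("severe", "moderate", "low",
                                         "optimum")) {
  stopifnot(length(breaks) == 3, length(labels) == 4, !is.unsorted(breaks))
  cut(values, c(-Inf, breaks, Inf), labels = labels, right = FALSE)
}

#' Write a raster as a headered ASCII grid
#'
#' ESRI ASCII grid format: `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value` header then rows north to south.
#'
#' @param grid A `raster_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster_ascii <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$origin[1]),
               sprintf("yllcorner %.10g", grid$origin[2]),
               sprintf("cellsize %.10g", grid$cellsize),
               sprintf("NODATA_value %g", grid$nodata)), con)
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a headered ASCII grid raster
#' @param path File written by [write_raster_ascii()].
#' @return A `raster_grid`.
#' @export
read_raster_ascii <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  val <- function(name) {
    for (p in kv) if (tolower(p[1]) == tolower(name)) return(as.numeric(p[2]))
    stop_value("missing header field ", name)
  }
  g <- raster_grid(c(val("xllcorner"), val("yllcorner")), val("cellsize"),
                   val("nrows"), val("ncols"))
  g$nodata <- val("NODATA_value")
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == g$nodata] <- NA_real_
  g$values <- m
  g
}
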