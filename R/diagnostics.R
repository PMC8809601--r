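#' Plant biovolume from height and basal diameter
#'
#' Cylinder approximation of plant size used as a crop-response proxy:
#' `BV = H * (BD/2)^2 * pi` with height and basal diameter in centimetres.
#'
#' @param H Plant height (cm), >= 0.
#' @param BD Basal diameter (cm, mean of duplicate measurements), >= 0.
#' @return Biovolume in cm^3.
#' @examples
#' biovolume(100, 2)  # 100 * pi
#' @export
biovolume <- function(H, BD) {
  if (any(H < 0, na.rm = TRUE) || any(BD < 0, na.rm = TRUE))
    stop_value("height and basal diameter must be non-negative")
  H * (BD / 2)^2 * pi
}

#' Descriptive statistics with CV and 95% confidence interval
#'
#' Summarises a numeric vector after dropping missing values: n, minimum,
#' maximum, median, mean, sample (n-1) standard deviation, coefficient of
#' variation as a percentage of the mean, and the Student-t 95% confidence
#' half-width of the mean.
#'
#' @param values Numeric vector (missing values dropped).
#' @return One-row data frame of class `descriptive_stats` with columns
#'   `n`, `min`, `max`, `median`, `mean`, `sd`, `cv`, `ci95_halfwidth`.
#' @export
describe_values <- function(values) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 2) stop_value("at least 2 non-missing values are required")
  m <- mean(x)
  s <- stats::sd(x)
  out <- data.frame(
    n = n, min = min(x), max = max(x), median = stats::median(x),
    mean = m, sd = s,
    cv = if (m != 0) 100 * s / m else NA_real_,
    ci95_halfwidth = stats::qt(0.975, n - 1) * s / sqrt(n))
  class(out) <- c("descriptive_stats", "data.frame")
  out
}

#' Classify deficiency against a critical threshold
#'
#' A unit is deficient when its soil-test (or tissue) value is strictly
#' below the critical threshold. Prevalence is the percentage of deficient
#' units among non-missing values.
#'
#' @param values Numeric vector; `NA` excluded from the prevalence.
#' @param threshold Finite critical value.
#' @return List with `deficient` (logical, `NA` preserved) and
#'   `prevalence` (percent).
#' @export
classify_deficiency <- function(values, threshold) {
  if (!is.finite(threshold)) stop_value("threshold must be finite")
  flags <- values < threshold
  list(deficient = flags, prevalence = 100 * mean(flags, na.rm = TRUE))
}

#' Cate-Nelson partitioning of a soil-test / yield scatter
#'
#' Exhaustive two-way scan locating the critical soil-test value and the
#' critical yield that best separate responsive from non-responsive plots.
#' Candidate splits are the midpoints of consecutive sorted unique `x` and
#' `y` values. The selected pair maximises the number of points in the
#' agreeing quadrants — II (x below critical, y below critical; responsive)
#' and IV (x and y at or above their criticals) — counted in excess of its
#' expectation under independent margins,
#' `(n_lowx * n_lowy + n_highx * n_highy) / n`. The chance correction is
#' what makes the scan noise-robust: without it a corner split isolating a
#' single extreme point scores `n - 1` agreeing points and always wins.
#' Ties are broken by the larger raw agreeing count, then the larger
#' binary-split R-squared of `y` on the x-split, then the smaller
#' `critical_x`, then the smaller `critical_y`.
#'
#' Quadrants are labelled I (x >= critical_x, y < critical_y),
#' II (x < critical_x, y < critical_y), III (x < critical_x,
#' y >= critical_y), IV (x >= critical_x, y >= critical_y).
#'
#' @param x Soil-test values.
#' @param y Paired yields (pairs with any `NA` are dropped).
#' @param ids Optional identifiers reported for the agreeing (responsive)
#'   plots; defaults to the row positions of the complete pairs.
#' @return A `cate_nelson` list: `critical_x`, `critical_y`, `counts`
#'   (quadrants I-IV), `responsive_ids`, `separation_r2` (fraction of points
#'   in the agreeing quadrants), `split_r2` (binary-split R-squared), `n`.
#' @export
cate_nelson <- function(x, y, ids = NULL) {
  keep <- !is.na(x) & !is.na(y)
  if (is.null(ids)) ids <- seq_along(x)
  x <- x[keep]; y <- y[keep]; ids <- ids[keep]
  n <- length(x)
  if (n < 8) stop_value("at least 8 complete pairs are required")
  ux <- sort(unique(x)); uy <- sort(unique(y))
  if (length(ux) < 2 || length(uy) < 2)
    stop_value("degenerate split: x or y is constant")
  cx_cand <- (ux[-1] + ux[-length(ux)]) / 2
  cy_cand <- (uy[-1] + uy[-length(uy)]) / 2

  ys <- sort(y)
  tss <- sum((y - mean(y))^2)
  n_lowy <- findInterval(cy_cand, ys)  # points with y below each cy
  best <- list(excess = -Inf, agree = -1, split_r2 = -1, cx = NA, cy = NA)
  for (cx in cx_cand) {
    low <- x < cx
    yl <- sort(y[low]); yh <- sort(y[!low])
    nl <- length(yl); nh <- length(yh)
    # counts below each candidate cy (no y ever equals a midpoint)
    n_low_below <- findInterval(cy_cand, yl)
    n_high_ge <- nh - findInterval(cy_cand, yh)
    agree <- n_low_below + n_high_ge
    expected <- (nl * n_lowy + nh * (n - n_lowy)) / n
    excess <- agree - expected
    # binary-split R2 of y on this x-split (cy-independent)
    sse <- sum((yl - mean(yl))^2) + sum((yh - mean(yh))^2)
    r2 <- if (tss > 0) 1 - sse / tss else 0
    j <- which.max(excess)  # smallest cy among maxima
    if (excess[j] > best$excess + 1e-9 ||
        (abs(excess[j] - best$excess) <= 1e-9 &&
         (agree[j] > best$agree ||
          (agree[j] == best$agree && r2 > best$split_r2 + 1e-12)))) {
      best <- list(excess = excess[j], agree = agree[j], split_r2 = r2,
                   cx = cx, cy = cy_cand[j])
    }
  }
  cx <- best$cx; cy <- best$cy
  qII <- x < cx & y < cy
  qIV <- x >= cx & y >= cy
  qI <- x >= cx & y < cy
  qIII <- x < cx & y >= cy
  structure(list(
    critical_x = cx, critical_y = cy,
    counts = c(I = sum(qI), II = sum(qII), III = sum(qIII), IV = sum(qIV)),
    responsive_ids = ids[qII | qIV],
    separation_r2 = best$agree / n,
    split_r2 = best$split_r2,
    n = n), class = "cate_nelson")
}

#' @export
print.cate_nelson <- function(x, ...) {
  cat(sprintf(
    "Cate-Nelson: critical_x = %.4g, critical_y = %.4g (n = %d)\n",
    x$critical_x, x$critical_y, x$n))
  cat(sprintf("  quadrants I-IV: %s; agreement = %.1f%%, split R2 = %.3f\n",
              paste(x$counts, collapse = "/"), 100 * x$separation_r2,
              x$split_r2))
  invisible(x)
}

#' Localized cut-off from the overlap of two frequency distributions
#'
#' Fits a normal density to the deficient and the sufficient subpopulation
#' (optionally on the natural-log scale) and returns the soil-test value
#' where the two density curves cross between the group means. When no
#' crossing lies between the means (possible with very unequal variances),
#' the cut-off falls back to the midpoint between the upper `ci_level`
#' population bound of the lower-mean group and the lower bound of the
#' other; the `method` tag records which branch ran.
#'
#' @param deficient_values,sufficient_values Numeric vectors, each with at
#'   least 5 non-missing values.
#' @param ci_level Population interval level for the fallback (default 0.90).
#' @param log_scale Fit and solve on the natural-log scale, reporting the
#'   cut-off back-transformed.
#' @return A `cutoff_result`: `cutoff`, per-group `mean`, `sd`, `n` and
#'   `ci` bounds (on the reporting scale), and `method`
#'   (`"density-crossing"` or `"ci-overlap-midpoint"`).
#' @export
derive_cutoff <- function(deficient_values, sufficient_values,
                          ci_level = 0.90, log_scale = FALSE) {
  d <- deficient_values[!is.na(deficient_values)]
  s <- sufficient_values[!is.na(sufficient_values)]
  if (length(d) < 5 || length(s) < 5)
    stop_value("each subpopulation needs at least 5 values")
  if (log_scale) {
    if (any(c(d, s) <= 0)) stop_value("log scale requires positive values")
    d <- log(d); s <- log(s)
  }
  md <- mean(d); sd_d <- stats::sd(d)
  ms <- mean(s); sd_s <- stats::sd(s)
  if (isTRUE(all.equal(md, ms)))
    stop_value("subpopulation means coincide; no cut-off exists")
  # solve with group 1 as the lower-mean group (label-symmetric)
  if (md <= ms) { m1 <- md; s1 <- sd_d; m2 <- ms; s2 <- sd_s }
  else { m1 <- ms; s1 <- sd_s; m2 <- md; s2 <- sd_d }

  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  cutoff <- NA_real_
  method <- NA_character_
  if (abs(s1 - s2) < 1e-12 * max(s1, s2)) {
    cutoff <- (m1 + m2) / 2
    method <- "density-crossing"
  } else {
    a <- 1 / s1^2 - 1 / s2^2
    b <- -2 * (m1 / s1^2 - m2 / s2^2)
    cc <- m1^2 / s1^2 - m2^2 / s2^2 + 2 * log(s1 / s2)
    disc <- b^2 - 4 * a * cc
    if (disc >= 0) {
      roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
      inside <- roots[roots > m1 & roots < m2]
      if (length(inside)) {
        cutoff <- inside[1]
        method <- "density-crossing"
      }
    }
    if (is.na(cutoff)) {
      cutoff <- ((m1 + z * s1) + (m2 - z * s2)) / 2
      method <- "ci-overlap-midpoint"
    }
  }
  back <- function(v) if (log_scale) exp(v) else v
  structure(list(
    cutoff = back(cutoff),
    deficient = list(mean = back(md), sd = sd_d, n = length(d),
                     ci = back(c(lower = md - z * sd_d, upper = md + z * sd_d))),
    sufficient = list(mean = back(ms), sd = sd_s, n = length(s),
                      ci = back(c(lower = ms - z * sd_s, upper = ms + z * sd_s))),
    ci_level = ci_level, log_scale = log_scale, method = method),
    class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("cutoff = %.4g (%s, %d%% CI%s)\n", x$cutoff, x$method,
              round(100 * x$ci_level), if (x$log_scale) ", log scale" else ""))
  invisible(x)
}

#' Flag one-sided high outliers
#'
#' Flags values exceeding `mean + k_sd * sd`, where mean and sd are computed
#' leaving the candidate value out, so an extreme point cannot mask itself
#' by inflating its own bound (in a sample of n the largest possible
#' within-sample z-score is `(n-1)/sqrt(n)`, so a self-inclusive 3-sd rule
#' can never fire for small n). Only the high side is screened, matching
#' the removal of rare very high tissue-N records, and the rule is applied
#' once, without iteration.
#'
#' @param values Numeric vector (`NA` ignored and never flagged).
#' @param k_sd Multiplier of the standard deviation (default 3).
#' @return List with `values` (kept non-missing values), `flags` (logical,
#'   same length as the input), and `bound` (per-value leave-one-out
#'   bounds, `NA` where the value is missing).
#' @export
remove_outliers <- function(values, k_sd = 3) {
  ok <- !is.na(values)
  x <- values[ok]
  n <- length(x)
  if (n < 3) stop_value("at least 3 non-missing values are required")
  s <- sum(x); q <- sum(x^2)
  mean_loo <- (s - x) / (n - 1)
  var_loo <- pmax(0, (q - x^2 - (n - 1) * mean_loo^2) / (n - 2))
  bound_x <- mean_loo + k_sd * sqrt(var_loo)
  flags <- logical(length(values))
  flags[ok] <- x > bound_x
  bound <- rep(NA_real_, length(values))
  bound[ok] <- bound_x
  list(values = values[ok & !flags], flags = flags, bound = bound)
}
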