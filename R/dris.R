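#' Split a survey into deficient and sufficient subpopulations
#'
#' Divides plot records on grain yield: sufficient plots have
#' `grain_yield >= yield_threshold`, deficient plots fall below it. Rows
#' with missing yield are excluded and counted. The threshold is typically
#' the critical yield from a Cate-Nelson analysis.
#'
#' @param survey A `survey_table` (any data frame with `grain_yield`).
#' @param yield_threshold Yield split point (Mg ha^-1).
#' @return List with `deficient` and `sufficient` row subsets and
#'   `n_missing_yield`.
#' @export
split_subpopulations <- function(survey, yield_threshold) {
  if (!"grain_yield" %in% names(survey))
    stop_value("survey must contain a grain_yield column")
  miss <- is.na(survey$grain_yield)
  suff <- !miss & survey$grain_yield >= yield_threshold
  def <- !miss & !suff
  if (!any(suff))
    stop_value("sufficient subpopulation is empty; norms cannot be computed")
  list(deficient = survey[def, , drop = FALSE],
       sufficient = survey[suff, , drop = FALSE],
       n_missing_yield = sum(miss))
}

tissue_ratios <- function(tab) {
  need <- c("tissue_N", "tissue_P", "tissue_K")
  if (!all(need %in% names(tab)))
    stop_value("table must contain tissue_N, tissue_P, tissue_K")
  N <- tab$tissue_N; P <- tab$tissue_P; K <- tab$tissue_K
  ok <- is.finite(N) & is.finite(P) & is.finite(K) & P > 0 & K > 0
  list(np = N[ok] / P[ok], nk = N[ok] / K[ok], pk = P[ok] / K[ok],
       ok = ok, n_excluded = sum(!ok))
}

#' Compute DRIS norms from the sufficient subpopulation
#'
#' Norms are the arithmetic means of the tissue nutrient ratios N/P, N/K and
#' P/K over the sufficient (high-yield) subpopulation, with their
#' coefficients of variation (percent). Records with a zero or missing
#' tissue denominator are excluded and counted. When the deficient
#' subpopulation is supplied, the deficient/sufficient variance ratio of
#' each ratio is attached with its two-sided F-test p-value, the classical
#' check that the two subpopulations genuinely separate.
#'
#' @param sufficient Data frame of sufficient-subpopulation tissue records.
#' @param deficient Optional data frame of deficient records.
#' @param k Sensitivity constant stored with the norms (default 1000).
#' @return A `dris_norms` list: `norms` (np, nk, pk), `cv` (percent), `n`,
#'   `n_excluded`, `k`, and optionally `variance_ratio` and `f_pvalue`.
#' @export
compute_norms <- function(sufficient, deficient = NULL, k = 1000) {
  r <- tissue_ratios(sufficient)
  n <- length(r$np)
  if (n < 2) stop_value("at least 2 complete sufficient records required")
  if (n < 10)
    warning("norms computed from fewer than 10 sufficient records",
            call. = FALSE)
  norms <- c(np = mean(r$np), nk = mean(r$nk), pk = mean(r$pk))
  cv <- c(np = 100 * stats::sd(r$np) / mean(r$np),
          nk = 100 * stats::sd(r$nk) / mean(r$nk),
          pk = 100 * stats::sd(r$pk) / mean(r$pk))
  out <- list(norms = norms, cv = cv, n = n, n_excluded = r$n_excluded,
              k = k)
  if (!is.null(deficient)) {
    rd <- tissue_ratios(deficient)
    if (length(rd$np) >= 2) {
      vr <- function(a, b) stats::var(a) / stats::var(b)
      pv <- function(a, b) {
        f <- stats::var(a) / stats::var(b)
        df1 <- length(a) - 1; df2 <- length(b) - 1
        2 * min(stats::pf(f, df1, df2), 1 - stats::pf(f, df1, df2))
      }
      out$variance_ratio <- c(np = vr(rd$np, r$np), nk = vr(rd$nk, r$nk),
                              pk = vr(rd$pk, r$pk))
      out$f_pvalue <- c(np = pv(rd$np, r$np), nk = pv(rd$nk, r$nk),
                        pk = pv(rd$pk, r$pk))
    }
  }
  structure(out, class = "dris_norms")
}

#' @export
print.dris_norms <- function(x, ...) {
  cat(sprintf(
    "DRIS norms (n = %d, k = %g): N/P = %.3f (CV %.1f%%), N/K = %.3f (CV %.1f%%), P/K = %.3f (CV %.1f%%)\n",
    x$n, x$k, x$norms[["np"]], x$cv[["np"]], x$norms[["nk"]], x$cv[["nk"]],
    x$norms[["pk"]], x$cv[["pk"]]))
  invisible(x)
}

#' DRIS ratio function
#'
#' Deviation of an observed tissue ratio from its norm, scaled by the
#' sensitivity constant over the sufficient-subpopulation CV:
#' `(observed/norm - 1) * k / cv_pct` when the observed ratio exceeds the
#' norm, `-(1 - observed/norm) * k / cv_pct` when it falls below, and 0 at
#' equality (the two branches join continuously).
#'
#' @param observed Observed tissue ratio(s).
#' @param norm Norm (mean sufficient-subpopulation ratio), > 0.
#' @param cv_pct Coefficient of variation of the ratio in percent, > 0.
#' @param k Sensitivity constant (default 1000).
#' @return Numeric, same length as `observed`.
#' @examples
#' dris_f_ratio(12, 10, 20)  # 10
#' dris_f_ratio(8, 10, 20)   # -10
#' @export
dris_f_ratio <- function(observed, norm, cv_pct, k = 1000) {
  if (any(norm <= 0)) stop_value("norm must be > 0")
  if (any(cv_pct <= 0)) stop_value("cv_pct must be > 0")
  ifelse(observed >= norm,
         (observed / norm - 1) * k / cv_pct,
         -(1 - observed / norm) * k / cv_pct)
}

#' Per-plot DRIS indices
#'
#' Combines the three ratio functions into nutrient indices with the sign
#' convention that subtracts a ratio's f where the nutrient appears in the
#' denominator, so the three indices of every plot sum to zero:
#' `index_N = (f_np + f_nk)/2`, `index_P = (-f_np + f_pk)/2`,
#' `index_K = (-f_nk - f_pk)/2`. The most negative index marks the most
#' limiting nutrient. Plots with missing or zero-denominator tissue values
#' are skipped and flagged.
#'
#' @param tissue Data frame with `tissue_N`, `tissue_P`, `tissue_K` (extra
#'   columns such as ids are carried through).
#' @param norms A `dris_norms` object.
#' @return A `dris_indices` data frame: carried id columns, `f_np`, `f_nk`,
#'   `f_pk`, `index_N`, `index_P`, `index_K`, `complete` flag.
#' @export
compute_indices <- function(tissue, norms) {
  stopifnot(inherits(norms, "dris_norms"))
  if (any(norms$cv <= 0))
    stop_value("ratio CV is zero; indices are undefined for a degenerate norm set")
  r <- tissue_ratios(tissue)
  n <- nrow(tissue)
  f_np <- f_nk <- f_pk <- rep(NA_real_, n)
  f_np[r$ok] <- dris_f_ratio(tissue$tissue_N[r$ok] / tissue$tissue_P[r$ok],
                             norms$norms[["np"]], norms$cv[["np"]], norms$k)
  f_nk[r$ok] <- dris_f_ratio(tissue$tissue_N[r$ok] / tissue$tissue_K[r$ok],
                             norms$norms[["nk"]], norms$cv[["nk"]], norms$k)
  f_pk[r$ok] <- dris_f_ratio(tissue$tissue_P[r$ok] / tissue$tissue_K[r$ok],
                             norms$norms[["pk"]], norms$cv[["pk"]], norms$k)
  id_cols <- intersect(c("plot_id", "field_id", "lon", "lat", "x", "y"),
                       names(tissue))
  out <- data.frame(tissue[, id_cols, drop = FALSE],
                    f_np = f_np, f_nk = f_nk, f_pk = f_pk,
                    index_N = (f_np + f_nk) / 2,
                    index_P = (-f_np + f_pk) / 2,
                    index_K = (-f_nk - f_pk) / 2,
                    complete = r$ok,
                    stringsAsFactors = FALSE)
  attr(out, "norms") <- norms
  class(out) <- c("dris_indices", "data.frame")
  out
}

#' Rank nutrient limitations from DRIS indices
#'
#' Orders nutrients by ascending mean index (the most negative mean is the
#' most limiting) and also reports the per-plot most-limiting nutrient
#' counts and prevalence, so both population-mean and per-field summaries
#' are available. All-zero indices are declared balanced with an empty
#' ranking.
#'
#' @param indices A `dris_indices` data frame.
#' @return List with `ranking` (nutrient names, most limiting first),
#'   `mean_indices`, `most_limiting_counts`, `most_limiting_prevalence`
#'   (percent), `balanced`, `n`.
#' @export
rank_limitations <- function(indices) {
  ok <- indices$complete & !is.na(indices$index_N)
  if (!any(ok)) stop_value("no plots with computed indices")
  m <- c(N = mean(indices$index_N[ok]), P = mean(indices$index_P[ok]),
         K = mean(indices$index_K[ok]))
  idx <- as.matrix(indices[ok, c("index_N", "index_P", "index_K")])
  if (all(abs(idx) < 1e-12)) {
    return(list(ranking = character(), mean_indices = m,
                most_limiting_counts = c(N = 0, P = 0, K = 0),
                most_limiting_prevalence = c(N = 0, P = 0, K = 0),
                balanced = TRUE, n = sum(ok)))
  }
  worst <- c("N", "P", "K")[apply(idx, 1, which.min)]
  counts <- c(N = sum(worst == "N"), P = sum(worst == "P"),
              K = sum(worst == "K"))
  list(ranking = names(sort(m)), mean_indices = m,
       most_limiting_counts = counts,
       most_limiting_prevalence = 100 * counts / sum(ok),
       balanced = FALSE, n = sum(ok))
}
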