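make_tissue <- function(N, P, K, ids = NULL) {
  data.frame(plot_id = ids %||% sprintf("p%03d", seq_along(N)),
             tissue_N = N, tissue_P = P, tissue_K = K,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("yield split honours the threshold and counts missing records", {
  sv <- default_survey(seed = 61)
  ymin <- min(sv$grain_yield, na.rm = TRUE)
  all_suff <- split_subpopulations(sv, ymin)
  expect_equal(nrow(all_suff$deficient), 0)
  expect_equal(nrow(all_suff$sufficient) + all_suff$n_missing_yield, nrow(sv))

  expect_error(split_subpopulations(sv, max(sv$grain_yield, na.rm = TRUE) + 1),
               "empty")

  # at the Cate-Nelson critical yield the two groups are of comparable size
  ok <- !is.na(sv$grain_yield)
  cn <- cate_nelson(sv$soil_N[ok], sv$grain_yield[ok])
  sp <- split_subpopulations(sv, cn$critical_y)
  total <- nrow(sp$deficient) + nrow(sp$sufficient)
  expect_gt(nrow(sp$deficient) / total, 0.2)
  expect_gt(nrow(sp$sufficient) / total, 0.2)
})

test_that("norms are ratio means with CVs and variance-ratio checks", {
  two <- make_tissue(N = c(8, 12), P = c(1, 1), K = c(2, 2))
  norms <- suppressWarnings(compute_norms(two))
  expect_equal(unname(norms$norms[["np"]]), 10)
  expect_equal(unname(norms$norms[["nk"]]), mean(c(4, 6)))

  # zero-denominator records are excluded and counted
  bad <- make_tissue(N = c(8, 12, 5), P = c(1, 1, 0), K = c(2, 2, 1))
  norms2 <- suppressWarnings(compute_norms(bad))
  expect_equal(norms2$n, 2)
  expect_equal(norms2$n_excluded, 1)

  # sampling-distribution oracle: norms from a known generating distribution
  set.seed(62)
  n <- 400
  suff <- make_tissue(N = rnorm(n, 3, 0.3), P = rnorm(n, 0.3, 0.03),
                      K = rnorm(n, 2, 0.2))
  norms3 <- compute_norms(suff)
  true_np <- mean(suff$tissue_N / suff$tissue_P)
  se_np <- sd(suff$tissue_N / suff$tissue_P) / sqrt(n)
  expect_lt(abs(norms3$norms[["np"]] - true_np), 2 * se_np + 1e-12)

  # deficient group with inflated spread yields variance ratios > 1
  def <- make_tissue(N = rnorm(n, 3, 0.9), P = rnorm(n, 0.3, 0.09),
                     K = rnorm(n, 2, 0.6))
  norms4 <- compute_norms(suff, def)
  expect_true(all(norms4$variance_ratio > 1))
  expect_true(all(norms4$f_pvalue < 0.01))
})

test_that("the ratio function matches hand evaluations and its sign law", {
  expect_equal(dris_f_ratio(12, 10, 20, 1000), 10)
  expect_equal(dris_f_ratio(10, 10, 20, 1000), 0)
  expect_equal(dris_f_ratio(8, 10, 20, 1000), -10)
  expect_error(dris_f_ratio(1, 10, 0), "cv_pct")
  expect_error(dris_f_ratio(1, 0, 20), "norm")

  # sign(f) = sign(observed - norm), |f| strictly increasing in |obs/norm - 1|
  obs <- seq(2, 30, by = 0.5)
  f <- dris_f_ratio(obs, 10, 25)
  expect_equal(sign(f), sign(obs - 10))
  dev <- abs(obs / 10 - 1)
  ord <- order(dev)
  expect_true(all(diff(abs(f)[ord]) >= 0))
})

test_that("indices sum to zero, respond to imbalance and ignore common scaling", {
  set.seed(63)
  n <- 120
  suff <- make_tissue(N = rnorm(n, 3, 0.3), P = rnorm(n, 0.3, 0.03),
                      K = rnorm(n, 2, 0.2))
  norms <- compute_norms(suff)

  tissue <- make_tissue(N = runif(30, 1, 5), P = runif(30, 0.1, 0.6),
                        K = runif(30, 0.5, 4))
  idx <- compute_indices(tissue, norms)
  sums <- idx$index_N + idx$index_P + idx$index_K
  expect_lt(max(abs(sums)), 1e-9)
  expect_equal(idx$index_N, (idx$f_np + idx$f_nk) / 2)
  expect_equal(idx$index_P, (-idx$f_np + idx$f_pk) / 2)
  expect_equal(idx$index_K, (-idx$f_nk - idx$f_pk) / 2)

  # a plot whose N/P and P/K ratios equal the norms has zero f for both
  # (ratio norms need not be mutually consistent, so N/K can still deviate)
  K0 <- 1; P0 <- norms$norms[["pk"]] * K0; N0 <- norms$norms[["np"]] * P0
  idxb <- compute_indices(make_tissue(N0, P0, K0), norms)
  expect_equal(idxb$f_np, 0, tolerance = 1e-9)
  expect_equal(idxb$f_pk, 0, tolerance = 1e-9)

  # common scaling of all tissue concentrations leaves indices unchanged
  scaled <- tissue
  scaled[, c("tissue_N", "tissue_P", "tissue_K")] <-
    tissue[, c("tissue_N", "tissue_P", "tissue_K")] * 3.7
  idx2 <- compute_indices(scaled, norms)
  expect_equal(idx2$index_N, idx$index_N, tolerance = 1e-9)
  expect_equal(idx2$index_P, idx$index_P, tolerance = 1e-9)

  # incomplete tissue records are skipped and flagged
  holes <- tissue
  holes$tissue_P[3] <- NA
  idx3 <- compute_indices(holes, norms)
  expect_false(idx3$complete[3])
  expect_true(is.na(idx3$index_N[3]))

  # degenerate norms (zero CV) refuse to produce indices
  const <- make_tissue(N = rep(3, 12), P = rep(0.3, 12), K = rep(2, 12))
  norms_const <- compute_norms(const)
  expect_error(compute_indices(tissue, norms_const), "degenerate")
})

test_that("ranking orders nutrients by ascending mean index", {
  idx <- structure(data.frame(
    index_N = c(-6.3, -6.3), index_P = c(-13.5, -13.5),
    index_K = c(-2.1, -2.1), f_np = 0, f_nk = 0, f_pk = 0,
    complete = TRUE), class = c("dris_indices", "data.frame"))
  r <- rank_limitations(idx)
  expect_equal(r$ranking, c("P", "N", "K"))
  expect_equal(unname(r$mean_indices), c(-6.3, -13.5, -2.1))
  expect_equal(unname(r$most_limiting_counts[["P"]]), 2)

  zero <- structure(data.frame(index_N = 0, index_P = 0, index_K = 0,
                               f_np = 0, f_nk = 0, f_pk = 0,
                               complete = TRUE),
                    class = c("dris_indices", "data.frame"))
  rz <- rank_limitations(zero)
  expect_true(rz$balanced)
  expect_length(rz$ranking, 0)

  single <- structure(data.frame(index_N = -2, index_P = 5, index_K = -3,
                                 f_np = 0, f_nk = 0, f_pk = 0,
                                 complete = TRUE),
                      class = c("dris_indices", "data.frame"))
  rs <- rank_limitations(single)
  expect_equal(rs$ranking, c("K", "N", "P"))
  expect_equal(unname(rs$most_limiting_counts[["K"]]), 1)
})
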