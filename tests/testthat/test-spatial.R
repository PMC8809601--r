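test_that("inverse-distance weights match direct computation", {
  tri <- cbind(c(0, 1, 2), c(0, 0, 0))
  w <- build_weights(tri, power = 1, row_standardize = FALSE)
  expect_equal(w$W[1, 2], 1)
  expect_equal(w$W[1, 3], 0.5)
  expect_equal(diag(w$W), rep(0, 3))

  ws <- build_weights(tri, power = 1, row_standardize = TRUE)
  expect_equal(unname(rowSums(ws$W)), rep(1, 3))

  set.seed(71)
  pts <- matrix(runif(40, 0, 1000), 20, 2)
  w2 <- build_weights(pts, power = 1.5, row_standardize = FALSE)
  # element-wise brute force
  for (i in 1:20) for (j in 1:20) {
    expected <- if (i == j) 0 else
      1 / sqrt(sum((pts[i, ] - pts[j, ])^2))^1.5
    expect_equal(w2$W[i, j], expected, tolerance = 1e-12)
  }

  # coincident points get a floored distance, all-coincident is an error
  dup <- rbind(pts[1:4, ], pts[1, ])
  wd <- build_weights(dup)
  expect_equal(wd$n_coincident_pairs, 1)
  expect_true(all(is.finite(wd$W)))
  expect_error(build_weights(matrix(1, 4, 2)), "coincident")
})

test_that("global Moran's I matches the brute-force double sum", {
  set.seed(72)
  pts <- matrix(runif(40, 0, 100), 20, 2)
  vals <- rnorm(20)
  for (rs in c(TRUE, FALSE)) {
    w <- build_weights(pts, row_standardize = rs)
    m <- morans_i_global(vals, w)
    expect_equal(m$I, moran_oracle(vals, w$W), tolerance = 1e-10)
    expect_equal(m$expected, -1 / 19)
  }
  w <- build_weights(pts)
  expect_error(morans_i_global(rep(1, 20), w), "variance")
  expect_error(morans_i_global(rnorm(10), w), "match")
})

test_that("Moran's I is negative on a checkerboard and positive on separated blobs", {
  grid <- expand.grid(x = 0:3, y = 0:3)
  checker <- ifelse((grid$x + grid$y) %% 2 == 0, 1, -1)
  w <- build_weights(as.matrix(grid), power = 3)  # near-neighbour dominated
  expect_lt(morans_i_global(checker, w)$I, 0)

  blob_pts <- rbind(matrix(runif(20, 0, 1), 10, 2),
                    matrix(runif(20, 9, 10), 10, 2))
  blob_vals <- c(rnorm(10, 10, 0.5), rnorm(10, -10, 0.5))
  wb <- build_weights(blob_pts)
  expect_gt(morans_i_global(blob_vals, wb)$I, 0)
})

test_that("Moran's I is invariant to shifts and positive scalings", {
  set.seed(73)
  pts <- matrix(runif(30, 0, 100), 15, 2)
  vals <- rnorm(15)
  w <- build_weights(pts)
  base <- morans_i_global(vals, w)$I
  expect_equal(morans_i_global(vals + 100, w)$I, base, tolerance = 1e-12)
  expect_equal(morans_i_global(vals * 7.3, w)$I, base, tolerance = 1e-12)
})

test_that("random relabelling centres Moran's I on -1/(n-1)", {
  set.seed(74)
  pts <- matrix(runif(60, 0, 100), 30, 2)
  vals <- rnorm(30)
  w <- build_weights(pts)
  Is <- replicate(200, morans_i_global(sample(vals), w)$I)
  se <- sd(Is) / sqrt(200)
  expect_lt(abs(mean(Is) - (-1 / 29)), 3 * se)
})

test_that("local Moran's I matches hand evaluation and averages to the global", {
  # 3-site hand-worked instance
  coords <- cbind(c(0, 1, 3), c(0, 0, 0))
  y <- c(2, 6, 10)
  w <- build_weights(coords, power = 1, row_standardize = FALSE)
  li <- morans_i_local(y, w)
  expect_equal(li, moran_local_oracle(y, w$W), tolerance = 1e-12)
  # site 2 sits exactly at the mean: its local I is 0
  expect_equal(li[2], 0)

  set.seed(75)
  pts <- matrix(runif(40, 0, 100), 20, 2)
  vals <- rnorm(20)
  ws <- build_weights(pts, row_standardize = TRUE)
  li2 <- morans_i_local(vals, ws)
  expect_equal(li2, moran_local_oracle(vals, ws$W), tolerance = 1e-10)
  # with row-standardised weights the locals average to the global
  expect_equal(mean(li2), morans_i_global(vals, ws)$I, tolerance = 1e-10)
})

test_that("permutation test is seeded, exact in the extreme case and granular", {
  blob_pts <- rbind(matrix(runif(40, 0, 1), 20, 2),
                    matrix(runif(40, 19, 20), 20, 2))
  blob_vals <- c(rnorm(20, 5, 0.1), rnorm(20, -5, 0.1))
  w <- build_weights(blob_pts)
  t1 <- permutation_test(blob_vals, w, n_perm = 599, seed = 9)
  expect_equal(t1$p_value, 1 / 600)
  t2 <- permutation_test(blob_vals, w, n_perm = 599, seed = 9)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$perm_I, t2$perm_I)

  t3 <- permutation_test(blob_vals, w, n_perm = 19, seed = 9)
  expect_equal(t3$p_value, 1 / 20)
  expect_error(permutation_test(blob_vals, w, n_perm = 5), "19")
})

test_that("permuted statistics match a brute-force permutation pathway", {
  set.seed(76)
  pts <- matrix(runif(20, 0, 10), 10, 2)
  vals <- rnorm(10)
  w <- build_weights(pts)
  res <- permutation_test(vals, w, n_perm = 25, seed = 123)
  # regenerate the same permutations and push them through the double-sum
  # oracle instead of the vectorised path
  z <- vals - mean(vals)
  perms <- with_seed(123, {
    vapply(1:25, function(i) z[sample.int(10)], numeric(10))
  })
  oracle_I <- apply(perms, 2, function(zz) moran_oracle(zz + mean(vals), w$W))
  expect_equal(res$perm_I, oracle_I, tolerance = 1e-10)
})

test_that("IDW interpolation is exact at data points and bounded by the data", {
  g <- raster_grid(c(0, 0), 1, 10, 10)
  single <- idw_interpolate(cbind(5, 5), 3.3, g)
  expect_equal(as.vector(single$values), rep(3.3, 100))

  # cell centre (0.5, 0.5) coincides with a data point
  pts <- rbind(c(0.5, 0.5), c(7.5, 7.5))
  vals <- c(0, 10)
  r <- idw_interpolate(pts, vals, g, power = 2)
  expect_equal(r$values[10, 1], 0)   # row 10 is the southernmost row
  expect_equal(r$values[3, 8], 10)
  expect_true(all(r$values >= 0 & r$values <= 10))

  # midpoint between two points of values 0 and 10 interpolates to 5
  g2 <- raster_grid(c(0, 0), 1, 1, 3)
  r2 <- idw_interpolate(rbind(c(0.5, 0.5), c(2.5, 0.5)), c(0, 10), g2)
  expect_equal(r2$values[1, 2], 5)

  expect_error(idw_interpolate(cbind(1, 1), 1, raster_grid(c(0, 0), 1, 0, 3)),
               "grid")
})

test_that("rasters round-trip through the ASCII grid format", {
  g <- raster_grid(c(100, 200), 25, 6, 8)
  set.seed(77)
  g$values <- matrix(rnorm(48), 6, 8)
  g$values[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster_ascii(g, path)
  back <- read_raster_ascii(path)
  expect_equal(back$values, g$values, tolerance = 1e-10)
  expect_equal(back$origin, c(100, 200))
  expect_equal(back$cellsize, 25)
  expect_equal(back$n_rows, 6)
  expect_equal(back$n_cols, 8)
})

test_that("severity binning uses the documented breaks", {
  v <- c(-1, 0.2, 0.5, 1.9, 2, 4.9, 5, 80)
  cls <- classify_severity(v)
  expect_equal(as.character(cls),
               c("severe", "severe", "moderate", "moderate",
                 "low", "low", "optimum", "optimum"))
  expect_equal(unname(table(cls)["severe"]), 2, ignore_attr = TRUE)
})
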