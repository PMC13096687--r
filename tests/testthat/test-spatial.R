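test_that("phylogenetic eigenvectors come from the double-centered PCoA", {
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  ev <- phylo_eigenvectors(tr2, 1)
  expect_equal(abs(as.numeric(ev$vectors)), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  set.seed(81)
  tr <- ape::rphylo(30, 1, 0)
  ev <- phylo_eigenvectors(tr, 10)
  # orthogonality and descending eigenvalues
  expect_equal(crossprod(ev$vectors), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(ev$eigenvalues) <= 1e-8))
  # ultrametric patristic distances embed with nonnegative retained eigenvalues
  expect_true(all(ev$eigenvalues >= -1e-8))
  # cross-check against cmdscale on the same distance matrix
  ref <- cmdscale(stats::cophenetic(tr), k = 3, eig = TRUE)
  expect_equal(abs(cor(ev$vectors[, 1], ref$points[, 1])), 1, tolerance = 1e-6)
  expect_error(phylo_eigenvectors(tr, 30), "smaller")
})

test_that("residualization projects out the basis", {
  set.seed(82)
  tr <- ape::rphylo(60, 1, 0)
  basis <- phylo_eigenvectors(tr, 10)
  y <- rbinom(60, 1, 0.3)
  res <- residualize(y, basis)
  expect_equal(sum(res), 0, tolerance = 1e-10)
  # y exactly in the span -> zero residuals
  y_span <- drop(cbind(1, basis$vectors) %*% rnorm(11))
  expect_equal(max(abs(residualize(y_span, basis))), 0, tolerance = 1e-8)
  # basis orthogonal to centered y -> residuals are y - mean(y)
  # (a constant column duplicates the intercept, hence the rank warning)
  expect_warning(
    res_c <- residualize(y, matrix(1, 60, 1) / sqrt(60)),
    "rank-deficient"
  )
  expect_equal(res_c, y - mean(y), tolerance = 1e-10)
})

test_that("Moran's I matches hand computation, brute force, and ape", {
  m <- morans_i(c(1, -1), matrix(c(0, 1, 1, 0), 2))
  expect_equal(m$I, -1)
  expect_equal(m$expected, -1)
  set.seed(83)
  for (i in 1:10) {
    n <- 50
    z <- rnorm(n)
    w <- matrix(runif(n * n), n); w <- w + t(w); diag(w) <- 0
    mine <- morans_i(z, w)
    expect_equal(mine$I, brute_moran(z, w), tolerance = 1e-10)
    expect_equal(mine$expected, -1 / (n - 1))
    # independent oracle: ape row-normalizes weights before computing I;
    # its variance uses the randomization (kurtosis) form, so the null sd
    # agrees only approximately with the normality form for Gaussian z
    wr <- w / rowSums(w)
    ref <- ape::Moran.I(z, wr)
    mine_r <- morans_i(z, wr)
    expect_equal(mine_r$I, ref$observed, tolerance = 1e-10)
    expect_equal(sqrt(mine_r$variance), ref$sd, tolerance = 0.05)
  }
})

test_that("Moran's I is invariant under affine transforms of z", {
  set.seed(84)
  z <- rnorm(40); w <- matrix(runif(1600), 40); w <- w + t(w); diag(w) <- 0
  base <- morans_i(z, w)
  shifted <- morans_i(3 + 2.5 * z, w)
  expect_equal(base$I, shifted$I, tolerance = 1e-12)
  expect_equal(base$p, shifted$p, tolerance = 1e-12)
  expect_error(morans_i(rep(1, 40), w), "zero variance")
  expect_error(morans_i(z, matrix(0, 40, 40)), "all weights are zero")
})

test_that("spatially clustered residuals are detected as positive autocorrelation", {
  set.seed(85)
  lon <- runif(80, -180, 180); lat <- runif(80, -60, 60)
  z <- sign(lon) + rnorm(80, 0, 0.4)   # east/west clustering
  w <- inverse_distance_weights(pairwise_geo_distances(cbind(lon, lat)))
  m <- morans_i(z, w)
  expect_gt(m$I, 0)
  expect_lt(m$p, 0.05)
})

test_that("inverse-distance weights cap coincident points at the max weight", {
  d <- pairwise_geo_distances(rbind(c(0, 0), c(0, 0), c(10, 10)))
  w <- inverse_distance_weights(d)
  expect_equal(attr(w, "n_coincident"), 2L)
  expect_equal(diag(unclass(w)), rep(0, 3))
  expect_equal(w[1, 2], max(w[1, 3], w[2, 3]))
  expect_true(all(is.finite(w)))
})

test_that("the assembled spatial stage runs on a benchmark dataset", {
  b <- make_benchmark(sim_config(n_tips = 120, seed = 6))
  sp <- spatial_autocorrelation(b$dataset, b$centroids)
  expect_s3_class(sp$moran, "slp_moran")
  expect_equal(sp$moran$expected, -1 / (b$dataset$n - 1))
  expect_equal(sum(sp$residuals), 0, tolerance = 1e-8)
  expect_gte(sp$moran$p, 0); expect_lte(sp$moran$p, 1)
})
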