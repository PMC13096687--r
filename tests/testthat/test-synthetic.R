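test_that("tree simulation is ultrametric, sized, and seed-deterministic", {
  cfg <- sim_config(n_tips = 50, seed = 1)
  tr1 <- simulate_tree(cfg)
  tr2 <- simulate_tree(cfg)
  expect_identical(tr1, tr2)
  expect_equal(ape::Ntip(tr1), 50L)
  depths <- ape::node.depth.edgelength(tr1)[1:50]
  expect_lt(diff(range(depths)), 1e-9)
  expect_error(sim_config(n_tips = 3), "n_tips")
  expect_error(sim_config(tree_model = "birthdeath", birth = 1, death = 1.5),
               "death < birth")
})

test_that("simulated geography honors the tropic fraction and never leaves a genus homeless", {
  cfg <- sim_config(n_tips = 60, n_regions = 100, tropic_fraction = 0.5, seed = 2)
  tr <- simulate_tree(cfg)
  geo <- simulate_geography(cfg, tr)
  # construction places exactly round(fraction * n) regions touching the band
  expect_equal(sum(geo$catalog$tropical), 50L)
  expect_true(all(lengths(geo$occupancy) >= 1L))
  expect_setequal(names(geo$occupancy), tr$tip.label)
  expect_true(all(geo$catalog$min_lat <= geo$catalog$max_lat))
  expect_true(all(geo$catalog$hotspot %in% 0:1))
})

test_that("sister genera share more regions than random tip pairs", {
  jacc <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  sis <- ran <- numeric(10)
  for (i in 1:10) {
    cfg <- sim_config(n_tips = 80, seed = 100 + i)
    tr <- simulate_tree(cfg)
    geo <- simulate_geography(cfg, tr)
    # sister pairs: two tips sharing an immediate parent
    tip_edges <- tr$edge[tr$edge[, 2] <= 80, ]
    par_tab <- split(tip_edges[, 2], tip_edges[, 1])
    sisters <- Filter(function(v) length(v) == 2, par_tab)
    sis[i] <- mean(vapply(sisters, function(v) {
      jacc(geo$occupancy[[v[1]]], geo$occupancy[[v[2]]])
    }, numeric(1)))
    prs <- replicate(40, sample(80, 2))
    ran[i] <- mean(apply(prs, 2, function(v) {
      jacc(geo$occupancy[[v[1]]], geo$occupancy[[v[2]]])
    }))
  }
  expect_gt(mean(sis), mean(ran))
})

test_that("trait generator respects its effect structure and degeneracy guard", {
  # symmetric threshold, no covariates, no signal -> prevalence near 0.5
  cfg <- sim_config(n_tips = 1000, beta = c(0, 0, 0, 0), signal_sd = 0,
                    trait_mode = "logistic", seed = 3)
  tr <- simulate_tree(cfg)
  X <- cbind(tropical = rep(0, 1000), hotspot = rep(0, 1000),
             species_richness = rep(1, 1000))
  rownames(X) <- tr$tip.label
  y <- simulate_trait(tr, X, cfg)
  expect_gt(mean(y), 0.44); expect_lt(mean(y), 0.56)
  # extreme intercept triggers the degeneracy guard but still yields 2 states
  cfg2 <- sim_config(n_tips = 50, beta = c(-40, 0, 0, 0), signal_sd = 0.1, seed = 4)
  tr2 <- simulate_tree(cfg2)
  X2 <- X[1:50, ]; rownames(X2) <- tr2$tip.label
  y2 <- simulate_trait(tr2, X2, cfg2)
  expect_equal(sort(unique(y2)), c(0L, 1L))
})

test_that("stronger liability signal lowers the D statistic of generated traits", {
  grid <- c(0.5, 1.5, 4)
  meanD <- vapply(grid, function(s) {
    mean(vapply(1:15, function(i) {
      cfg <- sim_config(n_tips = 100, beta = c(-1, 0, 0, 0), signal_sd = s,
                        seed = 500 + i)
      tr <- simulate_tree(cfg)
      X <- cbind(tropical = rep(0, 100), hotspot = rep(0, 100),
                 species_richness = rep(1, 100))
      rownames(X) <- tr$tip.label
      y <- simulate_trait(tr, X, cfg)
      phylo_d(tr, y, n_sim = 100)$D
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanD) < 0))
})

test_that("a larger tropical effect strengthens the trait-tropical association", {
  phi_at <- function(b_trop) {
    mean(vapply(1:10, function(i) {
      b <- make_benchmark(sim_config(n_tips = 150, beta = c(-1, b_trop, 0, 0),
                                     signal_sd = 0.5, seed = 900 + i))
      tb <- table(factor(b$dataset$trait, levels = c(1, 0)),
                  factor(b$dataset$design[, "tropical"], levels = c(1, 0)))
      if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) return(NA_real_)
      phi_coefficient(tb)$statistic
    }, numeric(1)), na.rm = TRUE)
  }
  expect_gt(phi_at(2), phi_at(0))
})

test_that("the benchmark is end-to-end deterministic and carries its truth", {
  cfg <- sim_config(n_tips = 100, seed = 11)
  b1 <- make_benchmark(cfg)
  b2 <- make_benchmark(cfg)
  expect_identical(b1$dataset$trait, b2$dataset$trait)
  expect_identical(b1$dataset$design, b2$dataset$design)
  expect_identical(b1$centroids, b2$centroids)
  expect_identical(b1$truth$config$beta, cfg$beta)
  expect_s3_class(b1$dataset, "slp_dataset")
  expect_equal(b1$dataset$n, 100L)
  # the largest family is focal and covers a reasonable share of tips
  expect_equal(b1$focal_family,
               names(which.max(table(b1$dataset$genera$family))))
})
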