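test_that("plain logistic regression reproduces closed-form intercepts", {
  expect_equal(unname(fit_logistic(rep(c(1, 0), 10))$beta), 0, tolerance = 1e-8)
  y <- c(rep(1, 25), rep(0, 75))
  expect_equal(unname(fit_logistic(y)$beta), log(1 / 3), tolerance = 1e-8)
})

test_that("perfect separation is flagged and handled by the Firth fallback", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  expect_warning(f <- fit_logistic(y, cbind(x = x)), "separation")
  expect_true(f$separation)
  expect_true(f$penalized)
  expect_true(all(is.finite(f$beta)))
})

test_that("phylogenetic logistic fit collapses to plain logistic on a star tree", {
  set.seed(71)
  star <- ape::stree(150, "star"); star$edge.length <- rep(1, 150)
  x <- cbind(a = rnorm(150), b = rbinom(150, 1, 0.5))
  y <- rbinom(150, 1, plogis(-0.5 + x[, 1] + 0.5 * x[, 2]))
  ref <- fit_logistic(y, x)
  fit <- fit_phyloglm(y, X = x, tree = star, penalized = FALSE)
  expect_equal(fit$beta, ref$beta, tolerance = 1e-3)
  expect_equal(fit$logLik, ref$logLik, tolerance = 1e-6)
  # and penalized mode collapses to the Firth fit
  reff <- fit_logistic(y, x, penalized = TRUE)
  fitf <- fit_phyloglm(y, X = x, tree = star, penalized = TRUE)
  expect_equal(fitf$beta, reff$beta, tolerance = 1e-3)
})

test_that("phylogenetic linear regression is GLS that reduces to OLS on a star", {
  set.seed(72)
  star <- ape::stree(100, "star"); star$edge.length <- rep(1, 100)
  x <- cbind(x1 = rnorm(100))
  y <- 1 + 2 * x[, 1] + rnorm(100)
  fit <- fit_phylolm(y, x, star)
  ols <- lm(y ~ x)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("phylolm recovers a known slope under Brownian residuals", {
  set.seed(73)
  est <- replicate(25, {
    tr <- ape::rphylo(100, 1, 0)
    x <- rnorm(100)
    y <- 2 + 1.5 * x + drop(slpbiogeo:::simulate_bm(tr, 1))
    fit_phylolm(stats::setNames(y, tr$tip.label), cbind(x = x), tr)$beta["x"]
  })
  expect_lt(abs(mean(est) - 1.5), 0.05)
})

test_that("partial likelihood-ratio R2 matches its closed form and bounds", {
  expect_equal(partial_r2lik(-10, -10, 100)$r2lik, 0)
  r <- partial_r2lik(-48, -50, 100)
  expect_equal(r$r2lik, 1 - exp(-0.04), tolerance = 1e-12)
  expect_equal(round(r$r2lik, 5), 0.03921)
  expect_equal(r$p, pchisq(4, 1, lower.tail = FALSE))
  expect_error(partial_r2lik(-1, -2, 0), "positive")
  expect_warning(partial_r2lik(-5, -4, 50), "clamping")
  # strictly increasing in the log-likelihood difference, bounded in [0,1)
  deltas <- seq(0, 30, by = 3)
  r2 <- vapply(deltas, function(d) partial_r2lik(0, -d, 50)$r2lik, numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_true(all(r2 >= 0 & r2 < 1))
})

test_that("full phylogenetic model never fits worse than its reductions", {
  # unpenalized mode on a non-separated (dense-trait) benchmark: the
  # reduced models are exactly nested in the full one
  b <- make_benchmark(sim_config(n_tips = 150, beta = c(-0.5, 0.8, 0.3, 0.01),
                                 signal_sd = 1, seed = 8))
  pr <- partial_r2_table(b$dataset, penalized = FALSE)
  expect_setequal(pr$table$component,
                  c("tropical", "hotspot", "species_richness", "phylogeny"))
  expect_true(all(pr$table$r2lik >= 0 & pr$table$r2lik < 1))
  full_ll <- pr$fits$full$logLik
  for (nm in grep("^drop_", names(pr$fits), value = TRUE)) {
    expect_gte(full_ll, pr$fits[[nm]]$logLik - 1e-6)
  }
})

test_that("AIC comparison computes deltas and normalized Akaike weights", {
  mk <- function(ll, k, n = 100) {
    structure(list(beta = numeric(k), alpha = 1, logLik = ll, n = n),
              class = "slp_phyloglm")
  }
  cmp <- compare_models(list(a = mk(-50, 2), b = mk(-50, 2)))
  expect_equal(cmp$akaike_weight, c(0.5, 0.5))
  # delta AIC (0, 2) -> weights (0.731, 0.269)
  cmp2 <- compare_models(list(a = mk(-50, 2), b = mk(-51, 2)))
  expect_equal(cmp2$akaike_weight, c(exp(0), exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(cmp2$akaike_weight, 3), c(0.731, 0.269))
  expect_equal(sum(cmp2$akaike_weight), 1, tolerance = 1e-12)
  expect_equal(min(cmp2$delta_aic), 0)
  expect_error(compare_models(list(a = mk(-50, 2), b = mk(-50, 2, n = 99))),
               "different size")
})

test_that("the tropical effect sign is recovered under the logistic generator", {
  hits <- vapply(1:25, function(i) {
    b <- make_benchmark(sim_config(n_tips = 200, beta = c(-1, 1, 0, 0),
                                   trait_mode = "logistic", seed = 700 + i))
    fit_phyloglm(b$dataset, c("tropical", "hotspot"))$beta["tropical"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
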