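#' Pearson chi-square test for a 2x2 contingency table
#'
#' Computed by [stats::chisq.test()]; the continuity correction defaults to
#' on, and both corrected and uncorrected statistics agree with the
#' closed-form n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d)) identities.
#'
#' @param table 2x2 matrix of counts (rows = trait state, columns =
#'   geographic state).
#' @param correction Apply Yates' continuity correction (default `TRUE`).
#' @return List with `statistic`, `df`, `p`, `method`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(10, 20, 20, 10), 2, byrow = TRUE), correction = FALSE)
chi_square_2x2 <- function(table, correction = TRUE) {
  tb <- check_2x2(table)
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    stop("chi-square statistic undefined: a marginal total is zero")
  }
  ct <- suppressWarnings(stats::chisq.test(tb, correct = correction))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       method = if (correction) "Pearson chi-square (Yates)" else "Pearson chi-square")
}

#' Phi coefficient of association for a 2x2 table
#'
#' phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)); the significance test uses
#' the identity chi-square = n * phi^2 on 1 degree of freedom.
#'
#' @inheritParams chi_square_2x2
#' @return List with `statistic` (phi), `df`, `p`, `method`.
#' @export
phi_coefficient <- function(table) {
  tb <- check_2x2(table)
  a <- tb[1, 1]; b <- tb[1, 2]; c <- tb[2, 1]; d <- tb[2, 2]
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) stop("phi undefined: a marginal total is zero")
  phi <- (a * d - b * c) / sqrt(prod(marg))
  n <- sum(tb)
  list(statistic = phi, df = 1,
       p = stats::pchisq(n * phi^2, df = 1, lower.tail = FALSE),
       method = "phi coefficient")
}

check_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!identical(dim(tb), c(2L, 2L))) stop("expected a 2x2 table")
  if (any(tb < 0) || any(tb != round(tb))) stop("counts must be nonnegative integers")
  if (sum(tb) == 0) stop("empty table")
  tb
}

#' Welch two-sample t-test
#'
#' Compares species richness between trait states without assuming equal
#' variances (Welch-Satterthwaite degrees of freedom, two-sided p).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return List with `statistic`, `df`, `p`, `method`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs at least 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("both groups have zero variance; t statistic undefined")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, method = "Welch two-sample t-test")
}

#' Variance inflation factors of a design matrix
#'
#' For each column k, VIF_k = 1 / (1 - R^2_k) where R^2_k comes from the
#' least-squares regression (with intercept) of column k on the remaining
#' columns. Exactly collinear columns are reported as `Inf` with a warning.
#'
#' @param design Numeric matrix with >= 2 named columns, each with nonzero
#'   variance.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2L) stop("need at least 2 predictor columns")
  if (any(apply(X, 2L, stats::var) == 0)) stop("a predictor column has zero variance")
  out <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  names(out) <- colnames(X)
  if (any(is.infinite(out))) warning("exactly collinear predictors: VIF reported as Inf")
  out
}

#' Collinearity report for the biogeographic predictors
#'
#' VIFs for all predictor columns plus the phi coefficient for each pair of
#' binary predictors.
#'
#' @param design Design matrix (columns e.g. `tropical`, `hotspot`,
#'   `species_richness`).
#' @return List with `vif` and `phi` (data frame of binary pairs).
#' @export
collinearity_report <- function(design) {
  X <- as.matrix(design)
  is_bin <- apply(X, 2L, function(v) all(v %in% c(0, 1)))
  pairs <- if (sum(is_bin) >= 2L) utils::combn(which(is_bin), 2L) else NULL
  phi_df <- NULL
  if (!is.null(pairs)) {
    phi_df <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      tb <- table(factor(X[, i1], levels = c(1, 0)), factor(X[, i2], levels = c(1, 0)))
      ph <- phi_coefficient(tb)
      data.frame(var1 = colnames(X)[i1], var2 = colnames(X)[i2],
                 phi = ph$statistic, p = ph$p, stringsAsFactors = FALSE)
    }))
  }
  list(vif = vif(X), phi = phi_df)
}

#' Exploratory association tests for an analysis dataset
#'
#' The non-phylogenetic first pass: chi-square association of the trait with
#' each binary geographic predictor, and a Welch t-test comparing species
#' richness between trait states.
#'
#' @param dataset An `slp_dataset`.
#' @param correction Continuity correction for the 2x2 chi-square tests.
#' @return List with one test result per comparison, plus the underlying
#'   2x2 tables.
#' @export
exploratory_tests <- function(dataset, correction = TRUE) {
  stopifnot(inherits(dataset, "slp_dataset"))
  y <- dataset$trait
  out <- list()
  for (v in intersect(c("tropical", "hotspot"), colnames(dataset$design))) {
    tb <- table(factor(y, levels = c(1, 0)),
                factor(dataset$design[, v], levels = c(1, 0)))
    out[[paste0("chisq_", v)]] <- tryCatch(chi_square_2x2(tb, correction),
                                           error = function(e) list(error = conditionMessage(e)))
    out[[paste0("table_", v)]] <- unclass(tb)
  }
  rich <- dataset$design[, "species_richness"]
  out$t_richness <- tryCatch(welch_t(rich[y == 1], rich[y == 0]),
                             error = function(e) list(error = conditionMessage(e)))
  out
}
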