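#' Phylogenetic eigenvectors from the patristic distance matrix
#'
#' Principal-coordinate decomposition of the patristic distance matrix:
#' Gower double-centering of \eqn{-\frac12 D \circ D}, then the top-k
#' eigenvectors by eigenvalue. Regressing a trait on these vectors absorbs
#' the broad-scale phylogenetic structure (phylogenetic eigenvector
#' regression).
#'
#' @param tree An [ape::phylo].
#' @param k Number of eigenvectors to retain (default 10); must satisfy
#'   `k <= n - 1`.
#' @return List with `vectors` (n x k matrix, rows named by tip) and
#'   `eigenvalues` (length k, descending).
#' @export
phylo_eigenvectors <- function(tree, k = 10L) {
  check_phylogeny(tree)
  n <- ape::Ntip(tree)
  if (k >= n) stop("k must be smaller than the number of tips")
  if (k < 1L) stop("k must be >= 1")
  D <- stats::cophenetic(tree)
  G <- -0.5 * D^2
  G <- sweep(G, 1L, rowMeans(G))
  G <- sweep(G, 2L, colMeans(G))  # second sweep also removes the grand mean
  # symmetrize against accumulated rounding before the eigendecomposition
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vec <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(vec) <- tree$tip.label
  colnames(vec) <- paste0("PE", seq_len(k))
  list(vectors = vec, eigenvalues = eg$values[seq_len(k)])
}

#' Residualize a trait on phylogenetic eigenvectors
#'
#' Ordinary least-squares residuals of the trait on an intercept plus the
#' eigenvector basis. For a 0/1 trait these residuals are the conventional
#' phylogenetically corrected input to Moran's I; Pearson residuals from a
#' logistic fit are offered as an alternative.
#'
#' @param y Numeric (typically 0/1) vector aligned with the basis rows.
#' @param basis Output of [phylo_eigenvectors()], or a plain matrix.
#' @param model `"linear"` (OLS residuals, default) or `"logistic"` (Pearson
#'   residuals of a logistic fit).
#' @return Numeric residual vector (sums to zero for the linear model).
#' @export
residualize <- function(y, basis, model = c("linear", "logistic")) {
  model <- match.arg(model)
  V <- if (is.list(basis)) basis$vectors else as.matrix(basis)
  if (length(y) != nrow(V)) stop("y and basis have different lengths")
  M <- cbind(1, V)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    warning("rank-deficient eigenvector basis; dropping dependent columns")
    M <- M[, qrM$pivot[seq_len(qrM$rank)], drop = FALSE]
  }
  if (model == "linear") {
    unname(stats::lm.fit(M, y)$residuals)
  } else {
    g <- suppressWarnings(stats::glm.fit(M, y, family = stats::binomial()))
    mu <- g$fitted.values
    unname((y - mu) / sqrt(pmax(mu * (1 - mu), 1e-12)))
  }
}

#' Inverse-distance spatial weights
#'
#' Reciprocal pairwise distances with the diagonal set to zero. Coincident
#' points (zero distance between distinct records) would give infinite
#' weight; they instead receive the maximum finite weight in the matrix, and
#' their count is recorded in the `"n_coincident"` attribute.
#'
#' @param distances Symmetric nonnegative distance matrix with zero diagonal
#'   (e.g. from [pairwise_geo_distances()]).
#' @return Symmetric weight matrix of class `slp_weights` with zero diagonal.
#' @export
inverse_distance_weights <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  w <- 1 / d
  diag(w) <- 0
  inf_off <- !is.finite(w)
  if (any(inf_off)) {
    w[inf_off] <- max(w[is.finite(w)])
  }
  structure(w, n_coincident = sum(inf_off), class = c("slp_weights", "matrix"))
}

#' Moran's I with closed-form null moments
#'
#' Global spatial autocorrelation of `z` under the weight matrix `w`:
#' \deqn{I = \frac{n}{S_0} \frac{\sum_i \sum_j w_{ij}(z_i-\bar z)(z_j-\bar z)}
#'   {\sum_i (z_i-\bar z)^2}}
#' with expectation \eqn{-1/(n-1)} and variance under the normality
#' assumption (standard closed form in the weight sums \eqn{S_0, S_1, S_2});
#' the two-sided p-value comes from the normal z-score.
#'
#' @param z Numeric vector with nonzero variance (n >= 2; n >= 3 for
#'   inference).
#' @param weights Nonnegative weight matrix with zero diagonal (e.g. from
#'   [inverse_distance_weights()]).
#' @return List of class `slp_moran`: `I`, `expected`, `variance`, `z_score`,
#'   `p`, `n`.
#' @export
#' @examples
#' morans_i(c(1, -1), matrix(c(0, 1, 1, 0), 2))  # I = -1
morans_i <- function(z, weights) {
  w <- unclass(as.matrix(weights))
  n <- length(z)
  if (n < 2L) stop("need at least 2 observations")
  if (nrow(w) != n || ncol(w) != n) stop("weight matrix does not match z")
  if (any(diag(w) != 0)) stop("weight matrix must have a zero diagonal")
  if (all(w == 0)) stop("all weights are zero; statistic undefined")
  zc <- z - mean(z)
  s2 <- sum(zc^2)
  if (s2 == 0) stop("z has zero variance")
  S0 <- sum(w)
  I <- (n / S0) * drop(zc %*% w %*% zc) / s2
  expected <- -1 / (n - 1)
  if (n < 3L) {
    return(structure(list(I = I, expected = expected, variance = NA_real_,
                          z_score = NA_real_, p = NA_real_, n = n),
                     class = "slp_moran"))
  }
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  var_I <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - expected^2
  zsc <- (I - expected) / sqrt(var_I)
  structure(list(I = I, expected = expected, variance = var_I,
                 z_score = zsc, p = 2 * stats::pnorm(-abs(zsc)), n = n),
            class = "slp_moran")
}

#' @export
print.slp_moran <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (expected %.4f, sd %.4f, z = %.3f, p = %.4g, n = %d)\n",
              x$I, x$expected, sqrt(x$variance), x$z_score, x$p, x$n))
  invisible(x)
}

#' Phylogenetically corrected spatial autocorrelation of a trait
#'
#' The full spatial stage: compute genus distribution centroids, build
#' inverse-distance weights, residualize the trait on the leading
#' phylogenetic eigenvectors, and test the residuals with Moran's I. A
#' significant I means the trait is spatially clustered beyond what
#' phylogenetic relatedness explains.
#'
#' @param dataset An `slp_dataset`.
#' @param centroids Two-column (lon, lat) matrix of genus distribution
#'   centroids, rows in tip order (e.g. from [genus_centroid()] applied per
#'   genus).
#' @param k Number of phylogenetic eigenvectors (default 10).
#' @param metric Distance metric for the weights, see
#'   [pairwise_geo_distances()].
#' @param residual_model Passed to [residualize()].
#' @return List with `moran` (`slp_moran`), `residuals`, `basis`, `weights`.
#' @export
spatial_autocorrelation <- function(dataset, centroids, k = 10L,
                                    metric = "greatcircle",
                                    residual_model = "linear") {
  stopifnot(inherits(dataset, "slp_dataset"))
  if (nrow(centroids) != dataset$n) stop("centroids do not match the dataset")
  basis <- phylo_eigenvectors(dataset$tree, k = min(k, dataset$n - 1L))
  res <- residualize(dataset$trait, basis, model = residual_model)
  w <- inverse_distance_weights(pairwise_geo_distances(centroids, metric))
  list(moran = morans_i(res, w), residuals = res, basis = basis, weights = w)
}
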