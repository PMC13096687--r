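# Shared fixtures and independent brute-force oracles.

balanced_tree <- function(n) {
  ape::compute.brlen(ape::stree(n, "balanced"))
}

# Brute-force recursive recomputation of the node-mean change sum: builds
# every node value explicitly by recursion, independent of the package's
# vectorized postorder accumulation.
brute_d_sum <- function(tree, trait) {
  n_tip <- ape::Ntip(tree)
  trait <- trait[tree$tip.label]
  node_value <- function(v) {
    if (v <= n_tip) return(as.numeric(trait[v]))
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    mean(vapply(kids, node_value, numeric(1)))
  }
  sum(vapply(seq_len(nrow(tree$edge)), function(e) {
    abs(node_value(tree$edge[e, 2]) - node_value(tree$edge[e, 1]))
  }, numeric(1)))
}

# Brute-force double-loop Moran's I.
brute_moran <- function(z, w) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + w[i, j] * zc[i] * zc[j]
  (n / sum(w)) * num / sum(zc^2)
}

# Patristic distance by explicit path-sum between two tips.
brute_patristic <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pth <- ape::nodepath(tree, ia, ib)
  sum(vapply(seq_len(length(pth) - 1L), function(k) {
    e <- which(tree$edge[, 1] == pth[k] & tree$edge[, 2] == pth[k + 1] |
               tree$edge[, 1] == pth[k + 1] & tree$edge[, 2] == pth[k])
    tree$edge.length[e]
  }, numeric(1)))
}

# A small genus table written to a temp TSV in the package's dialect.
write_toy_genus_table <- function(path = tempfile(fileext = ".tsv")) {
  df <- data.frame(
    genus = c("Psychotria", "Primula", "Linum", "Quercus", "Carex"),
    family = c("Rubiaceae", "Primulaceae", "Linaceae", "Fagaceae", "Cyperaceae"),
    slp = c(1, 1, 1, 0, 0),
    species_richness = c(1600, 500, 200, 430, 2000),
    regions = c("R001|R002", "R002|R003", "R003", "R001|R003", "")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_catalog <- function() {
  data.frame(
    region = c("R001", "R002", "R003"),
    min_lat = c(-10, 10, 40), max_lat = c(10, 30, 60),
    centroid_lon = c(0, 20, 40), centroid_lat = c(0, 20, 50),
    hotspot = c(1, 1, 0),
    tropical = c(1L, 1L, 0L),
    stringsAsFactors = FALSE
  )
}

# Brownian-threshold trait at a fixed prevalence (top-k liabilities).
bm_threshold_trait <- function(tree, k) {
  liab <- drop(slpbiogeo:::simulate_bm(tree, 1L))
  y <- integer(length(liab))
  y[order(-liab, seq_along(liab))[seq_len(k)]] <- 1L
  stats::setNames(y, tree$tip.label)
}
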