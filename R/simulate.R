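#' Configuration for the synthetic genus-level benchmark
#'
#' Parameters of the generator that emulates the structure of the real
#' analysis inputs: an ultrametric genus-level tree, a catalog of botanical
#' regions with latitudinal extents and hotspot flags, per-genus region
#' occupancy with phylogenetically structured geography, lognormal species
#' richness, and a binary trait with tunable phylogenetic signal and
#' covariate effects on the liability scale.
#'
#' Defaults mirror the study system: 368 regions, about half of them
#' touching the tropical band, trait prevalence around 2%, strongly
#' phylogenetically conserved (`signal_sd = 1` puts the Brownian liability
#' component on the same scale as a standard-normal deviate at the tips),
#' and a weak positive richness effect on the count scale.
#'
#' @param n_tips Number of genera (tips); >= 4.
#' @param tree_model `"yule"` or `"birthdeath"`.
#' @param birth,death Speciation and extinction rates for the tree simulation
#'   (`death < birth` required).
#' @param n_regions Number of regions in the catalog.
#' @param tropic_fraction Share of regions whose extent intersects the band.
#' @param hotspot_fraction Overall share of regions flagged as hotspot
#'   (enriched within the band, depleted outside).
#' @param occupancy_mean Mean number of occupied regions per genus
#'   (occupancy is 1 + Poisson(`occupancy_mean` - 1)).
#' @param richness_logmean,richness_logsd Lognormal parameters of genus
#'   species richness (rounded up to >= 1).
#' @param beta Length-4 liability effects: intercept, tropical, hotspot,
#'   species richness.
#' @param signal_sd Standard deviation of the Brownian liability component at
#'   the tips (0 = no phylogenetic signal).
#' @param trait_mode `"liability"` (Brownian threshold model, default) or
#'   `"logistic"` (independent Bernoulli draws with logit mean X beta, for
#'   exact calibration of the logistic estimators).
#' @param seed Integer seed; all generators are deterministic under it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tips = 500L, tree_model = c("yule", "birthdeath"),
                       birth = 1, death = 0, n_regions = 368L,
                       tropic_fraction = 0.5, hotspot_fraction = 0.5,
                       occupancy_mean = 5, richness_logmean = 1.8,
                       richness_logsd = 1.5,
                       beta = c(intercept = -3, tropical = 0.5,
                                hotspot = 0, richness = 0.3),
                       signal_sd = 1.2, trait_mode = c("liability", "logistic"),
                       seed = 1L) {
  tree_model <- match.arg(tree_model)
  trait_mode <- match.arg(trait_mode)
  if (n_tips < 4L) stop("n_tips must be >= 4")
  if (tree_model == "birthdeath" && death >= birth) {
    stop("birth-death simulation requires death < birth")
  }
  if (n_regions < 2L) stop("n_regions must be >= 2")
  stopifnot(tropic_fraction >= 0, tropic_fraction <= 1,
            hotspot_fraction >= 0, hotspot_fraction <= 1,
            occupancy_mean >= 1, signal_sd >= 0, length(beta) == 4L)
  structure(list(
    n_tips = as.integer(n_tips), tree_model = tree_model,
    birth = birth, death = death, n_regions = as.integer(n_regions),
    tropic_fraction = tropic_fraction, hotspot_fraction = hotspot_fraction,
    occupancy_mean = occupancy_mean, richness_logmean = richness_logmean,
    richness_logsd = richness_logsd,
    beta = stats::setNames(as.numeric(beta),
                           c("intercept", "tropical", "hotspot", "richness")),
    signal_sd = signal_sd, trait_mode = trait_mode, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an ultrametric genus-level tree
#'
#' Birth-death simulation conditioned on the number of tips
#' ([ape::rphylo()]); pure-birth (Yule) by default.
#'
#' @param config A [sim_config()].
#' @return An [ape::phylo] with tips `g0001`, `g0002`, ...
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_tips, birth = config$birth,
                    death = if (config$tree_model == "yule") 0 else config$death)
  tr$tip.label <- sprintf("g%04d", seq_len(config$n_tips))
  tr
}

#' Simulate a region catalog and phylogenetically structured occupancy
#'
#' Regions get latitudinal extents (a `tropic_fraction` share intersecting
#' the band), centroids, and hotspot flags enriched within the band. Each
#' genus evolves a Brownian "home latitude" on the tree and occupies the
#' regions whose centroids are nearest that home latitude (plus noise), so
#' closely related genera share regions -- reproducing the confounding
#' between phylogeny and geography that the analysis must disentangle.
#'
#' @param config A [sim_config()].
#' @param tree Tree from [simulate_tree()].
#' @return List with `catalog` (data frame: region, min_lat, max_lat,
#'   centroid_lon, centroid_lat, hotspot, tropical) and `occupancy` (named
#'   list of region-id vectors, never empty).
#' @export
simulate_geography <- function(config, tree) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_r <- config$n_regions
  band <- 23.45
  n_trop <- round(config$tropic_fraction * n_r)
  half <- stats::runif(n_r, 1, 8)
  center <- numeric(n_r)
  if (n_trop > 0L) center[seq_len(n_trop)] <- stats::runif(n_trop, -band, band)
  if (n_trop < n_r) {
    i <- (n_trop + 1L):n_r
    center[i] <- sample(c(-1, 1), length(i), TRUE) *
      stats::runif(length(i), band + half[i] + 0.1, 80)
  }
  min_lat <- pmax(center - half, -90)
  max_lat <- pmin(center + half, 90)
  in_band <- max_lat >= -band & min_lat <= band
  p_hot <- ifelse(in_band, pmin(1, 1.5 * config$hotspot_fraction),
                  0.5 * config$hotspot_fraction)
  catalog <- data.frame(
    region = sprintf("R%03d", seq_len(n_r)),
    min_lat = min_lat, max_lat = max_lat,
    centroid_lon = stats::runif(n_r, -180, 180),
    centroid_lat = center,
    hotspot = stats::rbinom(n_r, 1L, p_hot),
    stringsAsFactors = FALSE
  )
  catalog$tropical <- classify_region_tropical(cbind(min_lat, max_lat))
  home <- 25 * scaled_bm(tree)
  home <- pmin(pmax(home, -70), 70)
  occupancy <- lapply(seq_along(home), function(i) {
    m <- min(stats::rpois(1L, config$occupancy_mean - 1) + 1L, n_r)
    score <- abs(catalog$centroid_lat - home[i]) + stats::rnorm(n_r, 0, 2)
    catalog$region[order(score)[seq_len(m)]]
  })
  names(occupancy) <- tree$tip.label
  list(catalog = catalog, occupancy = occupancy, home_lat = home)
}

# Brownian motion at the tips rescaled to unit marginal SD (ultrametric
# trees: every tip sits at the same depth).
scaled_bm <- function(tree, n_sim = 1L) {
  bm <- simulate_bm(tree, n_sim)
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  bm / sqrt(depth)
}

#' Simulate a binary trait with phylogenetic signal and covariate effects
#'
#' Liability mode (default): the trait is 1 where
#' `intercept + X beta + signal_sd * BM(tree) > 0`, a Brownian threshold
#' model. Logistic mode: independent Bernoulli draws with success probability
#' `plogis(intercept + X beta)`, for exact calibration of the logistic
#' estimators. In both modes the richness effect acts per order of magnitude
#' (the liability uses `log10(species_richness)`), so the lognormal richness
#' tail cannot single-handedly determine the trait. If the draw is
#' degenerate (all 0 or all 1) the intercept is nudged toward the threshold
#' and the trait redrawn, up to 100 times.
#'
#' @param tree Tree from [simulate_tree()].
#' @param X Matrix with columns `tropical`, `hotspot`, `species_richness`
#'   aligned to the tips.
#' @param config A [sim_config()].
#' @return Named integer 0/1 vector in tip order.
#' @export
simulate_trait <- function(tree, X, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  b <- config$beta
  Xl <- as.matrix(X)
  if (!is.null(colnames(Xl))) {
    want <- c("tropical", "hotspot", "species_richness")
    if (!all(want %in% colnames(Xl))) stop("X must have columns ", paste(want, collapse = ", "))
    Xl <- Xl[, want, drop = FALSE]
    Xl[, "species_richness"] <- log10(Xl[, "species_richness"])
  }
  lin0 <- drop(Xl %*% b[c("tropical", "hotspot", "richness")])
  b0 <- b[["intercept"]]
  for (try in seq_len(100L)) {
    y <- if (config$trait_mode == "liability") {
      liab <- b0 + lin0 + config$signal_sd * drop(scaled_bm(tree))
      as.integer(liab > 0)
    } else {
      stats::rbinom(length(lin0), 1L, stats::plogis(b0 + lin0))
    }
    if (length(unique(y)) == 2L) {
      return(stats::setNames(y, tree$tip.label))
    }
    b0 <- b0 + if (all(y == 0L)) 0.5 else -0.5
  }
  stop("trait degenerate after 100 intercept adjustments")
}

#' Generate a complete synthetic benchmark dataset
#'
#' End-to-end generator: tree, geography, threshold coding, richness, trait,
#' and clade-based family labels, assembled through the same
#' [align_dataset()] path the real data would take. The generating
#' parameters are returned alongside for recovery tests.
#'
#' @param config A [sim_config()].
#' @param coding A [coding_config()] used for the tropical/hotspot coding.
#' @return List with `dataset` (an `slp_dataset`), `centroids` (per-genus
#'   distribution centroids in tip order), `catalog`, `occupancy`,
#'   `focal_family` (the largest synthetic family), and `truth` (the config
#'   plus the realized home latitudes).
#' @export
make_benchmark <- function(config = sim_config(), coding = coding_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config)
  geo <- simulate_geography(config, tree)
  cod <- code_genera(geo$occupancy, geo$catalog, coding)
  set.seed(config$seed + 3L)
  richness <- pmax(1, ceiling(stats::rlnorm(config$n_tips,
                                            config$richness_logmean,
                                            config$richness_logsd)))
  ci <- match(tree$tip.label, cod$genus)
  X <- cbind(tropical = cod$tropical[ci], hotspot = cod$hotspot[ci],
             species_richness = richness)
  rownames(X) <- tree$tip.label
  trait <- simulate_trait(tree, X, config)
  fams <- clade_families(tree)
  genera <- data.frame(
    genus = tree$tip.label, family = fams, slp = unname(trait),
    species_richness = richness, stringsAsFactors = FALSE
  )
  genera$regions <- geo$occupancy[genera$genus]
  genera$missing_distribution <- FALSE
  dataset <- align_dataset(genera, tree, cod)
  cen <- t(vapply(dataset$genera$genus, function(g) {
    r <- match(geo$occupancy[[g]], geo$catalog$region)
    as.numeric(genus_centroid(cbind(geo$catalog$centroid_lon[r],
                                    geo$catalog$centroid_lat[r])))
  }, numeric(2L)))
  colnames(cen) <- c("lon", "lat")
  list(dataset = dataset, centroids = cen, catalog = geo$catalog,
       occupancy = geo$occupancy,
       focal_family = names(which.max(table(fams))),
       truth = list(config = config, home_lat = geo$home_lat))
}

# Family labels from slicing the tree at 30% of its height below the root:
# each lineage crossing the slice founds one family, labelled Fam01, Fam02,
# ... in decreasing size order.
clade_families <- function(tree, frac = 0.3) {
  n_tip <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  slice <- frac * max(depth[seq_len(n_tip)])
  fam_id <- integer(n_tip)
  cw <- stats::reorder(tree, "cladewise")
  group <- integer(n_tip + tree$Nnode)  # founding node of each vertex
  root <- cw$edge[1L, 1L]
  group[root] <- 0L
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1L]; ch <- cw$edge[e, 2L]
    group[ch] <- if (group[p] > 0L) group[p]
                 else if (depth[ch] >= slice) ch
                 else 0L
  }
  fam_id <- group[seq_len(n_tip)]
  fam_id[fam_id == 0L] <- seq_len(n_tip)[fam_id == 0L]  # degenerate: own family
  sizes <- sort(table(fam_id), decreasing = TRUE)
  lab <- stats::setNames(sprintf("Fam%02d", seq_along(sizes)), names(sizes))
  unname(lab[as.character(fam_id)])
}
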