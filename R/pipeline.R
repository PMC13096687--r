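#' Run the full comparative study
#'
#' Orchestrates every stage of the analysis in order: threshold-based
#' biogeographic coding, exploratory association tests, collinearity
#' diagnostics, phylogenetic signal (D) for the trait and for each
#' geographic coding, the three phylogenetic logistic model configurations
#' with AIC comparison and partial likelihood-ratio R-squared, the
#' phylogenetically corrected spatial autocorrelation stage, and -- on the
#' family-excluded dataset -- the phylogenetic linear regression of species
#' richness on hotspot occupancy. The three datasets are the full data, the
#' focal family alone, and the data without the focal family.
#'
#' Stage failures are isolated: an error in one stage is recorded in its slot
#' and the remaining stages still run. All randomness derives from `seed`.
#'
#' @param benchmark A benchmark list from [make_benchmark()]; alternatively
#'   supply `tree`, `genera`, `catalog`, and `centroids` for real inputs.
#' @param tree,genera,catalog Real-data inputs: an [ape::phylo] (or Newick
#'   path), a genus table (or TSV path, see [read_genus_table()]), and a
#'   region catalog (or TSV path, see [read_region_catalog()]).
#' @param thresholds Occupancy thresholds for the tropical coding; the first
#'   is primary (all stages, all datasets), the rest are rerun on the full
#'   dataset only (exploratory tests, tropical D, all-predictor model).
#' @param focal_family Family defining the subset analyses; defaults to the
#'   benchmark's largest synthetic family, or `"Rubiaceae"` for real inputs.
#' @param n_sim Simulations per null model for the D statistics.
#' @param seed Integer seed governing all simulation-based stages.
#' @param penalized Use the Firth-type penalty in the logistic fits.
#' @param k_eigen Number of phylogenetic eigenvectors in the spatial stage.
#' @return A list of class `slp_study`: one element per dataset
#'   (`full`, `family`, `non_family`) plus `secondary_thresholds`, `meta`.
#' @export
run_study <- function(benchmark = NULL, tree = NULL, genera = NULL,
                      catalog = NULL, thresholds = c(0.5, 0.7),
                      focal_family = NULL, n_sim = 1000L, seed = 1L,
                      penalized = TRUE, k_eigen = 10L) {
  stopifnot(length(thresholds) >= 1L, all(thresholds > 0), all(thresholds <= 1))
  primary <- coding_config(occupancy_threshold = thresholds[1L])
  if (!is.null(benchmark)) {
    dataset <- benchmark$dataset
    catalog <- benchmark$catalog
    occupancy <- benchmark$occupancy
    centroids <- benchmark$centroids
    if (is.null(focal_family)) focal_family <- benchmark$focal_family
  } else {
    if (is.null(tree) || is.null(genera) || is.null(catalog)) {
      stop("supply either 'benchmark' or all of 'tree', 'genera', 'catalog'")
    }
    if (is.character(tree)) tree <- read_newick(tree)
    if (is.character(genera)) genera <- read_genus_table(genera)
    if (is.character(catalog)) catalog <- read_region_catalog(catalog, primary)
    occupancy <- stats::setNames(genera$regions, genera$genus)
    coding <- code_genera(occupancy[!genera$missing_distribution], catalog, primary)
    dataset <- align_dataset(genera, tree, coding)
    centroids <- compute_centroids(dataset, catalog, occupancy)
    if (is.null(focal_family)) focal_family <- "Rubiaceae"
  }
  set.seed(seed)
  datasets <- list(full = dataset)
  datasets$family <- try_stage(subset_by_family(dataset, focal_family, "include"))
  datasets$non_family <- try_stage(subset_by_family(dataset, focal_family, "exclude"))

  report <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    if (is_stage_error(ds)) { report[[nm]] <- ds; next }
    idx <- match(ds$genera$genus, dataset$genera$genus)
    report[[nm]] <- analyse_dataset(
      ds, centroids[idx, , drop = FALSE], n_sim = n_sim,
      seed = seed + match(nm, names(datasets)), penalized = penalized,
      k_eigen = k_eigen,
      richness_hotspot_lm = (nm == "non_family")
    )
  }

  report$secondary_thresholds <- lapply(thresholds[-1L], function(th) {
    try_stage(rerun_threshold(benchmark, tree, genera, catalog, occupancy,
                              dataset, th, n_sim, seed, penalized))
  })
  names(report$secondary_thresholds) <- as.character(thresholds[-1L])
  report$meta <- list(
    thresholds = thresholds, focal_family = focal_family, n_sim = n_sim,
    seed = seed, penalized = penalized, k_eigen = k_eigen, n_full = dataset$n,
    timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  class(report) <- "slp_study"
  report
}

try_stage <- function(expr) {
  tryCatch(expr, error = function(e) list(error = conditionMessage(e)))
}

is_stage_error <- function(x) is.list(x) && !is.null(x$error)

compute_centroids <- function(dataset, catalog, occupancy) {
  t(vapply(dataset$genera$genus, function(g) {
    r <- match(occupancy[[g]], catalog$region)
    as.numeric(genus_centroid(cbind(catalog$centroid_lon[r],
                                    catalog$centroid_lat[r])))
  }, numeric(2L)))
}

# All stages for one dataset; each stage isolated by try_stage().
analyse_dataset <- function(ds, centroids, n_sim, seed, penalized, k_eigen,
                            richness_hotspot_lm = FALSE) {
  out <- list(n = ds$n, n_polymorphic = sum(ds$trait),
              provenance = ds$provenance)
  out$exploratory <- try_stage(exploratory_tests(ds))
  out$collinearity <- try_stage(collinearity_report(ds$design))
  out$signal <- list(
    slp = try_stage(phylo_d(ds$tree, ds$trait, n_sim, seed = seed)),
    tropical = try_stage(phylo_d(ds$tree, ds$design[, "tropical"], n_sim,
                                 seed = seed + 100L)),
    hotspot = try_stage(phylo_d(ds$tree, ds$design[, "hotspot"], n_sim,
                                seed = seed + 200L))
  )
  configs <- list(all = c("tropical", "hotspot", "species_richness"),
                  no_hotspot = c("tropical", "species_richness"),
                  no_tropical = c("hotspot", "species_richness"))
  fits <- lapply(configs, function(pr) {
    try_stage(fit_phyloglm(ds, pr, penalized = penalized))
  })
  out$models <- fits
  ok <- !vapply(fits, is_stage_error, logical(1L))
  out$model_comparison <- if (sum(ok) >= 2L) {
    try_stage(compare_models(fits[ok]))
  } else list(error = "fewer than 2 model fits succeeded")
  out$partial_r2 <- if (!is_stage_error(fits$all)) {
    try_stage(partial_r2_table(ds, configs$all, penalized = penalized,
                               full = fits$all))
  } else list(error = "full model fit failed")
  out$spatial <- try_stage(
    spatial_autocorrelation(ds, centroids, k = min(k_eigen, ds$n - 2L))
  )
  if (richness_hotspot_lm) {
    out$richness_hotspot <- try_stage(
      fit_phylolm(ds$design[, "species_richness"],
                  ds$design[, "hotspot", drop = FALSE], ds$tree)
    )
  }
  out
}

# Secondary-threshold rerun on the full dataset only: recode the tropical
# predictor, then repeat the exploratory tests, the tropical-coding D, and
# the all-predictor model.
rerun_threshold <- function(benchmark, tree, genera, catalog, occupancy,
                            dataset, threshold, n_sim, seed, penalized) {
  cfg <- coding_config(occupancy_threshold = threshold)
  cod <- code_genera(occupancy[dataset$genera$genus], catalog, cfg)
  ds <- dataset
  ds$design[, "tropical"] <- cod$tropical[match(ds$genera$genus, cod$genus)]
  list(
    threshold = threshold,
    exploratory = try_stage(exploratory_tests(ds)),
    signal_tropical = try_stage(phylo_d(ds$tree, ds$design[, "tropical"],
                                        n_sim, seed = seed + 300L)),
    model_all = try_stage(fit_phyloglm(ds, penalized = penalized))
  )
}

#' @export
print.slp_study <- function(x, ...) {
  cat(sprintf("Comparative study report (n = %d genera, focal family: %s)\n",
              x$meta$n_full, x$meta$focal_family))
  for (nm in c("full", "family", "non_family")) {
    el <- x[[nm]]
    if (is_stage_error(el)) {
      cat(sprintf("  %-10s skipped: %s\n", nm, el$error)); next
    }
    d <- if (!is_stage_error(el$signal$slp)) sprintf("%.3f", el$signal$slp$D) else "NA"
    cat(sprintf("  %-10s n = %4d (%d polymorphic), trait D = %s\n",
                nm, el$n, el$n_polymorphic, d))
  }
  invisible(x)
}

#' Write a study report to JSON and TSV files
#'
#' Serializes the machine-readable core of an `slp_study` (statistics,
#' p-values, coefficient tables, model comparison, provenance) to
#' `report.json`, plus per-dataset coefficient tables as TSV.
#'
#' @param report An `slp_study` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "slp_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(simplify_report(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in c("full", "family", "non_family")) {
    el <- report[[nm]]
    if (is_stage_error(el) || is_stage_error(el$models$all)) next
    utils::write.table(coef_table(el$models$all),
                       file.path(dir, paste0("coefficients_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}

# Strip bulky simulation vectors and closures down to plain JSON-able values.
simplify_report <- function(x) {
  if (inherits(x, "phylo_d")) {
    return(list(D = x$D, d_obs = x$d_obs, p_random = x$p_random,
                p_brownian = x$p_brownian, n_sim = x$n_sim, n = x$n,
                prevalence = x$prevalence))
  }
  if (inherits(x, "slp_phyloglm") || inherits(x, "slp_logistic")) {
    out <- list(beta = as.list(x$beta), se = as.list(x$se),
                z = as.list(x$z), p = as.list(x$p),
                logLik = x$logLik, converged = x$converged, n = x$n)
    if (!is.null(x$alpha)) out$alpha <- x$alpha
    return(out)
  }
  if (inherits(x, "slp_phylolm")) {
    return(list(beta = as.list(x$beta), se = as.list(x$se), p = as.list(x$p),
                sigma2 = x$sigma2, logLik = x$logLik, n = x$n))
  }
  if (inherits(x, "slp_moran")) {
    return(list(I = x$I, expected = x$expected, variance = x$variance,
                z_score = x$z_score, p = x$p, n = x$n))
  }
  if (inherits(x, "slp_dataset")) return(NULL)
  if (is.matrix(x) && length(x) > 1000L) return(NULL)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    keep <- !vapply(x, function(el) inherits(el, "slp_weights") ||
                      is.function(el) || inherits(el, "phylo"), logical(1L))
    return(lapply(x[keep], simplify_report))
  }
  x
}
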