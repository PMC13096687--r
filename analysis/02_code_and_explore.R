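#!/usr/bin/env Rscript
# Stage 2: biogeographic coding at the 50% and 70% occupancy thresholds,
# then the non-phylogenetic first pass -- chi-square association of the
# trait with each geographic coding, Welch t-test on species richness, and
# the collinearity diagnostics (VIF, pairwise phi).
# Reads the files written by 01_simulate_benchmark.R.

library(slpbiogeo)

bdir <- "results/benchmark"
stopifnot(dir.exists(bdir))  # run 01_simulate_benchmark.R first
tree <- read_newick(file.path(bdir, "tree.nwk"))
genera <- read_genus_table(file.path(bdir, "genus_table.tsv"))
catalog <- read_region_catalog(file.path(bdir, "region_catalog.tsv"))
occ <- stats::setNames(genera$regions, genera$genus)

for (th in c(0.5, 0.7)) {
  cod <- code_genera(occ, catalog, coding_config(occupancy_threshold = th))
  cat(sprintf("threshold %.0f%%: %d/%d genera tropical, %d hotspot\n",
              100 * th, sum(cod$tropical), nrow(cod), sum(cod$hotspot)))
}

ds <- align_dataset(genera, tree, code_genera(occ, catalog))
ex <- exploratory_tests(ds)
cat("\nExploratory tests (50% threshold):\n")
for (nm in c("chisq_tropical", "chisq_hotspot", "t_richness")) {
  r <- ex[[nm]]
  if (is.null(r$error)) {
    cat(sprintf("  %-15s statistic = %8.3f  p = %.4g\n", nm, r$statistic, r$p))
  } else cat(sprintf("  %-15s skipped: %s\n", nm, r$error))
}

col <- collinearity_report(ds$design)
cat("\nVIF:\n"); print(round(col$vif, 3))
cat("Pairwise phi (binary predictors):\n"); print(col$phi)

dir.create("results", showWarnings = FALSE)
out <- list(exploratory = ex[grep("^table_", names(ex), invert = TRUE)],
            vif = as.list(col$vif), phi = col$phi)
jsonlite::write_json(out, "results/02_exploratory.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("\nwrote results/02_exploratory.json\n")
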