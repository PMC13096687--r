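#!/usr/bin/env Rscript
# Stage 4: phylogenetic logistic regression of the trait on tropical
# occurrence, hotspot occurrence and species richness. Three model
# configurations (all predictors / no hotspot / no tropical) are compared
# by AIC and Akaike weights, and the full model is decomposed into partial
# likelihood-ratio R-squared per component, including the phylogeny itself
# (full model vs ordinary logistic regression). The family subsets rerun
# the full configuration, and the family-excluded data get the
# richness ~ hotspot phylogenetic linear regression.

library(slpbiogeo)

bdir <- "results/benchmark"
stopifnot(dir.exists(bdir))
tree <- read_newick(file.path(bdir, "tree.nwk"))
genera <- read_genus_table(file.path(bdir, "genus_table.tsv"))
catalog <- read_region_catalog(file.path(bdir, "region_catalog.tsv"))
occ <- stats::setNames(genera$regions, genera$genus)
ds <- align_dataset(genera, tree, code_genera(occ, catalog))
focal <- names(which.max(table(ds$genera$family)))

configs <- list(all = c("tropical", "hotspot", "species_richness"),
                no_hotspot = c("tropical", "species_richness"),
                no_tropical = c("hotspot", "species_richness"))
fits <- lapply(configs, function(p) fit_phyloglm(ds, p))
cat("== Full dataset, all predictors ==\n"); print(fits$all)

cmp <- compare_models(fits)
cat("\nModel comparison (AIC):\n"); print(cmp, digits = 4)

pr <- partial_r2_table(ds, configs$all, full = fits$all)
cat("\nPartial likelihood-ratio R2:\n"); print(pr$table, digits = 4)

utils::write.table(cmp, "results/04_model_comparison.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(pr$table, "results/04_partial_r2.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

for (mode in c("include", "exclude")) {
  sub <- tryCatch(subset_by_family(ds, focal, mode), error = function(e) NULL)
  if (is.null(sub) || length(unique(sub$trait)) < 2) {
    cat(sprintf("\n%s %s: skipped (no trait variation)\n", mode, focal)); next
  }
  cat(sprintf("\n== %s %s (n = %d, %d polymorphic) ==\n",
              mode, focal, sub$n, sum(sub$trait)))
  print(tryCatch(fit_phyloglm(sub), error = function(e) e$message))
  if (mode == "exclude") {
    cat("\nrichness ~ hotspot (phylogenetic linear regression):\n")
    print(fit_phylolm(sub$design[, "species_richness"],
                      sub$design[, "hotspot", drop = FALSE], sub$tree))
  }
}
cat("\nwrote results/04_model_comparison.tsv, results/04_partial_r2.tsv\n")
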