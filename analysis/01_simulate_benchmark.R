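#!/usr/bin/env Rscript
# Stage 1: generate the synthetic genus-level benchmark that stands in for
# the real inputs (megaphylogeny, POWO-style occupancy, richness, trait).
# Writes the benchmark in the same Newick/TSV formats the package reads, so
# the later stages can be replayed from files.

library(slpbiogeo)

out <- "results/benchmark"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260920)
bench <- make_benchmark(cfg)
ds <- bench$dataset

cat(sprintf("Benchmark: %d genera, %d polymorphic (prevalence %.1f%%)\n",
            ds$n, sum(ds$trait), 100 * mean(ds$trait)))
cat(sprintf("Regions: %d (%d tropical, %d hotspot)\n",
            nrow(bench$catalog), sum(bench$catalog$tropical),
            sum(bench$catalog$hotspot)))
cat(sprintf("Focal family (largest clade-family): %s with %d genera\n",
            bench$focal_family,
            sum(ds$genera$family == bench$focal_family)))

write_newick(ds$tree, file.path(out, "tree.nwk"))
write_genus_table(ds$genera, file.path(out, "genus_table.tsv"))
utils::write.table(bench$catalog, file.path(out, "region_catalog.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(genus = ds$genera$genus, bench$centroids),
                   file.path(out, "centroids.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("wrote tree.nwk, genus_table.tsv, region_catalog.tsv, centroids.tsv to ",
    out, "\n", sep = "")
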