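#' Read a single rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' downstream analyses rely on: exactly one tree, unique tip labels,
#' non-negative branch lengths. Polytomies are allowed and retained.
#'
#' @param path Path to a Newick file containing one tree.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) {
    stop("failed to parse Newick file '", path, "': ", conditionMessage(e))
  })
  if (is.null(tr)) stop("failed to parse Newick file '", path, "'")
  if (inherits(tr, "multiPhylo")) stop("file contains more than one tree: ", path)
  check_phylogeny(tr)
  tr
}

#' Write a phylogeny to a Newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  check_phylogeny(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

check_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected an object of class 'phylo'")
  if (ape::Ntip(tree) < 2L) stop("phylogeny must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed")
  }
  invisible(tree)
}

#' Read a genus trait/distribution table
#'
#' The table is UTF-8 and tab-delimited with columns `genus`, `family`,
#' `slp` (0/1), `species_richness`, and `regions` (pipe-delimited list of
#' region identifiers). One row per genus.
#'
#' @param path Path to the table.
#' @return A data frame with one row per genus; `regions` is a list-column of
#'   character vectors. Genera with an empty region list are kept but flagged
#'   in the logical column `missing_distribution` and excluded downstream by
#'   [align_dataset()].
#' @export
read_genus_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                           na.strings = c("NA", ""))
  need <- c("genus", "family", "slp", "species_richness", "regions")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("genus table is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$genus)) {
    stop("duplicated genus: ",
         paste(unique(tab$genus[duplicated(tab$genus)]), collapse = ", "))
  }
  if (any(!tab$slp %in% c(0, 1))) stop("'slp' must be coded 0/1")
  bad_rich <- !is.na(tab$species_richness) & tab$species_richness < 1
  if (any(bad_rich)) stop("'species_richness' must be >= 1 when present")
  regions <- strsplit(ifelse(is.na(tab$regions), "", tab$regions), "|", fixed = TRUE)
  regions <- lapply(regions, function(r) r[nzchar(r)])
  tab$regions <- regions
  tab$missing_distribution <- lengths(regions) == 0L
  tab
}

#' Write a genus table in the package's tab-delimited dialect
#'
#' @param genera Data frame as returned by [read_genus_table()] (the `regions`
#'   list-column is re-joined with `|`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genus_table <- function(genera, path) {
  out <- genera[setdiff(names(genera), "missing_distribution")]
  out$regions <- vapply(genera$regions, paste, character(1L), collapse = "|")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Align a genus table with a phylogeny into an analysis dataset
#'
#' Prunes the tree to the genera with complete data (present in the tree,
#' non-missing distribution, non-missing species richness) and assembles the
#' binary trait vector and the design matrix in tip order. Genera failing any
#' requirement are dropped into the provenance counts rather than imputed.
#'
#' @param genera Data frame from [read_genus_table()].
#' @param tree An [ape::phylo] whose tip labels are genus names.
#' @param coding Data frame from [code_genera()] with columns `genus`,
#'   `tropical`, `hotspot` (one row per codable genus), or `NULL` to build a
#'   dataset without the geographic predictors.
#' @return An object of class `slp_dataset` with elements `tree`, `trait`
#'   (named 0/1 vector), `design` (matrix with columns `tropical`, `hotspot`,
#'   `species_richness`), `genera` (the retained rows), `n`, and `provenance`
#'   (counts of dropped genera by reason).
#' @export
align_dataset <- function(genera, tree, coding = NULL) {
  check_phylogeny(tree)
  in_tree <- genera$genus %in% tree$tip.label
  has_dist <- !genera$missing_distribution
  has_rich <- !is.na(genera$species_richness)
  keep <- in_tree & has_dist & has_rich
  prov <- list(
    input = nrow(genera),
    absent_from_tree = sum(!in_tree),
    missing_distribution = sum(in_tree & !has_dist),
    missing_richness = sum(in_tree & has_dist & !has_rich),
    tree_tips_without_data = sum(!tree$tip.label %in% genera$genus[keep]),
    retained = sum(keep)
  )
  if (prov$missing_richness > 0L) {
    warning(prov$missing_richness, " genera dropped for missing species richness")
  }
  if (prov$retained < 2L) stop("fewer than 2 genera with complete data overlap the tree")
  kept <- genera[keep, , drop = FALSE]
  pruned <- ape::drop.tip(tree, setdiff(tree$tip.label, kept$genus))
  ord <- match(pruned$tip.label, kept$genus)
  kept <- kept[ord, , drop = FALSE]
  design <- cbind(species_richness = as.numeric(kept$species_richness))
  if (!is.null(coding)) {
    ci <- match(kept$genus, coding$genus)
    if (anyNA(ci)) stop("coding table lacks entries for some retained genera")
    design <- cbind(tropical = as.numeric(coding$tropical[ci]),
                    hotspot = as.numeric(coding$hotspot[ci]),
                    design)
  }
  rownames(design) <- kept$genus
  new_slp_dataset(pruned, stats::setNames(as.integer(kept$slp), kept$genus),
                  design, kept, prov)
}

new_slp_dataset <- function(tree, trait, design, genera, provenance) {
  stopifnot(identical(tree$tip.label, names(trait)),
            identical(tree$tip.label, rownames(design)))
  structure(
    list(tree = tree, trait = trait, design = design, genera = genera,
         n = ape::Ntip(tree), provenance = provenance),
    class = "slp_dataset"
  )
}

#' @export
print.slp_dataset <- function(x, ...) {
  cat(sprintf("slp_dataset: %d genera (%d polymorphic), predictors: %s\n",
              x$n, sum(x$trait), paste(colnames(x$design), collapse = ", ")))
  pr <- x$provenance
  if (!is.null(pr)) {
    cat(sprintf("  provenance: %d input, %d absent from tree, %d missing distribution, %d missing richness\n",
                pr$input, pr$absent_from_tree, pr$missing_distribution, pr$missing_richness))
  }
  invisible(x)
}

#' Subset an analysis dataset by family
#'
#' Builds the family-restricted (or family-excluded) dataset with the tree
#' re-pruned and the row/tip order invariant maintained. The include and
#' exclude subsets for the same family partition the parent dataset.
#'
#' @param dataset An `slp_dataset` from [align_dataset()].
#' @param family Family name, e.g. `"Rubiaceae"`.
#' @param mode `"include"` to keep only that family, `"exclude"` to drop it.
#' @return An `slp_dataset`.
#' @export
subset_by_family <- function(dataset, family, mode = c("include", "exclude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "slp_dataset"))
  in_fam <- dataset$genera$family == family
  if (mode == "include" && !any(in_fam)) {
    stop("family '", family, "' does not occur in the dataset")
  }
  keep <- if (mode == "include") in_fam else !in_fam
  if (sum(keep) < 2L) stop("subset would retain fewer than 2 genera")
  if (all(keep)) return(dataset)
  pruned <- ape::drop.tip(dataset$tree, dataset$tree$tip.label[!keep])
  ord <- match(pruned$tip.label, dataset$genera$genus)
  prov <- dataset$provenance
  prov$subset <- sprintf("%s %s (kept %d of %d)", mode, family, sum(keep), dataset$n)
  new_slp_dataset(pruned, dataset$trait[ord],
                  dataset$design[ord, , drop = FALSE],
                  dataset$genera[ord, , drop = FALSE], prov)
}
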