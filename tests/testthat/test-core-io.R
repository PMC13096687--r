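test_that("read_newick parses standard trees and enforces its contracts", {
  f <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_equal(ape::Ntip(tr), 3L)
  root_children <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1L, 2]
  expect_length(root_children, 2L)

  writeLines("(A:1,B:1);", f)
  expect_equal(ape::Ntip(read_newick(f)), 2L)

  writeLines(c("(A:1,B:1);", "(C:1,D:1);"), f)
  expect_error(read_newick(f), "more than one tree")

  writeLines("((A:1,A:1):1,C:2);", f)
  expect_error(read_newick(f), "duplicate tip")
})

test_that("newick round-trip preserves topology and branch lengths", {
  set.seed(11)
  tr <- ape::rphylo(20, 1, 0)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
  expect_equal(stats::cophenetic(tr2)[tr$tip.label, tr$tip.label],
               stats::cophenetic(tr), tolerance = 1e-8)
})

test_that("read_genus_table parses records and flags empty distributions", {
  tab <- read_genus_table(write_toy_genus_table())
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$regions[[1]], c("R001", "R002"))
  expect_true(tab$missing_distribution[tab$genus == "Carex"])
  expect_false(any(tab$missing_distribution[tab$genus != "Carex"]))
})

test_that("read_genus_table rejects malformed tables", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genus\tfamily\tslp\tspecies_richness\tregions",
               "A\tF\t2\t10\tR001"), f)
  expect_error(read_genus_table(f), "0/1")
  writeLines(c("genus\tfamily\tslp\tspecies_richness\tregions",
               "A\tF\t1\t10\tR001", "A\tF\t0\t5\tR002"), f)
  expect_error(read_genus_table(f), "duplicated genus")
})

test_that("align_dataset prunes to the data/tree intersection with provenance", {
  tab <- read_genus_table(write_toy_genus_table())
  tree <- ape::read.tree(text = "((Psychotria:1,Primula:1):1,(Linum:1,(Quercus:0.5,Ilex:0.5):0.5):1);")
  cod <- code_genera(stats::setNames(tab$regions[!tab$missing_distribution],
                                     tab$genus[!tab$missing_distribution]),
                     toy_catalog())
  ds <- align_dataset(tab, tree, cod)
  # Carex (no distribution) and the absent-from-tree genera are dropped
  expect_equal(ds$n, 4L)
  expect_setequal(ds$genera$genus, c("Psychotria", "Primula", "Linum", "Quercus"))
  expect_equal(ds$provenance$absent_from_tree, 1L)   # Carex not in tree
  expect_equal(ds$provenance$missing_distribution, 0L)
  expect_equal(ds$provenance$tree_tips_without_data, 1L)  # Ilex
  # order invariant: tips, trait and design rows aligned
  expect_identical(ds$tree$tip.label, names(ds$trait))
  expect_identical(ds$tree$tip.label, rownames(ds$design))
})

test_that("pruning preserves patristic distances between retained tips", {
  set.seed(21)
  tr <- ape::rphylo(12, 1, 0)
  keep <- sample(tr$tip.label, 6)
  pruned <- ape::drop.tip(tr, setdiff(tr$tip.label, keep))
  for (pair in list(keep[1:2], keep[3:4], keep[c(1, 5)])) {
    expect_equal(stats::cophenetic(pruned)[pair[1], pair[2]],
                 brute_patristic(tr, pair[1], pair[2]), tolerance = 1e-10)
  }
})

test_that("family include/exclude subsets partition the parent dataset", {
  b <- make_benchmark(sim_config(n_tips = 80, seed = 3))
  ds <- b$dataset
  fam <- b$focal_family
  inc <- subset_by_family(ds, fam, "include")
  exc <- subset_by_family(ds, fam, "exclude")
  expect_equal(inc$n + exc$n, ds$n)
  expect_length(intersect(inc$genera$genus, exc$genera$genus), 0L)
  expect_setequal(c(inc$genera$genus, exc$genera$genus), ds$genera$genus)
  expect_true(all(inc$genera$family == fam))
  expect_true(all(exc$genera$family != fam))
  # excluding an absent family is the identity
  expect_identical(subset_by_family(ds, "NoSuchFamily", "exclude"), ds)
  expect_error(subset_by_family(ds, "NoSuchFamily", "include"), "does not occur")
})
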