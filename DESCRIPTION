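Package: slpbiogeo
Title: Phylogenetic Biogeography of Style-Length Polymorphisms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genus-level comparative analysis of the global distribution of
    style-length polymorphisms (heterostyly and related floral morph systems)
    across an angiosperm megaphylogeny. Provides threshold-based biogeographic
    coding of genera (tropical band and biodiversity-hotspot occupancy),
    exploratory association tests, a simulation-based D statistic for binary
    phylogenetic signal, phylogenetic logistic and linear regression with
    partial likelihood-ratio R-squared and AIC model comparison,
    phylogenetically corrected spatial autocorrelation (phylogenetic
    eigenvector residuals with Moran's I), and a synthetic-data generator so
    every stage of the workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
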