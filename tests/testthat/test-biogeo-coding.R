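test_that("tropical classification follows the closed-interval band rule", {
  expect_equal(classify_region_tropical(c(0, 10)), 1L)
  expect_equal(classify_region_tropical(c(30, 40)), 0L)
  # boundary touch counts as intersection under closed intervals
  expect_equal(classify_region_tropical(c(-30, -23.45)), 1L)
  expect_equal(classify_region_tropical(c(23.45, 40)), 1L)
  expect_error(classify_region_tropical(c(10, 0)), "extent")
  # monotone in band width
  ext <- cbind(runif(50, -90, 80), 0)
  ext[, 2] <- ext[, 1] + runif(50, 0, 20)
  ext <- pmin(ext, 90)
  narrow <- classify_region_tropical(ext, coding_config(tropic_band = 10))
  wide <- classify_region_tropical(ext, coding_config(tropic_band = 35))
  expect_true(all(wide >= narrow))
})

test_that("genus coding applies the at-least threshold with ties to state 1", {
  expect_equal(code_genus(c(1, 1, 0)), 1L)                                   # 2/3 >= 0.5
  expect_equal(code_genus(c(1, 1, 0), coding_config(occupancy_threshold = 0.7)), 0L)
  expect_equal(code_genus(c(1, 0)), 1L)                                      # tie at 0.5
  expect_error(code_genus(integer(0)), "no regions")
})

test_that("coding is monotone in the occupancy threshold", {
  set.seed(31)
  strict <- coding_config(occupancy_threshold = 0.7)
  for (i in 1:50) {
    flags <- rbinom(sample(1:12, 1), 1, runif(1))
    if (code_genus(flags, strict) == 1L) {
      expect_equal(code_genus(flags), 1L)  # 1 at 0.70 implies 1 at 0.50
    }
  }
})

test_that("genus centroids handle hulls and all degenerate cases", {
  expect_equal(as.numeric(genus_centroid(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))),
               c(1, 1))
  expect_equal(as.numeric(genus_centroid(rbind(c(5, 5)))), c(5, 5))
  expect_equal(as.numeric(genus_centroid(rbind(c(0, 0), c(4, 2)))), c(2, 1))
  # collinear: midpoint of the extreme points
  expect_equal(as.numeric(genus_centroid(rbind(c(0, 0), c(1, 0), c(2, 0)))), c(1, 0))
  # asymmetric hull: area centroid of the triangle, not the vertex mean bias
  tri <- rbind(c(0, 0), c(3, 0), c(0, 3))
  expect_equal(as.numeric(genus_centroid(tri)), c(1, 1))
  # interior points must not influence the hull centroid
  expect_equal(as.numeric(genus_centroid(rbind(tri, c(0.1, 0.1)))), c(1, 1))
})

test_that("hull centroid stays inside the bounding box of its inputs", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(3:15, 1)
    p <- cbind(runif(n, -180, 180), runif(n, -60, 60))
    cen <- genus_centroid(p)
    expect_gte(cen[1], min(p[, 1])); expect_lte(cen[1], max(p[, 1]))
    expect_gte(cen[2], min(p[, 2])); expect_lte(cen[2], max(p[, 2]))
  }
})

test_that("pairwise distances: haversine sphere and planar oracle values", {
  d <- pairwise_geo_distances(rbind(c(0, 0), c(0, 90)))
  expect_equal(d[1, 2], pi / 2 * 6371, tolerance = 1e-6)  # quarter meridian
  expect_equal(diag(d), c(0, 0))
  expect_equal(d, t(d))
  de <- pairwise_geo_distances(rbind(c(0, 0), c(3, 4)), metric = "euclidean")
  expect_equal(de[1, 2], 5)
  dd <- pairwise_geo_distances(rbind(c(10, 10), c(10, 10), c(0, 0)))
  expect_equal(attr(dd, "n_coincident"), 2L)
})

test_that("code_genera maps occupancy through the catalog flags", {
  occ <- list(GenA = c("R001", "R002"), GenB = c("R003"), GenC = c("R001", "R003"))
  cod <- code_genera(occ, toy_catalog())
  expect_equal(cod$tropical, c(1L, 0L, 1L))  # GenC: 1/2 tie -> tropical
  expect_equal(cod$hotspot, c(1L, 0L, 1L))
  expect_error(code_genera(list(G = "R999"), toy_catalog()), "absent from the catalog")
})
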