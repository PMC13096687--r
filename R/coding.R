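#' Coding configuration for biogeographic classification
#'
#' Bundles the two rules used to turn region occupancy into binary genus-level
#' states: the latitudinal tropic band and the occupancy threshold.
#'
#' @param tropic_band Half-width of the tropical band in degrees latitude.
#'   The default 23.45 corresponds to 23 degrees 27 minutes, i.e. the
#'   astronomical tropics.
#' @param occupancy_threshold Fraction of a genus's occupied regions that must
#'   carry a flag for the genus to be coded state 1. Must lie in (0, 1].
#'   Typical values are 0.5 (default) and the more conservative 0.7.
#' @return An object of class `coding_config`.
#' @export
#' @examples
#' coding_config()
#' coding_config(occupancy_threshold = 0.7)
coding_config <- function(tropic_band = 23.45, occupancy_threshold = 0.5) {
  stopifnot(is.numeric(tropic_band), length(tropic_band) == 1L, tropic_band > 0)
  if (!is.numeric(occupancy_threshold) || length(occupancy_threshold) != 1L ||
      occupancy_threshold <= 0 || occupancy_threshold > 1) {
    stop("'occupancy_threshold' must lie in (0, 1]")
  }
  structure(
    list(tropic_band = tropic_band, occupancy_threshold = occupancy_threshold),
    class = "coding_config"
  )
}

#' @export
print.coding_config <- function(x, ...) {
  cat(sprintf("Biogeographic coding: tropic band +/- %.2f deg, threshold >= %.0f%%\n",
              x$tropic_band, 100 * x$occupancy_threshold))
  invisible(x)
}

#' Classify a region as tropical from its latitudinal extent
#'
#' A region counts as tropical when its latitudinal extent intersects the
#' tropic band, i.e. when it at least partly extends into the tropics. Both
#' intervals are treated as closed, so a range that merely touches the band
#' boundary is tropical.
#'
#' @param lat_extent Numeric vector of length 2, `c(min_lat, max_lat)` in
#'   degrees; vectorized input may be an n x 2 matrix.
#' @param config A [coding_config()].
#' @return Integer 0/1 (vector for matrix input).
#' @export
#' @examples
#' classify_region_tropical(c(0, 10))    # 1
#' classify_region_tropical(c(30, 40))   # 0
classify_region_tropical <- function(lat_extent, config = coding_config()) {
  m <- if (is.matrix(lat_extent)) lat_extent else matrix(lat_extent, ncol = 2L)
  if (any(!is.finite(m)) || any(m[, 1L] > m[, 2L])) {
    stop("invalid latitudinal extent: need finite min_lat <= max_lat")
  }
  if (any(m < -90) || any(m > 90)) stop("latitudes must lie in [-90, 90]")
  b <- config$tropic_band
  out <- as.integer(m[, 2L] >= -b & m[, 1L] <= b)
  if (!is.matrix(lat_extent)) out <- out[1L]
  out
}

#' Code a genus from the flags of its occupied regions
#'
#' The genus receives state 1 when at least `occupancy_threshold` of its
#' occupied regions carry the flag ("at least" means the tie at exactly the
#' threshold resolves to state 1).
#'
#' @param flags Binary vector, one entry per occupied region.
#' @param config A [coding_config()].
#' @return Integer 0 or 1.
#' @export
#' @examples
#' code_genus(c(1, 1, 0))                                    # 2/3 >= 0.5 -> 1
#' code_genus(c(1, 1, 0), coding_config(occupancy_threshold = 0.7))  # -> 0
code_genus <- function(flags, config = coding_config()) {
  if (length(flags) == 0L) stop("genus occupies no regions; cannot code")
  if (any(!flags %in% c(0, 1))) stop("region flags must be 0/1")
  as.integer(mean(flags) >= config$occupancy_threshold)
}

#' Distribution centroid of a genus from its region centroids
#'
#' For three or more non-collinear points the centroid is the area centroid of
#' their 2-D convex hull in raw (lon, lat) coordinates. Degenerate cases: a
#' single point is its own centroid, two points give their midpoint, and
#' collinear points give the midpoint of the two extreme points.
#' Longitudes are not re-wrapped across the antimeridian; genera whose
#' longitudinal span exceeds 180 degrees are flagged via the
#' `"wide_lon_range"` attribute.
#'
#' @param points Two-column matrix or data frame of (lon, lat) in degrees.
#' @return Numeric vector `c(lon, lat)`.
#' @export
#' @examples
#' genus_centroid(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)))  # (1, 1)
genus_centroid <- function(points) {
  p <- as.matrix(points)
  if (nrow(p) < 1L || ncol(p) != 2L) stop("'points' must be an n x 2 (lon, lat) matrix with n >= 1")
  storage.mode(p) <- "double"
  p <- unique(p)
  wide <- diff(range(p[, 1L])) > 180
  out <- if (nrow(p) == 1L) {
    p[1L, ]
  } else if (nrow(p) == 2L) {
    colMeans(p)
  } else {
    h <- grDevices::chull(p)
    if (length(h) < 3L) {
      # collinear: midpoint of the extremes along the dominant axis
      ax <- which.max(c(diff(range(p[, 1L])), diff(range(p[, 2L]))))
      ext <- p[c(which.min(p[, ax]), which.max(p[, ax])), , drop = FALSE]
      colMeans(ext)
    } else {
      polygon_centroid(p[h, , drop = FALSE])
    }
  }
  out <- unname(out)
  attr(out, "wide_lon_range") <- wide
  out
}

# Shoelace area centroid of a simple polygon given as ordered vertices.
polygon_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(v))  # numerically degenerate hull
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Pairwise geographic distances between centroids
#'
#' @param points Two-column matrix of (lon, lat) in degrees.
#' @param metric `"greatcircle"` (haversine on a 6371-km sphere, result in km)
#'   or `"euclidean"` (planar distance in degrees, useful for oracle checks).
#' @return Symmetric matrix with zero diagonal. The attribute
#'   `"n_coincident"` counts off-diagonal zero distances (distinct records at
#'   identical coordinates), which [inverse_distance_weights()] must handle.
#' @export
pairwise_geo_distances <- function(points, metric = c("greatcircle", "euclidean")) {
  metric <- match.arg(metric)
  p <- as.matrix(points)
  if (nrow(p) < 2L || ncol(p) != 2L) stop("'points' must be an n x 2 (lon, lat) matrix with n >= 2")
  d <- if (metric == "greatcircle") {
    n <- nrow(p)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      ji <- (i + 1L):n
      m[i, ji] <- geosphere::distHaversine(p[i, ], p[ji, , drop = FALSE], r = 6371) # km
    }
    m + t(m)
  } else {
    as.matrix(stats::dist(p))
  }
  dimnames(d) <- list(rownames(points), rownames(points))
  attr(d, "n_coincident") <- sum(d[upper.tri(d)] == 0) * 2L
  d
}

#' Read a region catalog from a tab-delimited file
#'
#' Expected columns: `region`, `min_lat`, `max_lat`, `centroid_lon`,
#' `centroid_lat`, `hotspot` (0/1).
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row.
#' @return A data frame with one row per region, plus a `tropical` column
#'   computed from `config`.
#' @param config A [coding_config()] used to pre-compute the `tropical` flag.
#' @export
read_region_catalog <- function(path, config = coding_config()) {
  cat_df <- utils::read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("region", "min_lat", "max_lat", "centroid_lon", "centroid_lat", "hotspot")
  miss <- setdiff(need, names(cat_df))
  if (length(miss)) stop("region catalog is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cat_df$region)) stop("duplicated region identifiers in catalog")
  if (any(!cat_df$hotspot %in% c(0, 1))) stop("'hotspot' must be 0/1")
  cat_df$tropical <- classify_region_tropical(
    cbind(cat_df$min_lat, cat_df$max_lat), config
  )
  cat_df
}

#' Apply tropical/hotspot coding to genus occupancy lists
#'
#' Maps each genus's occupied regions onto the catalog flags and applies the
#' occupancy-threshold rule to produce the two binary predictors used in the
#' regressions. The hotspot coding always uses the 50% rule; the configurable
#' threshold applies to the tropical coding only, matching its gradient-based
#' definition (hotspot membership is categorical).
#'
#' @param occupancy Named list: for each genus, a character vector of region ids.
#' @param catalog Region catalog data frame from [read_region_catalog()] (or
#'   the synthetic generator), with `region`, `tropical`, `hotspot` columns.
#' @param config A [coding_config()].
#' @return Data frame with columns `genus`, `tropical`, `hotspot`, `n_regions`.
#' @export
code_genera <- function(occupancy, catalog, config = coding_config()) {
  stopifnot(is.list(occupancy), !is.null(names(occupancy)))
  unknown <- setdiff(unique(unlist(occupancy)), catalog$region)
  if (length(unknown)) {
    stop("occupancy refers to regions absent from the catalog: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  trop <- stats::setNames(catalog$tropical, catalog$region)
  hot <- stats::setNames(catalog$hotspot, catalog$region)
  half <- coding_config(config$tropic_band, 0.5)
  data.frame(
    genus = names(occupancy),
    tropical = vapply(occupancy, function(r) code_genus(trop[r], config), integer(1L)),
    hotspot = vapply(occupancy, function(r) code_genus(hot[r], half), integer(1L)),
    n_regions = lengths(occupancy),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
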