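#' Aggregate points into kilometre-scale density bins
#'
#' Projects points onto a local azimuthal-equidistant plane anchored at
#' their centroid (geodesic distance and bearing via the WGS84 ellipsoid),
#' snaps them to a fixed square grid of `bin_km` side, and counts points
#' per occupied bin. When a `species` column is present the per-bin species
#' richness is also returned. The binning is deterministic: it depends only
#' on the point set, not on its order.
#'
#' @param points data.frame with `longitude`, `latitude` (and optionally
#'   `species`), or a two-column (lon, lat) matrix.
#' @param bin_km bin side in kilometres (default 1, i.e., accessions within
#'   about 1 km aggregate into one density cell).
#' @return data.frame of class `"hotspot_bins"`: `bin_x`, `bin_y` (integer
#'   bin indices), `x_km`, `y_km` (bin centres in the local plane),
#'   `longitude`, `latitude` (bin centres back-projected), `count`, and
#'   `richness` when species are known; attributes `anchor` and `bin_km`.
#' @export
bin_points <- function(points, bin_km = 1.0) {
  stopifnot(bin_km > 0)
  if (is.matrix(points))
    points <- data.frame(longitude = points[, 1], latitude = points[, 2])
  n <- nrow(points)
  if (n == 0) {
    out <- data.frame(bin_x = integer(), bin_y = integer(),
                      x_km = numeric(), y_km = numeric(),
                      longitude = numeric(), latitude = numeric(),
                      count = integer())
    return(structure(out, class = c("hotspot_bins", "data.frame"),
                     anchor = c(NA_real_, NA_real_), bin_km = bin_km))
  }
  anchor <- c(mean(points$longitude), mean(points$latitude))
  p <- cbind(points$longitude, points$latitude)
  d <- geosphere::distGeo(anchor, p) / 1000           # km
  b <- geosphere::bearing(anchor, p) * pi / 180       # rad from north
  x <- ifelse(d == 0, 0, d * sin(b))
  y <- ifelse(d == 0, 0, d * cos(b))
  ix <- as.integer(floor(x / bin_km))
  iy <- as.integer(floor(y / bin_km))
  key <- paste(ix, iy)
  ord <- order(ix, iy)
  uk <- !duplicated(key[ord])
  ux <- ix[ord][uk]; uy <- iy[ord][uk]
  count <- as.integer(table(key)[paste(ux, uy)])
  cx <- (ux + 0.5) * bin_km; cy <- (uy + 0.5) * bin_km
  cd <- sqrt(cx^2 + cy^2) * 1000
  cb <- atan2(cx, cy) * 180 / pi
  ll <- geosphere::destPoint(anchor, cb, cd)
  out <- data.frame(bin_x = ux, bin_y = uy, x_km = cx, y_km = cy,
                    longitude = ll[, 1], latitude = ll[, 2], count = count)
  if ("species" %in% names(points)) {
    sp_key <- split(points$species[ord], factor(key[ord],
                                                levels = paste(ux, uy)))
    out$richness <- vapply(sp_key, function(s) length(unique(s)), integer(1))
  }
  rownames(out) <- NULL
  structure(out, class = c("hotspot_bins", "data.frame"),
            anchor = anchor, bin_km = bin_km)
}

#' Distance-band spatial weights
#'
#' Binary neighbor lists over bin centres in the local projected plane:
#' bins within `band_km` of each other (Euclidean, in km) are neighbors,
#' and every bin is its own neighbor (the "star" in Gi*).
#'
#' @param bins a `"hotspot_bins"` data.frame (needs `x_km`, `y_km`).
#' @param band_km neighborhood band distance in kilometres (default 50).
#' @return object of class `"spatial_weights"`: list of integer neighbor
#'   index vectors (self included), with attribute `band_km`.
#' @export
band_weights <- function(bins, band_km = 50) {
  stopifnot(band_km > 0)
  xy <- cbind(bins$x_km, bins$y_km)
  d <- as.matrix(stats::dist(xy))
  nb <- apply(d <= band_km, 1, which, simplify = FALSE)
  structure(nb, class = "spatial_weights", band_km = band_km)
}

#' Local Getis-Ord Gi* statistic
#'
#' For each bin i over the full set of occupied bins, the Gi* z-value
#' in its variance-corrected form with the focal bin included:
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar{X} S_{1i}}
#'   {S \sqrt{(n S_{2i} - S_{1i}^2)/(n - 1)}}}
#' with binary band weights (`S1 = S2 =` neighbor count), global mean
#' `X-bar` and population standard deviation `S` of the binned values.
#' A zero global variance yields z = 0 everywhere. Two-sided normal
#' p-values and significance classes at |z| thresholds 1.65/1.96/2.58
#' (90/95/99%) are attached.
#'
#' @param bins a `"hotspot_bins"` data.frame (n >= 2 rows).
#' @param weights a `"spatial_weights"` object covering all bins; built
#'   with [band_weights()] at `band_km` when omitted.
#' @param band_km neighborhood band used when `weights` is `NULL`.
#' @param value `"count"` (accession density, default) or `"richness"`
#'   (species diversity per bin).
#' @return the bins data.frame of class `"hotspot_cells"` with added
#'   columns `x` (the analyzed value), `gi_z`, `p_value`, `class`.
#' @export
gi_star <- function(bins, weights = NULL, band_km = 50,
                    value = c("count", "richness")) {
  value <- match.arg(value)
  n <- nrow(bins)
  if (n < 2) stop_ecogeo("Gi* needs at least 2 bins")
  if (value == "richness" && !"richness" %in% names(bins))
    stop_ecogeo("bins carry no richness (no species column when binning)")
  x <- as.numeric(bins[[value]])
  if (is.null(weights)) weights <- band_weights(bins, band_km)
  stopifnot(inherits(weights, "spatial_weights"), length(weights) == n)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  z <- numeric(n)
  if (S > 0) {
    for (i in seq_len(n)) {
      nb <- weights[[i]]
      s1 <- length(nb)                 # binary weights: S1 = S2
      den <- S * sqrt((n * s1 - s1^2) / (n - 1))
      z[i] <- if (den == 0) 0 else (sum(x[nb]) - xbar * s1) / den
    }
  }
  out <- as.data.frame(bins)
  out$x <- x
  out$gi_z <- z
  out$p_value <- 2 * stats::pnorm(-abs(z))
  out <- classify_spots(out)
  structure(out, class = c("hotspot_cells", "data.frame"),
            anchor = attr(bins, "anchor"), bin_km = attr(bins, "bin_km"),
            band_km = attr(weights, "band_km"), value = value)
}

#' Classify Gi* z-values into hot/cold spot classes
#'
#' @param cells data.frame with a `gi_z` column.
#' @param thresholds |z| cutoffs for the 90/95/99% classes.
#' @return `cells` with a `class` column in
#'   hot99/hot95/hot90/not_significant/cold90/cold95/cold99.
#' @export
classify_spots <- function(cells, thresholds = c(1.65, 1.96, 2.58)) {
  stopifnot("gi_z" %in% names(cells), length(thresholds) == 3)
  z <- cells$gi_z
  lev <- ifelse(abs(z) > thresholds[3], "99",
         ifelse(abs(z) > thresholds[2], "95",
         ifelse(abs(z) > thresholds[1], "90", "")))
  cells$class <- ifelse(lev == "", "not_significant",
                        paste0(ifelse(z > 0, "hot", "cold"), lev))
  cells
}

#' Write hotspot cells as GeoJSON points
#'
#' @param cells a `"hotspot_cells"` data.frame.
#' @param path output path (.geojson).
#' @return invisibly, the path.
#' @export
write_hotspots_geojson <- function(cells, path) {
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(cells$longitude[i],
                                         cells$latitude[i])),
         properties = list(count = cells$count[i], x = cells$x[i],
                           gi_z = cells$gi_z[i], p_value = cells$p_value[i],
                           class = cells$class[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
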