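test_that("binning conserves points and is order-independent", {
  pts <- data.frame(longitude = c(-74.5, -74.5), latitude = c(-10.5, -10.5))
  b <- bin_points(pts)
  expect_equal(nrow(b), 1)
  expect_equal(b$count, 2L)

  far <- data.frame(longitude = c(-74.5, -73.58), latitude = c(-10.5, -10.5))
  b2 <- bin_points(far)  # ~100 km apart
  expect_equal(nrow(b2), 2)
  expect_equal(b2$count, c(1L, 1L))

  set.seed(12)
  cl <- data.frame(longitude = rnorm(500, -74.5, 0.05),
                   latitude = rnorm(500, -10.5, 0.05),
                   species = sample(c("a", "b"), 500, replace = TRUE))
  b3 <- bin_points(cl, bin_km = 1)
  expect_equal(sum(b3$count), 500)
  expect_true(all(b3$richness <= 2 & b3$richness >= 1))
  perm <- bin_points(cl[sample(500), ], bin_km = 1)
  expect_equal(as.data.frame(perm), as.data.frame(b3))

  expect_equal(nrow(bin_points(cl[0, ])), 0)
})

test_that("bin centres back-project close to the original points", {
  pts <- data.frame(longitude = c(-74.123, -74.9, -73.777),
                    latitude = c(-10.001, -10.85, -10.5))
  b <- bin_points(pts, bin_km = 1)
  # every occupied 1-km bin centre lies within the bin's half diagonal
  # (~707 m) of some source point
  d <- geosphere::distm(cbind(b$longitude, b$latitude),
                        cbind(pts$longitude, pts$latitude))
  expect_true(all(apply(d, 1, min) < 750))
})

test_that("Gi* matches the brute-force double loop and its invariants", {
  set.seed(5)
  n <- 150
  pts <- data.frame(longitude = runif(n, -75, -74),
                    latitude = runif(n, -11, -10))
  bins <- bin_points(pts, bin_km = 5)
  cells <- gi_star(bins, band_km = 12)
  oracle <- gi_oracle(bins$x_km, bins$y_km, bins$count, band_km = 12)
  expect_equal(cells$gi_z, oracle, tolerance = 1e-10)
  expect_equal(sum(cells$x - mean(cells$x)), 0)
  # permutation of the source points leaves every z unchanged
  cells2 <- gi_star(bin_points(pts[sample(n), ], bin_km = 5), band_km = 12)
  expect_equal(cells2$gi_z, cells$gi_z, tolerance = 1e-12)
})

test_that("a uniform field gives z = 0 everywhere", {
  # one point per bin: every binned value equals 1
  g <- expand.grid(longitude = seq(-75, -74.5, by = 0.05),
                   latitude = seq(-10.5, -10, by = 0.05))
  cells <- gi_star(bin_points(g, bin_km = 1), band_km = 10)
  expect_true(all(cells$gi_z == 0))
  expect_true(all(cells$class == "not_significant"))
})

test_that("a planted dense cluster is flagged as a 99% hot spot", {
  set.seed(8)
  sparse <- data.frame(
    longitude = -75 + (0:49) * 0.05,  # 50 bins ~5.5 km apart, 1 point each
    latitude = rep(-10.5, 50))
  cluster <- data.frame(longitude = rep(-74.3001, 100),
                        latitude = rep(-10.5002, 100))
  cells <- gi_star(bin_points(rbind(sparse, cluster), bin_km = 1),
                   band_km = 10)
  hot <- cells[which.max(cells$count), ]
  expect_gte(hot$count, 100)
  expect_gt(hot$gi_z, 2.58)
  expect_equal(hot$class, "hot99")
})

test_that("significance classes follow the z thresholds", {
  cells <- data.frame(gi_z = c(3.0, -2.0, 0.5, -1.7, 2.0, -3.0, 1.0))
  got <- classify_spots(cells)$class
  expect_equal(got, c("hot99", "cold95", "not_significant", "cold90",
                      "hot95", "cold99", "not_significant"))
})

test_that("richness-valued Gi* runs when species are known", {
  set.seed(13)
  pts <- data.frame(longitude = runif(80, -75, -74.8),
                    latitude = runif(80, -10.2, -10),
                    species = sample(c("a", "b", "c"), 80, replace = TRUE))
  bins <- bin_points(pts, bin_km = 2)
  cells <- gi_star(bins, band_km = 6, value = "richness")
  expect_equal(cells$x, as.numeric(bins$richness))
  expect_error(gi_star(bin_points(pts[, 1:2], bin_km = 2),
                       value = "richness"), "richness")
})

test_that("GeoJSON export is a valid FeatureCollection", {
  pts <- data.frame(longitude = c(-74.5, -74.51, -74.49, -73.9),
                    latitude = c(-10.5, -10.5, -10.51, -10.2))
  cells <- gi_star(bin_points(pts), band_km = 5)
  path <- tempfile(fileext = ".geojson")
  write_hotspots_geojson(cells, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), nrow(cells))
  expect_equal(gj$features[[1]]$geometry$type, "Point")
  expect_true(!is.null(gj$features[[1]]$properties$gi_z))
})
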