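koppen_dict <- function(k) setNames(names(koppen_labels())[seq_len(k)],
                                    seq_len(k))

test_that("single-class species show 100% and richness 1", {
  g <- toy_grid(matrix(5L, 3, 4), name = "koppen", kind = "categorical")
  rec <- data.frame(species = rep("S. sitiens", 4),
                    longitude = runif(4, -75, -74.1),
                    latitude = runif(4, -10.7, -10.05))
  tab <- class_frequencies(rec, g, by = "species",
                           codes = koppen_dict(10))
  expect_equal(unname(tab$counts["S. sitiens", "BWk"]), 4)
  expect_equal(unname(tab$percentages["S. sitiens", "BWk"]), 100)
  expect_equal(unname(tab$richness["S. sitiens"]), 1)
})

test_that("counts, nodata exclusions and percentages reconcile per row", {
  v <- matrix(rep(1:4, 3), 3, 4, byrow = TRUE)
  v[1, 1] <- NA
  g <- toy_grid(v, name = "koppen", kind = "categorical")
  rec <- data.frame(
    species = rep(c("S. chilense", "S. sitiens"), c(5, 3)),
    longitude = c(-74.9, -74.6, -74.4, -74.1, -74.1, -74.9, -74.6, -74.4),
    latitude = c(-10.1, -10.1, -10.6, -10.6, -10.4, -10.4, -10.4, -10.1))
  tab <- class_frequencies(rec, g, by = "species", codes = koppen_dict(6))
  expect_equal(rowSums(tab$counts) + tab$excluded_nodata,
               c(`S. chilense` = 5, `S. sitiens` = 3))
  expect_equal(unname(rowSums(tab$percentages)), c(100, 100),
               tolerance = 1e-9)
  expect_equal(unname(richness(tab)),
               unname(apply(tab$counts, 1, function(r) length(which(r > 0)))))
})

test_that("unknown class codes are labeled and warned about", {
  g <- toy_grid(matrix(99L, 3, 4), name = "koppen", kind = "categorical")
  rec <- data.frame(species = "S. chilense", longitude = -74.5,
                    latitude = -10.5)
  expect_warning(tab <- class_frequencies(rec, g, by = "species",
                                          codes = koppen_dict(3)),
                 "99")
  expect_true("UNKNOWN_99" %in% colnames(tab$counts))
})

test_that("group tables equal species tables aggregated by the group map", {
  cfg <- small_config(seed = 3)
  occ <- synthetic_occurrences(cfg)
  g <- categorical_layer(cfg, c(0.4, 0.35, 0.25), name = "koppen")
  sp <- class_frequencies(occ$records, g, by = "species",
                          codes = koppen_dict(3))
  gr <- class_frequencies(occ$records, g, by = "group",
                          codes = koppen_dict(3))
  agg <- aggregate_to_groups(sp)
  expect_equal(agg$counts, gr$counts)
  expect_equal(agg$richness, gr$richness)
  expect_equal(sum(gr$counts) + sum(gr$excluded_nodata), nrow(occ$records))
})

test_that("categorical layers carry exact planted cell proportions", {
  cfg <- synthetic_config(seed = 8, extent = c(west = -75, south = -11,
                                               east = -74, north = -10),
                          cell_size = 0.1)  # 10 x 10 cells
  g5050 <- categorical_layer(cfg, c(0.5, 0.5))
  expect_equal(unname(table(g5050$values)), c(50L, 50L), ignore_attr = TRUE)
  g1 <- categorical_layer(cfg, 1.0)
  expect_true(all(g1$values == 1))
  g532 <- categorical_layer(cfg, c(0.5, 0.3, 0.2))
  expect_equal(as.vector(table(g532$values)), c(50L, 30L, 20L))
  # same config, same layer
  expect_identical(categorical_layer(cfg, c(0.5, 0.5))$values, g5050$values)
})

test_that("scattered points recover planted class proportions", {
  cfg <- synthetic_config(seed = 31)
  props <- c(0.5, 0.3, 0.2)
  g <- categorical_layer(cfg, props, name = "koppen")
  set.seed(99)
  n <- 2000
  rec <- data.frame(species = "S. chilense",
                    longitude = runif(n, cfg$extent[["west"]],
                                      cfg$extent[["east"]]),
                    latitude = runif(n, cfg$extent[["south"]],
                                     cfg$extent[["north"]]))
  tab <- class_frequencies(rec, g, by = "species", codes = koppen_dict(3))
  counts <- as.vector(tab$counts["S. chilense", c("Af", "Am", "Aw")])
  expect_true(in_multinomial_envelope(counts, n, props))
})
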