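test_that("well-formed CSV parses fully and dialects are equivalent", {
  df <- data.frame(species = c("S. sitiens", "S. chilense", "S. pennellii"),
                   longitude = c(-69.12, -70.5432, -71.0011),
                   latitude = c(-14.25, -12.1234, -9.7777))
  comma <- read_occurrences(write_occ_csv(df))
  expect_equal(nrow(comma$records), 3)
  expect_equal(nrow(comma$errors), 0)
  expect_equal(comma$records$species, df$species)
  expect_equal(comma$records$longitude, df$longitude)

  semi <- read_occurrences(write_occ_csv(df, sep = ";"), sep = ";")
  expect_equal(semi$records, comma$records)
})

test_that("malformed rows are reported with line numbers, not dropped silently", {
  df <- data.frame(species = c("S. chilense", "S. chilense", "", "S. sitiens"),
                   longitude = c(-70.11, -70.12, -70.13, "oops"),
                   latitude = c(91.0, -12.55, -12.66, -12.77))
  out <- read_occurrences(write_occ_csv(df))
  expect_equal(nrow(out$records), 1)
  expect_equal(sort(out$errors$line), c(2L, 4L, 5L))
  expect_true(any(grepl("latitude outside", out$errors$message)))
  expect_true(any(grepl("empty species", out$errors$message)))
  expect_true(any(grepl("unparseable longitude", out$errors$message)))
})

test_that("a missing required column is a hard error naming the column", {
  df <- data.frame(sp = "S. sitiens", longitude = -69.1, latitude = -14.2)
  expect_error(read_occurrences(write_occ_csv(df)), "'species'")
  got <- read_occurrences(write_occ_csv(df), col_map = c(species = "sp"))
  expect_equal(got$records$species, "S. sitiens")
})

test_that("custom column mapping reads arbitrary headers", {
  df <- data.frame(taxon = "S. chilense", x = -70.25, y = -12.5, id = "a1")
  out <- read_occurrences(write_occ_csv(df),
                          col_map = c(species = "taxon", longitude = "x",
                                      latitude = "y", record_id = "id"))
  expect_equal(out$records$record_id, "a1")
  expect_equal(out$records$latitude, -12.5)
})

make_recs <- function(species, lon, lat, id = NULL) {
  data.frame(record_id = id %||% sprintf("r%02d", seq_along(species)),
             species = species, longitude = lon, latitude = lat,
             source = NA_character_,
             lon_text = as.character(lon), lat_text = as.character(lat),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("cleaning rules fire in order and the report reconciles", {
  # altitude ramp: 0 m in the west column to 4500 m in the east column
  alt <- raster_grid(matrix(rep(c(0, 1500, 3000, 4500), times = 4), 4, 4,
                            byrow = TRUE),
                     west = -72, north = -10, cell_size = 0.25, name = "Alt")
  ranges <- data.frame(species = "S. chilense", min_alt = 0, max_alt = 3300)
  recs <- make_recs(
    rep("S. chilense", 6),
    c(-71.88, -71.88, -71.1, -71.88, -71.13, -60.1234),  # last is off-grid
    c(-10.12, -10.12, -10.9, -10.38, -10.62, -10.5678))
  recs$lat_text[3] <- "-10.9"  # one decimal: low precision
  recs$lon_text[3] <- "-71.1"
  out <- clean_occurrences(recs, altitude_grid = alt,
                           altitude_ranges = ranges, min_decimals = 2)
  # row 2 duplicates row 1; row 3 low precision; row 6 off-grid (nodata);
  # row 5 sits on the 4500 m column, above the 3300 m species ceiling
  expect_equal(out$report$dropped,
               list(duplicate = 1L, precision = 1L, nodata = 1L,
                    altitude = 1L))
  expect_equal(out$report$kept, 2)
  expect_equal(out$report$kept + Reduce(`+`, out$report$dropped),
               out$report$input)
  expect_equal(out$records$record_id, c("r01", "r04"))
})

test_that("a species absent from the altitude ranges is a hard error", {
  alt <- toy_grid(matrix(100, 2, 2), name = "Alt")
  recs <- make_recs("S. unknowniae", -74.91, -10.12)
  expect_error(clean_occurrences(recs, altitude_grid = alt,
                                 altitude_ranges = default_altitude_ranges()),
               "S. unknowniae")
})

test_that("cleaning is idempotent and its output order deterministic", {
  cfg <- small_config()
  occ <- synthetic_occurrences(cfg)
  land <- synthetic_landscape(cfg)
  once <- clean_occurrences(occ$records, altitude_grid = land$grids$Alt)
  twice <- clean_occurrences(once$records, altitude_grid = land$grids$Alt)
  expect_equal(twice$records, once$records)
  expect_equal(twice$report$kept, once$report$kept)
  expect_true(all(unlist(twice$report$dropped) == 0))
  expect_false(is.unsorted(once$records$species))
})

test_that("planted defect counts are recovered exactly by the cleaning report", {
  cfg <- small_config(seed = 11)
  occ <- synthetic_occurrences(cfg)
  land <- synthetic_landscape(cfg)
  out <- clean_occurrences(occ$records, altitude_grid = land$grids$Alt)
  expect_equal(out$report$dropped$duplicate, occ$ledger$duplicate)
  expect_equal(out$report$dropped$precision, occ$ledger$precision)
  expect_equal(out$report$dropped$altitude, occ$ledger$altitude)
  expect_equal(out$report$kept, occ$ledger$natural)
})

test_that("species-group map partitions the 16 taxa into six groups", {
  sg <- species_groups()
  expect_equal(nrow(sg), 16)
  expect_equal(anyDuplicated(sg$species), 0)
  expect_equal(sort(unique(sg$group_id)), 1:6)
  expect_equal(as.integer(table(sg$group_label)[c("Lycopersicon",
                                                  "Eriopersicon")]),
               c(3L, 5L))
  expect_setequal(default_altitude_ranges()$species, sg$species)
})
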