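# small in-code fixtures shared across test files

# flat-ish grid over a 1-degree window, optionally with nodata holes
toy_grid <- function(values = matrix(1:12, 3, 4), name = "toy",
                     kind = "continuous", west = -75, north = -10,
                     cell_size = 0.25) {
  raster_grid(values, west = west, north = north, cell_size = cell_size,
              name = name, kind = kind)
}

# write an occurrence CSV from a data.frame, returning its path
write_occ_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

# tiny synthetic study: fast enough for per-test use
small_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(seed = seed, cell_size = 0.1, n_per_species = 25,
         n_duplicates = 4, n_low_precision = 3, n_out_altitude = 3),
    list(...))
  do.call(synthetic_config, args)
}
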