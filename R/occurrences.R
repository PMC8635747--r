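#' Species-to-group classification of wild tomatoes and allied species
#'
#' The 16 taxa handled by the package and their six phylogenetic groups:
#' the Lycopersicon, Arcanum, Eriopersicon and Neolycopersicon groups of
#' *Solanum* sect. Lycopersicon, plus the allied sections Juglandifolia and
#' Lycopersicoides.
#'
#' @return A data.frame with columns `species`, `group_id` (1-6) and
#'   `group_label`.
#' @export
#' @examples
#' table(species_groups()$group_label)
species_groups <- function() {
  g <- list(
    list(1L, "Lycopersicon",
         c("S. pimpinellifolium", "S. cheesmaniae", "S. galapagense")),
    list(2L, "Arcanum",
         c("S. arcanum", "S. chmielewskii", "S. neorickii")),
    list(3L, "Eriopersicon",
         c("S. habrochaites", "S. huaylasense", "S. corneliomulleri",
           "S. peruvianum", "S. chilense")),
    list(4L, "Neolycopersicon", "S. pennellii"),
    list(5L, "Juglandifolia", c("S. juglandifolium", "S. ochranthum")),
    list(6L, "Lycopersicoides", c("S. lycopersicoides", "S. sitiens"))
  )
  do.call(rbind, lapply(g, function(x)
    data.frame(species = x[[3]], group_id = x[[1]], group_label = x[[2]],
               stringsAsFactors = FALSE)))
}

#' Default per-species altitude ranges (m)
#'
#' Elevational envelopes used by the "atypical data" cleaning rule: a record
#' whose grid altitude falls outside its species' range is treated as a
#' georeferencing error. The defaults span sea level to roughly 4,000 m, the
#' upper limit of the group's natural range, and are meant to be replaced
#' with curated values when available.
#'
#' @return data.frame with columns `species`, `min_alt`, `max_alt`.
#' @export
default_altitude_ranges <- function() {
  m <- rbind(
    c("S. cheesmaniae",      5, 1478), c("S. galapagense",       4,  868),
    c("S. pimpinellifolium", 1, 1774), c("S. arcanum",         132, 3292),
    c("S. chmielewskii",  1803, 3195), c("S. neorickii",      1202, 3262),
    c("S. huaylasense",    978, 3304), c("S. corneliomulleri", 1018, 3097),
    c("S. peruvianum",       2, 3191), c("S. chilense",          0, 3995),
    c("S. habrochaites",    40, 3692), c("S. pennellii",         5, 2921),
    c("S. juglandifolium", 1005, 3153), c("S. ochranthum",     1195, 4008),
    c("S. lycopersicoides", 1290, 3775), c("S. sitiens",       2276, 3330)
  )
  data.frame(species = m[, 1], min_alt = as.numeric(m[, 2]),
             max_alt = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

#' Read an occurrence table
#'
#' Reads a delimited text file of georeferenced accessions. Malformed rows
#' (unparseable or out-of-range coordinates, empty species) are collected
#' with their line numbers rather than silently dropped; a missing required
#' column is a hard error.
#'
#' @param path file path of the table (UTF-8).
#' @param sep field delimiter, default ",".
#' @param col_map named character vector mapping the roles `species`,
#'   `longitude`, `latitude` (required) and `record_id`, `source` (optional)
#'   to column names in the file.
#' @return A list with components `records` (data.frame: `record_id`,
#'   `species`, `longitude`, `latitude`, `source`, plus the verbatim
#'   coordinate text in `lon_text`/`lat_text`) and `errors` (data.frame:
#'   `line`, `message`), of class `"occurrence_set"`.
#' @export
read_occurrences <- function(path,
                             sep = ",",
                             col_map = c(species = "species",
                                         longitude = "longitude",
                                         latitude = "latitude")) {
  if (!file.exists(path)) stop_ecogeo("occurrence file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  mapped <- function(role)
    if (role %in% names(col_map)) col_map[[role]] else role
  for (role in c("species", "longitude", "latitude")) {
    if (!mapped(role) %in% names(raw))
      stop_ecogeo("required column '", mapped(role), "' (", role,
                  ") absent from ", path)
  }
  get_col <- function(role, default = NULL) {
    col <- mapped(role)
    if (col %in% names(raw)) raw[[col]] else default
  }
  n <- nrow(raw)
  sp <- trimws(get_col("species"))
  lon_text <- trimws(get_col("longitude"))
  lat_text <- trimws(get_col("latitude"))
  rid <- get_col("record_id", sprintf("rec%06d", seq_len(n)))
  src <- get_col("source", rep(NA_character_, n))

  lon <- suppressWarnings(as.numeric(lon_text))
  lat <- suppressWarnings(as.numeric(lat_text))

  msg <- rep(NA_character_, n)
  msg[is.na(lon)] <- "unparseable longitude"
  msg[is.na(lat) & is.na(msg)] <- "unparseable latitude"
  msg[is.na(msg) & (lon < -180 | lon > 180)] <- "longitude outside [-180, 180]"
  msg[is.na(msg) & (lat < -90 | lat > 90)] <- "latitude outside [-90, 90]"
  msg[is.na(msg) & sp == ""] <- "empty species"

  bad <- !is.na(msg)
  errors <- data.frame(line = which(bad) + 1L,  # +1 for the header line
                       message = msg[bad], stringsAsFactors = FALSE)
  records <- data.frame(record_id = rid[!bad], species = sp[!bad],
                        longitude = lon[!bad], latitude = lat[!bad],
                        source = src[!bad], lon_text = lon_text[!bad],
                        lat_text = lat_text[!bad], stringsAsFactors = FALSE)
  structure(list(records = records, errors = errors), class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat("Occurrence set:", nrow(x$records), "records,",
      nrow(x$errors), "malformed rows\n")
  invisible(x)
}

coord_key <- function(records) {
  lon <- ifelse(is.na(records$lon_text) | records$lon_text == "",
                coord_text(records$longitude), trimws(records$lon_text))
  lat <- ifelse(is.na(records$lat_text) | records$lat_text == "",
                coord_text(records$latitude), trimws(records$lat_text))
  paste(records$species, lon, lat, sep = "|")
}

#' Clean an occurrence table
#'
#' Applies the cleaning rules used to reduce a raw accession database to the
#' curated set, in a fixed order: exact duplicates (same species and the same
#' string-normalized coordinate pair) are reduced to one; records whose
#' coordinates carry fewer than `min_decimals` decimal digits are dropped as
#' imprecise; records falling on nodata cells (or outside the extent) of the
#' altitude grid are dropped; records whose grid altitude falls outside their
#' species' configured range are dropped as atypical.
#'
#' @param records data.frame as returned in `read_occurrences()$records`
#'   (or an `occurrence_set`).
#' @param altitude_grid a [raster_grid] of elevation (m), or `NULL` to skip
#'   the nodata and altitude rules.
#' @param altitude_ranges data.frame (`species`, `min_alt`, `max_alt`);
#'   must cover every species present when the altitude rule runs. Defaults
#'   to [default_altitude_ranges()].
#' @param min_decimals minimum decimal digits on both coordinates
#'   (default 2, about 1.1 km at the equator, matching a ~900 m layer
#'   resolution).
#' @return list of class `"cleaning_result"`: `records` (kept rows, sorted
#'   by species then record_id) and `report` (class `"cleaning_report"`:
#'   `input`, `kept` and per-rule `dropped` counts, which always reconcile).
#' @export
clean_occurrences <- function(records,
                              altitude_grid = NULL,
                              altitude_ranges = default_altitude_ranges(),
                              min_decimals = 2) {
  if (inherits(records, "occurrence_set")) records <- records$records
  stopifnot(is.data.frame(records), min_decimals >= 0)
  if (!"lon_text" %in% names(records))
    records$lon_text <- coord_text(records$longitude)
  if (!"lat_text" %in% names(records))
    records$lat_text <- coord_text(records$latitude)
  n_in <- nrow(records)
  dropped <- c(duplicate = 0L, precision = 0L, nodata = 0L, altitude = 0L)

  # 1. duplicates
  dup <- duplicated(coord_key(records))
  dropped["duplicate"] <- sum(dup)
  records <- records[!dup, , drop = FALSE]

  # 2. precision
  ok <- n_decimals(records$lon_text) >= min_decimals &
        n_decimals(records$lat_text) >= min_decimals
  dropped["precision"] <- sum(!ok)
  records <- records[ok, , drop = FALSE]

  if (!is.null(altitude_grid)) {
    alt <- extract_at_points(altitude_grid,
                             cbind(records$longitude, records$latitude))
    # 3. nodata / off-grid
    miss <- is.na(alt)
    dropped["nodata"] <- sum(miss)
    records <- records[!miss, , drop = FALSE]
    alt <- alt[!miss]

    # 4. altitude range
    absent <- setdiff(unique(records$species), altitude_ranges$species)
    if (length(absent))
      stop_ecogeo("species missing from altitude_ranges: ",
                  paste(absent, collapse = ", "))
    i <- match(records$species, altitude_ranges$species)
    out <- alt < altitude_ranges$min_alt[i] | alt > altitude_ranges$max_alt[i]
    dropped["altitude"] <- sum(out)
    records <- records[!out, , drop = FALSE]
  }

  records <- records[order(records$species, records$record_id), , drop = FALSE]
  rownames(records) <- NULL
  report <- structure(list(input = n_in, kept = nrow(records),
                           dropped = as.list(dropped)),
                      class = "cleaning_report")
  structure(list(records = records, report = report),
            class = "cleaning_result")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:", x$input, "in,", x$kept, "kept\n")
  for (r in names(x$dropped))
    cat(sprintf("  dropped (%s): %d\n", r, x$dropped[[r]]))
  invisible(x)
}

#' Write cleaned occurrences and the cleaning report
#'
#' @param result a `"cleaning_result"` from [clean_occurrences()].
#' @param csv_path,report_path output paths (CSV and JSON).
#' @return invisibly, the CSV path.
#' @export
write_cleaning_result <- function(result, csv_path, report_path) {
  rec <- result$records[, c("record_id", "species", "longitude", "latitude",
                            "source")]
  utils::write.csv(rec, csv_path, row.names = FALSE, quote = TRUE)
  write_json_report(unclass(result$report), report_path)
  invisible(csv_path)
}
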