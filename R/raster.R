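#' Construct a georeferenced regular grid
#'
#' A minimal in-memory raster: a rectangular grid of cells in WGS84 decimal
#' degrees, continuous or categorical, with a nodata convention. Cell (1,1)
#' is the northwest cell; rows increase southward, columns eastward.
#'
#' @param values numeric matrix, row 1 = northernmost row; `NA` marks nodata.
#' @param west,north longitude/latitude of the grid's outer northwest corner.
#' @param cell_size cell edge in decimal degrees (> 0); cells are square.
#' @param name variable code (e.g., "Bio12", "ET", "Alt", "BD", "pH").
#' @param kind `"continuous"` or `"categorical"` (integer class codes).
#' @param nodata sentinel written to file for `NA` cells.
#' @return object of class `"raster_grid"`.
#' @export
raster_grid <- function(values, west, north, cell_size,
                        name = "layer", kind = c("continuous", "categorical"),
                        nodata = -9999) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0,
            is.numeric(west), is.numeric(north))
  storage.mode(values) <- "double"
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop_ecogeo("categorical grid '", name, "' contains non-integer codes")
  }
  structure(list(name = name, kind = kind, west = west, north = north,
                 cell_size = cell_size, n_rows = nrow(values),
                 n_cols = ncol(values), nodata = nodata, values = values),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster_grid '%s' (%s): %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$name, x$kind, x$n_rows, x$n_cols, x$cell_size, x$west, x$north))
  invisible(x)
}

#' Read / write a grid in ESRI ASCII format
#'
#' `write_grid()` writes the standard 6-line `.asc` header
#' (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`) followed by
#' row-major values, northern row first, at full double precision so that a
#' write-read round trip is bit-exact. `read_grid()` auto-detects the format
#' from the extension; only the ASCII dialect is supported (no GDAL-backed
#' reader is bundled), so `.tif` inputs are rejected with a clear error.
#'
#' @param path file path; extension `.asc` (case-insensitive).
#' @param grid a [raster_grid].
#' @param name,kind metadata for the grid being read (the `.asc` format
#'   stores neither).
#' @return `read_grid()` a [raster_grid]; `write_grid()` the path, invisibly.
#' @export
read_grid <- function(path, name = NULL,
                      kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    stop_ecogeo("GeoTIFF input is not supported (no GDAL reader available); ",
                "convert to ESRI ASCII grid (.asc)")
  if (ext != "asc") stop_ecogeo("unknown raster format: .", ext)
  if (!file.exists(path)) stop_ecogeo("raster file not found: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]+$", tok[1])) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop_ecogeo("malformed .asc header in ", path, " (need ",
                paste(need, collapse = "/"), ")")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) {
    west <- hdr$xllcorner
  } else if (!is.null(hdr$xllcenter)) {
    west <- hdr$xllcenter - cs / 2
  } else stop_ecogeo("missing xllcorner/xllcenter in ", path)
  if (!is.null(hdr$yllcorner)) {
    yll <- hdr$yllcorner
  } else if (!is.null(hdr$yllcenter)) {
    yll <- hdr$yllcenter - cs / 2
  } else stop_ecogeo("missing yllcorner/yllcenter in ", path)
  vals <- scan(con, what = double(), quiet = TRUE)
  if (length(vals) != nr * nc)
    stop_ecogeo("inconsistent .asc payload in ", path, ": expected ",
                nr * nc, " values, found ", length(vals))
  nodata <- hdr$nodata_value %||% -9999
  vals[vals == nodata] <- NA_real_
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  raster_grid(m, west = west, north = yll + nr * cs, cell_size = cs,
              name = name %||% tools::file_path_sans_ext(basename(path)),
              kind = kind, nodata = nodata)
}

#' @rdname read_grid
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    stop_ecogeo("GeoTIFF output is not supported; use .asc")
  if (ext != "asc") stop_ecogeo("unknown raster format: .", ext)
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  # %.17g round-trips IEEE doubles exactly through text
  body <- apply(v, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.17g", grid$west),
           sprintf("yllcorner %.17g", grid$north - grid$n_rows * grid$cell_size),
           sprintf("cellsize %.17g", grid$cell_size),
           sprintf("NODATA_value %.17g", grid$nodata))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Sample grid values at points
#'
#' Point-in-pixel extraction with no interpolation: each point takes the
#' value of the cell containing it under half-open intervals
#' `[west, west + cell_size)` in longitude and `(north - cell_size, north]`
#' in latitude. Points outside the extent or on nodata cells yield `NA`
#' (missing is a value, not an error).
#'
#' @param grid a [raster_grid].
#' @param points two-column matrix or data.frame of (longitude, latitude)
#'   in WGS84 decimal degrees.
#' @return numeric vector, one value or `NA` per point.
#' @export
extract_at_points <- function(grid, points) {
  stopifnot(inherits(grid, "raster_grid"))
  points <- as.matrix(points)
  if (ncol(points) < 2) stop_ecogeo("points must have (lon, lat) columns")
  lon <- as.numeric(points[, 1]); lat <- as.numeric(points[, 2])
  cs <- grid$cell_size
  col <- floor((lon - grid$west) / cs) + 1
  row <- floor((grid$north - lat) / cs) + 1
  row[lat == grid$north] <- 1          # top edge belongs to the first row
  inside <- !is.na(lon) & !is.na(lat) &
    col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_real_, length(lon))
  out[inside] <- grid$values[cbind(row[inside], col[inside])]
  out
}

#' Assemble the accessions-by-variables environmental matrix
#'
#' Extracts every grid at every record's coordinates and assembles the
#' environmental matrix, one column per grid. Rows with any missing value
#' are excluded from the returned matrix (complete-case policy for the
#' downstream statistics) and reported.
#'
#' @param records data.frame with `record_id`, `species`, `longitude`,
#'   `latitude` (e.g., cleaned occurrences).
#' @param grids list of [raster_grid] objects with unique names.
#' @return list of class `"env_matrix"`: `env` (data.frame `record_id`,
#'   `species`, then one numeric column per grid; complete rows only) and
#'   `dropped` (data.frame `record_id`, `missing_in`).
#' @export
build_env_matrix <- function(records, grids) {
  nms <- vapply(grids, function(g) g$name, character(1))
  if (anyDuplicated(nms))
    stop_ecogeo("duplicate grid name: ", nms[duplicated(nms)][1])
  pts <- cbind(records$longitude, records$latitude)
  vals <- vapply(grids, function(g) extract_at_points(g, pts),
                 numeric(nrow(records)))
  if (nrow(records) == 1) vals <- matrix(vals, nrow = 1)
  colnames(vals) <- nms
  miss <- is.na(vals)
  bad <- rowSums(miss) > 0
  dropped <- data.frame(
    record_id = records$record_id[bad],
    missing_in = apply(miss[bad, , drop = FALSE], 1,
                       function(m) paste(nms[m], collapse = ";")),
    stringsAsFactors = FALSE)
  env <- cbind(data.frame(record_id = records$record_id[!bad],
                          species = records$species[!bad],
                          stringsAsFactors = FALSE),
               as.data.frame(vals[!bad, , drop = FALSE]))
  rownames(env) <- NULL
  structure(list(env = env, dropped = dropped), class = "env_matrix")
}

#' @export
print.env_matrix <- function(x, ...) {
  cat("env_matrix:", nrow(x$env), "complete rows x",
      ncol(x$env) - 2, "variables;", nrow(x$dropped), "rows dropped\n")
  invisible(x)
}
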