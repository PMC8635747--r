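# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count decimal digits of a coordinate as written
#'
#' Counts the digits after the decimal separator in the textual form of a
#' coordinate, the quantity used by the geographic-precision filter. Trailing
#' zeros count ("12.50" has 2 decimals); scientific notation is expanded
#' first; a bare integer has 0.
#'
#' @param x character or numeric vector.
#' @return integer vector of decimal counts.
#' @keywords internal
n_decimals <- function(x) {
  if (is.numeric(x)) x <- coord_text(x)
  x <- trimws(x)
  has_dot <- grepl(".", x, fixed = TRUE)
  out <- integer(length(x))
  out[has_dot] <- nchar(sub("^[^.]*\\.", "", x[has_dot]))
  out
}

# per-element shortest decimal text of a coordinate (vectorized format()
# would pad trailing zeros to a common width and distort decimal counts)
coord_text <- function(x) {
  vapply(x, function(v) format(v, scientific = FALSE, trim = TRUE,
                               digits = 15), character(1))
}

stop_ecogeo <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == round(x)

# deterministic JSON writer used for reports/manifests (no timestamps)
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
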