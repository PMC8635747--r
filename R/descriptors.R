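#' Sample quartiles
#'
#' First quartile, median and third quartile using linear interpolation at
#' positions `0.25/0.5/0.75 * (n - 1)` of the sorted sample (the classic
#' type-7 estimator); other standard sample-quantile types can be selected.
#'
#' @param values numeric vector, at least one finite value.
#' @param type sample-quantile type passed to [stats::quantile()]
#'   (default 7 = linear interpolation).
#' @return named numeric vector `c(q1, median, q3)`.
#' @export
#' @examples
#' quartiles(c(1, 2, 3, 4, 5))  # 2, 3, 4
quartiles <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_ecogeo("empty input to quartiles()")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

#' Per-species ecological descriptors
#'
#' For every species-by-variable cell, summarizes the environmental values
#' at that species' occurrence sites: n, extremes, quartiles, the half
#' interquartile range `Q = (Q3 - Q1) / 2`, and the quartile coefficient of
#' variation `CV = (Q / Med) * 100`. A zero median makes CV undefined; it
#' is then reported as 0 with `zero_median = TRUE`, mirroring the printed
#' convention for variables such as the precipitation of the driest month
#' in desert-adapted species. A negative median uses `|Med|` so CV stays
#' nonnegative.
#'
#' @param env an `"env_matrix"` (with its `species` column) or a data.frame
#'   containing `species` plus numeric variable columns.
#' @param variables variable codes to summarize (default: all numeric
#'   columns).
#' @param type sample-quantile type (see [quartiles()]); recorded in the
#'   result's `"quantile_type"` attribute.
#' @return data.frame (one row per species x variable) with columns
#'   `species`, `variable`, `n`, `min`, `q1`, `median`, `q3`, `max`, `q_half`,
#'   `cv`, `zero_median`. Species-variable cells with no usable rows are
#'   omitted with a warning.
#' @export
descriptor_table <- function(env, variables = NULL, type = 7) {
  if (inherits(env, "env_matrix")) env <- env$env
  stopifnot(is.data.frame(env), "species" %in% names(env))
  if (is.null(variables))
    variables <- setdiff(names(env)[vapply(env, is.numeric, logical(1))],
                         c("longitude", "latitude"))
  missing_vars <- setdiff(variables, names(env))
  if (length(missing_vars))
    stop_ecogeo("variables not in env: ", paste(missing_vars, collapse = ", "))
  out <- list()
  omitted <- character()
  for (sp in sort(unique(env$species))) {
    sub <- env[env$species == sp, , drop = FALSE]
    for (v in variables) {
      x <- sub[[v]][!is.na(sub[[v]])]
      if (!length(x)) {
        omitted <- c(omitted, paste0(sp, "/", v))
        next
      }
      q <- quartiles(x, type = type)
      qh <- (q[["q3"]] - q[["q1"]]) / 2
      zm <- q[["median"]] == 0
      cv <- if (zm) 0 else (qh / abs(q[["median"]])) * 100
      out[[length(out) + 1L]] <- data.frame(
        species = sp, variable = v, n = length(x),
        min = min(x), q1 = q[["q1"]], median = q[["median"]],
        q3 = q[["q3"]], max = max(x), q_half = qh, cv = cv,
        zero_median = zm, stringsAsFactors = FALSE)
    }
  }
  if (length(omitted))
    warning("species/variable cells with no usable rows omitted: ",
            paste(omitted, collapse = ", "))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "quantile_type") <- type
  res
}

#' Report-shaped descriptor table
#'
#' Reshapes the long descriptor table into the familiar publication layout:
#' one row per species, and per variable two text fields, the range
#' `"min-max"` and `"median (cv)"`.
#'
#' @param tab result of [descriptor_table()].
#' @return wide data.frame with columns `species` then
#'   `<variable>_range` and `<variable>_med_cv`.
#' @export
descriptor_report <- function(tab) {
  fmt <- function(x) trimws(formatC(x, format = "g", digits = 4))
  sp <- sort(unique(tab$species))
  vars <- unique(tab$variable)
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (v in vars) {
    sub <- tab[tab$variable == v, ]
    i <- match(sp, sub$species)
    out[[paste0(v, "_range")]] <-
      ifelse(is.na(i), NA, paste0(fmt(sub$min[i]), "-", fmt(sub$max[i])))
    out[[paste0(v, "_med_cv")]] <-
      ifelse(is.na(i), NA,
             paste0(fmt(sub$median[i]), " (", fmt(sub$cv[i]), ")"))
  }
  out
}
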