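#' Class vocabularies for categorical environmental layers
#'
#' `koppen_labels()` returns the 30 Köppen-Geiger climate-type codes with
#' short descriptions; `soil_unit_labels()` the 28 FAO/HWSD soil-unit codes.
#' These are the column vocabularies of the edaphoclimatic diversity tables;
#' synthetic layers may use any subset.
#'
#' @return named character vector, names = class codes.
#' @export
koppen_labels <- function() {
  c(Af = "tropical, rainforest", Am = "tropical, monsoon",
    Aw = "tropical, savannah", BWh = "arid, desert, hot",
    BWk = "arid, desert, cold", BSh = "arid, steppe, hot",
    BSk = "arid, steppe, cold", Csa = "temperate, dry summer, hot summer",
    Csb = "temperate, dry summer, warm summer",
    Csc = "temperate, dry summer, cold summer",
    Cwa = "temperate, dry winter, hot summer",
    Cwb = "temperate, dry winter, warm summer",
    Cwc = "temperate, dry winter, cold summer",
    Cfa = "temperate, no dry season, hot summer",
    Cfb = "temperate, no dry season, warm summer",
    Cfc = "temperate, no dry season, cold summer",
    Dsa = "cold, dry summer, hot summer",
    Dsb = "cold, dry summer, warm summer",
    Dsc = "cold, dry summer, cold summer",
    Dsd = "cold, dry summer, very cold winter",
    Dwa = "cold, dry winter, hot summer",
    Dwb = "cold, dry winter, warm summer",
    Dwc = "cold, dry winter, cold summer",
    Dwd = "cold, dry winter, very cold winter",
    Dfa = "cold, no dry season, hot summer",
    Dfb = "cold, no dry season, warm summer",
    Dfc = "cold, no dry season, cold summer",
    Dfd = "cold, no dry season, very cold winter",
    ET = "polar, tundra", EF = "polar, frost")
}

#' @rdname koppen_labels
#' @export
soil_unit_labels <- function() {
  c(AC = "Acrisol", AL = "Alisol", AN = "Andosol", AR = "Arenosol",
    AT = "Anthrosol", CH = "Chernozem", CL = "Calcisol", CM = "Cambisol",
    FL = "Fluvisol", FR = "Ferralsol", GL = "Gleysol", GR = "Greysem",
    GY = "Gypsisol", HS = "Histosol", KS = "Kastanozem", LP = "Leptosol",
    LV = "Luvisol", LX = "Lixisol", NT = "Nitisol", PD = "Podzoluvisol",
    PH = "Phaezem", PL = "Planosol", PT = "Plinthosol", PZ = "Podzol",
    RG = "Regosol", SC = "Solonchak", SN = "Solonetz", VR = "Vertisol")
}

#' Frequency table of categorical environmental classes
#'
#' Assigns each record the class of its containing cell in a categorical
#' grid (Köppen climate type or soil unit) and tabulates counts and
#' within-row percentages per species or per phylogenetic group, plus the
#' per-row class richness. Records on nodata cells are excluded and counted
#' separately. Integer codes not present in the dictionary are tolerated and
#' labeled `UNKNOWN_<code>` with a warning.
#'
#' @param records data.frame with `species`, `longitude`, `latitude`.
#' @param grid categorical [raster_grid].
#' @param by `"species"` or `"group"` (via [species_groups()]).
#' @param codes named character vector mapping integer cell codes (names)
#'   to class codes, e.g. `c("1" = "Af", "2" = "BWk")`.
#' @param group_map species-to-group table used when `by = "group"`.
#' @return object of class `"diversity_table"`: `kind` (the grid name),
#'   `by`, `counts` (rows x classes matrix), `percentages` (within-row,
#'   summing to 100), `richness`, and `excluded_nodata` per row.
#' @export
class_frequencies <- function(records, grid, by = c("species", "group"),
                              codes, group_map = species_groups()) {
  by <- match.arg(by)
  stopifnot(inherits(grid, "raster_grid"))
  if (grid$kind != "categorical")
    stop_ecogeo("grid '", grid$name, "' is not categorical")
  vals <- extract_at_points(grid, cbind(records$longitude, records$latitude))
  row_key <- if (by == "species") records$species else {
    i <- match(records$species, group_map$species)
    if (anyNA(i))
      stop_ecogeo("species not in group map: ",
                  paste(unique(records$species[is.na(i)]), collapse = ", "))
    group_map$group_label[i]
  }
  nodata <- is.na(vals)
  excluded <- tapply(nodata, row_key, sum)
  row_key2 <- row_key[!nodata]
  code_chr <- as.character(as.integer(vals[!nodata]))
  lab <- unname(codes[code_chr])
  unk <- is.na(lab)
  if (any(unk)) {
    warning("class codes absent from dictionary: ",
            paste(unique(code_chr[unk]), collapse = ", "))
    lab[unk] <- paste0("UNKNOWN_", code_chr[unk])
  }
  class_levels <- c(intersect(unname(codes), unique(lab)),
                    sort(unique(lab[startsWith(lab, "UNKNOWN_")])))
  counts <- table(factor(row_key2, levels = sort(unique(row_key))),
                  factor(lab, levels = class_levels))
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  tot <- rowSums(counts)
  pct <- counts / ifelse(tot == 0, 1, tot) * 100
  structure(list(kind = grid$name, by = by, counts = counts,
                 percentages = pct, richness = rowSums(counts > 0),
                 excluded_nodata = as.integer(excluded[rownames(counts)])),
            class = "diversity_table")
}

#' Per-row class richness
#'
#' Number of classes observed (count > 0) in each row of a diversity table.
#'
#' @param table a `"diversity_table"` (or a counts matrix).
#' @return named integer vector of richness per row.
#' @export
richness <- function(table) {
  counts <- if (inherits(table, "diversity_table")) table$counts else table
  rowSums(counts > 0)
}

#' @export
print.diversity_table <- function(x, ...) {
  cat(sprintf("Diversity table '%s' by %s: %d rows x %d classes, total richness %d\n",
              x$kind, x$by, nrow(x$counts), ncol(x$counts),
              sum(colSums(x$counts) > 0)))
  invisible(x)
}

#' Aggregate a species-level diversity table to groups
#'
#' @param table species-level `"diversity_table"`.
#' @param group_map species-to-group table (see [species_groups()]).
#' @return group-level `"diversity_table"`.
#' @export
aggregate_to_groups <- function(table, group_map = species_groups()) {
  stopifnot(inherits(table, "diversity_table"), table$by == "species")
  i <- match(rownames(table$counts), group_map$species)
  if (anyNA(i))
    stop_ecogeo("species not in group map: ",
                paste(rownames(table$counts)[is.na(i)], collapse = ", "))
  g <- group_map$group_label[i]
  counts <- rowsum(table$counts, g)
  tot <- rowSums(counts)
  structure(list(kind = table$kind, by = "group", counts = counts,
                 percentages = counts / ifelse(tot == 0, 1, tot) * 100,
                 richness = rowSums(counts > 0),
                 excluded_nodata = as.integer(
                   rowsum(table$excluded_nodata, g))),
            class = "diversity_table")
}
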