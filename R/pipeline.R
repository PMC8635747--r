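#' Pipeline configuration
#'
#' Assembles all parameters of the full analysis: paths, the collinearity
#' threshold (0.90), the quartile estimator, the 1-km density bin and the
#' Gi* band distance (50 km), significance thresholds, and the synthetic
#' study design (when the pipeline simulates its own inputs). Categorical
#' vocabularies default to the 12 Köppen climate types and 17 FAO soil
#' units typically observed in the wild-tomato range, with geometric
#' planted proportions.
#'
#' @param out_dir output directory; all stage artifacts live here.
#' @param seed integer seed for the synthetic stage.
#' @param threshold collinearity cutoff on |r|.
#' @param min_decimals coordinate precision floor for cleaning.
#' @param quartile_type sample-quantile type for descriptors.
#' @param bin_km,band_km hotspot bin size and Gi* band distance (km).
#' @param hotspot_value `"count"` or `"richness"`.
#' @param screen_rule `"conserve_hub"` or `"drop_hub"`.
#' @param synthetic a [synthetic_config()] (its seed is forced to `seed`).
#' @param climate_codes,soil_codes class codes for the categorical layers.
#' @param climate_props,soil_props planted class proportions.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1,
                            threshold = 0.90,
                            min_decimals = 2,
                            quartile_type = 7,
                            bin_km = 1.0,
                            band_km = 50,
                            hotspot_value = c("count", "richness"),
                            screen_rule = c("conserve_hub", "drop_hub"),
                            synthetic = synthetic_config(seed = seed),
                            climate_codes = c("Af", "Am", "Aw", "BWh", "BWk",
                                              "BSh", "BSk", "Csb", "Cwb",
                                              "Cwc", "Cfb", "ET"),
                            soil_codes = c("AC", "AN", "AR", "CH", "CM", "FL",
                                           "GL", "HS", "KS", "LP", "LV", "PH",
                                           "PL", "RG", "SC", "SN", "VR"),
                            climate_props = NULL,
                            soil_props = NULL) {
  geometric_props <- function(k, ratio) {
    p <- ratio^(seq_len(k) - 1)
    p / sum(p)
  }
  synthetic$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 threshold = threshold, min_decimals = min_decimals,
                 quartile_type = quartile_type, bin_km = bin_km,
                 band_km = band_km,
                 hotspot_value = match.arg(hotspot_value),
                 screen_rule = match.arg(screen_rule),
                 synthetic = synthetic,
                 climate_codes = climate_codes, soil_codes = soil_codes,
                 climate_props = climate_props %||%
                   geometric_props(length(climate_codes), 0.8),
                 soil_props = soil_props %||%
                   geometric_props(length(soil_codes), 0.85)),
            class = "pipeline_config")
}

path_in <- function(config, ...) file.path(config$out_dir, ...)

require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop_ecogeo("[", stage, "] missing input artifact: ", path,
                " (run the producing stage first)")
  path
}

read_env_csv <- function(path, stage) {
  env <- utils::read.csv(require_artifact(path, stage), check.names = FALSE,
                         stringsAsFactors = FALSE)
  structure(list(env = env,
                 dropped = data.frame(record_id = character(),
                                      missing_in = character())),
            class = "env_matrix")
}

stage_simulate <- function(config) {
  dir.create(path_in(config, "rasters"), recursive = TRUE,
             showWarnings = FALSE)
  land <- synthetic_landscape(config$synthetic)
  for (g in land$grids)
    write_grid(g, path_in(config, "rasters", paste0(g$name, ".asc")))
  kop <- categorical_layer(config$synthetic, config$climate_props,
                           name = "koppen", seed_offset = 1L)
  soi <- categorical_layer(config$synthetic, config$soil_props,
                           name = "soil_units", seed_offset = 2L)
  write_grid(kop, path_in(config, "rasters", "koppen.asc"))
  write_grid(soi, path_in(config, "rasters", "soil_units.asc"))
  occ <- synthetic_occurrences(config$synthetic)
  utils::write.csv(occ$records, path_in(config, "occurrences.csv"),
                   row.names = FALSE)
  write_json_report(
    list(planted_r = land$truth$planted_r,
         cleaning = occ$ledger,
         climate_props = config$climate_props,
         climate_codes = config$climate_codes,
         soil_props = config$soil_props,
         soil_codes = config$soil_codes),
    path_in(config, "truth.json"))
  c(records = nrow(occ$records),
    rasters = length(land$grids) + 2L)
}

stage_clean <- function(config) {
  occ <- read_occurrences(require_artifact(path_in(config, "occurrences.csv"),
                                           "clean"))
  alt <- read_grid(require_artifact(path_in(config, "rasters", "Alt.asc"),
                                    "clean"), name = "Alt")
  res <- clean_occurrences(occ, altitude_grid = alt,
                           min_decimals = config$min_decimals)
  write_cleaning_result(res, path_in(config, "cleaned.csv"),
                        path_in(config, "cleaning_report.json"))
  c(input = res$report$input, kept = res$report$kept)
}

stage_extract <- function(config) {
  rec <- utils::read.csv(require_artifact(path_in(config, "cleaned.csv"),
                                          "extract"),
                         stringsAsFactors = FALSE)
  rdir <- path_in(config, "rasters")
  if (!dir.exists(rdir)) stop_ecogeo("[extract] missing rasters directory: ",
                                     rdir)
  vars <- c(config$synthetic$climate_vars, config$synthetic$soil_vars)
  grids <- lapply(vars, function(v)
    read_grid(require_artifact(file.path(rdir, paste0(v, ".asc")), "extract"),
              name = v))
  em <- build_env_matrix(rec, grids)
  utils::write.csv(em$env, path_in(config, "env_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(em$dropped, path_in(config, "extract_dropped.csv"),
                   row.names = FALSE)
  c(rows = nrow(em$env), dropped = nrow(em$dropped))
}

stage_screen <- function(config) {
  em <- read_env_csv(path_in(config, "env_matrix.csv"), "screen")
  R <- pearson_matrix(em)
  scr <- screen_collinear(R, threshold = config$threshold,
                          rule = config$screen_rule)
  utils::write.csv(R, path_in(config, "correlation_matrix.csv"))
  utils::write.csv(scr$log, path_in(config, "screen_log.csv"),
                   row.names = FALSE)
  writeLines(scr$retained, path_in(config, "retained.txt"))
  c(retained = length(scr$retained), eliminated = length(scr$eliminated))
}

stage_cca <- function(config) {
  em <- read_env_csv(path_in(config, "env_matrix.csv"), "cca")
  retained <- readLines(require_artifact(path_in(config, "retained.txt"),
                                         "cca"))
  xv <- intersect(config$synthetic$climate_vars, retained)
  yv <- intersect(config$synthetic$soil_vars, retained)
  if (length(xv) < 2 || length(yv) < 2)
    stop_ecogeo("[cca] fewer than 2 retained variables in a block")
  fit <- fit_cca(em$env[, xv, drop = FALSE], em$env[, yv, drop = FALSE])
  utils::write.csv(
    data.frame(k = seq_along(fit$cor), cor = fit$cor,
               eigenvalue = fit$eigenvalues, proportion_pct = fit$proportions,
               wilks = fit$tests$lambda, chisq = fit$tests$chisq,
               df = fit$tests$df, p_value = fit$tests$p_value),
    path_in(config, "cca_summary.csv"), row.names = FALSE)
  utils::write.csv(fit$xload, path_in(config, "cca_climate_loadings.csv"))
  utils::write.csv(fit$yload, path_in(config, "cca_soil_loadings.csv"))
  utils::write.csv(fit$xcross, path_in(config, "cca_climate_cross.csv"))
  utils::write.csv(fit$ycross, path_in(config, "cca_soil_cross.csv"))
  utils::write.csv(fit$xcoef, path_in(config, "cca_climate_coef.csv"))
  utils::write.csv(fit$ycoef, path_in(config, "cca_soil_coef.csv"))
  utils::write.csv(
    cbind(data.frame(record_id = em$env$record_id,
                     species = em$env$species),
          fit$scores_x, fit$scores_y),
    path_in(config, "cca_scores.csv"), row.names = FALSE)
  c(pairs = length(fit$cor))
}

stage_descriptors <- function(config) {
  em <- read_env_csv(path_in(config, "env_matrix.csv"), "descriptors")
  retained <- readLines(require_artifact(path_in(config, "retained.txt"),
                                         "descriptors"))
  tab <- descriptor_table(em, variables = retained,
                          type = config$quartile_type)
  utils::write.csv(tab, path_in(config, "descriptors.csv"), row.names = FALSE)
  utils::write.csv(descriptor_report(tab),
                   path_in(config, "descriptors_wide.csv"), row.names = FALSE)
  c(cells = nrow(tab))
}

stage_diversity <- function(config) {
  rec <- utils::read.csv(require_artifact(path_in(config, "cleaned.csv"),
                                          "diversity"),
                         stringsAsFactors = FALSE)
  out <- c()
  for (kind in c("climate", "soil")) {
    grid_file <- if (kind == "climate") "koppen.asc" else "soil_units.asc"
    codes <- if (kind == "climate") config$climate_codes else
      config$soil_codes
    grid <- read_grid(require_artifact(path_in(config, "rasters", grid_file),
                                       "diversity"),
                      kind = "categorical")
    dict <- stats::setNames(codes, seq_along(codes))
    sp_tab <- class_frequencies(rec, grid, by = "species", codes = dict)
    gr_tab <- aggregate_to_groups(sp_tab)
    for (tab in list(sp_tab, gr_tab)) {
      stem <- paste0("diversity_", kind, "_", tab$by)
      utils::write.csv(tab$counts, path_in(config, paste0(stem,
                                                          "_counts.csv")))
      utils::write.csv(round(tab$percentages, 6),
                       path_in(config, paste0(stem, "_pct.csv")))
    }
    utils::write.csv(
      data.frame(row = rownames(sp_tab$counts), richness = sp_tab$richness),
      path_in(config, paste0("diversity_", kind, "_richness.csv")),
      row.names = FALSE)
    out[paste0(kind, "_classes")] <- sum(colSums(sp_tab$counts) > 0)
  }
  out
}

stage_hotspot <- function(config) {
  rec <- utils::read.csv(require_artifact(path_in(config, "cleaned.csv"),
                                          "hotspot"),
                         stringsAsFactors = FALSE)
  bins <- bin_points(rec, bin_km = config$bin_km)
  cells <- gi_star(bins, band_km = config$band_km,
                   value = config$hotspot_value)
  utils::write.csv(as.data.frame(cells), path_in(config, "hotspots.csv"),
                   row.names = FALSE)
  write_hotspots_geojson(cells, path_in(config, "hotspots.geojson"))
  c(bins = nrow(cells),
    hot99 = sum(cells$class == "hot99"),
    cold99 = sum(cells$class == "cold99"))
}

pipeline_stages <- function() {
  list(simulate = stage_simulate, clean = stage_clean,
       extract = stage_extract, screen = stage_screen, cca = stage_cca,
       descriptors = stage_descriptors, diversity = stage_diversity,
       hotspot = stage_hotspot)
}

#' Run the ecogeographic characterization pipeline
#'
#' Executes the requested stages in their fixed order
#' (simulate, clean, extract, screen, cca, descriptors, diversity,
#' hotspot). Stages communicate only through files in `config$out_dir`, so
#' any stage can be re-run independently from prior artifacts. A manifest
#' (package version, seed, configuration, per-stage counts, artifact
#' checksums — no timestamps, so identical runs are byte-identical) is
#' written at the end.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stage names (default: all).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, stages = names(pipeline_stages())) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- pipeline_stages()
  unknown <- setdiff(stages, names(all_stages))
  if (length(unknown)) stop_ecogeo("unknown stage: ",
                                   paste(unknown, collapse = ", "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  for (s in intersect(names(all_stages), stages)) {
    res <- tryCatch(all_stages[[s]](config), error = function(e)
      stop_ecogeo("stage '", s, "' failed: ", conditionMessage(e)))
    counts[[s]] <- as.list(res)
    message(sprintf("[%s] %s", s,
                    paste(names(res), res, sep = "=", collapse = " ")))
  }
  arts <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                       "manifest.json"))
  manifest <- list(
    package = "ecogeo",
    version = as.character(utils::packageVersion("ecogeo")),
    seed = config$seed,
    config = config_for_manifest(config),
    stage_counts = counts,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(config$out_dir, arts))), arts)))
  write_json_report(manifest, path_in(config, "manifest.json"))
  invisible(manifest)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  cfg$synthetic <- unclass(cfg$synthetic)
  cfg$synthetic$extent <- as.list(cfg$synthetic$extent)
  cfg
}
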