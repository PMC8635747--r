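#' Configuration for the synthetic study system
#'
#' Bundles every knob of the synthetic-data generator: the study window (a
#' 10 x 10 degree block of western South America, 200 x 200 cells of 0.05
#' degrees by default), the accession design (16 taxa, 200 accessions each,
#' dispersed ~60 km around species-specific niche centres placed so that
#' each species sits inside its altitude envelope), the planted
#' climate-soil structure (shared latent "humidity" field with loading 1
#' against layer-specific structure 1.2 and unit noise, which plants a
#' dominant canonical correlation near 0.8), and the planted cleaning
#' defects (10 duplicates, 5 low-precision, 5 out-of-altitude records).
#'
#' @param seed integer seed; every generator output is a pure function of
#'   the config including this seed.
#' @param extent named vector `c(west, south, east, north)` in degrees.
#' @param cell_size cell edge in degrees.
#' @param n_per_species accessions per species.
#' @param dispersion_km niche dispersion (Gaussian sd, km).
#' @param noise_sd per-layer noise sd, in units of the layer's scale.
#' @param beta,gamma loadings of the shared latent field and of the
#'   layer-specific smooth field.
#' @param n_duplicates,n_low_precision,n_out_altitude planted defects.
#' @param climate_vars,soil_vars layer codes of the two blocks ("Alt" is
#'   part of the climate block and is a pure deterministic altitude ramp).
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1,
                             extent = c(west = -80, south = -15,
                                        east = -70, north = -5),
                             cell_size = 0.05,
                             n_per_species = 200,
                             dispersion_km = 60,
                             noise_sd = 1.0,
                             beta = 1.0,
                             gamma = 1.2,
                             n_duplicates = 10,
                             n_low_precision = 5,
                             n_out_altitude = 5,
                             climate_vars = c("Bio1", "Bio2", "Bio3", "Bio7",
                                              "Bio12", "Bio14", "ET", "Alt"),
                             soil_vars = c("SA", "SI", "CL", "BD", "pH",
                                           "CEC", "BS", "CaCO3", "SAL",
                                           "SOD", "CO")) {
  stopifnot(extent["east"] > extent["west"], extent["north"] > extent["south"],
            cell_size > 0, noise_sd >= 0, n_per_species >= 1)
  structure(list(seed = as.integer(seed), extent = extent,
                 cell_size = cell_size, n_per_species = n_per_species,
                 dispersion_km = dispersion_km, noise_sd = noise_sd,
                 beta = beta, gamma = gamma,
                 n_duplicates = n_duplicates,
                 n_low_precision = n_low_precision,
                 n_out_altitude = n_out_altitude,
                 climate_vars = climate_vars, soil_vars = soil_vars),
            class = "synthetic_config")
}

# realistic centres and scales per layer code (units as in the field)
layer_scales <- function() {
  rbind(
    data.frame(name = c("Bio1", "Bio2", "Bio3", "Bio7", "Bio12", "Bio14",
                        "ET"),
               center = c(18, 12, 70, 20, 800, 10, 700),
               scale = c(5, 2, 10, 5, 500, 10, 400), block = "climate"),
    data.frame(name = c("SA", "SI", "CL", "BD", "pH", "CEC", "BS", "CaCO3",
                        "SAL", "SOD", "CO"),
               center = c(50, 30, 20, 1.3, 6.5, 15, 70, 2, 0.5, 5, 1.5),
               scale = c(15, 10, 8, 0.15, 1, 5, 20, 1.5, 0.4, 3, 0.8),
               block = "soil"))
}

grid_centers <- function(config) {
  ex <- config$extent; cs <- config$cell_size
  nc <- round((ex[["east"]] - ex[["west"]]) / cs)
  nr <- round((ex[["north"]] - ex[["south"]]) / cs)
  list(lon = ex[["west"]] + (seq_len(nc) - 0.5) * cs,
       lat = ex[["north"]] - (seq_len(nr) - 0.5) * cs,
       n_rows = nr, n_cols = nc)
}

# deterministic smooth scalar fields over the grid, standardized cell-wise
smooth_field <- function(lon, lat, ex, fx, fy, px, py) {
  u <- (lon - ex[["west"]]) / (ex[["east"]] - ex[["west"]])
  v <- (lat - ex[["south"]]) / (ex[["north"]] - ex[["south"]])
  f <- outer(v, u, function(vv, uu)
    sin(2 * pi * fx * uu + px) + cos(2 * pi * fy * vv + py) + uu + vv)
  (f - mean(f)) / stats::sd(f)
}

altitude_ramp <- function(config) {
  g <- grid_centers(config); ex <- config$extent
  u <- (g$lon - ex[["west"]]) / (ex[["east"]] - ex[["west"]])
  matrix(rep(4000 * u, each = g$n_rows), nrow = g$n_rows)
}

#' Generate the synthetic environmental landscape
#'
#' Builds one continuous grid per climate and soil variable. Each layer is
#' `center + scale * (beta * H + gamma * G_i + noise_sd * eps)`, where `H`
#' is a single smooth latent "humidity" field shared by the two blocks
#' (this is what plants the climate-soil canonical structure), `G_i` is a
#' layer-specific smooth field, and `eps` is seeded white noise. The "Alt"
#' layer is a pure monotone west-east altitude ramp (0 to 4,000 m) used by
#' the altitude-based cleaning rule. The returned truth ledger contains the
#' planted population canonical correlations, computed exactly from the
#' cell-wise covariance of the deterministic parts plus the noise variances
#' (the population a uniform sampling of cells would see).
#'
#' @param config a [synthetic_config()].
#' @return list with `grids` (named list of [raster_grid]) and `truth`
#'   (list: `planted_r`, `noise_sd`, `beta`, `gamma`).
#' @export
synthetic_landscape <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  g <- grid_centers(config); ex <- config$extent
  sc <- layer_scales()
  H <- smooth_field(g$lon, g$lat, ex, 1, 1, 0.3, 1.1)
  vars <- c(config$climate_vars, config$soil_vars)
  det_parts <- list(); noise_vars <- numeric(0)
  grids <- list()
  for (v in vars) {
    if (v == "Alt") {
      D <- altitude_ramp(config)
      vals <- D
      nv <- 0
    } else {
      i <- match(v, sc$name)
      if (is.na(i)) stop_ecogeo("no scale entry for layer '", v, "'")
      G <- smooth_field(g$lon, g$lat, ex,
                        fx = sample(1:3, 1), fy = sample(1:3, 1),
                        px = stats::runif(1, 0, 2 * pi),
                        py = stats::runif(1, 0, 2 * pi))
      D <- sc$center[i] + sc$scale[i] * (config$beta * H + config$gamma * G)
      nv <- (sc$scale[i] * config$noise_sd)^2
      vals <- D + matrix(stats::rnorm(length(D), 0, sqrt(nv)), nrow = nrow(D))
    }
    det_parts[[v]] <- as.vector(D)
    noise_vars[v] <- nv
    grids[[v]] <- raster_grid(vals, west = ex[["west"]], north = ex[["north"]],
                              cell_size = config$cell_size, name = v)
  }
  # population covariance under uniform cell sampling: deterministic parts
  # plus independent noise on the diagonal
  Dm <- do.call(cbind, det_parts)
  C <- stats::cov(Dm) + diag(noise_vars)
  R <- stats::cov2cor(C)
  cx <- config$climate_vars; cy <- config$soil_vars
  planted <- cca_core(R[cx, cx], R[cx, cy], R[cy, cy], ev_floor = 1e-12)$r
  list(grids = grids,
       truth = list(planted_r = planted, noise_sd = config$noise_sd,
                    beta = config$beta, gamma = config$gamma))
}

# niche placement: longitude follows the altitude ramp so every species'
# centre sits mid-envelope; latitude spreads the taxa across the window
niche_centers <- function(config, ranges = default_altitude_ranges()) {
  ex <- config$extent
  W <- ex[["east"]] - ex[["west"]]
  i <- order(ranges$species)
  ranges <- ranges[i, ]
  k <- nrow(ranges)
  mid <- (ranges$min_alt + ranges$max_alt) / 2
  lon <- ex[["west"]] + pmin(pmax(mid / 4000, 0.05), 0.95) * W
  lat <- ex[["south"]] + (seq_len(k) - 0.5) / k *
    (ex[["north"]] - ex[["south"]])
  data.frame(species = ranges$species, lon = lon, lat = lat,
             min_alt = ranges$min_alt, max_alt = ranges$max_alt,
             stringsAsFactors = FALSE)
}

# longitude band where a species' grid altitude is safely inside its
# envelope (margin in metres guards against cell-centre quantization)
safe_lon_band <- function(config, min_alt, max_alt, margin = 60) {
  ex <- config$extent; W <- ex[["east"]] - ex[["west"]]
  lo <- ex[["west"]] + pmax((min_alt + margin) / 4000, 0.001) * W
  hi <- ex[["west"]] + pmin((max_alt - margin) / 4000, 0.999) * W
  c(lo, hi)
}

#' Generate synthetic occurrence records with planted cleaning defects
#'
#' Draws accessions per species around its niche centre (Gaussian in km,
#' converted to degrees with the local-latitude cosine), clamped into the
#' species' altitude-safe longitude band and the grid extent so that every
#' natural record survives cleaning. On top, plants exactly accountable
#' defects: exact duplicate rows, coordinates rounded to one decimal (below
#' the two-decimal precision default), and records placed at altitudes
#' outside the species envelope. The returned ledger records the planted
#' counts so cleaning reports can be verified against ground truth.
#'
#' @param config a [synthetic_config()].
#' @param ranges per-species altitude ranges (defaults to the shipped set).
#' @return list with `records` (data.frame: `record_id`, `species`,
#'   `longitude`, `latitude`, `source`) and `ledger` (list of planted
#'   counts: `natural`, `duplicate`, `precision`, `altitude`, `nodata`).
#' @export
synthetic_occurrences <- function(config = synthetic_config(),
                                  ranges = default_altitude_ranges()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 1L)
  ex <- config$extent
  nc <- niche_centers(config, ranges)
  rows <- list()
  for (i in seq_len(nrow(nc))) {
    lat_c <- nc$lat[i]
    sd_lon <- config$dispersion_km / (111.32 * cos(lat_c * pi / 180))
    sd_lat <- config$dispersion_km / 110.57
    n <- config$n_per_species
    lon <- nc$lon[i] + stats::rnorm(n, 0, sd_lon)
    lat <- lat_c + stats::rnorm(n, 0, sd_lat)
    band <- safe_lon_band(config, nc$min_alt[i], nc$max_alt[i])
    clamped <- lon < band[1] | lon > band[2]
    lon[lon < band[1]] <- band[1] + stats::runif(sum(lon < band[1]), 0, 0.013)
    lon[lon > band[2]] <- band[2] - stats::runif(sum(lon > band[2]), 0, 0.013)
    lat <- pmin(pmax(lat, ex[["south"]] + config$cell_size),
                ex[["north"]] - config$cell_size)
    at_edge <- lat <= ex[["south"]] + config$cell_size |
      lat >= ex[["north"]] - config$cell_size
    lat[at_edge] <- lat[at_edge] +
      stats::runif(sum(at_edge), 0.001, 0.013) *
      ifelse(lat[at_edge] > (ex[["south"]] + ex[["north"]]) / 2, -1, 1)
    rows[[i]] <- data.frame(species = nc$species[i], longitude = lon,
                            latitude = lat, stringsAsFactors = FALSE)
  }
  nat <- do.call(rbind, rows)
  nat$source <- "synthetic"
  n_nat <- nrow(nat)

  key <- function(d) paste(d$species, coord_text(d$longitude),
                           coord_text(d$latitude))

  # planted duplicates: exact copies of distinct natural rows
  dup <- nat[sample.int(n_nat, config$n_duplicates), , drop = FALSE]

  # planted low-precision records: unique one-decimal coordinates
  lowp <- NULL
  if (config$n_low_precision > 0) {
    taken <- key(nat)
    made <- 0L
    while (made < config$n_low_precision) {
      i <- sample.int(nrow(nc), 1)
      cand <- data.frame(
        species = nc$species[i],
        longitude = round(stats::runif(1, ex[["west"]], ex[["east"]]), 1),
        latitude = round(stats::runif(1, ex[["south"]], ex[["north"]]), 1),
        stringsAsFactors = FALSE)
      if (!key(cand) %in% taken) {
        cand$source <- "synthetic"
        lowp <- rbind(lowp, cand)
        taken <- c(taken, key(cand))
        made <- made + 1L
      }
    }
  }

  # planted out-of-altitude records: species whose envelope floor leaves a
  # usable too-low longitude zone
  outa <- NULL
  if (config$n_out_altitude > 0) {
    W <- ex[["east"]] - ex[["west"]]
    elig <- nc[nc$min_alt > 300, ]
    for (j in seq_len(config$n_out_altitude)) {
      sp <- elig[1 + (j - 1) %% nrow(elig), ]
      hi <- ex[["west"]] + (sp$min_alt - 150) / 4000 * W
      outa <- rbind(outa, data.frame(
        species = sp$species,
        longitude = stats::runif(1, ex[["west"]] + 0.05, hi),
        latitude = stats::runif(1, ex[["south"]] + 0.1, ex[["north"]] - 0.1),
        source = "synthetic", stringsAsFactors = FALSE))
    }
  }

  recs <- rbind(nat, dup, lowp, outa)
  recs$record_id <- sprintf("syn%05d", seq_len(nrow(recs)))
  recs <- recs[, c("record_id", "species", "longitude", "latitude", "source")]
  rownames(recs) <- NULL
  list(records = recs,
       ledger = list(natural = n_nat,
                     duplicate = config$n_duplicates,
                     precision = config$n_low_precision,
                     altitude = config$n_out_altitude,
                     nodata = 0L))
}

#' Categorical layer with exact planted class proportions
#'
#' Thresholds a seeded smooth field at its empirical quantiles so that the
#' class cell counts match the requested proportions exactly (largest
#' remainder apportionment over the cells, ranked by field value with
#' deterministic tie-breaks). Class codes are the integers `1..k`.
#'
#' @param config a [synthetic_config()].
#' @param proportions numeric vector summing to 1.
#' @param name grid name (e.g., "koppen", "soil_units").
#' @param seed_offset offset added to the config seed so several layers
#'   from one config differ.
#' @return a categorical [raster_grid]; attribute `"proportions"` records
#'   the planted truth.
#' @export
categorical_layer <- function(config = synthetic_config(), proportions,
                              name = "classes", seed_offset = 0L) {
  stopifnot(inherits(config, "synthetic_config"),
            abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0))
  set.seed(config$seed + 1000L + seed_offset)
  g <- grid_centers(config); ex <- config$extent
  f <- smooth_field(g$lon, g$lat, ex,
                    fx = sample(1:3, 1), fy = sample(1:3, 1),
                    px = stats::runif(1, 0, 2 * pi),
                    py = stats::runif(1, 0, 2 * pi))
  n <- length(f)
  k <- length(proportions)
  base <- floor(proportions * n)
  rem <- n - sum(base)
  frac <- proportions * n - base
  extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1
  codes <- rep.int(seq_len(k), base)
  cls <- integer(n)
  cls[order(as.vector(f), seq_len(n))] <- codes
  grid <- raster_grid(matrix(cls, nrow = g$n_rows),
                      west = ex[["west"]], north = ex[["north"]],
                      cell_size = config$cell_size, name = name,
                      kind = "categorical")
  attr(grid, "proportions") <- proportions
  grid
}

#' Paired sample with planted canonical correlations
#'
#' Draws two blocks whose *population* canonical correlations are exactly
#' `rho`: shared latent variables `z_k` give `u_k = z_k` and
#' `v_k = rho_k z_k + sqrt(1 - rho_k^2) e_k`, the blocks are padded to
#' widths `p` and `q` with independent normals, and a fixed random
#' invertible mixing matrix is applied within each block (canonical
#' correlations are invariant to invertible within-block mixing).
#'
#' @param n sample size (> p + q).
#' @param p,q block widths.
#' @param rho planted canonical correlations, non-increasing, each in
#'   `[0, 1)`, length <= `min(p, q)`.
#' @param seed integer seed (optional; the current RNG state is used when
#'   `NULL`).
#' @return list with `X` (n x p), `Y` (n x q) and `truth` (list: `rho`,
#'   `mix_x`, `mix_y`).
#' @export
planted_cca_sample <- function(n, p, q, rho, seed = NULL) {
  s <- length(rho)
  if (s > min(p, q)) stop_ecogeo("length(rho) must be <= min(p, q)")
  if (any(diff(rho) > 0)) stop_ecogeo("rho must be non-increasing")
  if (any(rho < 0 | rho >= 1)) stop_ecogeo("rho must lie in [0, 1)")
  if (n <= p + q) stop_ecogeo("need n > p + q")
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(stats::rnorm(n * s), n, s)
  e <- matrix(stats::rnorm(n * s), n, s)
  U <- cbind(z, matrix(stats::rnorm(n * (p - s)), n, p - s))
  V <- cbind(sweep(z, 2, rho, `*`) + sweep(e, 2, sqrt(1 - rho^2), `*`),
             matrix(stats::rnorm(n * (q - s)), n, q - s))
  rand_invertible <- function(k) {
    repeat {
      M <- matrix(stats::rnorm(k * k), k, k)
      if (abs(det(M)) > 1e-6) return(M)
    }
  }
  Mx <- rand_invertible(p); My <- rand_invertible(q)
  X <- U %*% Mx; Y <- V %*% My
  colnames(X) <- paste0("X", seq_len(p)); colnames(Y) <- paste0("Y", seq_len(q))
  list(X = X, Y = Y, truth = list(rho = rho, mix_x = Mx, mix_y = My))
}
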