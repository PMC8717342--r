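#' Configure a synthetic climate world
#'
#' Defines a seed-reproducible virtual study region with smooth
#' latitudinally and seasonally structured monthly climate fields, standing
#' in for interpolated observational climatologies and for future-scenario
#' projections from several circulation-model variants.
#'
#' Minimum temperature follows
#' `T(lat, m) = base_temp - lat_lapse * lat + seasonal_amp * cos(2*pi*(m - 7)/12)`
#' plus cell-level Gaussian noise, so July (m = 7) is the warmest month and
#' temperature declines northward. Precipitation is analogous with its own
#' phase month and latitudinal gradient, truncated at zero. Future scenarios
#' add a positive warming offset (and multiply precipitation); each
#' model variant perturbs the scenario offset with an independent
#' seeded draw so variant averaging is meaningful.
#'
#' @param grid_rows,grid_cols grid dimensions (>= 2).
#' @param lat_range,lon_range extent in decimal degrees, `c(min, max)`.
#' @param base_temp intercept of minimum temperature at latitude 0 (deg C).
#' @param lat_lapse cooling per degree latitude (deg C / degree).
#' @param seasonal_amp seasonal half-amplitude of temperature (deg C).
#' @param precip_base precipitation intercept at latitude 0 (mm/month).
#' @param precip_lat_gradient precipitation change per degree latitude (mm).
#' @param precip_seasonal_amp seasonal half-amplitude of precipitation (mm).
#' @param precip_phase_month month of peak precipitation (1-12).
#' @param noise_sd_temp,noise_sd_precip SD of cell-level weather noise.
#' @param variant_sd_temp,variant_sd_precip SD of the per-variant
#'   perturbation of the scenario warming offset (deg C) and of the
#'   log precipitation multiplier.
#' @param scenario_deltas named list: scenario id -> `list(temp_delta,
#'   precip_mult)`. Offsets of future scenarios must be > 0 and every
#'   multiplier > 0. The `"current"` baseline is implicit and need not be
#'   listed.
#' @param variants character vector of model-variant ids for future
#'   scenarios.
#' @param extra_temp_vars if `TRUE`, also generate `mT_mean` and `mT_max`
#'   layers (offset from `mT_min` with small noise, hence highly
#'   correlated) to exercise the variable correlation screen.
#' @param year_range inclusive year span occurrence records are drawn from.
#' @param seed integer RNG seed.
#' @return a `WorldConfig` list.
#' @export
world_config <- function(grid_rows = 60, grid_cols = 60,
                         lat_range = c(25, 50), lon_range = c(-110, -90),
                         base_temp = 36, lat_lapse = 0.8, seasonal_amp = 14,
                         precip_base = 80, precip_lat_gradient = -1.2,
                         precip_seasonal_amp = 45, precip_phase_month = 6,
                         noise_sd_temp = 0.5, noise_sd_precip = 4,
                         variant_sd_temp = 0.3, variant_sd_precip = 0.02,
                         scenario_deltas = list(
                           rcp45 = list(temp_delta = 2, precip_mult = 0.95),
                           rcp85 = list(temp_delta = 4, precip_mult = 0.90)),
                         variants = c("gcm1", "gcm2", "gcm3", "gcm4"),
                         extra_temp_vars = FALSE,
                         year_range = c(1990, 2017),
                         seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              lat_range = lat_range, lon_range = lon_range,
              base_temp = base_temp, lat_lapse = lat_lapse,
              seasonal_amp = seasonal_amp, precip_base = precip_base,
              precip_lat_gradient = precip_lat_gradient,
              precip_seasonal_amp = precip_seasonal_amp,
              precip_phase_month = precip_phase_month,
              noise_sd_temp = noise_sd_temp,
              noise_sd_precip = noise_sd_precip,
              variant_sd_temp = variant_sd_temp,
              variant_sd_precip = variant_sd_precip,
              scenario_deltas = scenario_deltas, variants = variants,
              extra_temp_vars = isTRUE(extra_temp_vars),
              year_range = year_range, seed = as.integer(seed))
  class(cfg) <- "WorldConfig"
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  if (cfg$grid_rows < 2L || cfg$grid_cols < 2L)
    stop("configuration error: grid dimensions must be >= 2", call. = FALSE)
  if (diff(cfg$lat_range) <= 0 || diff(cfg$lon_range) <= 0)
    stop("configuration error: degenerate lat/lon range", call. = FALSE)
  for (sc in names(cfg$scenario_deltas)) {
    d <- cfg$scenario_deltas[[sc]]
    if (!identical(sc, "current") && d$temp_delta <= 0)
      stop("configuration error: warming offset for future scenario '",
           sc, "' must be > 0", call. = FALSE)
    if (d$precip_mult <= 0)
      stop("configuration error: precipitation multiplier for '", sc,
           "' must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Define a virtual species with a Gaussian climatic niche
#'
#' The species' suitability at a cell is a bivariate independent Gaussian
#' in (mT_min, mPPT) space,
#' `S = exp(-0.5 * (((T - mu_T)/sigma_T)^2 + ((P - mu_P)/sigma_P)^2))`,
#' and its adults are observable only in `phenology_months` (e.g. 3:5 for
#' a spring-active species, 7:9 for a late-summer one).
#'
#' @param name species label.
#' @param mu_T,sigma_T niche optimum and breadth on the minimum-temperature
#'   axis (deg C); `sigma_T > 0`.
#' @param mu_P,sigma_P optimum and breadth on the precipitation axis (mm);
#'   `sigma_P > 0`.
#' @param phenology_months non-empty integer vector of months 1-12 in which
#'   adults occur.
#' @param detection probability scaling factor in (0, 1].
#' @return a `VirtualSpecies` list.
#' @export
virtual_species <- function(name, mu_T, sigma_T, mu_P, sigma_P,
                            phenology_months, detection = 1) {
  stopifnot(sigma_T > 0, sigma_P > 0,
            length(phenology_months) > 0,
            all(phenology_months %in% 1:12),
            detection > 0, detection <= 1)
  structure(list(name = name, mu_T = mu_T, sigma_T = sigma_T,
                 mu_P = mu_P, sigma_P = sigma_P,
                 phenology_months = as.integer(phenology_months),
                 detection = detection),
            class = "VirtualSpecies")
}

#' Build the synthetic monthly climate stack
#'
#' Generates `mPPT` and `mT_min` (and optionally `mT_mean`/`mT_max`) layers
#' for all 12 months under the `"current"` baseline (variant `"baseline"`)
#' and under every configured future scenario x model variant. Future
#' layers are the current layers plus the scenario warming offset (times
#' the precipitation multiplier), each variant perturbed by one seeded
#' draw, so with all noise SDs at zero a future temperature layer is
#' exactly `current + temp_delta`.
#'
#' @param config a [world_config()].
#' @return a [climate_stack()].
#' @export
build_climate_stack <- function(config) {
  validate_world_config(config)
  nr <- config$grid_rows; nc <- config$grid_cols
  dy <- diff(config$lat_range) / nr
  dx <- diff(config$lon_range) / nc
  lat <- config$lat_range[2] - dy * (seq_len(nr) - 0.5)   # row 1 = north
  lon <- config$lon_range[1] + dx * (seq_len(nc) - 0.5)
  latm <- matrix(lat, nr, nc)

  withr::with_seed(config$seed, {
    layers <- list()
    for (m in 1:12) {
      tmin <- config$base_temp - config$lat_lapse * latm +
        config$seasonal_amp * cos(2 * pi * (m - 7) / 12) +
        matrix(rnorm(nr * nc, 0, config$noise_sd_temp), nr, nc)
      ppt <- pmax(config$precip_base +
        config$precip_lat_gradient * latm +
        config$precip_seasonal_amp *
          cos(2 * pi * (m - config$precip_phase_month) / 12) +
        matrix(rnorm(nr * nc, 0, config$noise_sd_precip), nr, nc), 0)
      layers[[layer_key("mT_min", "current", "baseline", m)]] <- tmin
      layers[[layer_key("mPPT", "current", "baseline", m)]] <- ppt
      if (config$extra_temp_vars) {
        layers[[layer_key("mT_mean", "current", "baseline", m)]] <-
          tmin + 8 + matrix(rnorm(nr * nc, 0, 0.8), nr, nc)
        layers[[layer_key("mT_max", "current", "baseline", m)]] <-
          tmin + 16 + matrix(rnorm(nr * nc, 0, 1.0), nr, nc)
      }
    }
    tvars <- c("mT_min", if (config$extra_temp_vars) c("mT_mean", "mT_max"))
    for (sc in setdiff(names(config$scenario_deltas), "current")) {
      d <- config$scenario_deltas[[sc]]
      for (v in config$variants) {
        eta_T <- rnorm(1, 0, config$variant_sd_temp)
        eta_P <- exp(rnorm(1, 0, config$variant_sd_precip))
        for (m in 1:12) {
          for (tv in tvars) {
            cur <- layers[[layer_key(tv, "current", "baseline", m)]]
            layers[[layer_key(tv, sc, v, m)]] <- cur + d$temp_delta + eta_T
          }
          curp <- layers[[layer_key("mPPT", "current", "baseline", m)]]
          layers[[layer_key("mPPT", sc, v, m)]] <- curp * d$precip_mult * eta_P
        }
      }
    }
    climate_stack(layers, lat = lat, lon = lon)
  })
}

#' True suitability surface of a virtual species
#'
#' Evaluates the species' Gaussian niche on the climate of one
#' month/scenario/variant. Values lie in `[0, 1]` and reach exactly 1 where
#' the cell climate coincides with the niche optimum.
#'
#' @param species a [virtual_species()].
#' @param stack a [climate_stack()].
#' @inheritParams get_layer
#' @return a [suitability_map()] with the species' name attached.
#' @export
true_suitability_map <- function(species, stack, month,
                                 scenario = "current",
                                 variant = "baseline") {
  tmin <- get_layer(stack, "mT_min", month, scenario, variant)
  ppt <- get_layer(stack, "mPPT", month, scenario, variant)
  s <- exp(-0.5 * (((tmin - species$mu_T) / species$sigma_T)^2 +
                     ((ppt - species$mu_P) / species$sigma_P)^2))
  suitability_map(s, lat = stack$lat, lon = stack$lon,
                  species = species$name, month = month,
                  scenario = scenario, variant = variant)
}

#' Sample presence-only occurrence records from a virtual species
#'
#' Emulates presence-only biodiversity-database sampling: (month, cell)
#' pairs are drawn jointly over the species' phenology window with
#' probability proportional to true suitability times the detection
#' factor, so months in which the species finds little suitable climate
#' contribute proportionally few records. Coordinates are cell centres.
#' Sampling is unbiased with respect to space (no collector-effort model).
#'
#' @param species a [virtual_species()].
#' @param stack a [climate_stack()].
#' @param n number of records (>= 0).
#' @param seed integer RNG seed.
#' @param scenario,variant climate slice to sample from.
#' @param year_range inclusive integer year span.
#' @return data.frame with columns `species`, `lat`, `lon`, `month`,
#'   `year`, `record_id`.
#' @export
sample_occurrences <- function(species, stack, n, seed,
                               scenario = "current", variant = "baseline",
                               year_range = c(1990, 2017)) {
  stopifnot(n >= 0)
  empty <- data.frame(species = character(0), lat = numeric(0),
                      lon = numeric(0), month = integer(0),
                      year = integer(0), record_id = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  suit <- lapply(species$phenology_months, function(m)
    unclass(true_suitability_map(species, stack, m, scenario, variant)) *
      species$detection)
  names(suit) <- as.character(species$phenology_months)
  if (all(vapply(suit, function(s) sum(s, na.rm = TRUE), 0) == 0))
    stop("sampling error: suitability is zero everywhere in every ",
         "phenology month for species '", species$name, "'", call. = FALSE)
  nr <- length(stack$lat); nc <- length(stack$lon)
  withr::with_seed(as.integer(seed), {
    # joint (month, cell) sampling proportional to suitability: month
    # weight = that month's total suitability across the grid
    w_month <- vapply(suit, function(s) sum(s, na.rm = TRUE), 0)
    months <- species$phenology_months[
      sample.int(length(species$phenology_months), n, replace = TRUE,
                 prob = w_month)]
    cell <- integer(n)
    for (m in unique(months)) {
      idx <- which(months == m)
      w <- as.vector(suit[[as.character(m)]])
      w[is.na(w)] <- 0
      if (sum(w) == 0)
        stop("sampling error: zero suitability in month ", m, call. = FALSE)
      cell[idx] <- sample.int(nr * nc, length(idx), replace = TRUE, prob = w)
    }
    years <- sample(seq(year_range[1], year_range[2]), n, replace = TRUE)
    row <- (cell - 1L) %% nr + 1L
    col <- (cell - 1L) %/% nr + 1L
    data.frame(species = species$name,
               lat = stack$lat[row], lon = stack$lon[col],
               month = as.integer(months), year = as.integer(years),
               record_id = sprintf("synth-%05d", seq_len(n)),
               stringsAsFactors = FALSE)
  })
}

#' Configure occurrence-table contamination
#'
#' Counts of records to inject, each violating exactly one cleaning rule,
#' so that per-rule removal counts can be asserted exactly.
#'
#' @param n_null_fields records with one of lat/lon/month/year missing.
#' @param n_zero_coord records with latitude or longitude exactly 0.
#' @param n_capital_coord records within the capital tolerance of a
#'   capital-city coordinate.
#' @param n_duplicate exact copies of existing records.
#' @param n_south_of_min_lat records south of the minimum latitude.
#' @param seed integer RNG seed.
#' @return a `ContaminationConfig` list.
#' @export
contamination_config <- function(n_null_fields = 0, n_zero_coord = 0,
                                 n_capital_coord = 0, n_duplicate = 0,
                                 n_south_of_min_lat = 0, seed = 1L) {
  counts <- c(n_null_fields, n_zero_coord, n_capital_coord, n_duplicate,
              n_south_of_min_lat)
  if (any(counts < 0)) stop("contamination counts must be >= 0")
  structure(list(n_null_fields = n_null_fields, n_zero_coord = n_zero_coord,
                 n_capital_coord = n_capital_coord,
                 n_duplicate = n_duplicate,
                 n_south_of_min_lat = n_south_of_min_lat,
                 seed = as.integer(seed)),
            class = "ContaminationConfig")
}

#' Inject rule-violating records into an occurrence table
#'
#' Appends contaminated records at the end of the table (so originals keep
#' their positions) and returns a manifest mapping each injected record to
#' the single cleaning rule it violates. Duplicates copy the coordinates,
#' month and year of randomly chosen clean records, so under the default
#' duplicate key the original survives and the copy is dropped.
#'
#' @param records occurrence data.frame (see [sample_occurrences()]).
#' @param config a [contamination_config()].
#' @param capitals data.frame with `lat`, `lon` of capital cities
#'   (default: packaged US state capitals).
#' @param min_lat southern latitude limit used for the out-of-range rule.
#' @return list with elements `records` (augmented data.frame) and
#'   `manifest` (data.frame `record_id`, `rule`).
#' @export
contaminate <- function(records, config, capitals = us_capitals(),
                        min_lat = 20) {
  stopifnot(inherits(config, "ContaminationConfig"))
  base <- records
  lat0 <- if (nrow(base)) mean(base$lat, na.rm = TRUE) else min_lat + 10
  lon0 <- if (nrow(base)) mean(base$lon, na.rm = TRUE) else -100
  sp <- if (nrow(base)) base$species[1] else "synthetic"
  mk <- function(k, rule) {
    if (k == 0) return(NULL)
    data.frame(species = sp, lat = lat0 + runif(k, -1, 1),
               lon = lon0 + runif(k, -1, 1),
               month = sample(1:12, k, replace = TRUE),
               year = sample(1990:2017, k, replace = TRUE),
               record_id = paste0("contam-", rule, "-", seq_len(k)),
               rule = rule, stringsAsFactors = FALSE)
  }
  withr::with_seed(config$seed, {
    inj <- list()
    nf <- mk(config$n_null_fields, "null")
    if (!is.null(nf)) {
      fields <- rep(c("lat", "lon", "month", "year"),
                    length.out = nrow(nf))
      for (i in seq_len(nrow(nf))) nf[i, fields[i]] <- NA
      inj$null <- nf
    }
    zc <- mk(config$n_zero_coord, "zero")
    if (!is.null(zc)) {
      ax <- rep(c("lat", "lon"), length.out = nrow(zc))
      for (i in seq_len(nrow(zc))) zc[i, ax[i]] <- 0
      inj$zero <- zc
    }
    cc <- mk(config$n_capital_coord, "capital")
    if (!is.null(cc)) {
      pick <- sample.int(nrow(capitals), nrow(cc), replace = TRUE)
      cc$lat <- capitals$lat[pick] + runif(nrow(cc), -0.004, 0.004)
      cc$lon <- capitals$lon[pick] + runif(nrow(cc), -0.004, 0.004)
      inj$capital <- cc
    }
    if (config$n_duplicate > 0) {
      if (nrow(base) == 0)
        stop("cannot inject duplicates into an empty table")
      pick <- sample.int(nrow(base), config$n_duplicate, replace = FALSE)
      dup <- base[pick, , drop = FALSE]
      dup$record_id <- paste0("contam-duplicate-", seq_len(nrow(dup)))
      dup$rule <- "duplicate"
      inj$duplicate <- dup
    }
    so <- mk(config$n_south_of_min_lat, "south")
    if (!is.null(so)) {
      so$lat <- min_lat - runif(nrow(so), 0.5, 10)
      inj$south <- so
    }
    injected <- do.call(rbind, inj)
    if (is.null(injected)) {
      manifest <- data.frame(record_id = character(0), rule = character(0),
                             stringsAsFactors = FALSE)
      return(list(records = base, manifest = manifest))
    }
    manifest <- data.frame(record_id = injected$record_id,
                           rule = injected$rule, stringsAsFactors = FALSE)
    injected$rule <- NULL
    rownames(injected) <- NULL
    list(records = rbind(base, injected), manifest = manifest)
  })
}
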