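#' Suitability map container
#'
#' A matrix of per-cell occurrence probabilities (row 1 = north) with grid
#' and provenance metadata; `NA` cells are nodata/masked.
#'
#' @param values numeric matrix in `[0, 1]` (NA allowed).
#' @param lat,lon cell-centre coordinate vectors (lat decreasing).
#' @param species,month,scenario,variant provenance labels; `variant` is
#'   `"stacked"` for variant-averaged maps.
#' @return object of class `SuitabilityMap`.
#' @export
suitability_map <- function(values, lat, lon, species = NA_character_,
                            month = NA_integer_, scenario = NA_character_,
                            variant = NA_character_) {
  stopifnot(is.matrix(values), nrow(values) == length(lat),
            ncol(values) == length(lon))
  rng <- suppressWarnings(range(values, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    stop("suitability values must lie in [0, 1]")
  structure(values, lat = lat, lon = lon, species = species,
            month = as.integer(month), scenario = scenario,
            variant = variant, class = "SuitabilityMap")
}

map_meta <- function(map) {
  attributes(map)[c("lat", "lon", "species", "month", "scenario",
                    "variant")]
}

.check_geometry <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !isTRUE(all.equal(attr(a, "lat"), attr(b, "lat"))) ||
      !isTRUE(all.equal(attr(a, "lon"), attr(b, "lon"))))
    stop("grid error: map geometries differ", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.SuitabilityMap <- function(x, ...) {
  cat(sprintf("SuitabilityMap %s month=%s %s/%s: %d x %d cells (%d masked)\n",
              attr(x, "species"), attr(x, "month"), attr(x, "scenario"),
              attr(x, "variant"), nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Project a fitted ensemble onto one month's climate grid
#'
#' Builds the (mPPT, mT_min) covariate pair for every grid cell of the
#' requested month/scenario/variant, standardizes with the ensemble's
#' stored scaler parameters, predicts with all nine classifiers, and
#' averages the probabilities (unweighted). Cells with nodata in either
#' covariate propagate to nodata.
#'
#' @param ensemble a `FittedEnsemble` from [fit_ensemble()].
#' @param stack a [climate_stack()].
#' @inheritParams get_layer
#' @param species species label carried in the output metadata.
#' @return a [suitability_map()].
#' @export
project_month <- function(ensemble, stack, month, scenario = "current",
                          variant = "baseline", species = NA_character_) {
  ppt <- get_layer(stack, "mPPT", month, scenario, variant)
  tmin <- get_layer(stack, "mT_min", month, scenario, variant)
  if (!identical(dim(ppt), dim(tmin)))
    stop("grid error: variable layers disagree in geometry", call. = FALSE)
  valid <- !is.na(ppt) & !is.na(tmin)
  vals <- matrix(NA_real_, nrow(ppt), ncol(ppt))
  if (any(valid)) {
    pts <- data.frame(mPPT = ppt[valid], mT_min = tmin[valid])
    pts <- apply_scaler(ensemble$scaler, pts)
    pred <- suppressWarnings(predict_probability(ensemble$models, pts))
    vals[valid] <- pred$ensemble
  }
  suitability_map(vals, stack$lat, stack$lon, species = species,
                  month = month, scenario = scenario, variant = variant)
}

#' Average suitability maps across model variants
#'
#' Cell-wise unweighted mean of maps that share geometry, species, month
#' and scenario; the result carries variant label `"stacked"`.
#'
#' @param maps list of [suitability_map()] objects.
#' @return a [suitability_map()].
#' @export
stack_variants <- function(maps) {
  stopifnot(length(maps) >= 1)
  ref <- maps[[1]]
  for (m in maps[-1]) .check_geometry(ref, m)
  arr <- vapply(maps, function(m) unclass(m), matrix(0, nrow(ref), ncol(ref)))
  vals <- apply(arr, c(1, 2), mean)
  suitability_map(vals, attr(ref, "lat"), attr(ref, "lon"),
                  species = attr(ref, "species"),
                  month = attr(ref, "month"),
                  scenario = attr(ref, "scenario"), variant = "stacked")
}

#' Rasterize a polygon to a cell-centre mask
#'
#' A cell is inside if its centre falls within the polygon ring.
#'
#' @param polygon matrix/data.frame of ring vertices with columns `lon`,
#'   `lat`.
#' @param lat,lon grid cell-centre coordinates.
#' @return logical matrix.
#' @export
polygon_mask <- function(polygon, lat, lon) {
  poly <- as.matrix(as.data.frame(polygon)[, c("lon", "lat")])
  pts <- cbind(rep(lon, each = length(lat)), rep(lat, times = length(lon)))
  matrix(mgcv::in.out(poly, pts), length(lat), length(lon))
}

#' Clip a suitability map to a study-region mask
#'
#' Cells outside the mask become nodata; inside values are unchanged.
#'
#' @param map a [suitability_map()].
#' @param mask logical matrix of the map's dimensions, or a polygon
#'   (columns `lon`, `lat`) rasterized with [polygon_mask()].
#' @return the clipped [suitability_map()].
#' @export
clip_to_mask <- function(map, mask) {
  if (!is.logical(mask))
    mask <- polygon_mask(mask, attr(map, "lat"), attr(map, "lon"))
  if (!identical(dim(mask), dim(map)))
    stop("grid error: mask geometry differs from map", call. = FALSE)
  vals <- unclass(map)
  vals[!mask] <- NA_real_
  if (all(is.na(vals)))
    warning("mask does not intersect the map; all cells are nodata")
  meta <- map_meta(map)
  suitability_map(vals, meta$lat, meta$lon, meta$species, meta$month,
                  meta$scenario, meta$variant)
}

#' Change in habitat suitability between two maps
#'
#' Cell-wise `future - current`; the nodata mask is the union of the input
#' masks. Values lie in `[-1, 1]`.
#'
#' @param future,current [suitability_map()]s of identical geometry,
#'   species and month.
#' @return a `DeltaMap` (matrix with metadata, class `DeltaMap`).
#' @export
delta_map <- function(future, current) {
  .check_geometry(future, current)
  if (!identical(attr(future, "species"), attr(current, "species")) ||
      !identical(attr(future, "month"), attr(current, "month")))
    stop("grid error: maps describe different species or months",
         call. = FALSE)
  vals <- unclass(future) - unclass(current)
  structure(vals, lat = attr(future, "lat"), lon = attr(future, "lon"),
            species = attr(future, "species"),
            month = attr(future, "month"),
            scenario_pair = c(attr(future, "scenario"),
                              attr(current, "scenario")),
            class = "DeltaMap")
}

#' Suitable habitat area in grid cells
#'
#' Counts unmasked cells whose probability strictly exceeds the threshold
#' (a cell at exactly the threshold is not suitable).
#'
#' @param map a [suitability_map()].
#' @param threshold suitability cut-off (default 0.5).
#' @return integer cell count.
#' @export
habitat_area <- function(map, threshold = 0.5) {
  sum(unclass(map) > threshold, na.rm = TRUE)
}

#' Percent change in suitable habitat area
#'
#' @param current_count,future_count non-negative cell counts;
#'   `current_count` must be positive.
#' @return `100 * (future - current) / current`.
#' @export
area_change_pct <- function(current_count, future_count) {
  if (current_count <= 0)
    stop("undefined baseline: current habitat area is zero", call. = FALSE)
  100 * (future_count - current_count) / current_count
}

#' Mean latitude of suitable cells
#'
#' Convenience statistic for poleward-shift analyses: the average latitude
#' of unmasked cells with suitability strictly above the threshold.
#'
#' @inheritParams habitat_area
#' @return mean latitude in degrees, or `NaN` if no cell is suitable.
#' @export
mean_suitable_latitude <- function(map, threshold = 0.5) {
  suit <- unclass(map) > threshold
  suit[is.na(suit)] <- FALSE
  latm <- matrix(attr(map, "lat"), nrow(map), ncol(map))
  mean(latm[suit])
}

#' Write a suitability or delta map as an ESRI ASCII grid
#'
#' @param map a [suitability_map()] or `DeltaMap`.
#' @param path output path (`.asc`).
#' @export
write_map <- function(map, path) {
  lat <- attr(map, "lat"); lon <- attr(map, "lon")
  dy <- if (length(lat) > 1) abs(diff(lat[1:2])) else 1
  dx <- if (length(lon) > 1) diff(lon[1:2]) else 1
  write_ascii_grid(unclass(map), path, xll = min(lon) - dx / 2,
                   yll = min(lat) - dy / 2, dx = dx, dy = dy)
  invisible(path)
}
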