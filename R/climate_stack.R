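#' Gridded monthly climate layers
#'
#' A `ClimateStack` holds one matrix layer per (variable, month, scenario,
#' model-variant) combination on a shared regular latitude/longitude grid.
#' Matrices follow raster convention: row 1 is the northernmost row, column 1
#' the westernmost column, and `NA` is nodata. Cell centres are at
#' `lat[i]`, `lon[j]`.
#'
#' @param layers named list of numeric matrices, keyed as produced by
#'   [layer_key()].
#' @param lat numeric vector of cell-centre latitudes, strictly decreasing.
#' @param lon numeric vector of cell-centre longitudes, strictly increasing.
#' @return An object of class `ClimateStack`.
#' @seealso [build_climate_stack()] for the synthetic generator,
#'   [write_climate_stack()] for on-disk serialization.
#' @export
climate_stack <- function(layers, lat, lon) {
  stopifnot(is.list(layers), length(layers) > 0L)
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != length(lat)) || any(dims[2, ] != length(lon)))
    stop("all layers must be length(lat) x length(lon) matrices")
  if (is.unsorted(rev(lat), strictly = TRUE))
    stop("'lat' must be strictly decreasing (row 1 = north)")
  if (is.unsorted(lon, strictly = TRUE))
    stop("'lon' must be strictly increasing")
  structure(list(layers = layers, lat = as.numeric(lat),
                 lon = as.numeric(lon)),
            class = "ClimateStack")
}

#' Layer naming convention
#'
#' Builds the canonical key `<var>_<scenario>_<variant>_m<MM>` used both as
#' the list name inside a [climate_stack()] and as the file stem on disk.
#'
#' @param var variable name, e.g. `"mPPT"` or `"mT_min"`.
#' @param scenario scenario id, e.g. `"current"`, `"rcp45"`.
#' @param variant circulation-model variant id, e.g. `"gcm1"`.
#' @param month integer month 1-12.
#' @return character key.
#' @export
layer_key <- function(var, scenario, variant, month) {
  stopifnot(month %in% 1:12)
  sprintf("%s_%s_%s_m%02d", var, scenario, variant, as.integer(month))
}

#' Fetch one layer from a climate stack
#'
#' @param stack a [climate_stack()].
#' @inheritParams layer_key
#' @return numeric matrix (row 1 = north).
#' @export
get_layer <- function(stack, var, month, scenario = "current",
                      variant = "baseline") {
  key <- layer_key(var, scenario, variant, month)
  lyr <- stack$layers[[key]]
  if (is.null(lyr))
    stop("no layer for key '", key, "' in climate stack", call. = FALSE)
  lyr
}

#' @export
print.ClimateStack <- function(x, ...) {
  cat("ClimateStack:", length(x$layers), "layers on a",
      length(x$lat), "x", length(x$lon), "grid\n")
  cat("  lat:", max(x$lat), "..", min(x$lat),
      " lon:", min(x$lon), "..", max(x$lon), "\n")
  invisible(x)
}

# Grid spacing; stacks are built on regular grids so spacing is constant.
.grid_res <- function(stack) {
  list(dy = if (length(stack$lat) > 1) abs(diff(stack$lat[1:2])) else 1,
       dx = if (length(stack$lon) > 1) diff(stack$lon[1:2]) else 1)
}

# Map lon/lat to (row, col); NA where outside the grid extent.
.cell_index <- function(stack, lon, lat) {
  res <- .grid_res(stack)
  lat_max <- max(stack$lat) + res$dy / 2
  lat_min <- min(stack$lat) - res$dy / 2
  lon_min <- min(stack$lon) - res$dx / 2
  lon_max <- max(stack$lon) + res$dx / 2
  row <- floor((lat_max - lat) / res$dy) + 1L
  col <- floor((lon - lon_min) / res$dx) + 1L
  # points exactly on the max edge belong to the last cell
  row[lat == lat_min] <- length(stack$lat)
  col[lon == lon_max] <- length(stack$lon)
  out <- lat > lat_max | lat < lat_min | lon < lon_min | lon > lon_max |
    is.na(lat) | is.na(lon)
  row[out] <- NA_integer_
  col[out] <- NA_integer_
  cbind(row = row, col = col)
}

#' Write / read a climate stack as ESRI ASCII grids
#'
#' Each layer is written to `<var>_<scenario>_<variant>_m<MM>.asc`, a plain
#' text raster format (header lines `ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize` — or `dx`/`dy` when the cell is not square —
#' and `NODATA_value`, then one whitespace-separated row of values per grid
#' row from north to south).
#'
#' @param stack a [climate_stack()].
#' @param dir directory to write into (created if missing).
#' @return `write_climate_stack()` returns the written paths invisibly;
#'   `read_climate_stack()` returns a [climate_stack()].
#' @export
write_climate_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- .grid_res(stack)
  paths <- character(0)
  for (key in names(stack$layers)) {
    path <- file.path(dir, paste0(key, ".asc"))
    write_ascii_grid(stack$layers[[key]], path,
                     xll = min(stack$lon) - res$dx / 2,
                     yll = min(stack$lat) - res$dy / 2,
                     dx = res$dx, dy = res$dy)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_climate_stack
#' @export
read_climate_stack <- function(dir) {
  files <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (length(files) == 0L) stop("no .asc layers found in ", dir)
  layers <- list()
  meta <- NULL
  for (f in files) {
    g <- read_ascii_grid(f)
    layers[[sub("\\.asc$", "", basename(f))]] <- g$values
    meta <- g
  }
  nr <- nrow(meta$values); nc <- ncol(meta$values)
  lat <- meta$yll + meta$dy * ((nr:1) - 0.5)
  lon <- meta$xll + meta$dx * ((1:nc) - 0.5)
  climate_stack(layers, lat = rev(sort(lat)), lon = lon)
}

# Minimal ESRI ASCII grid writer; allows rectangular cells via dx/dy lines.
write_ascii_grid <- function(m, path, xll, yll, dx, dy,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m))), con)
  writeLines(c(paste("xllcorner", xll), paste("yllcorner", yll)), con)
  if (isTRUE(all.equal(dx, dy))) {
    writeLines(paste("cellsize", dx), con)
  } else {
    writeLines(c(paste("dx", dx), paste("dy", dy)), con)
  }
  writeLines(paste("NODATA_value", nodata), con)
  vals <- m
  vals[is.na(vals)] <- nodata
  writeLines(apply(vals, 1L, paste, collapse = " "), con)
  invisible(path)
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- do.call(rbind, lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  nodata <- hdr$nodata_value %||% -9999
  vals[vals == nodata] <- NA_real_
  dx <- hdr$dx %||% hdr$cellsize
  dy <- hdr$dy %||% hdr$cellsize
  list(values = vals, xll = hdr$xllcorner, yll = hdr$yllcorner,
       dx = dx, dy = dy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
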