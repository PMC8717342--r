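#' US state capital coordinates
#'
#' The 50 US state capitals with approximate decimal-degree coordinates,
#' used by the capital-coincidence cleaning rule (records georeferenced to
#' a capital city are usually place-name centroids, not field sightings).
#'
#' @return data.frame with columns `capital`, `state`, `lat`, `lon`.
#' @export
us_capitals <- function() {
  path <- system.file("extdata", "us_state_capitals.csv",
                      package = "phenoENM", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

# Column-name synonyms accepted on read.
.col_aliases <- list(
  species = c("species", "scientificname", "scientific_name", "name"),
  lat = c("lat", "decimallatitude", "latitude", "decimal_latitude"),
  lon = c("lon", "decimallongitude", "longitude", "decimal_longitude",
          "lng"),
  month = c("month"),
  year = c("year"))

#' Read occurrence records from a delimited text file
#'
#' Accepts the common column spellings (`decimalLatitude`/`lat`, ...).
#' Unparseable numeric cells become `NA` rather than errors, so malformed
#' rows flow into [clean_records()] where they are dropped and counted.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @return data.frame with columns `species`, `lat`, `lon`, `month`,
#'   `year`, `record_id`.
#' @export
read_occurrences <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, sep = if (format == "csv") "," else "\t",
                  stringsAsFactors = FALSE, colClasses = "character")
  lower <- tolower(names(raw))
  out <- list()
  for (field in names(.col_aliases)) {
    hit <- which(lower %in% .col_aliases[[field]])
    if (length(hit) == 0L)
      stop("format error: required column '", field,
           "' not found in ", basename(path), call. = FALSE)
    out[[field]] <- raw[[hit[1]]]
  }
  df <- data.frame(
    species = out$species,
    lat = suppressWarnings(as.numeric(out$lat)),
    lon = suppressWarnings(as.numeric(out$lon)),
    month = suppressWarnings(as.integer(out$month)),
    year = suppressWarnings(as.integer(out$year)),
    stringsAsFactors = FALSE)
  id_col <- which(lower %in% c("record_id", "gbifid", "id", "occurrenceid"))
  df$record_id <- if (length(id_col)) raw[[id_col[1]]] else
    sprintf("row-%d", seq_len(nrow(df)))
  df$month[!is.na(df$month) & !(df$month %in% 1:12)] <- NA_integer_
  df
}

#' Write occurrence records to CSV
#'
#' Uses the interchange column names `species`, `decimalLatitude`,
#' `decimalLongitude`, `month`, `year`.
#'
#' @param records occurrence data.frame.
#' @param path output path.
#' @export
write_occurrences <- function(records, path) {
  out <- data.frame(species = records$species,
                    decimalLatitude = records$lat,
                    decimalLongitude = records$lon,
                    month = records$month, year = records$year,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Clean occurrence records with per-rule accounting
#'
#' Applies, in order: (1) drop records with a missing latitude, longitude,
#' month or year; (2) drop records with latitude or longitude exactly 0;
#' (3) drop records whose coordinates match a capital city to within `tol`
#' decimal degrees on both axes; (4) drop duplicate coordinates, keeping
#' observations made in different months and years; (5) drop records inside
#' any exclusion polygon or south of `min_lat`. Cleaning never raises on a
#' bad record — it drops and counts it.
#'
#' Two duplicate interpretations are supported. The default
#' (`duplicate_mode = "conservative"`) treats records as duplicates only
#' when coordinates, month and year all match, i.e. a repeat observation is
#' kept if either its month or its year differs. `"strict"` drops a record
#' sharing coordinates with an earlier survivor unless both its month and
#' its year differ.
#'
#' @param records occurrence data.frame (see [read_occurrences()]).
#' @param capitals data.frame with `lat`, `lon` columns.
#' @param tol capital-coincidence tolerance, decimal degrees per axis.
#' @param min_lat southern latitude limit (degrees north).
#' @param exclusions list of polygons; each a matrix/data.frame with
#'   columns `lon`, `lat` (vertices of a closed ring).
#' @param duplicate_mode `"conservative"` (default) or `"strict"`.
#' @return list with `records` (survivors) and `report` (a
#'   `CleaningReport`: input_count, dropped_null, dropped_zero,
#'   dropped_capital, dropped_duplicate, dropped_exclusion, dropped_south,
#'   output_count).
#' @export
clean_records <- function(records, capitals = us_capitals(), tol = 0.01,
                          min_lat = 20, exclusions = list(),
                          duplicate_mode = c("conservative", "strict")) {
  duplicate_mode <- match.arg(duplicate_mode)
  stopifnot(tol >= 0)
  rec <- records
  report <- list(input_count = nrow(rec))

  bad <- is.na(rec$lat) | is.na(rec$lon) | is.na(rec$month) |
    is.na(rec$year)
  report$dropped_null <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]

  bad <- rec$lat == 0 | rec$lon == 0
  report$dropped_zero <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]

  if (nrow(rec) > 0 && nrow(capitals) > 0) {
    near <- outer(rec$lat, capitals$lat, function(a, b) abs(a - b) <= tol) &
      outer(rec$lon, capitals$lon, function(a, b) abs(a - b) <= tol)
    bad <- rowSums(near) > 0
  } else bad <- logical(nrow(rec))
  report$dropped_capital <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]

  keep <- .duplicate_keep(rec, duplicate_mode)
  report$dropped_duplicate <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]

  in_excl <- logical(nrow(rec))
  for (poly in exclusions) {
    poly <- as.matrix(as.data.frame(poly)[, c("lon", "lat")])
    if (nrow(rec) > 0)
      in_excl <- in_excl | mgcv::in.out(poly, cbind(rec$lon, rec$lat))
  }
  report$dropped_exclusion <- sum(in_excl)
  rec <- rec[!in_excl, , drop = FALSE]

  bad <- rec$lat < min_lat
  report$dropped_south <- sum(bad)
  rec <- rec[!bad, , drop = FALSE]

  report$output_count <- nrow(rec)
  rownames(rec) <- NULL
  structure(list(records = rec,
                 report = structure(report, class = "CleaningReport")),
            class = "CleanedOccurrences")
}

.duplicate_keep <- function(rec, mode) {
  n <- nrow(rec)
  if (n == 0) return(logical(0))
  if (mode == "conservative") {
    key <- paste(rec$lat, rec$lon, rec$month, rec$year, sep = "|")
    return(!duplicated(key))
  }
  # strict: within a coordinate group, keep only records differing from
  # every earlier survivor in BOTH month and year
  keep <- logical(n)
  groups <- split(seq_len(n), paste(rec$lat, rec$lon, sep = "|"))
  for (idx in groups) {
    kept <- integer(0)
    for (i in idx) {
      clash <- any(rec$month[kept] == rec$month[i] |
                     rec$year[kept] == rec$year[i])
      if (!length(kept) || !clash) kept <- c(kept, i)
    }
    keep[kept] <- TRUE
  }
  keep
}

#' @export
print.CleaningReport <- function(x, ...) {
  cat("Cleaning report:\n")
  for (k in names(x)) cat(sprintf("  %-18s %d\n", k, x[[k]]))
  invisible(x)
}

#' Serialize a cleaning report as JSON
#'
#' @param report a `CleaningReport` from [clean_records()].
#' @param path output path.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
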