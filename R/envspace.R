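#' Pair occurrence records with their month's climate
#'
#' Looks up, for each record, the mPPT and mT_min layer values of the
#' record's month at the record's location. Records falling outside the
#' grid extent or on nodata cells are dropped; their counts are attached
#' as the `"dropped"` attribute (`outside`, `nodata`).
#'
#' @param records cleaned occurrence data.frame.
#' @param stack a [climate_stack()].
#' @param scenario,variant climate slice (presence data are extracted from
#'   the current baseline).
#' @return data.frame of environmental samples: `mPPT`, `mT_min`, `month`,
#'   `label` (= 1), `lat`, `lon`.
#' @export
extract_env_samples <- function(records, stack, scenario = "current",
                                variant = "baseline") {
  if (nrow(records) == 0)
    return(structure(.empty_env_samples(),
                     dropped = list(outside = 0L, nodata = 0L)))
  idx <- .cell_index(stack, records$lon, records$lat)
  outside <- is.na(idx[, "row"])
  ppt <- tmin <- rep(NA_real_, nrow(records))
  for (m in sort(unique(records$month))) {
    sel <- which(records$month == m & !outside)
    if (!length(sel)) next
    lp <- get_layer(stack, "mPPT", m, scenario, variant)
    lt <- get_layer(stack, "mT_min", m, scenario, variant)
    ij <- idx[sel, , drop = FALSE]
    ppt[sel] <- lp[ij]
    tmin[sel] <- lt[ij]
  }
  nodata <- !outside & (is.na(ppt) | is.na(tmin))
  keep <- !outside & !nodata
  out <- data.frame(mPPT = ppt[keep], mT_min = tmin[keep],
                    month = as.integer(records$month[keep]),
                    label = rep(1L, sum(keep)),
                    lat = records$lat[keep], lon = records$lon[keep],
                    stringsAsFactors = FALSE)
  structure(out, dropped = list(outside = sum(outside),
                                nodata = sum(nodata)))
}

.empty_env_samples <- function() {
  data.frame(mPPT = numeric(0), mT_min = numeric(0), month = integer(0),
             label = integer(0), lat = numeric(0), lon = numeric(0))
}

#' Screen out highly correlated candidate variables
#'
#' Greedy forward selection: variables are visited in priority order and a
#' variable is retained only if its absolute Pearson correlation with every
#' already-retained variable is at or below `threshold`. With the default
#' priority, precipitation and minimum temperature are considered first,
#' so a set of mutually collinear temperature variables collapses to
#' minimum temperature alone.
#'
#' @param x data.frame or matrix of candidate variables (columns), >= 3
#'   rows.
#' @param threshold absolute Pearson correlation above which a variable is
#'   dropped (default 0.90).
#' @param priority character vector of column names to consider first;
#'   remaining columns follow in their original order.
#' @return character vector of retained variable names.
#' @export
correlation_screen <- function(x, threshold = 0.90,
                               priority = c("mPPT", "mT_min")) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 candidate variables")
  if (nrow(x) < 3) stop("need at least 3 observations")
  zv <- vapply(x, function(v) stats::var(v) == 0 || !is.finite(stats::var(v)),
               logical(1))
  if (any(zv)) {
    warning("excluding zero-variance variable(s): ",
            paste(names(x)[zv], collapse = ", "))
    x <- x[, !zv, drop = FALSE]
  }
  order_names <- c(intersect(priority, names(x)),
                   setdiff(names(x), priority))
  retained <- character(0)
  for (v in order_names) {
    if (!length(retained)) { retained <- v; next }
    r <- vapply(retained, function(u) abs(cor(x[[u]], x[[v]])), 0)
    if (all(r <= threshold)) retained <- c(retained, v)
  }
  retained
}

#' Deduplicate samples in environmental space
#'
#' Lays an `n_bins` x `n_bins` grid of evenly spaced bins over the sample's
#' own (mPPT, mT_min) range and keeps at most one sample per occupied bin
#' (the first in input order), removing environmental pseudoreplicates
#' that would otherwise dominate model fitting. Bin edges span
#' `[min, max]` of each variable; the maximum edge is inclusive.
#'
#' @param samples environmental sample data.frame (see
#'   [extract_env_samples()]).
#' @param n_bins number of bins per axis (default 50).
#' @return the surviving subset, with the bin grid (`ppt_edges`,
#'   `tmin_edges`) attached as the `"bin_grid"` attribute.
#' @export
environmental_filter <- function(samples, n_bins = 50) {
  stopifnot(nrow(samples) >= 1, n_bins >= 2,
            all(is.finite(samples$mPPT)), all(is.finite(samples$mT_min)))
  grid <- env_bin_grid(samples, n_bins)
  bi <- .bin_index(samples$mPPT, grid$ppt_edges)
  bj <- .bin_index(samples$mT_min, grid$tmin_edges)
  keep <- !duplicated(paste(bi, bj))
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, bin_grid = grid)
}

#' @rdname environmental_filter
#' @export
env_bin_grid <- function(samples, n_bins = 50) {
  structure(list(
    n_bins = as.integer(n_bins),
    ppt_edges = seq(min(samples$mPPT), max(samples$mPPT),
                    length.out = n_bins + 1),
    tmin_edges = seq(min(samples$mT_min), max(samples$mT_min),
                     length.out = n_bins + 1)),
    class = "EnvBinGrid")
}

# Bin index with inclusive max edge; constant variables collapse to bin 1.
.bin_index <- function(x, edges) {
  if (edges[1] == edges[length(edges)]) return(rep(1L, length(x)))
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Observations per month
#'
#' @param samples environmental sample data.frame.
#' @return named integer vector, month -> count (months with zero
#'   observations omitted).
#' @export
monthly_counts <- function(samples) {
  tab <- table(factor(samples$month, levels = 1:12))
  counts <- as.integer(tab)
  names(counts) <- 1:12
  counts[counts > 0]
}

#' Generate month-matched pseudoabsences
#'
#' For every month with `counts[m] > 0`, draws that many cells uniformly at
#' random (with replacement) from the valid cells of the study region and
#' labels them 0, carrying the month's mPPT and mT_min values — so
#' presences and pseudoabsences are exactly balanced within every month
#' (1:1 overall). A simple random pattern is used deliberately: no
#' distance weighting or environmental stratification.
#'
#' @param counts named integer vector (month -> presence count), e.g. from
#'   [monthly_counts()].
#' @param stack a [climate_stack()].
#' @param mask optional logical matrix (same dimensions as the layers);
#'   `TRUE` cells are eligible. `NULL` means the whole grid.
#' @param seed integer RNG seed.
#' @param scenario,variant climate slice to draw from.
#' @param exclude_cells optional integer matrix of (row, col) presence
#'   cells to exclude; off by default (pseudoabsences may coincide with
#'   presences under the pure simple-random scheme).
#' @return data.frame of samples with `label` = 0.
#' @export
generate_pseudoabsences <- function(counts, stack, mask = NULL, seed = 1L,
                                    scenario = "current",
                                    variant = "baseline",
                                    exclude_cells = NULL) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(.empty_env_samples())
  nr <- length(stack$lat); nc <- length(stack$lon)
  withr::with_seed(as.integer(seed), {
    out <- vector("list", length(counts))
    for (k in seq_along(counts)) {
      m <- as.integer(names(counts)[k])
      lp <- get_layer(stack, "mPPT", m, scenario, variant)
      lt <- get_layer(stack, "mT_min", m, scenario, variant)
      valid <- !is.na(lp) & !is.na(lt)
      if (!is.null(mask)) valid <- valid & mask
      if (!is.null(exclude_cells))
        valid[exclude_cells] <- FALSE
      cells <- which(valid)
      if (!length(cells))
        stop("generation error: no valid cells for month ", m,
             call. = FALSE)
      pick <- cells[sample.int(length(cells), counts[k], replace = TRUE)]
      row <- (pick - 1L) %% nr + 1L
      col <- (pick - 1L) %/% nr + 1L
      out[[k]] <- data.frame(mPPT = lp[pick], mT_min = lt[pick],
                             month = m, label = 0L,
                             lat = stack$lat[row], lon = stack$lon[col],
                             stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Write environmental samples to CSV
#'
#' @param samples environmental sample data.frame.
#' @param path output path.
#' @export
write_env_samples <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
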