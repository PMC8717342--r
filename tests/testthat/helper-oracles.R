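# Independent oracles and small fixtures shared across tests.

# Exhaustive Mann-Whitney pair counting (ties = 1/2).
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (a in neg)
    total <- total + (p > a) + 0.5 * (p == a)
  total / (length(pos) * length(neg))
}

# Brute-force environmental-bin survivor count: first sample per occupied
# cell of an n x n grid spanning the data range, max edge inclusive.
brute_bin_survivors <- function(samples, n_bins) {
  bin_of <- function(x, lo, hi) {
    if (lo == hi) return(rep(1L, length(x)))
    b <- floor((x - lo) / (hi - lo) * n_bins) + 1L
    pmin(pmax(b, 1L), n_bins)
  }
  bi <- bin_of(samples$mPPT, min(samples$mPPT), max(samples$mPPT))
  bj <- bin_of(samples$mT_min, min(samples$mT_min), max(samples$mT_min))
  seen <- character(0)
  keep <- logical(nrow(samples))
  for (i in seq_len(nrow(samples))) {
    key <- paste(bi[i], bj[i])
    if (!(key %in% seen)) { seen <- c(seen, key); keep[i] <- TRUE }
  }
  keep
}

# A small, quiet world used where climate detail does not matter.
tiny_world <- function(seed = 42, ...) {
  world_config(grid_rows = 20, grid_cols = 20, noise_sd_temp = 0.3,
               noise_sd_precip = 2, seed = seed, ...)
}

# A noiseless world for exact algebraic checks.
silent_world <- function(seed = 1, ...) {
  world_config(grid_rows = 10, grid_cols = 10, noise_sd_temp = 0,
               noise_sd_precip = 0, variant_sd_temp = 0,
               variant_sd_precip = 0, seed = seed, ...)
}

early_species <- function(...) {
  virtual_species("early_virtual", mu_T = 6, sigma_T = 2, mu_P = 95,
                  sigma_P = 12, phenology_months = 3:5, ...)
}

late_species <- function(...) {
  virtual_species("late_virtual", mu_T = 22, sigma_T = 3, mu_P = 40,
                  sigma_P = 15, phenology_months = 7:9, ...)
}

# Minimal valid occurrence table.
make_records <- function(lat, lon, month = 6, year = 2000,
                         species = "sp") {
  n <- length(lat)
  data.frame(species = rep_len(species, n), lat = rep_len(lat, n),
             lon = rep_len(lon, n), month = rep_len(month, n),
             year = rep_len(year, n),
             record_id = sprintf("r%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Cleanly separable two-class environmental table (standardizable).
separable_samples <- function(n_per_class = 150, seed = 9, gap = 6) {
  withr::with_seed(seed, {
    pres <- data.frame(mPPT = rnorm(n_per_class, 100, 5),
                       mT_min = rnorm(n_per_class, 5, 1),
                       month = sample(3:5, n_per_class, TRUE), label = 1L,
                       lat = NA_real_, lon = NA_real_)
    abs_ <- data.frame(mPPT = rnorm(n_per_class, 100 - gap * 5, 5),
                       mT_min = rnorm(n_per_class, 5 + gap, 1),
                       month = sample(3:5, n_per_class, TRUE), label = 0L,
                       lat = NA_real_, lon = NA_real_)
    rbind(pres, abs_)
  })
}
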