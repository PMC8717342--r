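test_that("degenerate configs produce degenerate fields and errors", {
  flat <- world_config(grid_rows = 5, grid_cols = 5, lat_lapse = 0,
                       seasonal_amp = 0, noise_sd_temp = 0,
                       noise_sd_precip = 0, seed = 1)
  st <- build_climate_stack(flat)
  for (m in c(1, 4, 12)) {
    lyr <- get_layer(st, "mT_min", m)
    expect_equal(max(lyr) - min(lyr), 0)
    expect_equal(lyr[1, 1], flat$base_temp)
  }
  expect_error(world_config(grid_rows = 1), "grid dimensions")
  expect_error(world_config(scenario_deltas = list(
    bad = list(temp_delta = -1, precip_mult = 1))), "warming offset")
  expect_error(world_config(scenario_deltas = list(
    bad = list(temp_delta = 1, precip_mult = 0))), "multiplier")
})

test_that("future layers are exact additive offsets when noise is zero", {
  cfg <- silent_world(scenario_deltas = list(
    plus2 = list(temp_delta = 2, precip_mult = 0.9)),
    variants = c("a", "b"))
  st <- build_climate_stack(cfg)
  for (v in c("a", "b")) for (m in c(2, 7)) {
    expect_equal(get_layer(st, "mT_min", m, "plus2", v),
                 get_layer(st, "mT_min", m) + 2.0)
    expect_equal(get_layer(st, "mPPT", m, "plus2", v),
                 get_layer(st, "mPPT", m) * 0.9)
  }
})

test_that("warming monotonicity holds cell-wise for positive deltas", {
  st <- build_climate_stack(silent_world())
  for (sc in c("rcp45", "rcp85")) for (m in 1:12) {
    expect_true(all(get_layer(st, "mT_min", m, sc, "gcm1") >
                      get_layer(st, "mT_min", m)))
  }
})

test_that("stacks and samples are deterministic given config and seed", {
  cfg <- tiny_world(seed = 77)
  s1 <- build_climate_stack(cfg)
  s2 <- build_climate_stack(cfg)
  expect_identical(s1, s2)
  sp <- early_species()
  expect_identical(sample_occurrences(sp, s1, 50, seed = 3),
                   sample_occurrences(sp, s2, 50, seed = 3))
})

test_that("truth map follows the Gaussian niche closed form", {
  st <- build_climate_stack(silent_world())
  # pick an actual cell climate as the optimum so the max hits exactly 1
  t0 <- get_layer(st, "mT_min", 4)[5, 5]
  p0 <- get_layer(st, "mPPT", 4)[5, 5]
  sp <- virtual_species("opt", mu_T = t0, sigma_T = 2, mu_P = p0,
                        sigma_P = 10, phenology_months = 4)
  tm <- true_suitability_map(sp, st, 4)
  expect_equal(tm[5, 5], 1.0)
  expect_true(all(tm >= 0 & tm <= 1))
  # one niche-breadth away on one axis: exp(-0.5)
  sp2 <- virtual_species("off", mu_T = t0 + 2, sigma_T = 2, mu_P = p0,
                         sigma_P = 10, phenology_months = 4)
  expect_equal(true_suitability_map(sp2, st, 4)[5, 5], exp(-0.5),
               tolerance = 1e-12)
  # far-off optimum: suitability collapses towards 0
  sp3 <- virtual_species("far", mu_T = t0 + 100, sigma_T = 2, mu_P = p0,
                         sigma_P = 10, phenology_months = 4)
  expect_lt(max(true_suitability_map(sp3, st, 4)), 1e-10)
  expect_error(true_suitability_map(sp, st, 4, scenario = "nope"),
               "no layer")
})

test_that("occurrence sampling respects n, phenology, and suitability", {
  st <- build_climate_stack(tiny_world())
  sp <- early_species()
  expect_equal(nrow(sample_occurrences(sp, st, 0, seed = 1)), 0)
  one_month <- virtual_species("april", mu_T = 8, sigma_T = 3, mu_P = 85,
                               sigma_P = 15, phenology_months = 4)
  occ <- sample_occurrences(one_month, st, 80, seed = 2)
  expect_equal(nrow(occ), 80)
  expect_true(all(occ$month == 4))
  expect_true(all(occ$lat %in% st$lat & occ$lon %in% st$lon))

  # narrow niche (optimum inside the April climate envelope): mean
  # sampled climate within one breadth of the optimum
  narrow <- virtual_species("narrow", mu_T = 10, sigma_T = 1.5, mu_P = 63,
                            sigma_P = 8, phenology_months = 4)
  occ <- sample_occurrences(narrow, st, 500, seed = 5)
  env <- extract_env_samples(occ, st)
  expect_lt(abs(mean(env$mT_min) - narrow$mu_T), narrow$sigma_T)
  expect_lt(abs(mean(env$mPPT) - narrow$mu_P), narrow$sigma_P)

  hopeless <- virtual_species("void", mu_T = 500, sigma_T = 0.1,
                              mu_P = 5000, sigma_P = 0.1,
                              phenology_months = 1)
  expect_error(sample_occurrences(hopeless, st, 5, seed = 1),
               "sampling error")
})

test_that("cell-visit frequencies track the truth map (r > 0.9)", {
  st <- build_climate_stack(tiny_world(seed = 12))
  sp <- virtual_species("wide", mu_T = 9, sigma_T = 3, mu_P = 85,
                        sigma_P = 15, phenology_months = 4)
  occ <- sample_occurrences(sp, st, 5000, seed = 8)
  tm <- true_suitability_map(sp, st, 4)
  counts <- matrix(0, nrow = 20, ncol = 20)
  idx <- cbind(match(occ$lat, st$lat), match(occ$lon, st$lon))
  for (i in seq_len(nrow(idx)))
    counts[idx[i, 1], idx[i, 2]] <- counts[idx[i, 1], idx[i, 2]] + 1
  expect_gt(cor(as.vector(counts), as.vector(unclass(tm))), 0.9)
})

test_that("contamination appends exactly the configured violations", {
  st <- build_climate_stack(tiny_world())
  base <- sample_occurrences(early_species(), st, 60, seed = 4)
  base <- clean_records(base)$records   # start from a known-clean table

  none <- contaminate(base, contamination_config(seed = 1))
  expect_identical(none$records, base)
  expect_equal(nrow(none$manifest), 0)

  cc <- contamination_config(n_null_fields = 2, n_zero_coord = 3,
                             n_capital_coord = 2, n_duplicate = 4,
                             n_south_of_min_lat = 5, seed = 31)
  out <- contaminate(base, cc, min_lat = 20)
  expect_equal(nrow(out$records), nrow(base) + 16)
  expect_identical(out$records[seq_len(nrow(base)), ], base)
  expect_equal(unname(table(out$manifest$rule)[c("null", "zero",
    "capital", "duplicate", "south")]), c(2L, 3L, 2L, 4L, 5L),
    ignore_attr = TRUE)
  zero_rows <- out$records[out$records$record_id %in%
    out$manifest$record_id[out$manifest$rule == "zero"], ]
  expect_true(all(zero_rows$lat == 0 | zero_rows$lon == 0))
})
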