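# Shared fixture: a small world and one fitted ensemble.
proj_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    st <- build_climate_stack(tiny_world(seed = 55, scenario_deltas = list(
      plus2 = list(temp_delta = 2, precip_mult = 0.95))))
    sp <- early_species()
    occ <- sample_occurrences(sp, st, 250, seed = 56)
    env <- extract_env_samples(clean_records(occ)$records, st)
    filt <- environmental_filter(env)
    pa <- generate_pseudoabsences(monthly_counts(filt), st, seed = 57)
    ens <- fit_ensemble(rbind(filt, pa), seed = 58)
    cache <<- list(stack = st, species = sp, ensemble = ens)
    cache
  }
})

test_that("project_month produces bounded maps and propagates nodata", {
  fx <- proj_fixture()
  pm <- project_month(fx$ensemble, fx$stack, 4, species = "early_virtual")
  expect_s3_class(pm, "SuitabilityMap")
  expect_true(all(pm >= 0 & pm <= 1, na.rm = TRUE))
  expect_equal(sum(is.na(pm)), 0)

  st2 <- fx$stack
  st2$layers[[layer_key("mPPT", "current", "baseline", 4)]][1, 1] <- NA
  pm2 <- project_month(fx$ensemble, st2, 4)
  expect_true(is.na(pm2[1, 1]))
  expect_equal(sum(is.na(pm2)), 1)
})

test_that("grid projection agrees with point prediction at training cells", {
  fx <- proj_fixture()
  pm <- project_month(fx$ensemble, fx$stack, 4)
  lp <- get_layer(fx$stack, "mPPT", 4)
  lt <- get_layer(fx$stack, "mT_min", 4)
  cells <- cbind(c(3, 10, 17), c(5, 12, 19))
  pts <- data.frame(mPPT = lp[cells], mT_min = lt[cells])
  pts <- apply_scaler(fx$ensemble$scaler, pts)
  pred <- suppressWarnings(
    predict_probability(fx$ensemble$models, pts))$ensemble
  expect_equal(pm[cells], pred)
})

test_that("stack_variants averages cell-wise and labels 'stacked'", {
  fx <- proj_fixture()
  pm <- project_month(fx$ensemble, fx$stack, 4)
  same <- stack_variants(list(pm, pm, pm, pm))
  expect_equal(unclass(same), unclass(pm), ignore_attr = TRUE)
  expect_equal(attr(same, "variant"), "stacked")

  meta <- list(lat = attr(pm, "lat"), lon = attr(pm, "lon"))
  a <- suitability_map(matrix(0.2, 20, 20), meta$lat, meta$lon, month = 4)
  b <- suitability_map(matrix(0.6, 20, 20), meta$lat, meta$lon, month = 4)
  expect_true(all(stack_variants(list(a, b)) == 0.4))

  withr::with_seed(9, maps <- lapply(1:5, function(i)
    suitability_map(matrix(runif(400), 20, 20), meta$lat, meta$lon)))
  stacked <- stack_variants(maps)
  arr <- simplify2array(lapply(maps, unclass))
  expect_true(all(stacked >= apply(arr, c(1, 2), min) - 1e-12))
  expect_true(all(stacked <= apply(arr, c(1, 2), max) + 1e-12))

  small <- suitability_map(matrix(0.5, 5, 5), meta$lat[1:5], meta$lon[1:5])
  expect_error(stack_variants(list(a, small)), "grid error")
})

test_that("clip_to_mask masks outside cells only; warns on empty overlap", {
  fx <- proj_fixture()
  pm <- project_month(fx$ensemble, fx$stack, 4)
  all_in <- matrix(TRUE, 20, 20)
  expect_equal(unclass(clip_to_mask(pm, all_in)), unclass(pm),
               ignore_attr = TRUE)
  expect_warning(out <- clip_to_mask(pm, matrix(FALSE, 20, 20)),
                 "does not intersect")
  expect_true(all(is.na(out)))

  # half-plane polygon mask vs direct rasterization oracle
  half <- data.frame(lon = c(-200, -100, -100, -200, -200),
                     lat = c(-90, -90, 90, 90, -90))
  clipped <- clip_to_mask(pm, half)
  inside <- outer(rep(TRUE, 20), fx$stack$lon <= -100)
  expect_equal(sum(!is.na(clipped)), sum(inside))
  expect_equal(unclass(clipped)[inside], unclass(pm)[inside])
})

test_that("delta maps subtract, unite masks, and are antisymmetric", {
  fx <- proj_fixture()
  cur <- project_month(fx$ensemble, fx$stack, 4, species = "e")
  fut <- project_month(fx$ensemble, fx$stack, 4, scenario = "plus2",
                       variant = "gcm1", species = "e")
  d <- delta_map(fut, cur)
  expect_equal(unclass(d), unclass(fut) - unclass(cur),
               ignore_attr = TRUE)
  expect_equal(unclass(delta_map(cur, fut)), -unclass(d),
               ignore_attr = TRUE)
  expect_true(all(delta_map(cur, cur) == 0))
  lat <- attr(cur, "lat"); lon <- attr(cur, "lon")
  other <- suitability_map(matrix(1, 20, 20), lat, lon, species = "f",
                           month = 4)
  expect_error(delta_map(other, cur), "different species")
})

test_that("habitat_area uses a strict threshold and matches a full scan", {
  lat <- seq(50, 25, length.out = 10); lon <- seq(-110, -90,
                                                 length.out = 10)
  m <- suitability_map(matrix(0.6, 10, 10), lat, lon)
  expect_equal(habitat_area(m), 100)
  expect_equal(habitat_area(suitability_map(matrix(0.5, 10, 10), lat, lon)),
               0)   # cells exactly at the threshold are not suitable
  withr::with_seed(14, vals <- matrix(runif(100), 10, 10))
  vals[c(3, 7), ] <- NA
  mm <- suitability_map(vals, lat, lon)
  scan <- 0
  for (i in 1:10) for (j in 1:10)
    if (!is.na(vals[i, j]) && vals[i, j] > 0.5) scan <- scan + 1
  expect_equal(habitat_area(mm), scan)
  # clip-then-count equals count-then-clip
  mask <- matrix(rep(c(TRUE, FALSE), 50), 10, 10)
  direct <- sum(vals > 0.5 & mask, na.rm = TRUE)
  expect_equal(habitat_area(clip_to_mask(mm, mask)), direct)
})

test_that("area_change_pct follows its definition and guards zero base", {
  expect_equal(area_change_pct(100, 150), 50)
  expect_equal(area_change_pct(50, 40), -20)
  expect_equal(area_change_pct(123, 123), 0)
  expect_error(area_change_pct(0, 10), "undefined baseline")
})

test_that("maps round-trip through the ASCII grid format", {
  fx <- proj_fixture()
  pm <- project_month(fx$ensemble, fx$stack, 4)
  path <- withr::local_tempfile(fileext = ".asc")
  write_map(pm, path)
  g <- phenoENM:::read_ascii_grid(path)
  expect_equal(g$values, unclass(pm), ignore_attr = TRUE,
               tolerance = 1e-12)
})
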