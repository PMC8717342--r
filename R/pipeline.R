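#' Build and validate a pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one nested list.
#' Defaults are the standard analysis settings: 20 degN southern limit,
#' 0.01 degree capital tolerance, 50 environmental bins, 1:1
#' pseudoabsence ratio, 66/33 stratified split, 0.5 suitability
#' threshold, 0.90 correlation threshold.
#'
#' @param paths list: `occurrences` (CSV path or `NULL` when simulating),
#'   `climate_dir` (directory of `.asc` layers or `NULL`), `mask`
#'   (GeoJSON-style polygon file or `NULL`), `output_dir`.
#' @param simulate list: `enabled`, `world` (a [world_config()]),
#'   `species` (list of [virtual_species()]), `n_occurrences` per species.
#' @param cleaning list: `min_lat`, `capital_tol`, `capitals_file`
#'   (`NULL` = packaged US capitals), `exclusions_file` (`NULL` = none),
#'   `duplicate_mode`.
#' @param filtering list: `n_bins`.
#' @param pseudoabsence list: `ratio` (must be 1), `seed`.
#' @param modeling list: `train_frac`, `seed`.
#' @param projection list: `threshold`, `scenarios`, `variants`, `months`.
#' @param correlation_threshold pairwise |r| above which covariates are
#'   dropped.
#' @return validated `PipelineConfig`.
#' @export
pipeline_config <- function(paths = list(output_dir = tempfile("phenoENM-")),
                            simulate = list(enabled = TRUE),
                            cleaning = list(), filtering = list(),
                            pseudoabsence = list(), modeling = list(),
                            projection = list(),
                            correlation_threshold = 0.90) {
  defaults <- list(
    paths = list(occurrences = NULL, climate_dir = NULL, mask = NULL,
                 output_dir = tempfile("phenoENM-")),
    simulate = list(enabled = TRUE, world = world_config(),
                    species = list(
                      virtual_species("early_virtual", mu_T = 8,
                                      sigma_T = 3, mu_P = 80, sigma_P = 20,
                                      phenology_months = 3:5),
                      virtual_species("late_virtual", mu_T = 16,
                                      sigma_T = 3, mu_P = 45, sigma_P = 20,
                                      phenology_months = 7:9)),
                    n_occurrences = 400L, seed = 101L),
    cleaning = list(min_lat = 20, capital_tol = 0.01,
                    capitals_file = NULL, exclusions_file = NULL,
                    duplicate_mode = "conservative"),
    filtering = list(n_bins = 50L),
    pseudoabsence = list(ratio = 1, seed = 202L),
    modeling = list(train_frac = 0.66, seed = 303L),
    projection = list(threshold = 0.5, scenarios = c("rcp45", "rcp85"),
                      variants = NULL, months = 1:12),
    correlation_threshold = correlation_threshold)
  cfg <- defaults
  cfg$paths <- utils::modifyList(defaults$paths, paths)
  cfg$simulate <- utils::modifyList(defaults$simulate, simulate,
                                    keep.null = TRUE)
  # modifyList merges lists recursively; species/world are replacements
  if (!is.null(simulate$species)) cfg$simulate$species <- simulate$species
  if (!is.null(simulate$world)) cfg$simulate$world <- simulate$world
  cfg$cleaning <- utils::modifyList(defaults$cleaning, cleaning,
                                    keep.null = TRUE)
  cfg$filtering <- utils::modifyList(defaults$filtering, filtering)
  cfg$pseudoabsence <- utils::modifyList(defaults$pseudoabsence,
                                         pseudoabsence)
  cfg$modeling <- utils::modifyList(defaults$modeling, modeling)
  cfg$projection <- utils::modifyList(defaults$projection, projection)
  class(cfg) <- "PipelineConfig"
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config object to validate.
#' @export
validate_pipeline_config <- function(config) {
  tf <- config$modeling$train_frac
  if (!is.numeric(tf) || tf <= 0 || tf >= 1)
    stop("validation error: modeling$train_frac must lie in (0, 1)",
         call. = FALSE)
  th <- config$projection$threshold
  if (!is.numeric(th) || th <= 0 || th >= 1)
    stop("validation error: projection$threshold must lie in (0, 1)",
         call. = FALSE)
  if (config$filtering$n_bins < 2)
    stop("validation error: filtering$n_bins must be >= 2", call. = FALSE)
  if (config$pseudoabsence$ratio != 1)
    stop("validation error: only a 1:1 pseudoabsence ratio is supported",
         call. = FALSE)
  if (config$correlation_threshold <= 0 || config$correlation_threshold > 1)
    stop("validation error: correlation_threshold must lie in (0, 1]",
         call. = FALSE)
  if (!config$simulate$enabled &&
      (is.null(config$paths$occurrences) || is.null(config$paths$climate_dir)))
    stop("validation error: occurrences and climate_dir paths are ",
         "required when the simulate stage is disabled", call. = FALSE)
  invisible(config)
}

#' Read a pipeline configuration from a JSON file
#'
#' Keys mirror the arguments of [pipeline_config()]; omitted keys take
#' their defaults. The `simulate$world` and `simulate$species` entries,
#' when present, are passed to [world_config()] and [virtual_species()].
#'
#' @param path JSON file path.
#' @return validated `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  args <- list()
  for (k in c("paths", "cleaning", "filtering", "pseudoabsence",
              "modeling", "projection"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$correlation_threshold))
    args$correlation_threshold <- raw$correlation_threshold
  if (!is.null(raw$simulate)) {
    sim <- raw$simulate
    if (!is.null(sim$world)) sim$world <- do.call(world_config, sim$world)
    if (!is.null(sim$species))
      sim$species <- lapply(sim$species, function(s)
        do.call(virtual_species, s))
    args$simulate <- sim
  }
  do.call(pipeline_config, args)
}

#' Run the full modelling pipeline
#'
#' Chains simulate (or load) -> clean -> extract/filter -> pseudoabsence
#' -> fit -> project -> report. All stage outputs are written under the
#' configured output directory, and a JSON manifest records seeds,
#' per-stage record counts, the per-species AUC table, and the
#' habitat-area-change table.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines.
#' @return the run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  validate_pipeline_config(config)
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_ <- function(...) if (!quiet) message("[phenoENM] ", ...)
  manifest <- list(package_version = as.character(
    utils::packageVersion("phenoENM")),
    seeds = list(simulate = config$simulate$seed,
                 pseudoabsence = config$pseudoabsence$seed,
                 modeling = config$modeling$seed),
    stages = list())
  stage <- "simulate"
  result <- tryCatch({
    # --- climate + occurrences -----------------------------------------
    if (config$simulate$enabled) {
      log_("simulate: building synthetic climate stack")
      stack <- build_climate_stack(config$simulate$world)
      species_list <- config$simulate$species
      occ <- list()
      for (i in seq_along(species_list)) {
        sp <- species_list[[i]]
        occ[[sp$name]] <- sample_occurrences(
          sp, stack, n = config$simulate$n_occurrences,
          seed = config$simulate$seed + i,
          year_range = config$simulate$world$year_range)
      }
      records <- do.call(rbind, occ)
      rownames(records) <- NULL
      write_occurrences(records, file.path(out_dir, "occurrences_raw.csv"))
      variants <- config$projection$variants %||%
        config$simulate$world$variants
    } else {
      log_("load: reading occurrences and climate layers")
      records <- read_occurrences(config$paths$occurrences)
      stack <- read_climate_stack(config$paths$climate_dir)
      variants <- config$projection$variants %||% "baseline"
    }
    manifest$stages$simulate <- list(n_records = nrow(records),
                                     n_layers = length(stack$layers))

    mask <- NULL
    if (!is.null(config$paths$mask)) {
      poly <- jsonlite::read_json(config$paths$mask, simplifyVector = TRUE)
      mask <- polygon_mask(as.data.frame(poly), stack$lat, stack$lon)
    }

    # --- clean ---------------------------------------------------------
    stage <- "clean"
    capitals <- if (is.null(config$cleaning$capitals_file)) us_capitals()
      else read.csv(config$cleaning$capitals_file)
    exclusions <- if (is.null(config$cleaning$exclusions_file)) list()
      else .read_exclusions(config$cleaning$exclusions_file)
    per_species <- split(records, records$species)
    cleaned <- lapply(per_species, function(rec) {
      clean_records(rec, capitals = capitals,
                    tol = config$cleaning$capital_tol,
                    min_lat = config$cleaning$min_lat,
                    exclusions = exclusions,
                    duplicate_mode = config$cleaning$duplicate_mode)
    })
    manifest$stages$clean <- lapply(cleaned, function(cl)
      unclass(cl$report))
    for (sp in names(cleaned))
      log_("clean: ", sp, " ", cleaned[[sp]]$report$input_count, " -> ",
           cleaned[[sp]]$report$output_count)

    # --- extract + filter ----------------------------------------------
    stage <- "filter"
    filtered <- list()
    for (sp in names(cleaned)) {
      samples <- extract_env_samples(cleaned[[sp]]$records, stack)
      filtered[[sp]] <- environmental_filter(samples,
                                             config$filtering$n_bins)
    }
    manifest$stages$filter <- lapply(filtered, nrow)

    # --- pseudoabsences -------------------------------------------------
    stage <- "pseudoabsence"
    tables <- list()
    for (i in seq_along(filtered)) {
      sp <- names(filtered)[i]
      counts <- monthly_counts(filtered[[sp]])
      pa <- generate_pseudoabsences(counts, stack, mask = mask,
                                    seed = config$pseudoabsence$seed + i)
      tables[[sp]] <- rbind(filtered[[sp]], pa)
      write_env_samples(tables[[sp]],
                        file.path(out_dir, paste0("samples_", sp, ".csv")))
    }
    manifest$stages$pseudoabsence <- lapply(tables, function(t)
      list(presences = sum(t$label == 1), pseudoabsences = sum(t$label == 0)))

    # --- fit -------------------------------------------------------------
    stage <- "fit"
    ensembles <- list()
    auc_table <- list()
    for (i in seq_along(tables)) {
      sp <- names(tables)[i]
      log_("fit: ", sp)
      ens <- fit_ensemble(tables[[sp]], seed = config$modeling$seed + i,
                          train_frac = config$modeling$train_frac)
      ensembles[[sp]] <- ens
      auc_table[[sp]] <- c(as.list(round_half_up(ens$auc, 2)),
                           ensemble_mean = round_half_up(ens$ensemble_mean, 2),
                           ensemble_sd = round_half_up(ens$ensemble_sd, 2))
    }
    manifest$stages$fit <- auc_table

    # --- project + report -------------------------------------------------
    stage <- "project"
    scen_list <- config$projection$scenarios
    area_rows <- list()
    for (sp in names(ensembles)) {
      months <- intersect(config$projection$months,
        if (config$simulate$enabled)
          .species_months(config$simulate$species, sp) else 1:12)
      for (m in months) {
        cur <- project_month(ensembles[[sp]], stack, m, species = sp)
        if (!is.null(mask)) cur <- clip_to_mask(cur, mask)
        write_map(cur, file.path(out_dir,
          sprintf("suit_%s_current_m%02d.asc", sp, m)))
        cur_area <- habitat_area(cur, config$projection$threshold)
        for (sc in scen_list) {
          maps <- lapply(variants, function(v)
            project_month(ensembles[[sp]], stack, m, scenario = sc,
                          variant = v, species = sp))
          fut <- stack_variants(maps)
          if (!is.null(mask)) fut <- clip_to_mask(fut, mask)
          write_map(fut, file.path(out_dir,
            sprintf("suit_%s_%s_stacked_m%02d.asc", sp, sc, m)))
          dm <- delta_map(fut, cur)
          write_map(dm, file.path(out_dir,
            sprintf("delta_%s_%s_m%02d.asc", sp, sc, m)))
          fut_area <- habitat_area(fut, config$projection$threshold)
          area_rows[[length(area_rows) + 1L]] <- data.frame(
            species = sp, month = m, scenario = sc,
            current_cells = cur_area, future_cells = fut_area,
            pct_change = if (cur_area > 0)
              area_change_pct(cur_area, fut_area) else NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
    area_table <- do.call(rbind, area_rows)
    write.csv(area_table, file.path(out_dir, "area_change.csv"),
              row.names = FALSE)
    manifest$stages$project <- list(n_area_rows = nrow(area_table))
    manifest$area_change <- area_table
    manifest$status <- "complete"
    manifest
  }, error = function(e) {
    manifest$status <- "failed"
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(e)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(result, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  log_("complete: outputs in ", out_dir)
  invisible(result)
}

.species_months <- function(species_list, name) {
  for (sp in species_list) if (sp$name == name) return(sp$phenology_months)
  1:12
}

.read_exclusions <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) return(list(raw))
  lapply(raw, as.data.frame)
}
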