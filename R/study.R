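#' Configuration of an end-to-end remodeling study
#'
#' Bundles the population settings, pacing protocol, scenario list and
#' output options of one full study run: build a calibrated control
#' population, apply each remodeling scenario to every model, re-simulate,
#' extract biomarkers, classify calcium-wave phenotypes, and tabulate
#' population summaries.
#'
#' @param scenarios scenario ids to run (always includes `"control"`).
#' @param n_accept control population size.
#' @param n_candidates candidate pool size for calibration.
#' @param seed global seed, recorded in every output.
#' @param ranges sampling ranges ([sample_candidates()]).
#' @param criteria calibration criteria.
#' @param cycle_length pacing cycle length, ms.
#' @param n_prebeats unrecorded conditioning beats per run.
#' @param n_recorded recorded beats per run.
#' @param dt integrator step, ms.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param write_linescans write each model's line-scan matrix.
#' @export
study_config <- function(scenarios = c(1:8), n_accept = 16L,
                         n_candidates = 300L, seed = 1L,
                         ranges = default_sampling_ranges(),
                         criteria = calibration_criteria(),
                         cycle_length = 1000, n_prebeats = 60L,
                         n_recorded = 10L, dt = 0.02, out_dir = NULL,
                         write_linescans = FALSE) {
  scenarios <- unique(c("control", as.character(scenarios)))
  structure(list(scenarios = scenarios, n_accept = n_accept,
                 n_candidates = n_candidates, seed = seed, ranges = ranges,
                 criteria = criteria, cycle_length = cycle_length,
                 n_prebeats = n_prebeats, n_recorded = n_recorded, dt = dt,
                 out_dir = out_dir, write_linescans = write_linescans),
            class = "study_config")
}

study_protocol <- function(config) {
  pacing_protocol(cycle_length = config$cycle_length,
                  n_beats = config$n_prebeats + config$n_recorded,
                  record_last_n_beats = config$n_recorded, dt = config$dt)
}

#' Simulate and classify one population under one scenario
#'
#' Applies the scenario to every model, re-simulates under the protocol and
#' returns per-model classifications and biomarkers. A model whose
#' simulation diverges is classified `"other"` rather than aborting the
#' population.
#'
#' @param population a `model_population`.
#' @param scenario a scenario id or object.
#' @param protocol a [pacing_protocol()].
#' @param keep_results keep the full simulation results (memory-heavy).
#' @export
run_scenario <- function(population, scenario, protocol,
                         keep_results = FALSE) {
  if (!inherits(scenario, "scenario")) scenario <- get_scenario(scenario)
  models <- population$models
  out <- vector("list", length(models))
  for (i in seq_along(models)) {
    id <- attr(models[[i]], "model_id")
    if (is.null(id)) id <- i
    p <- apply_scenario(models[[i]], scenario)
    res <- tryCatch(
      run_paced(p, protocol,
                meta = list(model_id = id, scenario_id = scenario$id)),
      simulation_failed = function(e) e)
    cls <- classify(res)
    bm <- if (inherits(res, "simulation_failed")) NULL
          else beat_biomarkers(res)
    out[[i]] <- list(model_id = id, category = as.character(cls$category),
                     evidence = cls$evidence, biomarkers = bm,
                     result = if (keep_results) res else NULL)
  }
  structure(list(scenario = scenario, models = out), class = "scenario_run")
}

scenario_categories <- function(run)
  vapply(run$models, `[[`, character(1), "category")

#' Run the full remodeling study
#'
#' Builds (or reuses) the calibrated control population, runs every
#' configured scenario, and assembles the two study tables: the per-
#' population biomarker summary and the per-population calcium-wave
#' category percentages. With `out_dir` set, writes
#' `table2_summary.csv`, `table3_categories.csv`, the calibration report,
#' population parameters, and a JSON provenance sidecar carrying the seed
#' and a hash of the configuration.
#'
#' @param config a [study_config()].
#' @param population optional pre-built `model_population` (skips
#'   calibration).
#' @return list with `population`, per-scenario `runs`, `biomarker_summary`
#'   and `category_table`.
#' @export
run_study <- function(config = study_config(), population = NULL) {
  protocol <- study_protocol(config)
  if (is.null(population))
    population <- build_population(
      n_accept = config$n_accept, n_candidates = config$n_candidates,
      seed = config$seed, ranges = config$ranges,
      criteria = config$criteria, protocol = protocol)
  if (!length(population$models))
    stop("calibration accepted no models; widen the candidate pool")

  runs <- list()
  summaries <- list()
  cat_rows <- list()
  for (sid in config$scenarios) {
    run <- run_scenario(population, sid, protocol,
                        keep_results = isTRUE(config$write_linescans))
    runs[[as.character(sid)]] <- run
    bms <- Filter(Negate(is.null), lapply(run$models, `[[`, "biomarkers"))
    if (length(bms))
      summaries[[length(summaries) + 1L]] <-
        summarize_biomarkers(bms, population = as.character(sid))
    pct <- summarize_population(scenario_categories(run))
    cat_rows[[length(cat_rows) + 1L]] <-
      data.frame(population = as.character(sid), t(as.numeric(pct)))
  }
  biomarker_summary <- do.call(rbind, summaries)
  category_table <- do.call(rbind, cat_rows)
  names(category_table) <- c("population", wave_categories)

  study <- list(population = population, runs = runs,
                biomarker_summary = biomarker_summary,
                category_table = category_table, config = config)
  if (!is.null(config$out_dir)) write_study(study, config$out_dir)
  study
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$biomarker_summary,
                   file.path(dir, "table2_summary.csv"), row.names = FALSE)
  utils::write.csv(study$category_table,
                   file.path(dir, "table3_categories.csv"),
                   row.names = FALSE)
  write_population(study$population, dir)
  prov <- list(seed = study$config$seed,
               config = unclass(study$config),
               config_hash = config_hash(study$config),
               n_models = length(study$population$models),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  if (isTRUE(study$config$write_linescans)) {
    for (sid in names(study$runs)) {
      run <- study$runs[[sid]]
      for (m in run$models)
        if (!is.null(m$result))
          write_simulation_result(
            m$result, file.path(dir, "linescans"),
            prefix = sprintf("scenario_%s_model_%02d", sid, m$model_id))
    }
  }
  invisible(dir)
}
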