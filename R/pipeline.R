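# End-to-end orchestration: inputs -> baseline population -> scenarios
# -> transport/activity/health results, with a reproducibility manifest.

#' Assemble a run configuration
#'
#' Collects the inputs the pipeline needs. Either supply in-memory
#' objects (a `travel_survey`, activity sample, burden table) or a
#' `simulate` block describing the synthetic generators; scenarios are
#' either an explicit list of [scenario_spec()]s or `"enumerate"` to
#' expand all level x equity x e-bike combinations for the survey's
#' geography.
#'
#' @param survey a [travel_survey()], or `NULL` to simulate.
#' @param simulate a [population_config()] used when `survey` is
#'   `NULL`.
#' @param activity a non-travel activity sample (defaults to a
#'   synthetic sample).
#' @param burden a burden table (defaults to a synthetic table for the
#'   survey's geography).
#' @param scenarios list of [scenario_spec()]s, or `"enumerate"`.
#' @param intensities an [intensity_config()].
#' @param emissions an [emission_config()].
#' @param dr a [dose_response()].
#' @param bands a [distance_bands()] table.
#' @param ebike_tables an `ebike_reference` (defaults to
#'   [ebike_reference()]).
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param seed global seed; per-scenario child seeds are derived from
#'   it with [scenario_child_seed()].
#' @return list of class `run_config`.
#' @export
run_config <- function(survey = NULL, simulate = NULL, activity = NULL,
                       burden = NULL, scenarios = list(),
                       intensities = intensity_config(),
                       emissions = emission_config(),
                       dr = default_dose_response(),
                       bands = distance_bands(),
                       ebike_tables = NULL,
                       out_dir = NULL, seed = 1L) {
  if (is.null(survey) && is.null(simulate)) {
    abort("run_config needs either a survey or a simulate block", "cycleimpacts_config_error")
  }
  structure(
    list(
      survey = survey, simulate = simulate, activity = activity,
      burden = burden, scenarios = scenarios, intensities = intensities,
      emissions = emissions, dr = dr, bands = bands,
      ebike_tables = ebike_tables, out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' File-based front end to [run_config()]: paths to the persons/trips/
#' stages CSVs (or a `simulate` block of [population_config()] fields),
#' optional activity, burden and dose-response CSVs, a scenario list,
#' and intensity/emission overrides.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)

  for (p in c("persons", "trips", "dose_response", "activity", "burden")) {
    if (!is.null(raw[[p]]) && !file.exists(resolve(raw[[p]]))) {
      abort(sprintf("config references missing file: %s", raw[[p]]), "cycleimpacts_config_error")
    }
  }
  survey <- if (!is.null(raw$persons)) {
    read_survey(resolve(raw$persons), resolve(raw$trips),
      stage_path = resolve(raw$stages),
      geography = raw$geography %||% "England"
    )
  }
  simulate <- if (!is.null(raw$simulate)) do.call(population_config, raw$simulate)
  activity <- if (!is.null(raw$activity)) {
    structure(utils::read.csv(resolve(raw$activity)),
      class = c("nontravel_activity_sample", "data.frame")
    )
  }
  burden <- if (!is.null(raw$burden)) {
    structure(utils::read.csv(resolve(raw$burden)),
      class = c("burden_table", "data.frame")
    )
  }
  dr <- if (!is.null(raw$dose_response)) {
    read_dose_response_csv(resolve(raw$dose_response))
  } else {
    default_dose_response()
  }
  scenarios <- if (identical(raw$scenarios, "enumerate")) {
    "enumerate"
  } else if (length(raw$scenarios) > 0) {
    lapply(seq_len(NROW(raw$scenarios)), function(i) {
      s <- if (is.data.frame(raw$scenarios)) as.list(raw$scenarios[i, ]) else raw$scenarios[[i]]
      scenario_spec(
        geography = s$geography %||% (raw$geography %||% "England"),
        target_pct = s$target_pct,
        equity = isTRUE(s$equity), ebike = isTRUE(s$ebike),
        seed = s$seed %||% 0L
      )
    })
  } else {
    list()
  }
  run_config(
    survey = survey, simulate = simulate, activity = activity, burden = burden,
    scenarios = scenarios,
    intensities = do.call(intensity_config, raw$intensities %||% list()),
    emissions = do.call(emission_config, raw$emissions %||% list()),
    dr = dr,
    out_dir = raw$out_dir,
    seed = raw$seed %||% 1L
  )
}

#' Run the full modelling pipeline
#'
#' Stages: (1) load or simulate the baseline travel survey and apply
#' diary preprocessing (public-transport walking minutes where stages
#' exist, short-walk replication); (2) estimate the propensity, speed
#' and e-bike tables and fuse non-travel activity; (3) run every
#' requested scenario (Steps 1 and 2); (4) compute transport, activity
#' and health outcomes per scenario. When `out_dir` is set, writes
#' per-scenario outcome CSVs and a JSON manifest (inputs, seeds,
#' package version, input digests); re-running the same configuration
#' reproduces outputs bit-exactly.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with `baseline` summaries,
#'   per-scenario `results` (each holding the `scenario_result`,
#'   `outcomes`, `activity` and `health` blocks) and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()

  # stage 1: baseline population
  survey <- config$survey
  if (is.null(survey)) {
    message(sprintf(
      "stage 1: simulating population (n = %d, seed = %d)",
      config$simulate$n_persons, config$simulate$seed
    ))
    survey <- generate_population(config$simulate)
  }
  if (!is.null(survey$stages)) survey <- derive_pt_walk_minutes(survey)
  survey <- replicate_short_walks(survey)
  message(sprintf(
    "stage 1: baseline %s: %d persons, %d trips (%.1f%% current cyclists)",
    survey$geography, nrow(survey$persons), nrow(survey$trips),
    100 * baseline_prevalence(survey)
  ))

  # stage 2: estimation and fusion
  propensity <- estimate_propensity(survey, config$bands)
  speeds <- estimate_speeds(survey)
  ebike_tabs <- config$ebike_tables %||% ebike_reference(config$bands)
  activity <- config$activity %||% generate_activity_survey(seed = config$seed)
  nontravel <- fuse_nontravel(survey, activity, config$intensities, seed = config$seed)
  baseline_profiles <- activity_profiles(survey, nontravel, config$intensities)
  burden <- config$burden %||%
    generate_burden_table(geographies = survey$geography)
  message(sprintf(
    "stage 2: propensity (%d cells), speeds, activity fusion done",
    nrow(propensity)
  ))

  # stage 3-4: scenarios and outcomes
  specs <- config$scenarios
  if (identical(specs, "enumerate")) {
    specs <- enumerate_scenarios(
      data.frame(
        geography = survey$geography,
        baseline_prevalence = baseline_prevalence(survey)
      ),
      global_seed = config$seed
    )
  }
  results <- list()
  for (spec in specs) {
    if (spec$seed == 0L) spec$seed <- scenario_child_seed(config$seed, spec)
    sid <- scenario_id(spec)
    res <- tryCatch(
      run_scenario(survey, spec, propensity, speeds, ebike_tabs),
      error = function(e) {
        abort(
          sprintf("scenario %s failed in Step 1/2: %s", sid, conditionMessage(e)),
          "cycleimpacts_pipeline_error"
        )
      }
    )
    scen_profiles <- activity_profiles(res$survey, nontravel, config$intensities)
    pifs <- pif_by_stratum(survey, baseline_profiles, scen_profiles, config$dr)
    health <- yll_averted(pifs, burden)
    outcomes <- outcome_report(survey, res, config$emissions)
    att_b <- guideline_attainment(baseline_profiles, config$intensities)
    att_s <- guideline_attainment(scen_profiles, config$intensities)
    message(sprintf(
      "stage 3: %s: %d switched trips; car miles %+.2f%%; YLL averted %.2f%%",
      sid, length(res$switched_trip_ids), outcomes$pct_change_car_miles,
      health$pct_yll_averted
    ))
    results[[sid]] <- list(
      spec = spec, scenario = res, outcomes = outcomes,
      activity = list(
        mean_total_mmeth_baseline = mean(baseline_profiles$total_mmeth),
        mean_total_mmeth_scenario = mean(scen_profiles$total_mmeth),
        mean_travel_mmeth_baseline = mean(baseline_profiles$travel_mmeth),
        mean_travel_mmeth_scenario = mean(scen_profiles$travel_mmeth),
        attainment_baseline = att_b, attainment_scenario = att_s
      ),
      health = health
    )
  }

  manifest <- list(
    package = "cycleimpacts",
    version = as.character(utils::packageVersion("cycleimpacts")),
    seed = config$seed,
    geography = survey$geography,
    n_persons = nrow(survey$persons),
    n_trips = nrow(survey$trips),
    scenario_seeds = lapply(results, function(r) r$spec$seed),
    inputs = list(
      simulated = is.null(config$survey),
      baseline_prevalence = baseline_prevalence(survey)
    ),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  out <- structure(
    list(
      baseline = list(
        survey = survey, propensity = propensity, speeds = speeds,
        profiles = baseline_profiles, burden = burden
      ),
      results = results, manifest = manifest
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' Write pipeline outputs to disk
#'
#' Per-scenario tidy outcome CSVs, group-label CSVs, health CSVs and
#' the JSON run manifest.
#'
#' @param x a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(x, dir) {
  stopifnot(inherits(x, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(x$results)) {
    r <- x$results[[sid]]
    utils::write.csv(report_to_long(r$outcomes),
      file.path(dir, paste0(sid, "_outcomes.csv")),
      row.names = FALSE
    )
    utils::write.csv(r$scenario$groups,
      file.path(dir, paste0(sid, "_groups.csv")),
      row.names = FALSE
    )
    utils::write.csv(r$health$by_stratum,
      file.path(dir, paste0(sid, "_health.csv")),
      row.names = FALSE
    )
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
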