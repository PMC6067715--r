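# The two-step scenario engine: Step 1 converts non-cyclists into
# regular cyclists by exact quota (uniformly under equity, weighted by
# current-cyclist demographics otherwise); Step 2 switches the converted
# persons' trips to cycling/e-biking by distance-band propensity.

target_levels <- function() c(5L, 10L, 25L, 50L, 75L, 100L)

#' Specify a cycling-uptake scenario
#'
#' The three scenario parameters: the target share of the population who
#' are regular cyclists, whether uptake is equitable across age and
#' gender, and whether new cyclists have access to e-bikes.
#'
#' @param geography geography label the scenario applies to.
#' @param target_pct target percentage of the population who are
#'   regular cyclists; one of 5, 10, 25, 50, 75, 100. The 5% level is
#'   only meaningful where baseline prevalence is below 4% (checked at
#'   run time against the survey).
#' @param equity if `TRUE`, every eligible non-cyclist is equally likely
#'   to convert; if `FALSE`, conversion probability follows the current
#'   age/gender profile of cyclists.
#' @param ebike if `TRUE`, all new cyclists have e-bike access and trips
#'   switch using the e-bike owner propensity and e-bike/traditional
#'   choice tables.
#' @param seed integer seed driving both steps' randomness.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(geography = "England", target_pct, equity = FALSE,
                          ebike = FALSE, seed = 1L) {
  target_pct <- as.integer(target_pct)
  if (!target_pct %in% target_levels()) {
    abort(
      sprintf(
        "target_pct must be one of %s",
        paste(target_levels(), collapse = ", ")
      ),
      "cycleimpacts_config_error"
    )
  }
  structure(
    list(
      geography = geography, target_pct = target_pct,
      equity = isTRUE(equity), ebike = isTRUE(ebike), seed = as.integer(seed)
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s: %d%% regular cyclists, equity %s, e-bike %s (seed %d)\n",
    x$geography, x$target_pct, if (x$equity) "on" else "off",
    if (x$ebike) "on" else "off", x$seed
  ))
  invisible(x)
}

scenario_id <- function(spec) {
  sprintf(
    "%s_%d_eq%d_eb%d", gsub("[^A-Za-z0-9]+", "-", spec$geography),
    spec$target_pct, as.integer(spec$equity), as.integer(spec$ebike)
  )
}

#' Step 1: select non-cyclists who become regular cyclists
#'
#' Converts an exact quota of eligible non-cyclists so that the share of
#' the population who are current-or-regular cyclists reaches the
#' scenario target: `round((target_pct/100 - baseline) * N)` persons are
#' drawn without replacement from non-cyclists aged under 80. Under
#' equity the draw is uniform; otherwise each person's sampling weight
#' is their age-band x gender stratum's baseline cyclist prevalence, so
#' e.g. a younger man is selected in proportion to how over-represented
#' younger men are among current cyclists. Deterministic given
#' `spec$seed`.
#'
#' @param survey a [travel_survey()].
#' @param spec a [scenario_spec()].
#' @param baseline baseline cyclist prevalence; computed from the survey
#'   if omitted.
#' @return character vector of converted `person_id`s (empty, with a
#'   warning, if the target does not exceed baseline).
#' @export
select_regular_cyclists <- function(survey, spec, baseline = NULL) {
  stopifnot(inherits(survey, "travel_survey"), inherits(spec, "scenario_spec"))
  persons <- survey$persons
  cyclists <- classify_current_cyclists(survey)
  baseline <- baseline %||% baseline_prevalence(survey)
  if (spec$target_pct == 5L && baseline >= 0.04) {
    abort(
      sprintf(
        "the 5%% scenario is only defined where baseline prevalence is below 4%% (observed %.1f%%)",
        100 * baseline
      ),
      "cycleimpacts_config_error"
    )
  }
  increment <- spec$target_pct / 100 - baseline
  if (increment <= 0) {
    warning(sprintf(
      "target (%d%%) does not exceed baseline prevalence (%.1f%%); no conversions",
      spec$target_pct, 100 * baseline
    ))
    return(character(0))
  }
  n_new <- round(increment * nrow(persons))
  eligible <- persons[!persons$person_id %in% cyclists & persons$age < 80, , drop = FALSE]
  if (spec$target_pct == 100L) {
    # at the 100% level everyone eligible converts: persons aged 80+ are
    # outside uptake, so the ceiling is the whole under-80 population
    n_new <- min(n_new, nrow(eligible))
  }
  if (n_new > nrow(eligible)) {
    abort(
      sprintf(
        "cannot convert %d persons: only %d eligible non-cyclists under 80",
        n_new, nrow(eligible)
      ),
      "cycleimpacts_scenario_error"
    )
  }
  if (spec$equity) {
    prob <- NULL
  } else {
    # stratum prevalence observed in this survey; zero-prevalence strata
    # keep weight 0 and so are never converted
    key <- paste(persons$age_band, persons$gender)
    is_cyc <- persons$person_id %in% cyclists
    prev <- tapply(is_cyc, key, mean)
    prob <- unname(prev[paste(eligible$age_band, eligible$gender)])
    prob[is.na(prob)] <- 0
    if (sum(prob > 0) < n_new) {
      abort(
        "not enough eligible non-cyclists in strata with non-zero baseline prevalence",
        "cycleimpacts_scenario_error"
      )
    }
  }
  with_seed(spec$seed, {
    sort(sample(eligible$person_id, n_new, replace = FALSE, prob = prob))
  })
}

#' Step 2: switch converted cyclists' trips to cycling
#'
#' Applies the distance-band propensity to every trip of every converted
#' (regular) cyclist. Without e-bikes a trip switches to `cycle` with
#' the propensity of the person's age/gender stratum and the trip's
#' band. With e-bikes the cycled-vs-not decision uses the e-bike owner
#' propensity for the band (flat across strata), and cycled trips are
#' then assigned e-bike vs traditional bike by the band's choice
#' probability. Switched trips get their duration recomputed as
#' `distance / speed * 60` with the mode- and stratum-specific speed,
#' and any embedded public-transport walking minutes zeroed (the whole
#' door-to-door trip becomes cycling). Existing cyclists' and
#' non-converted persons' trips are untouched; trip ids and distances
#' never change.
#'
#' @param survey baseline [travel_survey()].
#' @param regular_ids person ids converted in Step 1.
#' @param propensity a `propensity_table` from [estimate_propensity()].
#' @param speeds a `speed_table` from [estimate_speeds()].
#' @param ebike_tables an `ebike_reference`; required when
#'   `spec$ebike` is `TRUE`.
#' @param spec the [scenario_spec()].
#' @return an object of class `scenario_result`: list with the
#'   post-switch `survey`, the four-way `groups` data frame
#'   (`person_id`, `group` in existing_cyclist / new_cyclist /
#'   regular_cyclist / non_cyclist), `switched_trip_ids`, `spec` and
#'   `baseline_prevalence`.
#' @export
switch_trips <- function(survey, regular_ids, propensity, speeds,
                         ebike_tables = NULL, spec) {
  stopifnot(
    inherits(survey, "travel_survey"), inherits(spec, "scenario_spec"),
    inherits(propensity, "propensity_table"), inherits(speeds, "speed_table")
  )
  if (spec$ebike && is.null(ebike_tables)) {
    abort("e-bike scenario requires ebike_tables", "cycleimpacts_config_error")
  }
  bands <- attr(propensity, "bands")
  persons <- survey$persons
  trips <- survey$trips
  baseline_cyclists <- classify_current_cyclists(survey)
  baseline_prev <- baseline_prevalence(survey)

  idx <- which(trips$person_id %in% regular_ids)
  switched_ids <- character(0)
  if (length(idx) > 0) {
    sub <- trips[idx, , drop = FALSE]
    pidx <- match(sub$person_id, persons$person_id)
    aband <- persons$age_band[pidx]
    gender <- persons$gender[pidx]
    b <- band_index(sub$distance_miles, bands)
    if (any(b < 1 | b > nrow(bands))) {
      abort("trip distance outside distance-band coverage", "cycleimpacts_scenario_error")
    }
    new_mode <- rep(NA_character_, nrow(sub))
    with_seed(spec$seed + 1L, {
      if (spec$ebike) {
        p_band <- ebike_tables$ebike_propensity_by_band
        nb_ref <- length(p_band)
        b_ref <- pmin(b, nb_ref)
        cycled <- stats::runif(nrow(sub)) < p_band[b_ref]
        choice <- ebike_tables$choice_prob_by_band[b_ref]
        use_eb <- stats::runif(nrow(sub)) < choice
        new_mode[cycled] <- ifelse(use_eb[cycled], "ebike", "cycle")
      } else {
        pkey <- paste(aband, gender, bands$lower[b])
        tkey <- paste(
          propensity$age_band, propensity$gender,
          propensity$band_lower_miles
        )
        p <- propensity$p_cycle[match(pkey, tkey)]
        if (anyNA(p)) {
          abort(
            sprintf(
              "propensity table lacks cells for: %s",
              id_list(unique(pkey[is.na(p)]))
            ),
            "cycleimpacts_scenario_error"
          )
        }
        cycled <- stats::runif(nrow(sub)) < p
        new_mode[cycled] <- "cycle"
      }
    })
    sw <- !is.na(new_mode)
    if (any(sw)) {
      speed <- lookup_speed(speeds, new_mode[sw], aband[sw], gender[sw])
      if (spec$ebike && !is.null(ebike_tables$ebike_speed_mph)) {
        speed[new_mode[sw] == "ebike"] <- ebike_tables$ebike_speed_mph
      }
      trips$main_mode[idx[sw]] <- new_mode[sw]
      trips$duration_min[idx[sw]] <- sub$distance_miles[sw] / speed * 60
      trips$pt_walk_minutes[idx[sw]] <- 0
      switched_ids <- sub$trip_id[sw]
    }
  }
  survey$trips <- trips

  group <- rep("non_cyclist", nrow(persons))
  group[persons$person_id %in% baseline_cyclists] <- "existing_cyclist"
  converted <- persons$person_id %in% regular_ids
  has_switch <- persons$person_id %in% trips$person_id[trips$trip_id %in% switched_ids]
  group[converted] <- ifelse(has_switch[converted], "new_cyclist", "regular_cyclist")

  structure(
    list(
      survey = survey,
      groups = data.frame(person_id = persons$person_id, group = group),
      switched_trip_ids = switched_ids,
      spec = spec,
      baseline_prevalence = baseline_prev
    ),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  tab <- table(x$groups$group)
  cat(sprintf(
    "<scenario_result> %s (%d%%, equity %s, e-bike %s)\n",
    x$spec$geography, x$spec$target_pct,
    if (x$spec$equity) "on" else "off", if (x$spec$ebike) "on" else "off"
  ))
  cat(sprintf("  switched trips: %d\n", length(x$switched_trip_ids)))
  for (g in names(tab)) cat(sprintf("  %s: %d\n", g, tab[[g]]))
  invisible(x)
}

#' Run one scenario end to end (Steps 1 and 2)
#'
#' @inheritParams switch_trips
#' @param spec a [scenario_spec()].
#' @return a `scenario_result`.
#' @export
run_scenario <- function(survey, spec, propensity, speeds, ebike_tables = NULL) {
  baseline <- baseline_prevalence(survey)
  regular <- select_regular_cyclists(survey, spec, baseline)
  res <- switch_trips(survey, regular, propensity, speeds, ebike_tables, spec)
  res$baseline_prevalence <- baseline
  res
}

#' Enumerate scenario specifications across geographies
#'
#' All combinations of uptake level (5/10/25/50/75/100) x equity on/off
#' x e-bike on/off give 24 raw combinations per geography. Geographies
#' whose baseline prevalence is 4% or higher drop the four 5%
#' combinations, and one duplicate is removed at the 100% level (where
#' the equity setting no longer changes who converts), leaving 23 specs
#' for a low-baseline geography and 19 otherwise; ten geographies of
#' which four are low-baseline therefore yield 206 scenarios.
#'
#' @param baselines data frame (`geography`, `baseline_prevalence`) or
#'   a named numeric vector of baseline proportions (e.g.
#'   [default_region_baselines()]).
#' @param global_seed integer seed from which each spec's child seed is
#'   derived via [scenario_child_seed()].
#' @return list of [scenario_spec()] objects.
#' @export
enumerate_scenarios <- function(baselines = default_region_baselines(),
                                global_seed = 1L) {
  if (is.numeric(baselines) && !is.null(names(baselines))) {
    baselines <- data.frame(
      geography = names(baselines),
      baseline_prevalence = unname(baselines)
    )
  }
  stopifnot(all(c("geography", "baseline_prevalence") %in% names(baselines)))
  specs <- list()
  for (i in seq_len(nrow(baselines))) {
    geo <- baselines$geography[i]
    base <- baselines$baseline_prevalence[i]
    levels <- target_levels()
    if (base >= 0.04) levels <- setdiff(levels, 5L)
    grid <- expand.grid(
      target_pct = levels, equity = c(FALSE, TRUE), ebike = c(FALSE, TRUE),
      KEEP.OUT.ATTRS = FALSE
    )
    # at 100% the equity setting is irrelevant; one duplicate removed
    # (per-geography counts 23 with the 5% level, 19 without)
    grid <- grid[!(grid$target_pct == 100L & grid$equity & !grid$ebike), , drop = FALSE]
    for (j in seq_len(nrow(grid))) {
      sp <- scenario_spec(
        geography = geo, target_pct = grid$target_pct[j],
        equity = grid$equity[j], ebike = grid$ebike[j], seed = 0L
      )
      sp$seed <- scenario_child_seed(global_seed, sp)
      specs[[length(specs) + 1L]] <- sp
    }
  }
  specs
}
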