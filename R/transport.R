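# Transport and emissions outcomes: mode share, miles cycled, car
# vehicle-miles and CO2e, and journey-time changes for switched trips,
# stratifiable by any person-level subgroup.

#' Emission configuration
#'
#' @param kg_co2e_per_car_mile kg CO2-equivalent emitted per private
#'   motor-vehicle mile (default 0.313).
#' @return list of class `emission_config`.
#' @export
emission_config <- function(kg_co2e_per_car_mile = 0.313) {
  if (kg_co2e_per_car_mile <= 0) {
    abort("kg_co2e_per_car_mile must be positive", "cycleimpacts_config_error")
  }
  structure(
    list(kg_co2e_per_car_mile = kg_co2e_per_car_mile),
    class = "emission_config"
  )
}

# Apply a named subgroup filter (person-level fields) to a survey.
filter_subgroup <- function(survey, subgroup = NULL) {
  if (is.null(subgroup)) {
    return(survey)
  }
  persons <- survey$persons
  keep <- rep(TRUE, nrow(persons))
  for (field in names(subgroup)) {
    if (!field %in% names(persons)) {
      abort(sprintf("unknown subgroup field '%s'", field), "cycleimpacts_config_error")
    }
    keep <- keep & persons[[field]] %in% subgroup[[field]]
  }
  survey$persons <- persons[keep, , drop = FALSE]
  survey$trips <- survey$trips[
    survey$trips$person_id %in% survey$persons$person_id, ,
    drop = FALSE
  ]
  survey
}

subgroup_label <- function(subgroup) {
  if (is.null(subgroup)) {
    return("all")
  }
  paste(
    vapply(
      names(subgroup),
      function(f) paste0(f, "=", paste(subgroup[[f]], collapse = "|")), ""
    ),
    collapse = ","
  )
}

#' Trip mode share
#'
#' Survey-weighted share of trips by main mode (replicated short walks
#' count with their multiplicity, as intended by the replication). The
#' combined car (driver + passenger) share is attached as attribute
#' `car_combined`.
#'
#' @param survey a [travel_survey()].
#' @param subgroup optional named list of person-level filters, e.g.
#'   `list(gender = "female", ethnicity = "non-white")`.
#' @return data frame (`mode`, `share`) over the eight main modes;
#'   shares sum to 1.
#' @export
mode_share <- function(survey, subgroup = NULL) {
  survey <- filter_subgroup(survey, subgroup)
  trips <- survey$trips
  if (nrow(trips) == 0) {
    abort(
      sprintf("no trips after applying subgroup filter (%s)", subgroup_label(subgroup)),
      "cycleimpacts_filter_error"
    )
  }
  w <- survey$persons$survey_weight[match(trips$person_id, survey$persons$person_id)]
  tot <- tapply(w, factor(trips$main_mode, main_modes()), sum)
  tot[is.na(tot)] <- 0
  share <- as.numeric(tot) / sum(tot)
  out <- data.frame(mode = main_modes(), share = share)
  attr(out, "car_combined") <- sum(share[out$mode %in% c("car_driver", "car_passenger")])
  out
}

#' Miles cycled per person per week
#'
#' Weighted cycle + e-bike trip miles divided by the weighted person
#' count (the diary week is the natural time unit).
#'
#' @inheritParams mode_share
#' @return miles/person/week (scalar).
#' @export
miles_cycled_pppw <- function(survey, subgroup = NULL) {
  survey <- filter_subgroup(survey, subgroup)
  trips <- survey$trips[survey$trips$main_mode %in% cycling_modes(), , drop = FALSE]
  w <- survey$persons$survey_weight[match(trips$person_id, survey$persons$person_id)]
  denom <- sum(survey$persons$survey_weight)
  if (denom == 0) {
    abort("no persons after subgroup filter", "cycleimpacts_filter_error")
  }
  sum(w * trips$distance_miles) / denom
}

#' Car vehicle-miles and CO2e per person per week
#'
#' Vehicle-miles count car-driver trips only (passenger trips would
#' double-count the vehicle); CO2e is exactly
#' `car_miles x kg_co2e_per_car_mile`, so percentage changes in the two
#' quantities are identical. Public-transport reductions carry no CO2
#' credit.
#'
#' @inheritParams mode_share
#' @param config an [emission_config()].
#' @param include_passenger also count car-passenger miles (off by
#'   default).
#' @return named numeric `c(car_miles_pppw = , co2_kg_pppw = )`.
#' @export
car_miles_and_co2 <- function(survey, config = emission_config(),
                              subgroup = NULL, include_passenger = FALSE) {
  survey <- filter_subgroup(survey, subgroup)
  modes <- if (include_passenger) c("car_driver", "car_passenger") else "car_driver"
  trips <- survey$trips[survey$trips$main_mode %in% modes, , drop = FALSE]
  denom <- sum(survey$persons$survey_weight)
  if (denom == 0) {
    abort("no persons after subgroup filter", "cycleimpacts_filter_error")
  }
  w <- survey$persons$survey_weight[match(trips$person_id, survey$persons$person_id)]
  miles <- sum(w * trips$distance_miles) / denom
  c(car_miles_pppw = miles, co2_kg_pppw = miles * config$kg_co2e_per_car_mile)
}

#' Journey-time changes for switched trips
#'
#' Per switched trip, the change in duration (recomputed cycling time
#' minus the previously self-reported duration, which for public
#' transport includes waiting), the prior mode, and the shares of
#' switched trips that become faster (`delta < 0`) or slower
#' (`delta > 0`); exact ties count as neither.
#'
#' @param baseline the baseline [travel_survey()].
#' @param result a `scenario_result` from [switch_trips()].
#' @param subgroup optional person-level filter.
#' @return list with `deltas` (data frame `trip_id`, `person_id`,
#'   `prior_mode`, `new_mode`, `delta_min`), `pct_faster`,
#'   `pct_slower`, and `by_prior_mode` (shares within each prior mode).
#' @export
journey_time_deltas <- function(baseline, result, subgroup = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  ids <- result$switched_trip_ids
  base_f <- filter_subgroup(baseline, subgroup)
  ids <- ids[ids %in% base_f$trips$trip_id]
  bt <- base_f$trips[match(ids, base_f$trips$trip_id), , drop = FALSE]
  st <- result$survey$trips[match(ids, result$survey$trips$trip_id), , drop = FALSE]
  deltas <- data.frame(
    trip_id = ids,
    person_id = bt$person_id,
    prior_mode = bt$main_mode,
    new_mode = st$main_mode,
    delta_min = st$duration_min - bt$duration_min
  )
  share <- function(x) if (nrow(deltas) == 0) NA_real_ else 100 * mean(x)
  by_mode <- if (nrow(deltas) > 0) {
    do.call(rbind, lapply(split(deltas, deltas$prior_mode), function(d) {
      data.frame(
        prior_mode = d$prior_mode[1], n = nrow(d),
        pct_faster = 100 * mean(d$delta_min < 0),
        pct_slower = 100 * mean(d$delta_min > 0)
      )
    }))
  } else {
    data.frame(
      prior_mode = character(0), n = integer(0),
      pct_faster = numeric(0), pct_slower = numeric(0)
    )
  }
  rownames(by_mode) <- NULL
  list(
    deltas = deltas,
    pct_faster = share(deltas$delta_min < 0),
    pct_slower = share(deltas$delta_min > 0),
    by_prior_mode = by_mode
  )
}

#' Baseline-vs-scenario outcome report
#'
#' Convenience wrapper assembling mode shares, miles cycled, car miles,
#' CO2e and journey-time shares for a baseline survey and a scenario
#' result, with percentage changes.
#'
#' @param baseline the baseline [travel_survey()].
#' @param result a `scenario_result`.
#' @param emissions an [emission_config()].
#' @param subgroup optional person-level filter.
#' @return list of class `outcome_report`.
#' @export
outcome_report <- function(baseline, result, emissions = emission_config(),
                           subgroup = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  scen <- result$survey
  ms_b <- mode_share(baseline, subgroup)
  ms_s <- mode_share(scen, subgroup)
  car_b <- car_miles_and_co2(baseline, emissions, subgroup)
  car_s <- car_miles_and_co2(scen, emissions, subgroup)
  jt <- journey_time_deltas(baseline, result, subgroup)
  structure(
    list(
      scenario_id = scenario_id(result$spec),
      subgroup = subgroup_label(subgroup),
      mode_share_baseline = ms_b,
      mode_share_scenario = ms_s,
      miles_cycled_pppw_baseline = miles_cycled_pppw(baseline, subgroup),
      miles_cycled_pppw_scenario = miles_cycled_pppw(scen, subgroup),
      car_baseline = car_b,
      car_scenario = car_s,
      pct_change_car_miles = 100 * (car_s[["car_miles_pppw"]] - car_b[["car_miles_pppw"]]) /
        car_b[["car_miles_pppw"]],
      pct_change_co2 = 100 * (car_s[["co2_kg_pppw"]] - car_b[["co2_kg_pppw"]]) /
        car_b[["co2_kg_pppw"]],
      pct_trips_faster = jt$pct_faster,
      pct_trips_slower = jt$pct_slower,
      journey_time_by_prior_mode = jt$by_prior_mode
    ),
    class = "outcome_report"
  )
}

#' Tidy long-format view of an outcome report
#'
#' @param report an [outcome_report()].
#' @return data frame (`scenario_id`, `subgroup`, `outcome`, `value`).
#' @export
report_to_long <- function(report) {
  stopifnot(inherits(report, "outcome_report"))
  rows <- rbind(
    data.frame(
      outcome = paste0("mode_share_baseline_", report$mode_share_baseline$mode),
      value = report$mode_share_baseline$share
    ),
    data.frame(
      outcome = paste0("mode_share_scenario_", report$mode_share_scenario$mode),
      value = report$mode_share_scenario$share
    ),
    data.frame(
      outcome = c(
        "miles_cycled_pppw_baseline", "miles_cycled_pppw_scenario",
        "car_miles_pppw_baseline", "car_miles_pppw_scenario",
        "co2_kg_pppw_baseline", "co2_kg_pppw_scenario",
        "pct_change_car_miles", "pct_change_co2",
        "pct_trips_faster", "pct_trips_slower"
      ),
      value = c(
        report$miles_cycled_pppw_baseline, report$miles_cycled_pppw_scenario,
        report$car_baseline[["car_miles_pppw"]], report$car_scenario[["car_miles_pppw"]],
        report$car_baseline[["co2_kg_pppw"]], report$car_scenario[["co2_kg_pppw"]],
        report$pct_change_car_miles, report$pct_change_co2,
        report$pct_trips_faster, report$pct_trips_slower
      )
    )
  )
  cbind(
    data.frame(scenario_id = report$scenario_id, subgroup = report$subgroup),
    rows
  )
}
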