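# Physical-activity accounting in marginal MET-hours per week (MMETh):
# travel MMETh from the diary, non-travel MMETh fused from an activity
# survey by within-stratum rank matching, totals and guideline
# attainment.

#' Physical-activity intensity configuration
#'
#' Marginal MET intensities (activity above rest) and the weekly
#' guideline thresholds. The thresholds are constructed from the
#' guideline hours at the moderate-intensity midpoint: 2.5 h/week x 3.5
#' MMET = 8.75 MMETh and 5 h/week x 3.5 MMET = 17.5 MMETh.
#'
#' @param walk_mmet marginal MET of walking for transport (default 2.6).
#' @param cycle_mmet marginal MET of pedal cycling (default 4.6).
#' @param ebike_mmet marginal MET of e-bike cycling (default 3.5).
#' @param moderate_mmet midpoint intensity of the moderate activity
#'   range used to convert guideline hours to MMETh (default 3.5).
#' @param guideline_low_hours,guideline_high_hours recommended weekly
#'   hours of moderate activity (defaults 2.5 and 5).
#' @return list of class `intensity_config` with `walk_mmet`,
#'   `cycle_mmet`, `ebike_mmet`, `guideline_low` and `guideline_high`
#'   (MMETh/week).
#' @export
intensity_config <- function(walk_mmet = 2.6, cycle_mmet = 4.6,
                             ebike_mmet = 3.5, moderate_mmet = 3.5,
                             guideline_low_hours = 2.5,
                             guideline_high_hours = 5) {
  vals <- c(walk_mmet, cycle_mmet, ebike_mmet, moderate_mmet,
    guideline_low_hours, guideline_high_hours)
  if (any(vals <= 0)) {
    abort("intensities and guideline hours must be positive", "cycleimpacts_config_error")
  }
  if (guideline_low_hours >= guideline_high_hours) {
    abort("guideline_low_hours must be below guideline_high_hours", "cycleimpacts_config_error")
  }
  structure(
    list(
      walk_mmet = walk_mmet, cycle_mmet = cycle_mmet, ebike_mmet = ebike_mmet,
      guideline_low = guideline_low_hours * moderate_mmet,
      guideline_high = guideline_high_hours * moderate_mmet
    ),
    class = "intensity_config"
  )
}

#' Weekly travel MMETh of a set of trips
#'
#' Sums intensity x duration over active travel: walk trips at the
#' walking intensity, cycle trips at the cycling intensity, e-bike
#' trips at the e-bike intensity, plus the embedded walking minutes of
#' public-transport trips at the walking intensity. Motorised trips
#' otherwise contribute nothing. Durations are minutes; the result is
#' MMET-hours.
#'
#' @param trips a trips data frame (one person's trips, or any subset).
#' @param intensities an [intensity_config()].
#' @return total MMETh (scalar).
#' @export
travel_mmeth <- function(trips, intensities = intensity_config()) {
  if (nrow(trips) == 0) {
    return(0)
  }
  if (any(trips$duration_min < 0) || any(trips$pt_walk_minutes < 0)) {
    abort("negative durations in trips", "cycleimpacts_validation_error")
  }
  hours <- trips$duration_min / 60
  pt_hours <- ifelse(trips$main_mode %in% pt_modes(), trips$pt_walk_minutes, 0) / 60
  mmet <- c(
    walk = intensities$walk_mmet, cycle = intensities$cycle_mmet,
    ebike = intensities$ebike_mmet
  )[trips$main_mode]
  mmet[is.na(mmet)] <- 0
  sum(hours * mmet + pt_hours * intensities$walk_mmet)
}

#' Weekly travel MMETh for every person in a survey
#'
#' Vectorised [travel_mmeth()]; persons with no trips get 0.
#'
#' @param survey a [travel_survey()].
#' @param intensities an [intensity_config()].
#' @return data frame (`person_id`, `travel_mmeth`).
#' @export
travel_mmeth_by_person <- function(survey, intensities = intensity_config()) {
  trips <- survey$trips
  if (nrow(trips) > 0 &&
    (any(trips$duration_min < 0) || any(trips$pt_walk_minutes < 0))) {
    abort("negative durations in trips", "cycleimpacts_validation_error")
  }
  mmet <- c(
    walk = intensities$walk_mmet, cycle = intensities$cycle_mmet,
    ebike = intensities$ebike_mmet
  )[trips$main_mode]
  mmet[is.na(mmet)] <- 0
  contrib <- trips$duration_min / 60 * mmet +
    ifelse(trips$main_mode %in% pt_modes(), trips$pt_walk_minutes, 0) / 60 *
      intensities$walk_mmet
  agg <- tapply(contrib, trips$person_id, sum)
  out <- data.frame(person_id = survey$persons$person_id)
  out$travel_mmeth <- unname(agg[match(out$person_id, names(agg))])
  out$travel_mmeth[is.na(out$travel_mmeth)] <- 0
  out
}

#' Fuse non-travel activity into the survey by rank matching
#'
#' Within each age-band x gender stratum, survey persons are ranked by
#' their travel MMETh (ties broken by a seeded random draw) and assigned
#' the matching quantile of the stratum's weighted non-travel MMETh
#' distribution from the activity sample. This preserves the shape of
#' both marginals and induces a monotone coupling between travel and
#' non-travel activity within stratum; it is deterministic given the
#' seed. Store the result once at baseline — non-travel activity is
#' assumed unchanged in every scenario, so scenario totals must reuse
#' the baseline assignment.
#'
#' @param survey a [travel_survey()].
#' @param activity a non-travel activity sample
#'   ([generate_activity_survey()] or same-schema data), covering every
#'   stratum present in the survey.
#' @param intensities an [intensity_config()] used to compute the travel
#'   MMETh ranking.
#' @param seed integer seed for tie-breaking.
#' @return data frame (`person_id`, `nontravel_mmeth`).
#' @export
fuse_nontravel <- function(survey, activity, intensities = intensity_config(),
                           seed = 1L) {
  stopifnot(all(c("age_band", "gender", "nontravel_mmeth", "weight") %in% names(activity)))
  persons <- survey$persons
  tm <- travel_mmeth_by_person(survey, intensities)
  tm$age_band <- persons$age_band[match(tm$person_id, persons$person_id)]
  tm$gender <- persons$gender[match(tm$person_id, persons$person_id)]

  strata <- unique(paste(tm$age_band, tm$gender))
  have <- unique(paste(activity$age_band, activity$gender))
  missing <- setdiff(strata, have)
  if (length(missing) > 0) {
    abort(
      sprintf("activity sample lacks stratum(s): %s", paste(missing, collapse = "; ")),
      "cycleimpacts_fusion_error"
    )
  }

  out <- with_seed(seed, {
    tm$tiebreak <- stats::runif(nrow(tm))
    res <- lapply(strata, function(s) {
      sel <- paste(tm$age_band, tm$gender) == s
      grp <- tm[sel, , drop = FALSE]
      samp <- activity[paste(activity$age_band, activity$gender) == s, , drop = FALSE]
      ord <- order(samp$nontravel_mmeth)
      vals <- samp$nontravel_mmeth[ord]
      cw <- cumsum(samp$weight[ord]) / sum(samp$weight)
      r <- integer(nrow(grp))
      r[order(grp$travel_mmeth, grp$tiebreak)] <- seq_len(nrow(grp))
      q <- (r - 0.5) / nrow(grp)
      # weighted empirical quantile (type-1 inverse CDF)
      assigned <- vals[pmin(length(vals), findInterval(q, cw, left.open = TRUE) + 1L)]
      data.frame(person_id = grp$person_id, nontravel_mmeth = assigned)
    })
    do.call(rbind, res)
  })
  out <- out[match(persons$person_id, out$person_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble per-person activity profiles
#'
#' @param survey a [travel_survey()] (baseline or scenario).
#' @param nontravel data frame (`person_id`, `nontravel_mmeth`) from
#'   [fuse_nontravel()] at baseline — the same assignment must be reused
#'   for scenarios.
#' @param intensities an [intensity_config()].
#' @return data frame of class `activity_profiles` with columns
#'   `person_id`, `travel_mmeth`, `nontravel_mmeth`, `total_mmeth`.
#' @export
activity_profiles <- function(survey, nontravel, intensities = intensity_config()) {
  tm <- travel_mmeth_by_person(survey, intensities)
  tm$nontravel_mmeth <- nontravel$nontravel_mmeth[
    match(tm$person_id, nontravel$person_id)
  ]
  if (anyNA(tm$nontravel_mmeth)) {
    abort(
      sprintf(
        "non-travel activity missing for person(s): %s",
        id_list(tm$person_id[is.na(tm$nontravel_mmeth)])
      ),
      "cycleimpacts_fusion_error"
    )
  }
  tm$total_mmeth <- tm$travel_mmeth + tm$nontravel_mmeth
  structure(tm, class = c("activity_profiles", "data.frame"))
}

#' Share of the population meeting activity guidelines
#'
#' Survey-weighted shares of persons whose total weekly MMETh meets the
#' lower and higher guideline thresholds (closed lower bounds: "at
#' least" the threshold counts).
#'
#' @param profiles an [activity_profiles()] data frame.
#' @param intensities an [intensity_config()] carrying the thresholds.
#' @param weights optional named weights (by `person_id`); defaults to
#'   unit weights.
#' @return named numeric `c(low = , high = )` of proportions.
#' @export
guideline_attainment <- function(profiles, intensities = intensity_config(),
                                 weights = NULL) {
  if (nrow(profiles) == 0) {
    abort("no activity profiles supplied", "cycleimpacts_validation_error")
  }
  w <- if (is.null(weights)) {
    rep(1, nrow(profiles))
  } else {
    unname(weights[profiles$person_id])
  }
  c(
    low = sum(w * (profiles$total_mmeth >= intensities$guideline_low)) / sum(w),
    high = sum(w * (profiles$total_mmeth >= intensities$guideline_high)) / sum(w)
  )
}
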