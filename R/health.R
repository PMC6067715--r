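# Comparative risk assessment: total weekly MMETh is mapped to an
# all-cause-mortality relative risk through a monotone dose-response
# lookup, stratum population impact fractions are computed from
# individual-level baseline and scenario exposures, and applied to a
# years-of-life-lost burden table for ages 20-79.

#' Dose-response curve for physical activity and all-cause mortality
#'
#' A monotone lookup table of relative risk against weekly MMETh,
#' linearly interpolated between knots and flat beyond the last knot.
#' The first knot must sit at exposure 0 with relative risk 1 and the
#' curve must be non-increasing with all risks in (0, 1].
#'
#' @param exposure numeric vector of MMETh/week knot positions.
#' @param rr numeric vector of relative risks at the knots.
#' @return data frame (`exposure`, `rr`) of class `dose_response`.
#' @export
dose_response <- function(exposure, rr) {
  if (length(exposure) != length(rr) || length(exposure) < 2) {
    abort("dose_response needs matching exposure and rr vectors (>= 2 knots)",
      class = "cycleimpacts_config_error"
    )
  }
  if (exposure[1] != 0 || rr[1] != 1) {
    abort("the first dose-response knot must be (0, 1)", "cycleimpacts_config_error")
  }
  if (is.unsorted(exposure, strictly = TRUE)) {
    abort("dose-response exposures must be strictly increasing", "cycleimpacts_config_error")
  }
  if (any(diff(rr) > 0) || any(rr <= 0) || any(rr > 1)) {
    abort("relative risks must be non-increasing and lie in (0, 1]", "cycleimpacts_config_error")
  }
  structure(data.frame(exposure = exposure, rr = rr), class = c("dose_response", "data.frame"))
}

#' Default (illustrative) dose-response curve
#'
#' A monotone curve with steep early gains and a plateau around 0.66 at
#' high activity volumes, the shape reported by pooled cohort
#' meta-analyses of physical activity and all-cause mortality. Bundled
#' as an illustrative default; substitute a published curve via
#' [dose_response()] or [read_dose_response_csv()] for applied work.
#'
#' @return a `dose_response`.
#' @export
default_dose_response <- function() {
  dose_response(
    exposure = c(0, 4.375, 8.75, 17.5, 35, 70),
    rr = c(1, 0.90, 0.81, 0.73, 0.67, 0.66)
  )
}

#' Read/write a dose-response CSV (`exposure_mmeth`, `rr`)
#' @param path CSV path.
#' @return a `dose_response` (read) or `path` (write), invisibly.
#' @export
read_dose_response_csv <- function(path) {
  tab <- utils::read.csv(path)
  dose_response(tab$exposure_mmeth, tab$rr)
}

#' @rdname read_dose_response_csv
#' @param dr a `dose_response`.
#' @export
write_dose_response_csv <- function(dr, path) {
  utils::write.csv(
    data.frame(exposure_mmeth = dr$exposure, rr = dr$rr),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' Individual relative risk at a given activity volume
#'
#' Linear interpolation between dose-response knots; flat extrapolation
#' beyond the last knot; `rr(0) = 1` by construction.
#'
#' @param total_mmeth numeric vector of weekly MMETh (>= 0).
#' @param dr a [dose_response()].
#' @return numeric vector of relative risks.
#' @export
individual_rr <- function(total_mmeth, dr = default_dose_response()) {
  if (any(total_mmeth < 0)) {
    abort("exposure (MMETh/week) must be non-negative", "cycleimpacts_validation_error")
  }
  stats::approx(dr$exposure, dr$rr, xout = total_mmeth, rule = 2)$y
}

#' Population impact fraction for one stratum
#'
#' `PIF = 1 - sum(w * rr_scenario) / sum(w * rr_baseline)` over the
#' stratum's persons, using individual-level exposures on the nonlinear
#' dose-response. Identical profiles give exactly 0; the PIF is
#' positive whenever scenario activity is higher.
#'
#' @param baseline,scenario [activity_profiles()] rows for the same set
#'   of persons.
#' @param dr a [dose_response()].
#' @param weights optional named weights by `person_id` (default unit).
#' @return the PIF (scalar in `(-Inf, 1]`).
#' @export
stratum_pif <- function(baseline, scenario, dr = default_dose_response(),
                        weights = NULL) {
  if (nrow(baseline) == 0) {
    return(0)
  }
  if (!setequal(baseline$person_id, scenario$person_id) ||
    nrow(baseline) != nrow(scenario)) {
    abort("baseline and scenario profiles must cover the same persons",
      class = "cycleimpacts_validation_error"
    )
  }
  scenario <- scenario[match(baseline$person_id, scenario$person_id), , drop = FALSE]
  w <- if (is.null(weights)) rep(1, nrow(baseline)) else unname(weights[baseline$person_id])
  rr_b <- individual_rr(baseline$total_mmeth, dr)
  rr_s <- individual_rr(scenario$total_mmeth, dr)
  1 - sum(w * rr_s) / sum(w * rr_b)
}

#' Population impact fractions by burden stratum
#'
#' Computes the PIF within every geography x age-band x gender burden
#' cell (ages 20-79; persons aged 18-19 or 80+ are excluded from burden
#' attribution). Strata with no scenario persons get PIF 0.
#'
#' @param survey the baseline [travel_survey()] (for ages, genders,
#'   regions and weights).
#' @param baseline,scenario [activity_profiles()] for the same persons.
#' @param dr a [dose_response()].
#' @param geography geography label for the output (default the
#'   survey's).
#' @return data frame (`geography`, `age_band`, `gender`, `pif`, `n`).
#' @export
pif_by_stratum <- function(survey, baseline, scenario,
                           dr = default_dose_response(), geography = NULL) {
  persons <- survey$persons
  geography <- geography %||% survey$geography
  bb <- age_to_burden_band(persons$age)
  w <- stats::setNames(persons$survey_weight, persons$person_id)
  grid <- expand.grid(
    age_band = burden_age_bands(), gender = genders(),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  grid$geography <- geography
  grid$pif <- 0
  grid$n <- 0L
  for (i in seq_len(nrow(grid))) {
    ids <- persons$person_id[!is.na(bb) & bb == grid$age_band[i] &
      persons$gender == grid$gender[i]]
    if (length(ids) == 0) next
    b <- baseline[baseline$person_id %in% ids, , drop = FALSE]
    s <- scenario[scenario$person_id %in% ids, , drop = FALSE]
    grid$pif[i] <- stratum_pif(b, s, dr, weights = w)
    grid$n[i] <- length(ids)
  }
  grid[, c("geography", "age_band", "gender", "pif", "n")]
}

#' Apply population impact fractions to a burden table
#'
#' Absolute burden averted per stratum is `PIF x stratum YLL` (deaths
#' handled identically); the aggregate percentage is the burden-weighted
#' total over ages 20-79: `100 x sum(averted) / sum(yll)`.
#'
#' @param pifs data frame from [pif_by_stratum()] (or any table with
#'   `geography`, `age_band`, `gender`, `pif`). Burden strata lacking a
#'   PIF get 0.
#' @param burden a burden table ([generate_burden_table()] or
#'   same-schema data).
#' @return list with `by_stratum` (the burden table with `pif`,
#'   `yll_averted`, `deaths_averted` columns), `yll_averted`,
#'   `pct_yll_averted`, `deaths_averted`, `pct_deaths_averted`.
#' @export
yll_averted <- function(pifs, burden) {
  stopifnot(all(c("geography", "age_band", "gender", "yll") %in% names(burden)))
  key <- paste(burden$geography, burden$age_band, burden$gender)
  pkey <- paste(pifs$geography, pifs$age_band, pifs$gender)
  burden$pif <- pifs$pif[match(key, pkey)]
  burden$pif[is.na(burden$pif)] <- 0
  burden$yll_averted <- burden$pif * burden$yll
  burden$deaths_averted <- if ("deaths" %in% names(burden)) {
    burden$pif * burden$deaths
  } else {
    NA_real_
  }
  list(
    by_stratum = burden,
    yll_averted = sum(burden$yll_averted),
    pct_yll_averted = 100 * sum(burden$yll_averted) / sum(burden$yll),
    deaths_averted = sum(burden$deaths_averted),
    pct_deaths_averted = if ("deaths" %in% names(burden)) {
      100 * sum(burden$deaths_averted) / sum(burden$deaths)
    } else {
      NA_real_
    }
  )
}
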