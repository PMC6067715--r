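# Distance-band propensity estimation: the probability that a current
# cyclist cycles a trip of a given length, by age-band x gender stratum;
# cycling speeds; and the e-bike choice/propensity reference tables.

#' Distance bands
#'
#' Contiguous half-open trip-distance intervals `[lower, upper)` covering
#' `(0, Inf)`, over which switching propensity is taken as constant. The
#' default bands give resolution where cycling is plausible and an
#' open-ended tail beyond 12 miles.
#'
#' @param breaks increasing numeric vector of band edges in miles,
#'   starting at 0 and ending at `Inf`.
#' @return data frame (`lower`, `upper`) of class `distance_bands`.
#' @export
distance_bands <- function(breaks = c(0, 1, 2, 3, 5, 8, 12, Inf)) {
  stopifnot(is.numeric(breaks), length(breaks) >= 2)
  if (breaks[1] != 0 || !is.infinite(breaks[length(breaks)]) || is.unsorted(breaks, strictly = TRUE)) {
    abort(
      "distance band breaks must start at 0, be strictly increasing and end at Inf",
      "cycleimpacts_config_error"
    )
  }
  structure(
    data.frame(lower = breaks[-length(breaks)], upper = breaks[-1]),
    class = c("distance_bands", "data.frame")
  )
}

#' Band index of a trip distance
#'
#' @param distance numeric vector of distances (miles, > 0).
#' @param bands a [distance_bands()] table.
#' @return integer vector of band row indices.
#' @export
band_index <- function(distance, bands) {
  findInterval(distance, c(bands$lower, Inf), left.open = FALSE)
}

band_label <- function(bands) {
  sprintf("[%g,%s)", bands$lower, ifelse(is.infinite(bands$upper), "Inf", bands$upper))
}

#' Estimate cycling propensity by distance band and stratum
#'
#' For each age-band x gender stratum and distance band, the
#' survey-weighted share of current cyclists' trips in that band that
#' are actually cycled:
#' `p_cycle = cycled trips in band / all trips in band`, among the
#' stratum's current cyclists. Cells supported by fewer than
#' `min_support` trips fall back to the band's all-strata pooled
#' estimate (flagged in the `pooled` column); bands with no cyclist
#' trips anywhere get 0 with a warning.
#'
#' @param survey a [travel_survey()] containing at least one current
#'   cyclist.
#' @param bands a [distance_bands()] table.
#' @param strata_age_bands age bands defining the strata (default the
#'   three uptake bands; ages 80+ are excluded from uptake).
#' @param min_support minimum unweighted trip count for a cell to use
#'   its own estimate (default 30).
#' @return data frame of class `propensity_table` with columns
#'   `age_band`, `gender`, `band_lower_miles`, `band_upper_miles`,
#'   `p_cycle`, `n_trips`, `pooled`.
#' @export
estimate_propensity <- function(survey, bands = distance_bands(),
                                strata_age_bands = uptake_age_bands(),
                                min_support = 30L) {
  stopifnot(inherits(survey, "travel_survey"))
  cyclists <- classify_current_cyclists(survey)
  if (length(cyclists) == 0) {
    abort("survey contains no current cyclists; propensity cannot be estimated",
      class = "cycleimpacts_estimation_error"
    )
  }
  persons <- survey$persons
  trips <- survey$trips[survey$trips$person_id %in% cyclists, , drop = FALSE]
  pidx <- match(trips$person_id, persons$person_id)
  trips$age_band <- persons$age_band[pidx]
  trips$gender <- persons$gender[pidx]
  trips$w <- persons$survey_weight[pidx]
  trips <- trips[trips$age_band %in% strata_age_bands, , drop = FALSE]
  trips$band <- band_index(trips$distance_miles, bands)
  trips$cycled <- trips$main_mode %in% cycling_modes()

  grid <- expand.grid(
    age_band = strata_age_bands, gender = genders(),
    band = seq_len(nrow(bands)),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  cell_key <- paste(trips$age_band, trips$gender, trips$band)
  grid_key <- paste(grid$age_band, grid$gender, grid$band)
  num <- tapply(trips$w * trips$cycled, cell_key, sum)
  den <- tapply(trips$w, cell_key, sum)
  cnt <- tapply(rep(1L, nrow(trips)), cell_key, sum)
  grid$wt_cycled <- unname(num[match(grid_key, names(num))])
  grid$wt_all <- unname(den[match(grid_key, names(den))])
  grid$n_trips <- unname(cnt[match(grid_key, names(cnt))])
  grid$wt_cycled[is.na(grid$wt_cycled)] <- 0
  grid$wt_all[is.na(grid$wt_all)] <- 0
  grid$n_trips[is.na(grid$n_trips)] <- 0L

  band_f <- factor(grid$band, levels = seq_len(nrow(bands)))
  pool_num <- tapply(grid$wt_cycled, band_f, sum)
  pool_den <- tapply(grid$wt_all, band_f, sum)
  pooled_p <- ifelse(pool_den > 0, pool_num / pool_den, NA_real_)
  if (anyNA(pooled_p)) {
    warning(sprintf(
      "no cyclist trips observed in band(s) %s; propensity set to 0 there",
      paste(band_label(bands)[is.na(pooled_p)], collapse = ", ")
    ))
    pooled_p[is.na(pooled_p)] <- 0
  }

  own_p <- ifelse(grid$wt_all > 0, grid$wt_cycled / grid$wt_all, NA_real_)
  use_pooled <- grid$n_trips < min_support | is.na(own_p)
  grid$p_cycle <- ifelse(use_pooled, pooled_p[grid$band], own_p)
  grid$pooled <- use_pooled

  out <- data.frame(
    age_band = grid$age_band, gender = grid$gender,
    band_lower_miles = bands$lower[grid$band],
    band_upper_miles = bands$upper[grid$band],
    p_cycle = grid$p_cycle, n_trips = grid$n_trips, pooled = grid$pooled
  )
  out <- out[order(out$age_band, out$gender, out$band_lower_miles), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
    class = c("propensity_table", "data.frame"),
    bands = bands
  )
}

#' Pooled (all-strata) propensity by band
#'
#' Ratio-of-sums pooled estimate per distance band from a
#' `propensity_table`'s un-pooled cells; equals the support-weighted
#' average of the stratum propensities.
#'
#' @param survey,bands,strata_age_bands as in [estimate_propensity()].
#' @return data frame (`band_lower_miles`, `band_upper_miles`,
#'   `p_cycle`, `n_trips`).
#' @export
pooled_propensity <- function(survey, bands = distance_bands(),
                              strata_age_bands = uptake_age_bands()) {
  tab <- estimate_propensity(survey, bands, strata_age_bands, min_support = 0L)
  # reconstruct weighted cells: with min_support = 0 every cell with
  # trips uses its own ratio, so pooling is exact ratio-of-sums
  cyclists <- classify_current_cyclists(survey)
  persons <- survey$persons
  trips <- survey$trips[survey$trips$person_id %in% cyclists, , drop = FALSE]
  pidx <- match(trips$person_id, persons$person_id)
  keep <- persons$age_band[pidx] %in% strata_age_bands
  trips <- trips[keep, , drop = FALSE]
  w <- persons$survey_weight[match(trips$person_id, persons$person_id)]
  b <- band_index(trips$distance_miles, bands)
  cycled <- trips$main_mode %in% cycling_modes()
  num <- tapply(w * cycled, factor(b, seq_len(nrow(bands))), sum)
  den <- tapply(w, factor(b, seq_len(nrow(bands))), sum)
  n <- tapply(rep(1L, nrow(trips)), factor(b, seq_len(nrow(bands))), sum)
  data.frame(
    band_lower_miles = bands$lower,
    band_upper_miles = bands$upper,
    p_cycle = ifelse(!is.na(den) & den > 0, num / den, 0),
    n_trips = ifelse(is.na(n), 0L, n)
  )
}

#' Estimate cycling speeds by stratum
#'
#' Stratum mean cycling speed as a weighted ratio of sums: total cycled
#' miles over total cycled hours among the stratum's cycle trips. Strata
#' with no cycle trips fall back to the all-strata pooled speed, then to
#' `default_speed_mph` with a warning. E-bike speed is taken from the
#' reference configuration, constant across strata, not estimated.
#'
#' @param survey a [travel_survey()].
#' @param strata_age_bands age bands defining the strata.
#' @param ebike_speed_mph e-bike speed to attach (default 9.5).
#' @param default_speed_mph fallback traditional-bike speed when the
#'   survey has no usable cycle trips (default 8).
#' @return data frame of class `speed_table` with columns `age_band`,
#'   `gender`, `mode`, `speed_mph`.
#' @export
estimate_speeds <- function(survey, strata_age_bands = uptake_age_bands(),
                            ebike_speed_mph = 9.5, default_speed_mph = 8) {
  stopifnot(inherits(survey, "travel_survey"))
  persons <- survey$persons
  trips <- survey$trips[survey$trips$main_mode == "cycle", , drop = FALSE]
  pidx <- match(trips$person_id, persons$person_id)
  trips$age_band <- persons$age_band[pidx]
  trips$gender <- persons$gender[pidx]
  trips$w <- persons$survey_weight[pidx]
  trips <- trips[trips$age_band %in% strata_age_bands, , drop = FALSE]

  grid <- expand.grid(
    age_band = strata_age_bands, gender = genders(),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  key <- paste(trips$age_band, trips$gender)
  gkey <- paste(grid$age_band, grid$gender)
  miles <- tapply(trips$w * trips$distance_miles, key, sum)
  hours <- tapply(trips$w * trips$duration_min / 60, key, sum)
  grid$miles <- unname(miles[match(gkey, names(miles))])
  grid$hours <- unname(hours[match(gkey, names(hours))])

  pooled <- if (nrow(trips) > 0 && sum(trips$w * trips$duration_min) > 0) {
    sum(trips$w * trips$distance_miles) / sum(trips$w * trips$duration_min / 60)
  } else {
    NA_real_
  }
  speed <- ifelse(!is.na(grid$hours) & grid$hours > 0, grid$miles / grid$hours, pooled)
  if (anyNA(speed)) {
    warning(sprintf(
      "no cycle trips available for speed estimation; using default %g mph",
      default_speed_mph
    ))
    speed[is.na(speed)] <- default_speed_mph
  } else if (any(is.na(grid$hours) | grid$hours == 0)) {
    warning("some strata have no cycle trips; pooled speed used there")
  }

  out <- rbind(
    data.frame(
      age_band = grid$age_band, gender = grid$gender,
      mode = "cycle", speed_mph = speed
    ),
    data.frame(
      age_band = grid$age_band, gender = grid$gender,
      mode = "ebike", speed_mph = ebike_speed_mph
    )
  )
  rownames(out) <- NULL
  structure(out, class = c("speed_table", "data.frame"))
}

#' Look up a speed for a mode and stratum
#'
#' @param speeds a `speed_table`.
#' @param mode `"cycle"` or `"ebike"` (vectorised).
#' @param age_band,gender stratum fields (vectorised).
#' @return numeric speeds in mph.
#' @export
lookup_speed <- function(speeds, mode, age_band, gender) {
  key <- paste(mode, age_band, gender)
  skey <- paste(speeds$mode, speeds$age_band, speeds$gender)
  out <- speeds$speed_mph[match(key, skey)]
  if (anyNA(out)) {
    abort(
      sprintf("speed table lacks entries for: %s", id_list(unique(key[is.na(out)]))),
      "cycleimpacts_estimation_error"
    )
  }
  out
}

#' Build e-bike choice and propensity tables
#'
#' Either validates a supplied [ebike_reference()] or estimates the two
#' per-band tables from an e-bike-recording (Dutch-style) travel survey:
#' among e-bike owners (persons with at least one e-bike trip),
#' `choice_prob_by_band` is P(e-bike | cycled trip) and
#' `ebike_propensity_by_band` is P(cycled | trip in band). Both are flat
#' across age/gender strata; trips beyond the last band carry the last
#' band's values.
#'
#' @param reference an `ebike_reference`, or `NULL` to estimate from
#'   `survey`.
#' @param survey a `travel_survey` recording `ebike` as a mode.
#' @param bands a [distance_bands()] table.
#' @return an `ebike_reference`.
#' @export
build_ebike_tables <- function(reference = NULL, survey = NULL,
                               bands = distance_bands()) {
  if (!is.null(reference)) {
    probs <- c(reference$choice_prob_by_band, reference$ebike_propensity_by_band,
      reference$own_both_share %||% 0.53)
    if (any(probs < 0 | probs > 1)) {
      abort(
        "e-bike reference probabilities must lie in [0, 1]",
        "cycleimpacts_validation_error"
      )
    }
    if (length(reference$choice_prob_by_band) != nrow(bands) ||
      length(reference$ebike_propensity_by_band) != nrow(bands)) {
      abort(
        "e-bike reference tables must have one entry per distance band",
        "cycleimpacts_validation_error"
      )
    }
    reference$bands <- bands
    class(reference) <- "ebike_reference"
    return(reference)
  }
  stopifnot(inherits(survey, "travel_survey"))
  owners <- unique(survey$trips$person_id[survey$trips$main_mode == "ebike"])
  if (length(owners) == 0) {
    abort(
      "survey contains no e-bike trips; supply the e-bike reference tables directly",
      "cycleimpacts_estimation_error"
    )
  }
  trips <- survey$trips[survey$trips$person_id %in% owners, , drop = FALSE]
  b <- factor(band_index(trips$distance_miles, bands), seq_len(nrow(bands)))
  cycled <- trips$main_mode %in% cycling_modes()
  is_eb <- trips$main_mode == "ebike"
  n_cycled <- tapply(cycled, b, sum)
  n_eb <- tapply(is_eb, b, sum)
  n_all <- tapply(rep(1L, nrow(trips)), b, sum)
  choice <- ifelse(!is.na(n_cycled) & n_cycled > 0, n_eb / n_cycled, NA_real_)
  prop <- ifelse(!is.na(n_all) & n_all > 0, n_cycled / n_all, NA_real_)
  # carry last observed value into empty tail bands (open-ended contract)
  for (i in seq_along(choice)) {
    if (i > 1 && is.na(choice[i])) choice[i] <- choice[i - 1]
    if (i > 1 && is.na(prop[i])) prop[i] <- prop[i - 1]
  }
  choice[is.na(choice)] <- 0.5
  prop[is.na(prop)] <- 0
  structure(
    list(
      own_both_share = mean(tapply(trips$main_mode == "cycle", trips$person_id, any)),
      choice_prob_by_band = unname(choice),
      ebike_propensity_by_band = unname(prop),
      ebike_speed_mph = 9.5,
      bands = bands
    ),
    class = "ebike_reference"
  )
}

#' Serialise estimation tables to CSV
#'
#' @param x a `propensity_table`, `speed_table` or `ebike_reference`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  if (inherits(x, "ebike_reference")) {
    x <- data.frame(
      band_lower_miles = x$bands$lower,
      band_upper_miles = x$bands$upper,
      choice_prob = x$choice_prob_by_band,
      ebike_propensity = x$ebike_propensity_by_band,
      own_both_share = x$own_both_share,
      ebike_speed_mph = x$ebike_speed_mph
    )
  }
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a propensity table written by [write_table_csv()]
#' @param path CSV path.
#' @return a `propensity_table`.
#' @export
read_propensity_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  breaks <- sort(unique(c(tab$band_lower_miles, Inf)))
  structure(tab,
    class = c("propensity_table", "data.frame"),
    bands = distance_bands(breaks)
  )
}

#' Read an e-bike reference written by [write_table_csv()]
#' @param path CSV path.
#' @return an `ebike_reference`.
#' @export
read_ebike_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  bands <- distance_bands(sort(unique(c(tab$band_lower_miles, Inf))))
  build_ebike_tables(
    reference = structure(
      list(
        own_both_share = tab$own_both_share[1],
        choice_prob_by_band = tab$choice_prob,
        ebike_propensity_by_band = tab$ebike_propensity,
        ebike_speed_mph = tab$ebike_speed_mph[1],
        bands = bands
      ),
      class = "ebike_reference"
    ),
    bands = bands
  )
}
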