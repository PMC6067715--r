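# Seeded generators for synthetic travel surveys, non-travel activity
# samples, e-bike reference tables and disease-burden tables. These
# emulate the statistical structure of the restricted survey inputs
# (stratum-specific cyclist prevalence, per-mode distance distributions,
# trips-per-person counts, non-travel activity marginals) so the whole
# pipeline is runnable and testable end to end.

english_regions <- function() {
  c(
    "North East", "North West", "Yorkshire and the Humber",
    "East Midlands", "West Midlands", "East of England",
    "London", "South East", "South West"
  )
}

#' Default baseline cyclist prevalence by region
#'
#' Regional baseline prevalences used by the synthetic generator and the
#' scenario enumeration examples. The North East (3.1%) and South West
#' (6.1%) anchors are national-survey figures; the remainder are
#' illustrative, chosen so that exactly four regions fall below the 4%
#' threshold that gates the 5% scenario.
#'
#' @return named numeric vector of proportions, including `"England"`.
#' @export
default_region_baselines <- function() {
  c(
    "England" = 0.048,
    "North East" = 0.031,
    "West Midlands" = 0.035,
    "Yorkshire and the Humber" = 0.036,
    "East Midlands" = 0.039,
    "North West" = 0.046,
    "London" = 0.049,
    "East of England" = 0.053,
    "South East" = 0.055,
    "South West" = 0.061
  )
}

#' Default cyclist prevalence by age band and gender
#'
#' National-survey baseline shares of adults reporting at least one
#' cycle trip per week: 8.4% for males and 3.7% for females aged 18-59,
#' 4.4% for males and 1.6% for females aged 60-79; 0 for ages 80+
#' (excluded from uptake).
#'
#' @return data frame with columns `age_band`, `gender`, `prevalence`.
#' @export
default_cyclist_prevalence <- function() {
  data.frame(
    age_band = rep(age_bands(), each = 2),
    gender = rep(genders(), times = 4),
    prevalence = c(
      0.084, 0.037, # 18-39
      0.084, 0.037, # 40-59
      0.044, 0.016, # 60-79
      0.000, 0.000 # 80+
    )
  )
}

default_mode_share <- function() {
  c(
    walk = 0.220, cycle = 0.017, ebike = 0.000,
    car_driver = 0.527, car_passenger = 0.144,
    bus = 0.060, rail = 0.025, other = 0.007
  )
}

default_distance_params <- function() {
  # lognormal (meanlog, sdlog) of trip distance in miles, per mode
  data.frame(
    mode = main_modes(),
    meanlog = log(c(0.5, 2.0, 3.0, 5.0, 5.0, 3.0, 10.0, 4.0)),
    sdlog = c(0.8, 0.8, 0.8, 1.1, 1.1, 0.9, 0.9, 1.0)
  )
}

default_speeds_mph <- function() {
  c(
    walk = 3, cycle = 8, ebike = 9.5, car_driver = 24, car_passenger = 24,
    bus = 12, rail = 22, other = 20
  )
}

#' Configuration for the synthetic population generator
#'
#' Collects the demographic composition, cyclist prevalences, trip-rate
#' and per-mode distance/speed assumptions from which
#' [generate_population()] draws a travel survey.
#'
#' @param n_persons number of adults to generate.
#' @param regions region labels; persons are spread over them by
#'   `region_shares`.
#' @param region_shares proportions over `regions` (default uniform).
#' @param age_shares named proportions over the four age bands.
#' @param gender_shares named proportions over male/female.
#' @param ethnicity_shares named proportions over white/non-white.
#' @param cyclist_prevalence data frame (`age_band`, `gender`,
#'   `prevalence`) of baseline current-cyclist shares; defaults to
#'   [default_cyclist_prevalence()].
#' @param region_prevalence_scale optional named multiplier on the
#'   stratum prevalences per region (so regional baselines can differ);
#'   defaults to `default_region_baselines()` scaled by the England
#'   baseline.
#' @param trips_per_person_mean Poisson mean weekly trip count.
#' @param mode_share named trip-share vector over the eight main modes
#'   (must sum to 1). The cycle share is realised by concentrating cycle
#'   trips in the flagged cyclists.
#' @param distance_params per-mode lognormal (meanlog, sdlog) of trip
#'   distance in miles.
#' @param speeds_mph named per-mode mean speeds used to derive
#'   durations.
#' @param duration_sdlog lognormal noise (sdlog) multiplying the
#'   distance/speed duration.
#' @param decay_intercept,decay_slope parameters of the internal
#'   logistic distance-decay rule `plogis(intercept - slope * log(d))`
#'   by which flagged cyclists cycle a subset of their trips; the slope
#'   makes shorter trips more likely to be cycled, giving the propensity
#'   estimator real structure to recover.
#' @param car_access_prob probability a person has household car access.
#' @param nssec_levels socioeconomic class labels.
#' @param seed integer seed; the generator is a pure function of
#'   `(config, seed)`.
#' @return an object of class `population_config`.
#' @export
population_config <- function(n_persons = 10000L,
                              regions = "England",
                              region_shares = NULL,
                              age_shares = c("18-39" = 0.36, "40-59" = 0.34, "60-79" = 0.24, "80+" = 0.06),
                              gender_shares = c(male = 0.5, female = 0.5),
                              ethnicity_shares = c(white = 0.86, "non-white" = 0.14),
                              cyclist_prevalence = default_cyclist_prevalence(),
                              region_prevalence_scale = NULL,
                              trips_per_person_mean = 14,
                              mode_share = default_mode_share(),
                              distance_params = default_distance_params(),
                              speeds_mph = default_speeds_mph(),
                              duration_sdlog = 0.15,
                              decay_intercept = 1.0,
                              decay_slope = 1.3,
                              car_access_prob = 0.8,
                              nssec_levels = c(
                                "managerial_professional", "intermediate",
                                "routine_manual", "never_worked"
                              ),
                              seed = 1L) {
  region_shares <- region_shares %||% stats::setNames(
    rep(1 / length(regions), length(regions)), regions
  )
  if (is.null(region_prevalence_scale)) {
    rb <- default_region_baselines()
    region_prevalence_scale <- stats::setNames(
      ifelse(regions %in% names(rb), rb[regions] / rb[["England"]], 1),
      regions
    )
  }
  cfg <- structure(
    list(
      n_persons = as.integer(n_persons), regions = regions,
      region_shares = region_shares, age_shares = age_shares,
      gender_shares = gender_shares, ethnicity_shares = ethnicity_shares,
      cyclist_prevalence = cyclist_prevalence,
      region_prevalence_scale = region_prevalence_scale,
      trips_per_person_mean = trips_per_person_mean,
      mode_share = mode_share, distance_params = distance_params,
      speeds_mph = speeds_mph, duration_sdlog = duration_sdlog,
      decay_intercept = decay_intercept, decay_slope = decay_slope,
      car_access_prob = car_access_prob, nssec_levels = nssec_levels,
      seed = as.integer(seed)
    ),
    class = "population_config"
  )
  validate_population_config(cfg)
  cfg
}

validate_population_config <- function(cfg) {
  stopifnot(cfg$n_persons >= 0)
  for (nm in c("region_shares", "age_shares", "gender_shares", "ethnicity_shares")) {
    s <- cfg[[nm]]
    if (abs(sum(s) - 1) > 1e-9 || any(s < 0)) {
      abort(sprintf("%s must be non-negative and sum to 1", nm), "cycleimpacts_config_error")
    }
  }
  if (abs(sum(cfg$mode_share) - 1) > 1e-9 || any(cfg$mode_share < 0)) {
    abort("mode_share must be non-negative and sum to 1", "cycleimpacts_config_error")
  }
  prev <- cfg$cyclist_prevalence$prevalence
  if (any(prev < 0 | prev > 1)) {
    abort("cyclist prevalences must lie in [0, 1]", "cycleimpacts_config_error")
  }
  # feasibility: all cycle trips must be attributable to flagged cyclists
  m <- merge(
    expand.grid(
      age_band = names(cfg$age_shares), gender = names(cfg$gender_shares),
      stringsAsFactors = FALSE
    ),
    cfg$cyclist_prevalence,
    by = c("age_band", "gender")
  )
  overall_prev <- sum(
    cfg$age_shares[m$age_band] * cfg$gender_shares[m$gender] * m$prevalence
  ) * max(cfg$region_prevalence_scale %||% 1)
  cycle_share <- cfg$mode_share[["cycle"]] + cfg$mode_share[["ebike"]]
  if (cycle_share > overall_prev) {
    abort(
      sprintf(
        "infeasible config: cycle+ebike mode share (%.3f) exceeds the share of trips made by flagged cyclists (~%.3f)",
        cycle_share, overall_prev
      ),
      "cycleimpacts_config_error"
    )
  }
  invisible(cfg)
}

#' Generate a synthetic travel survey
#'
#' Draws persons from the configured demographic composition, flags
#' current cyclists per stratum prevalence, draws Poisson trip counts,
#' per-mode lognormal distances and speed-based durations, and assigns
#' cycle trips to flagged cyclists through a logistic distance-decay
#' rule so that (a) the overall cycle mode share matches the config in
#' expectation and (b) cyclists cycle a distance-decaying subset of
#' their trips, as real diaries show. Deterministic given
#' `config$seed`.
#'
#' @param config a [population_config()].
#' @return a validated [travel_survey()].
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "population_config"))
  with_seed(config$seed, {
    n <- config$n_persons
    geo <- if (length(config$regions) == 1) config$regions else "all"
    if (n == 0) {
      persons <- data.frame(
        person_id = character(0), age = integer(0), gender = character(0),
        ethnicity = character(0), nssec = character(0), car_access = logical(0),
        region = character(0), survey_weight = numeric(0)
      )
      trips <- data.frame(
        trip_id = character(0), person_id = character(0), main_mode = character(0),
        distance_miles = numeric(0), duration_min = numeric(0), day_index = integer(0),
        purpose = character(0), pt_walk_minutes = numeric(0),
        replicate_of = character(0)
      )
      return(travel_survey(persons, trips, geography = geo))
    }

    band <- sample(names(config$age_shares), n, replace = TRUE, prob = config$age_shares)
    age_lo <- c("18-39" = 18, "40-59" = 40, "60-79" = 60, "80+" = 80)[band]
    age_hi <- c("18-39" = 39, "40-59" = 59, "60-79" = 79, "80+" = 94)[band]
    persons <- data.frame(
      person_id = sprintf("p%06d", seq_len(n)),
      age = as.integer(age_lo + floor(stats::runif(n) * (age_hi - age_lo + 1))),
      gender = sample(names(config$gender_shares), n, replace = TRUE, prob = config$gender_shares),
      ethnicity = sample(names(config$ethnicity_shares), n, replace = TRUE, prob = config$ethnicity_shares),
      nssec = sample(config$nssec_levels, n, replace = TRUE),
      car_access = stats::runif(n) < config$car_access_prob,
      region = sample(config$regions, n, replace = TRUE, prob = config$region_shares),
      survey_weight = 1.0
    )
    persons$age_band <- age_to_band(persons$age)

    prev_tab <- config$cyclist_prevalence
    key <- paste(persons$age_band, persons$gender)
    prev <- prev_tab$prevalence[match(key, paste(prev_tab$age_band, prev_tab$gender))]
    prev <- prev * config$region_prevalence_scale[persons$region]
    prev[is.na(prev)] <- 0
    is_cyclist <- stats::runif(n) < pmin(prev, 1)

    # trips: Poisson counts, modes drawn from the non-cycle share for
    # everyone; cycle/ebike trips are then carved out of cyclists' trips
    n_trips <- stats::rpois(n, config$trips_per_person_mean)
    total <- sum(n_trips)
    owner <- rep(seq_len(n), n_trips)
    share <- config$mode_share
    non_cycle <- share[setdiff(names(share), cycling_modes())]
    non_cycle <- non_cycle / sum(non_cycle)
    mode <- sample(names(non_cycle), total, replace = TRUE, prob = non_cycle)

    dp <- config$distance_params
    mi <- match(mode, dp$mode)
    distance <- pmax(0.1, stats::rlnorm(total, dp$meanlog[mi], dp$sdlog[mi]))

    # logistic distance-decay: flagged cyclists cycle shorter trips
    # preferentially; the scale factor pins the expected cycle trip
    # count to the configured mode share
    cyclist_trip <- is_cyclist[owner]
    target_cycling <- (share[["cycle"]] + share[["ebike"]]) * total
    cycled <- rep(FALSE, total)
    if (target_cycling > 0 && any(cyclist_trip)) {
      w <- stats::plogis(config$decay_intercept - config$decay_slope * log(distance))
      w[!cyclist_trip] <- 0
      s <- target_cycling / sum(w)
      p <- pmin(1, s * w)
      cycled <- stats::runif(total) < p
    }
    mode[cycled] <- "cycle"
    if (share[["ebike"]] > 0 && any(cycled)) {
      eb_frac <- share[["ebike"]] / (share[["cycle"]] + share[["ebike"]])
      eb <- cycled & stats::runif(total) < eb_frac
      mode[eb] <- "ebike"
    }

    speed <- config$speeds_mph[mode]
    duration <- distance / speed * 60 * stats::rlnorm(total, 0, config$duration_sdlog)
    duration <- pmax(duration, 1)

    trips <- data.frame(
      trip_id = sprintf("t%07d", seq_len(total)),
      person_id = persons$person_id[owner],
      main_mode = mode,
      distance_miles = distance,
      duration_min = duration,
      day_index = sample(1:7, total, replace = TRUE),
      purpose = sample(c("commute", "shopping", "leisure", "personal_business"),
        total,
        replace = TRUE, prob = c(0.25, 0.3, 0.3, 0.15)
      ),
      pt_walk_minutes = 0,
      replicate_of = NA_character_
    )
    # embedded walking for public-transport trips (walk ~ 15% of door-to-
    # door time, capped)
    is_pt <- trips$main_mode %in% pt_modes()
    trips$pt_walk_minutes[is_pt] <- pmin(
      trips$duration_min[is_pt] * 0.15 * stats::rlnorm(sum(is_pt), 0, 0.3),
      trips$duration_min[is_pt]
    )
    travel_survey(persons, trips, geography = geo)
  })
}

#' Generate a synthetic non-travel activity sample
#'
#' Gamma-distributed non-travel marginal MET-hours per week per
#' age-band x gender stratum, standing in for a cross-sectional activity
#' survey.
#'
#' @param n records per stratum.
#' @param gamma_params data frame (`age_band`, `gender`, `shape`,
#'   `scale`); defaults give a realistic right-skewed distribution with
#'   stratum means declining with age.
#' @param seed integer seed.
#' @return data frame (`age_band`, `gender`, `nontravel_mmeth`,
#'   `weight`) of class `nontravel_activity_sample`.
#' @export
generate_activity_survey <- function(n = 1000L,
                                     gamma_params = default_activity_params(),
                                     seed = 1L) {
  stopifnot(all(c("age_band", "gender", "shape", "scale") %in% names(gamma_params)))
  if (any(gamma_params$shape <= 0) || any(gamma_params$scale <= 0)) {
    abort("gamma shape and scale must be positive", "cycleimpacts_config_error")
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(gamma_params)), function(i) {
      g <- gamma_params[i, ]
      data.frame(
        age_band = g$age_band, gender = g$gender,
        nontravel_mmeth = stats::rgamma(n, shape = g$shape, scale = g$scale),
        weight = 1.0
      )
    }))
    rownames(out) <- NULL
    class(out) <- c("nontravel_activity_sample", "data.frame")
    out
  })
}

#' @rdname generate_activity_survey
#' @export
default_activity_params <- function() {
  data.frame(
    age_band = rep(age_bands(), each = 2),
    gender = rep(genders(), times = 4),
    shape = rep(c(1.2, 1.2, 1.0, 0.8), each = 2),
    scale = c(7.5, 6.5, 7.0, 6.0, 5.5, 4.5, 3.0, 2.5)
  )
}

#' Generate a synthetic disease-burden table
#'
#' Converts years-of-life-lost (and death) rates per 100,000 into
#' absolute stratum burdens: `yll = rate x population / 1e5`.
#'
#' @param geographies character vector of geography labels.
#' @param rates data frame (`age_band`, `gender`, `yll_per_100k`,
#'   `deaths_per_100k`); defaults are illustrative all-cause burden
#'   rates rising steeply with age.
#' @param populations data frame (`geography`, `age_band`, `gender`,
#'   `population`), or a single total population per geography spread
#'   by the default age/gender composition.
#' @return data frame (`geography`, `age_band`, `gender`, `yll`,
#'   `deaths`) of class `burden_table`, age bands 20-39/40-59/60-79.
#' @export
generate_burden_table <- function(geographies = "England",
                                  rates = default_burden_rates(),
                                  populations = 1e6) {
  stopifnot(all(c("age_band", "gender", "yll_per_100k", "deaths_per_100k") %in% names(rates)))
  if (any(rates$yll_per_100k < 0) || any(rates$deaths_per_100k < 0)) {
    abort("burden rates must be non-negative", "cycleimpacts_validation_error")
  }
  if (is.numeric(populations)) {
    comp <- c("20-39" = 0.38, "40-59" = 0.36, "60-79" = 0.26)
    populations <- do.call(rbind, lapply(geographies, function(g) {
      data.frame(
        geography = g,
        age_band = rep(names(comp), each = 2),
        gender = rep(genders(), times = 3),
        population = rep(comp, each = 2) / 2 * populations[[1]]
      )
    }))
  }
  if (any(populations$population < 0)) {
    abort("populations must be non-negative", "cycleimpacts_validation_error")
  }
  tab <- merge(populations, rates, by = c("age_band", "gender"))
  tab$yll <- tab$yll_per_100k * tab$population / 1e5
  tab$deaths <- tab$deaths_per_100k * tab$population / 1e5
  tab <- tab[order(tab$geography, tab$age_band, tab$gender),
    c("geography", "age_band", "gender", "yll", "deaths"),
    drop = FALSE
  ]
  rownames(tab) <- NULL
  class(tab) <- c("burden_table", "data.frame")
  tab
}

#' @rdname generate_burden_table
#' @export
default_burden_rates <- function() {
  data.frame(
    age_band = rep(burden_age_bands(), each = 2),
    gender = rep(genders(), times = 3),
    yll_per_100k = c(4500, 2500, 9000, 6000, 28000, 20000),
    deaths_per_100k = c(90, 45, 350, 230, 1900, 1300)
  )
}

#' Default e-bike reference tables
#'
#' Stand-in for the Dutch-survey-derived e-bike reference: the share of
#' e-bike owners who also own a traditional bike (53%), the per-band
#' probability that a cycled trip is made by e-bike rather than
#' traditional bike (rising with distance), and the per-band cycling
#' propensity of e-bike owners (a flatter distance decay than
#' traditional-bike cyclists). Values other than the 53% ownership
#' share are illustrative.
#'
#' @param bands a [distance_bands()] table.
#' @param ebike_speed_mph e-bike mean speed (default 9.5 mph).
#' @return list of class `ebike_reference` with elements
#'   `own_both_share`, `choice_prob_by_band`, `ebike_propensity_by_band`,
#'   `ebike_speed_mph`, `bands`.
#' @export
ebike_reference <- function(bands = distance_bands(), ebike_speed_mph = 9.5) {
  nb <- nrow(bands)
  choice <- c(0.25, 0.32, 0.38, 0.45, 0.55, 0.65, 0.72)
  propensity <- c(0.50, 0.46, 0.42, 0.37, 0.30, 0.22, 0.12)
  structure(
    list(
      own_both_share = 0.53,
      choice_prob_by_band = rep_len(choice, nb),
      ebike_propensity_by_band = rep_len(propensity, nb),
      ebike_speed_mph = ebike_speed_mph,
      bands = bands
    ),
    class = "ebike_reference"
  )
}
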