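# Fixtures built in code: a minimal hand-written survey and helpers to
# construct synthetic populations and constant tables.

mini_persons <- function() {
  data.frame(
    person_id = c("a", "b", "c"),
    age = c(30L, 55L, 70L),
    gender = c("male", "female", "male"),
    ethnicity = c("white", "non-white", "white"),
    nssec = c("intermediate", "routine_manual", "managerial_professional"),
    car_access = c(TRUE, TRUE, FALSE),
    region = "England",
    survey_weight = c(1, 1, 1)
  )
}

mini_trips <- function() {
  data.frame(
    trip_id = c("t1", "t2", "t3", "t4"),
    person_id = c("a", "a", "b", "c"),
    main_mode = c("cycle", "car_driver", "bus", "walk"),
    distance_miles = c(2.0, 10.0, 5.0, 0.4),
    duration_min = c(15, 25, 40, 10),
    day_index = c(1L, 2L, 3L, 7L),
    purpose = c("commute", "shopping", "commute", "leisure"),
    pt_walk_minutes = c(0, 0, 8, 0)
  )
}

mini_stages <- function() {
  data.frame(
    stage_id = c("s1", "s2", "s3"),
    trip_id = c("t3", "t3", "t3"),
    mode = c("walk", "bus", "walk"),
    duration_min = c(5, 30, 3)
  )
}

make_mini_survey <- function(stages = FALSE) {
  travel_survey(mini_persons(), mini_trips(),
    stages = if (stages) mini_stages(),
    geography = "England"
  )
}

make_population <- function(n = 2000, seed = 1, ...) {
  generate_population(population_config(n_persons = n, seed = seed, ...))
}

# A propensity table with a constant probability everywhere (or one
# value per band, recycled across strata).
flat_propensity <- function(p, bands = distance_bands()) {
  grid <- expand.grid(
    age_band = uptake_age_bands(), gender = genders(),
    band = seq_len(nrow(bands)),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  p_band <- rep_len(p, nrow(bands))
  out <- data.frame(
    age_band = grid$age_band, gender = grid$gender,
    band_lower_miles = bands$lower[grid$band],
    band_upper_miles = bands$upper[grid$band],
    p_cycle = p_band[grid$band], n_trips = 1000L, pooled = FALSE
  )
  structure(out, class = c("propensity_table", "data.frame"), bands = bands)
}

flat_speeds <- function(cycle = 8, ebike = 9.5) {
  grid <- expand.grid(
    age_band = uptake_age_bands(), gender = genders(),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  structure(
    rbind(
      data.frame(age_band = grid$age_band, gender = grid$gender, mode = "cycle", speed_mph = cycle),
      data.frame(age_band = grid$age_band, gender = grid$gender, mode = "ebike", speed_mph = ebike)
    ),
    class = c("speed_table", "data.frame")
  )
}

# A survey of n single-trip adults, all in one stratum/band; useful for
# binomial switch-rate checks.
single_trip_population <- function(n, distance = 1.5, mode = "car_driver",
                                   duration = 10) {
  persons <- data.frame(
    person_id = sprintf("p%05d", seq_len(n)),
    age = 30L, gender = "male", ethnicity = "white",
    nssec = "intermediate", car_access = TRUE,
    region = "England", survey_weight = 1
  )
  trips <- data.frame(
    trip_id = sprintf("t%05d", seq_len(n)),
    person_id = persons$person_id,
    main_mode = mode, distance_miles = distance, duration_min = duration,
    day_index = 1L, purpose = "commute", pt_walk_minutes = 0
  )
  travel_survey(persons, trips)
}
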