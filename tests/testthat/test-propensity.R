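# Distance-band propensity, speed estimation and e-bike tables.

# Build a one-stratum survey with specified cycled flags, distances and
# weights: person-level weight equals each trip's weight (one trip per
# person keeps the weighting transparent).
propensity_fixture <- function(cycled, distance = 0.5, weights = NULL) {
  n <- length(cycled)
  weights <- weights %||% rep(1, n)
  persons <- data.frame(
    person_id = sprintf("p%03d", seq_len(n)), age = 30L, gender = "male",
    ethnicity = "white", nssec = "intermediate", car_access = TRUE,
    region = "England", survey_weight = weights
  )
  trips <- data.frame(
    trip_id = sprintf("t%03d", seq_len(n)), person_id = persons$person_id,
    main_mode = ifelse(cycled, "cycle", "car_driver"),
    distance_miles = distance, duration_min = 10, day_index = 1L,
    purpose = "commute", pt_walk_minutes = 0
  )
  # make every person a current cyclist by adding a marker cycle trip in
  # the last band, so non-cycled trips still count in the denominator
  marker <- data.frame(
    trip_id = sprintf("m%03d", seq_len(n)), person_id = persons$person_id,
    main_mode = "cycle", distance_miles = 50, duration_min = 300,
    day_index = 2L, purpose = "commute", pt_walk_minutes = 0
  )
  travel_survey(persons, rbind(trips, marker))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("cell propensity is the (weighted) cycled share of cyclists' trips", {
  # all 5 trips in band [0,1) cycled -> p = 1
  s <- propensity_fixture(rep(TRUE, 5))
  tab <- suppressWarnings(estimate_propensity(s, min_support = 0))
  cell <- tab[tab$age_band == "18-39" & tab$gender == "male" & tab$band_lower_miles == 0, ]
  expect_equal(cell$p_cycle, 1.0)
  expect_equal(cell$n_trips, 5L)

  # 3 cycled of 10 -> 0.3
  s2 <- propensity_fixture(rep(c(TRUE, FALSE), c(3, 7)))
  tab2 <- suppressWarnings(estimate_propensity(s2, min_support = 0))
  expect_equal(
    tab2$p_cycle[tab2$age_band == "18-39" & tab2$gender == "male" &
      tab2$band_lower_miles == 0],
    0.3
  )

  # weights (2,1,1) with the weight-2 trip cycled -> 2/4 = 0.5
  s3 <- propensity_fixture(c(TRUE, FALSE, FALSE), weights = c(2, 1, 1))
  tab3 <- suppressWarnings(estimate_propensity(s3, min_support = 0))
  expect_equal(
    tab3$p_cycle[tab3$age_band == "18-39" & tab3$gender == "male" &
      tab3$band_lower_miles == 0],
    0.5
  )
})

test_that("propensity requires current cyclists and fills empty bands", {
  s <- single_trip_population(10) # no cycle trips at all
  expect_error(estimate_propensity(s), class = "cycleimpacts_estimation_error")

  # cyclists exist but band [8,12) has no trips anywhere -> 0 + warning
  s2 <- propensity_fixture(c(TRUE, FALSE))
  expect_warning(tab <- estimate_propensity(s2, min_support = 0), regexp = "band")
  expect_true(all(tab$p_cycle[tab$band_lower_miles == 8] == 0))
})

test_that("low-support cells fall back to the pooled band estimate", {
  s <- make_population(n = 20000, seed = 3)
  tab_own <- estimate_propensity(s, min_support = 0)
  tab_fb <- estimate_propensity(s, min_support = 1e6) # force pooling everywhere
  pooled <- pooled_propensity(s)
  expect_true(all(tab_fb$pooled))
  for (b in unique(tab_fb$band_lower_miles)) {
    expect_equal(
      unique(tab_fb$p_cycle[tab_fb$band_lower_miles == b]),
      pooled$p_cycle[pooled$band_lower_miles == b],
      tolerance = 1e-12
    )
  }
  # pooling identity: support-weighted average of stratum propensities
  # equals the pooled ratio-of-sums (weights = cell denominators; unit
  # survey weights make denominators the trip counts)
  for (b in unique(tab_own$band_lower_miles)) {
    cells <- tab_own[tab_own$band_lower_miles == b & tab_own$n_trips > 0, ]
    expect_equal(
      sum(cells$p_cycle * cells$n_trips) / sum(cells$n_trips),
      pooled$p_cycle[pooled$band_lower_miles == b],
      tolerance = 1e-9
    )
  }
})

test_that("speeds are weighted ratios of sums with pooled/default fallback", {
  # one trip: 3 miles in 20 min -> 9 mph
  p <- data.frame(
    person_id = "a", age = 30L, gender = "male", ethnicity = "white",
    nssec = "intermediate", car_access = TRUE, region = "England",
    survey_weight = 1
  )
  t1 <- data.frame(
    trip_id = "t1", person_id = "a", main_mode = "cycle",
    distance_miles = 3, duration_min = 20, day_index = 1L,
    purpose = "commute", pt_walk_minutes = 0
  )
  sp <- suppressWarnings(estimate_speeds(travel_survey(p, t1)))
  expect_equal(
    sp$speed_mph[sp$age_band == "18-39" & sp$gender == "male" & sp$mode == "cycle"],
    9
  )

  # two trips (2 mi/10 min, 2 mi/30 min) -> ratio of sums 4/(40/60) = 6,
  # not the mean of 12 and 4
  t2 <- rbind(t1, t1)
  t2$trip_id <- c("t1", "t2")
  t2$distance_miles <- c(2, 2)
  t2$duration_min <- c(10, 30)
  sp2 <- suppressWarnings(estimate_speeds(travel_survey(p, t2)))
  expect_equal(
    sp2$speed_mph[sp2$age_band == "18-39" & sp2$gender == "male" & sp2$mode == "cycle"],
    6
  )
  # splitting a trip into two with the same totals leaves speed unchanged
  t3 <- rbind(t2, t2)
  t3$trip_id <- sprintf("t%d", 1:4)
  t3$distance_miles <- c(1, 1, 1, 1)
  t3$duration_min <- c(5, 5, 15, 15)
  sp3 <- suppressWarnings(estimate_speeds(travel_survey(p, t3)))
  expect_equal(sp3$speed_mph, sp2$speed_mph)

  # no cycle trips anywhere -> config default + warning
  s_none <- single_trip_population(5)
  expect_warning(sp4 <- estimate_speeds(s_none, default_speed_mph = 8), "default")
  expect_true(all(sp4$speed_mph[sp4$mode == "cycle"] == 8))
  expect_true(all(sp4$speed_mph[sp4$mode == "ebike"] == 9.5))
})

test_that("e-bike tables estimate choice and propensity per band", {
  # one band-[0,1) cell with 4 e-bike and 6 cycle trips among owners
  n <- 20
  persons <- data.frame(
    person_id = sprintf("p%02d", seq_len(2)), age = 40L, gender = "female",
    ethnicity = "white", nssec = "intermediate", car_access = TRUE,
    region = "NL", survey_weight = 1
  )
  trips <- data.frame(
    trip_id = sprintf("t%02d", seq_len(n)),
    person_id = rep_len(persons$person_id, n), # both persons own e-bikes
    main_mode = c(rep("ebike", 4), rep("cycle", 6), rep("car_driver", 10)),
    distance_miles = 0.5, duration_min = 6, day_index = 1L,
    purpose = "commute", pt_walk_minutes = 0
  )
  ref <- build_ebike_tables(survey = travel_survey(persons, trips, geography = "NL"))
  expect_equal(ref$choice_prob_by_band[1], 0.4) # 4 / (4 + 6)
  expect_equal(ref$ebike_propensity_by_band[1], 0.5) # 10 cycled of 20

  # supplied reference returned unchanged after validation
  ref2 <- ebike_reference()
  expect_equal(
    build_ebike_tables(reference = ref2)$choice_prob_by_band,
    ref2$choice_prob_by_band
  )
  # invalid probability rejected
  bad <- ebike_reference()
  bad$choice_prob_by_band[1] <- 1.2
  expect_error(build_ebike_tables(reference = bad), class = "cycleimpacts_validation_error")
  # survey without e-bike trips directs the user to supply the table
  expect_error(
    build_ebike_tables(survey = single_trip_population(5)),
    regexp = "supply", class = "cycleimpacts_estimation_error"
  )
})
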