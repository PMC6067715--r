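# Two-step scenario engine: quota conversion, trip switching,
# four-group partition and enumeration.

test_that("Step 1 converts an exact quota reaching the target prevalence", {
  s <- make_population(n = 5000, seed = 2)
  base <- baseline_prevalence(s)
  spec <- scenario_spec("England", 25, seed = 9)
  ids <- select_regular_cyclists(s, spec)
  expect_equal(length(ids), round((0.25 - base) * nrow(s$persons)))
  # converted persons are non-cyclists under 80
  cyc <- classify_current_cyclists(s)
  conv <- s$persons[s$persons$person_id %in% ids, ]
  expect_false(any(ids %in% cyc))
  expect_true(all(conv$age < 80))
  # achieved prevalence is exact
  achieved <- (length(cyc) + length(ids)) / nrow(s$persons)
  expect_equal(achieved, 0.25, tolerance = 1 / nrow(s$persons))
  # deterministic given seed
  expect_identical(ids, select_regular_cyclists(s, spec))
  expect_false(identical(ids, select_regular_cyclists(s, scenario_spec("England", 25, seed = 10))))
})

test_that("a target at or below baseline converts nobody, with a warning", {
  s <- make_population(n = 3000, seed = 4)
  # force baseline above 10% by making 400 distinct non-cyclists cycle
  non_cyc <- !s$trips$person_id %in% classify_current_cyclists(s)
  first_trip <- !duplicated(s$trips$person_id)
  idx <- which(non_cyc & first_trip)[1:400]
  s$trips$main_mode[idx] <- "cycle"
  s$trips$pt_walk_minutes[idx] <- 0
  expect_gt(baseline_prevalence(s), 0.10)
  expect_warning(
    ids <- select_regular_cyclists(s, scenario_spec("England", 10, seed = 1)),
    regexp = "does not exceed"
  )
  expect_length(ids, 0)
})

test_that("the 5% level is refused where baseline prevalence is 4% or more", {
  s <- make_population(n = 5000, seed = 6)
  expect_gte(baseline_prevalence(s), 0.04)
  expect_error(
    select_regular_cyclists(s, scenario_spec("England", 5, seed = 1)),
    class = "cycleimpacts_config_error"
  )
})

test_that("non-equity conversion follows baseline stratum prevalence ratios", {
  # toy population: two strata with 8% vs 2% baseline prevalence; the
  # expected converted-count ratio is 4:1; verified within 3 SE of the
  # weighted-sampling oracle over 200 seeds
  n_per <- 500
  persons <- data.frame(
    person_id = sprintf("p%04d", 1:(2 * n_per)),
    age = rep(c(30L, 65L), each = n_per),
    gender = "male", ethnicity = "white", nssec = "intermediate",
    car_access = TRUE, region = "England", survey_weight = 1
  )
  n_cyc <- c(0.08, 0.02) * n_per
  cyc_ids <- c(persons$person_id[1:n_cyc[1]], persons$person_id[n_per + 1:n_cyc[2]])
  trips <- data.frame(
    trip_id = sprintf("t%04d", seq_len(2 * n_per)),
    person_id = persons$person_id,
    main_mode = ifelse(persons$person_id %in% cyc_ids, "cycle", "car_driver"),
    distance_miles = 2, duration_min = 15, day_index = 1L,
    purpose = "commute", pt_walk_minutes = 0
  )
  s <- travel_survey(persons, trips)
  n_young <- vapply(1:200, function(seed) {
    ids <- select_regular_cyclists(s, scenario_spec("England", 10, equity = FALSE, seed = seed))
    sum(s$persons$age_band[s$persons$person_id %in% ids] == "18-39")
  }, numeric(1))
  n_new <- round((0.10 - 0.05) * 1000)
  # oracle: direct weighted sampling without replacement from the same pool
  elig_band <- s$persons$age_band[!s$persons$person_id %in% cyc_ids]
  w <- ifelse(elig_band == "18-39", 0.08, 0.02)
  oracle <- vapply(1:500, function(i) {
    set.seed(10000 + i)
    sum(elig_band[sample.int(length(w), n_new, prob = w)] == "18-39")
  }, numeric(1))
  se <- stats::sd(oracle) / sqrt(200)
  expect_lt(abs(mean(n_young) - mean(oracle)), 3 * se + stats::sd(oracle) / sqrt(500) * 3)
  # sanity: close to the 4:1 expectation
  expect_gt(mean(n_young) / (n_new - mean(n_young)), 3)
})

test_that("equity conversion matches the eligible pool's composition", {
  s <- make_population(n = 4000, seed = 5)
  cyc <- classify_current_cyclists(s)
  elig <- s$persons[!s$persons$person_id %in% cyc & s$persons$age < 80, ]
  pool_share <- mean(elig$gender == "female")
  shares <- vapply(1:50, function(seed) {
    ids <- select_regular_cyclists(s, scenario_spec("England", 25, equity = TRUE, seed = seed))
    mean(s$persons$gender[s$persons$person_id %in% ids] == "female")
  }, numeric(1))
  n_new <- length(select_regular_cyclists(s, scenario_spec("England", 25, equity = TRUE, seed = 1)))
  se <- sqrt(pool_share * (1 - pool_share) / n_new) / sqrt(50)
  expect_lt(abs(mean(shares) - pool_share), 4 * se)
})

test_that("Step 2 switches trips at the banded propensity and relabels groups", {
  # p = 0 everywhere: converted persons stay regular cyclists
  s <- single_trip_population(50)
  spec <- scenario_spec("England", 25, seed = 3)
  ids <- s$persons$person_id[1:10]
  res0 <- switch_trips(s, ids, flat_propensity(0), flat_speeds(), spec = spec)
  expect_length(res0$switched_trip_ids, 0)
  expect_equal(sum(res0$groups$group == "regular_cyclist"), 10)
  expect_equal(sum(res0$groups$group == "new_cyclist"), 0)

  # p = 1 everywhere: every trip of every converted person switches
  res1 <- switch_trips(s, ids, flat_propensity(1), flat_speeds(), spec = spec)
  expect_length(res1$switched_trip_ids, 10)
  expect_equal(sum(res1$groups$group == "new_cyclist"), 10)
  scen_modes <- res1$survey$trips$main_mode[res1$survey$trips$person_id %in% ids]
  expect_true(all(scen_modes == "cycle"))
  # switched durations recomputed at the stratum speed: 1.5 mi at 8 mph
  expect_equal(
    unique(res1$survey$trips$duration_min[res1$survey$trips$trip_id %in% res1$switched_trip_ids]),
    1.5 / 8 * 60
  )
})

test_that("switch rate matches the propensity within 3 binomial SE at n = 10,000", {
  s <- single_trip_population(10000) # all trips in band [1,2)
  ids <- s$persons$person_id
  res <- switch_trips(s, ids, flat_propensity(0.3), flat_speeds(),
    spec = scenario_spec("England", 100, seed = 17)
  )
  rate <- length(res$switched_trip_ids) / 10000
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("switching conserves trips, distances and the four-group partition", {
  s <- make_population(n = 3000, seed = 8)
  spec <- scenario_spec("England", 50, seed = 21)
  pt <- estimate_propensity(s)
  sp <- estimate_speeds(s)
  res <- run_scenario(s, spec, pt, sp)
  # trip conservation: identical ids, distances unchanged
  expect_setequal(res$survey$trips$trip_id, s$trips$trip_id)
  m <- match(s$trips$trip_id, res$survey$trips$trip_id)
  expect_equal(res$survey$trips$distance_miles[m], s$trips$distance_miles)
  # only switched trips changed mode/duration
  changed <- which(res$survey$trips$main_mode[m] != s$trips$main_mode)
  expect_setequal(s$trips$trip_id[changed], res$switched_trip_ids)
  # four groups partition the population and agree with baseline classes
  expect_setequal(res$groups$person_id, s$persons$person_id)
  cyc <- classify_current_cyclists(s)
  expect_setequal(res$groups$person_id[res$groups$group == "existing_cyclist"], cyc)
  conv_groups <- res$groups$group[!res$groups$person_id %in% cyc]
  expect_true(all(conv_groups %in% c("regular_cyclist", "new_cyclist", "non_cyclist")))
  # every switched trip belongs to a converted person
  owners <- res$survey$trips$person_id[res$survey$trips$trip_id %in% res$switched_trip_ids]
  own_groups <- res$groups$group[match(unique(owners), res$groups$person_id)]
  expect_true(all(own_groups == "new_cyclist"))
  # switched PT trips lose their embedded walking minutes
  sw <- res$survey$trips$trip_id %in% res$switched_trip_ids
  expect_true(all(res$survey$trips$pt_walk_minutes[sw] == 0))
  # determinism
  res2 <- run_scenario(s, spec, pt, sp)
  expect_identical(res2$survey$trips, res$survey$trips)
})

test_that("cycling volume is non-decreasing in the uptake target", {
  s <- make_population(n = 3000, seed = 14)
  pt <- estimate_propensity(s)
  sp <- estimate_speeds(s)
  counts <- vapply(c(10, 25, 50, 75, 100), function(tgt) {
    res <- run_scenario(s, scenario_spec("England", tgt, seed = 31), pt, sp)
    sum(res$survey$trips$main_mode %in% c("cycle", "ebike"))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("e-bike scenarios emit both e-bike and traditional-bike trips", {
  s <- make_population(n = 3000, seed = 9)
  spec <- scenario_spec("England", 50, ebike = TRUE, seed = 12)
  res <- run_scenario(s, spec, estimate_propensity(s), estimate_speeds(s),
    ebike_tables = ebike_reference()
  )
  sw_modes <- res$survey$trips$main_mode[res$survey$trips$trip_id %in% res$switched_trip_ids]
  expect_setequal(unique(sw_modes), c("cycle", "ebike"))
  # e-bike durations use the flat e-bike speed
  eb <- res$survey$trips$trip_id %in% res$switched_trip_ids &
    res$survey$trips$main_mode == "ebike"
  expect_equal(
    res$survey$trips$duration_min[eb],
    res$survey$trips$distance_miles[eb] / 9.5 * 60
  )
  expect_error(
    run_scenario(s, spec, estimate_propensity(s), estimate_speeds(s)),
    class = "cycleimpacts_config_error"
  )
})

test_that("scenario enumeration reproduces the per-geography counts", {
  # 24 raw combinations before exclusions
  expect_equal(nrow(expand.grid(c(5, 10, 25, 50, 75, 100), c(TRUE, FALSE), c(TRUE, FALSE))), 24)
  # low-baseline geography: 24 - 1 duplicate at 100% = 23
  low <- enumerate_scenarios(c("North East" = 0.031))
  expect_length(low, 23)
  # baseline >= 4%: the four 5% combinations drop too -> 19
  high <- enumerate_scenarios(c("South West" = 0.061))
  expect_length(high, 19)
  expect_false(any(vapply(high, function(s) s$target_pct == 5, logical(1))))
  # England + 9 regions with 4 low-baseline regions -> 6*19 + 4*23 = 206
  all_specs <- enumerate_scenarios(default_region_baselines())
  expect_length(all_specs, 206)
  # child seeds are order-independent and below 2^31
  seeds <- vapply(all_specs, function(s) s$seed, numeric(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  spec1 <- all_specs[[1]]
  expect_equal(spec1$seed, scenario_child_seed(1L, spec1))
})
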