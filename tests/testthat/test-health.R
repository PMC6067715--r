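# Dose-response, population impact fractions and burden application.

toy_dr <- function() dose_response(c(0, 10, 20), c(1.0, 0.8, 0.7))

make_profiles <- function(ids, total) {
  structure(
    data.frame(
      person_id = ids, travel_mmeth = 0,
      nontravel_mmeth = total, total_mmeth = total
    ),
    class = c("activity_profiles", "data.frame")
  )
}

test_that("relative risk interpolates linearly with a flat tail", {
  dr <- toy_dr()
  expect_equal(individual_rr(0, dr), 1.0)
  expect_equal(individual_rr(5, dr), 0.9) # midway 1.0 -> 0.8
  expect_equal(individual_rr(10, dr), 0.8)
  expect_equal(individual_rr(100, dr), 0.7) # flat beyond last knot
  expect_error(individual_rr(-1, dr), class = "cycleimpacts_validation_error")
  # malformed curves rejected
  expect_error(dose_response(c(0, 10), c(0.9, 0.8)), class = "cycleimpacts_config_error")
  expect_error(dose_response(c(0, 10, 20), c(1, 0.8, 0.9)), class = "cycleimpacts_config_error")
  expect_error(dose_response(c(0, 10, 20), c(1, 0.5, -0.1)), class = "cycleimpacts_config_error")
  # bundled default curve satisfies the invariants
  def <- default_dose_response()
  expect_equal(def$rr[1], 1)
  expect_true(all(diff(def$rr) <= 0))
})

test_that("PIF matches hand-computed and closed-form cases", {
  dr <- toy_dr()
  ids <- c("a", "b")
  base <- make_profiles(ids, c(0, 0)) # rr (1.0, 1.0)
  expect_equal(stratum_pif(base, base, dr), 0) # identical profiles
  scen <- make_profiles(ids, c(10, 0)) # rr (0.8, 1.0)
  expect_equal(stratum_pif(base, scen, dr), 0.1) # 1 - 1.8/2.0
  # all persons at the rr floor: PIF = 1 - rr_min / mean(baseline rr)
  base2 <- make_profiles(ids, c(0, 10))
  scen2 <- make_profiles(ids, c(50, 50))
  expect_equal(stratum_pif(base2, scen2, dr), 1 - 0.7 / mean(c(1.0, 0.8)))
  # mismatched person sets rejected
  expect_error(
    stratum_pif(base, make_profiles(c("a", "z"), c(0, 0)), dr),
    class = "cycleimpacts_validation_error"
  )
  # scale invariance in the weights
  w1 <- c(a = 1, b = 3)
  expect_equal(
    stratum_pif(base, scen, dr, weights = w1),
    stratum_pif(base, scen, dr, weights = w1 * 100)
  )
  # positivity under dominance: everyone gains, at least one strictly
  scen3 <- make_profiles(ids, c(5, 0))
  expect_gt(stratum_pif(base, scen3, dr), 0)
})

test_that("stratum_pif agrees with a brute-force oracle on small populations", {
  # oracle: scalar loop with explicit piecewise-linear interpolation,
  # independent of the package's vectorised path
  oracle_rr <- function(x, dr) {
    if (x >= dr$exposure[nrow(dr)]) {
      return(dr$rr[nrow(dr)])
    }
    i <- max(which(dr$exposure <= x))
    if (dr$exposure[i] == x) {
      return(dr$rr[i])
    }
    frac <- (x - dr$exposure[i]) / (dr$exposure[i + 1] - dr$exposure[i])
    dr$rr[i] + frac * (dr$rr[i + 1] - dr$rr[i])
  }
  dr <- default_dose_response()
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(3:20, 1)
    ids <- sprintf("p%02d", seq_len(n))
    base <- make_profiles(ids, round(stats::runif(n, 0, 60), 2))
    scen <- make_profiles(ids, base$total_mmeth + round(stats::runif(n, 0, 10), 2))
    w <- stats::setNames(stats::runif(n, 0.5, 2), ids)
    num <- sum(w * vapply(scen$total_mmeth, oracle_rr, 0, dr = dr))
    den <- sum(w * vapply(base$total_mmeth, oracle_rr, 0, dr = dr))
    expect_equal(stratum_pif(base, scen, dr, weights = w), 1 - num / den,
      tolerance = 1e-12
    )
  }
})

test_that("burden application multiplies PIFs into YLL and aggregates", {
  burden1 <- data.frame(
    geography = "England", age_band = "40-59", gender = "male",
    yll = 2000, deaths = 100
  )
  pifs1 <- data.frame(
    geography = "England", age_band = "40-59", gender = "male", pif = 0.05
  )
  h <- yll_averted(pifs1, burden1)
  expect_equal(h$yll_averted, 100)
  expect_equal(h$pct_yll_averted, 5)
  expect_equal(h$deaths_averted, 5)

  # two strata (0.1 x 1000, 0 x 1000) -> aggregate 5%
  burden2 <- data.frame(
    geography = "England", age_band = c("40-59", "60-79"), gender = "male",
    yll = c(1000, 1000), deaths = c(10, 10)
  )
  pifs2 <- data.frame(
    geography = "England", age_band = c("40-59", "60-79"),
    gender = "male", pif = c(0.1, 0)
  )
  h2 <- yll_averted(pifs2, burden2)
  expect_equal(h2$yll_averted, 100)
  expect_equal(h2$pct_yll_averted, 5)
  # zero PIF everywhere -> nothing averted
  pifs0 <- pifs2
  pifs0$pif <- 0
  expect_equal(yll_averted(pifs0, burden2)$yll_averted, 0)
  # burden strata without a PIF entry default to 0
  h3 <- yll_averted(pifs1, burden2)
  expect_equal(h3$by_stratum$pif, c(0.05, 0))
})

test_that("a uniform exposure shift recovers the closed-form PIF x YLL", {
  # single-stratum synthetic population; scenario adds exactly delta
  # MMETh to everyone, so PIF has a closed form via the rr curve
  dr <- toy_dr()
  n <- 50
  ids <- sprintf("p%02d", seq_len(n))
  base_x <- rep(5, n)
  delta <- 5
  base <- make_profiles(ids, base_x)
  scen <- make_profiles(ids, base_x + delta)
  pif_closed <- 1 - individual_rr(10, dr) / individual_rr(5, dr) # 0.8/0.9
  expect_equal(stratum_pif(base, scen, dr), pif_closed, tolerance = 1e-15)
  burden <- data.frame(
    geography = "England", age_band = "20-39", gender = "male",
    yll = 12345, deaths = 100
  )
  pifs <- data.frame(
    geography = "England", age_band = "20-39", gender = "male",
    pif = stratum_pif(base, scen, dr)
  )
  h <- yll_averted(pifs, burden)
  expect_equal(h$yll_averted, pif_closed * 12345, tolerance = 1e-12)
})

test_that("burden strata use ages 20-79 and exclude 18-19 and 80+", {
  persons <- data.frame(
    person_id = c("teen", "mid", "old"),
    age = c(19L, 45L, 85L), gender = "male", ethnicity = "white",
    nssec = "intermediate", car_access = TRUE, region = "England",
    survey_weight = 1
  )
  trips <- data.frame(
    trip_id = c("t1", "t2", "t3"), person_id = persons$person_id,
    main_mode = "walk", distance_miles = 0.5, duration_min = 10,
    day_index = 1L, purpose = "x", pt_walk_minutes = 0
  )
  s <- travel_survey(persons, trips)
  base <- make_profiles(persons$person_id, c(0, 0, 0))
  scen <- make_profiles(persons$person_id, c(50, 50, 50))
  pifs <- pif_by_stratum(s, base, scen, toy_dr())
  expect_setequal(unique(pifs$age_band), c("20-39", "40-59", "60-79"))
  # only the 45-year-old contributes; his stratum has positive PIF
  expect_gt(pifs$pif[pifs$age_band == "40-59" & pifs$gender == "male"], 0)
  expect_equal(sum(pifs$n), 1)
})
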