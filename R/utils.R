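# Shared vocabularies and small helpers used across modules.

#' Controlled vocabularies
#'
#' Main-mode, age-band, gender, ethnicity and population-group label sets
#' used throughout the package. Distances are miles, durations minutes,
#' speeds mph everywhere.
#'
#' @name vocabularies
#' @keywords internal
NULL

main_modes <- function() {
  c("walk", "cycle", "ebike", "car_driver", "car_passenger", "bus", "rail", "other")
}

cycling_modes <- function() c("cycle", "ebike")

pt_modes <- function() c("bus", "rail")

age_bands <- function() c("18-39", "40-59", "60-79", "80+")

#' Uptake strata: age bands eligible for conversion and trip switching
#' (persons aged 80+ are retained in the data but never converted).
#' @keywords internal
uptake_age_bands <- function() c("18-39", "40-59", "60-79")

#' Burden age bands used by the health module (ages 20-79).
#' @keywords internal
burden_age_bands <- function() c("20-39", "40-59", "60-79")

genders <- function() c("male", "female")

#' Map exact age in years to the survey age band
#'
#' @param age integer vector of ages (years, >= 18).
#' @return character vector of age-band labels.
#' @export
age_to_band <- function(age) {
  stopifnot(is.numeric(age))
  cut(age,
    breaks = c(18, 40, 60, 80, Inf), right = FALSE,
    labels = age_bands()
  ) |> as.character()
}

#' Map exact age to the burden age band (NA outside 20-79)
#' @keywords internal
age_to_burden_band <- function(age) {
  out <- rep(NA_character_, length(age))
  out[age >= 20 & age < 40] <- "20-39"
  out[age >= 40 & age < 60] <- "40-59"
  out[age >= 60 & age < 80] <- "60-79"
  out
}

#' Unit conversion helpers
#'
#' Internal units are fixed (miles, minutes, mph); these helpers convert
#' metric inputs at the boundary.
#'
#' @param km,miles numeric vectors.
#' @return numeric vector in the other unit.
#' @export
miles_from_km <- function(km) km / 1.609344

#' @rdname miles_from_km
#' @export
km_from_miles <- function(miles) miles * 1.609344

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards. All stochastic operations in the package route
# through this so results are pure functions of their seed argument.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit string hash (polynomial rolling hash); used to derive
# per-scenario child seeds that do not depend on enumeration order.
hash_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a deterministic child seed for a scenario
#'
#' Combines a global seed with a stable hash of the scenario's defining
#' fields so that each scenario's randomness is independent of the order
#' in which scenarios are enumerated or run.
#'
#' @param global_seed integer global seed.
#' @param spec a [scenario_spec()].
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
scenario_child_seed <- function(global_seed, spec) {
  key <- paste(spec$geography, spec$target_pct,
    as.integer(spec$equity), as.integer(spec$ebike),
    sep = "|"
  )
  as.integer((as.numeric(global_seed) + hash_string(key)) %% 2147483647)
}

# stop() with a class so callers/tests can match specific failures.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "cycleimpacts_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Collapse a vector of ids into a short diagnostic string.
id_list <- function(ids, max = 10L) {
  ids <- as.character(ids)
  shown <- utils::head(ids, max)
  extra <- length(ids) - length(shown)
  paste0(
    paste(shown, collapse = ", "),
    if (extra > 0) sprintf(" ... and %d more", extra)
  )
}
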