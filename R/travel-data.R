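# Travel-diary data model: persons + trips (+ optional stages), CSV IO,
# and diary preprocessing (short-walk replication, public-transport
# walking minutes, current-cyclist classification).

person_columns <- function() {
  c(
    "person_id", "age", "gender", "ethnicity", "nssec", "car_access",
    "region", "survey_weight"
  )
}

trip_columns <- function() {
  c(
    "trip_id", "person_id", "main_mode", "distance_miles", "duration_min",
    "day_index", "purpose"
  )
}

stage_columns <- function() c("stage_id", "trip_id", "mode", "duration_min")

#' Construct a travel survey
#'
#' Bundles a persons table, a trips table and an optional stages table
#' into a validated `travel_survey` object — the one-week travel diary
#' that every downstream module consumes.
#'
#' @param persons data frame with columns `person_id`, `age`, `gender`,
#'   `ethnicity`, `nssec`, `car_access`, `region`, `survey_weight`. An
#'   `age_band` column is derived from `age` if absent.
#' @param trips data frame with columns `trip_id`, `person_id`,
#'   `main_mode`, `distance_miles`, `duration_min`, `day_index`,
#'   `purpose`, and optionally `pt_walk_minutes` (walking embedded in
#'   public-transport trips; defaults to 0) and `replicate_of` (set on
#'   copies created by [replicate_short_walks()]; defaults to `NA`).
#' @param stages optional data frame with columns `stage_id`, `trip_id`,
#'   `mode`, `duration_min`.
#' @param geography geography label for the survey (e.g. a region name
#'   or `"England"`).
#' @param trip_distance_min minimum recorded trip distance in miles
#'   (0.1 for English-diary conventions; use
#'   `miles_from_km(0.1)` for 100 m Dutch-style recording).
#' @param validate run full validation (default `TRUE`).
#' @return an object of class `travel_survey`.
#' @seealso [read_survey()], [validate_survey()]
#' @export
travel_survey <- function(persons, trips, stages = NULL,
                          geography = "England",
                          trip_distance_min = 0.1,
                          validate = TRUE) {
  persons <- as.data.frame(persons)
  trips <- as.data.frame(trips)
  if (!is.null(stages)) stages <- as.data.frame(stages)

  if (!"age_band" %in% names(persons) && "age" %in% names(persons)) {
    persons$age_band <- age_to_band(persons$age)
  }
  if (!"pt_walk_minutes" %in% names(trips)) trips$pt_walk_minutes <- 0
  trips$pt_walk_minutes[is.na(trips$pt_walk_minutes)] <- 0
  if (!"replicate_of" %in% names(trips)) trips$replicate_of <- NA_character_

  x <- structure(
    list(
      persons = persons, trips = trips, stages = stages,
      geography = geography, trip_distance_min = trip_distance_min
    ),
    class = "travel_survey"
  )
  if (validate) validate_survey(x) else x
}

#' @export
print.travel_survey <- function(x, ...) {
  cat(sprintf(
    "<travel_survey> %s: %d persons, %d trips%s\n",
    x$geography, nrow(x$persons), nrow(x$trips),
    if (!is.null(x$stages)) sprintf(", %d stages", nrow(x$stages)) else ""
  ))
  n_cyc <- length(classify_current_cyclists(x))
  cat(sprintf("  current cyclists: %d (%.1f%%)\n", n_cyc, 100 * n_cyc / max(1, nrow(x$persons))))
  invisible(x)
}

#' Validate a travel survey
#'
#' Checks schema, type invariants and referential integrity. Errors carry
#' row-level diagnostics (the offending ids) and a condition class so
#' callers can distinguish schema errors (`cycleimpacts_schema_error`),
#' integrity errors (`cycleimpacts_integrity_error`) and value-level
#' violations (`cycleimpacts_validation_error`).
#'
#' @param x a `travel_survey`.
#' @param stage_tolerance_min slack, in minutes, allowed when stage
#'   durations of a trip are compared against the trip duration
#'   (self-reported stage and trip times are rounded independently).
#' @return `x`, invisibly amended (age bands derived), if valid.
#' @export
validate_survey <- function(x, stage_tolerance_min = 5) {
  stopifnot(inherits(x, "travel_survey"))
  persons <- x$persons
  trips <- x$trips

  miss_p <- setdiff(person_columns(), names(persons))
  if (length(miss_p) > 0) {
    abort(
      sprintf("persons table is missing mandatory column(s): %s", paste(miss_p, collapse = ", ")),
      "cycleimpacts_schema_error"
    )
  }
  miss_t <- setdiff(trip_columns(), names(trips))
  if (length(miss_t) > 0) {
    abort(
      sprintf("trips table is missing mandatory column(s): %s", paste(miss_t, collapse = ", ")),
      "cycleimpacts_schema_error"
    )
  }

  bad <- character(0)
  if (anyDuplicated(persons$person_id)) {
    bad <- c(bad, sprintf(
      "duplicate person_id: %s",
      id_list(persons$person_id[duplicated(persons$person_id)])
    ))
  }
  if (any(persons$age < 18, na.rm = TRUE)) {
    bad <- c(bad, sprintf(
      "persons under 18 (adult survey): %s",
      id_list(persons$person_id[persons$age < 18])
    ))
  }
  band <- age_to_band(persons$age)
  if (!is.null(persons$age_band) && any(persons$age_band != band, na.rm = TRUE)) {
    bad <- c(bad, sprintf(
      "age_band inconsistent with age for: %s",
      id_list(persons$person_id[persons$age_band != band])
    ))
  }
  if (any(persons$survey_weight < 0, na.rm = TRUE)) {
    bad <- c(bad, sprintf(
      "negative survey_weight for: %s",
      id_list(persons$person_id[persons$survey_weight < 0])
    ))
  }
  if (any(!persons$gender %in% genders())) {
    bad <- c(bad, sprintf(
      "unknown gender for: %s",
      id_list(persons$person_id[!persons$gender %in% genders()])
    ))
  }

  if (anyDuplicated(trips$trip_id)) {
    bad <- c(bad, sprintf(
      "duplicate trip_id: %s",
      id_list(trips$trip_id[duplicated(trips$trip_id)])
    ))
  }
  if (any(!trips$main_mode %in% main_modes())) {
    bad <- c(bad, sprintf(
      "unknown main_mode in trips: %s",
      id_list(trips$trip_id[!trips$main_mode %in% main_modes()])
    ))
  }
  too_short <- trips$distance_miles < x$trip_distance_min | trips$distance_miles <= 0
  if (any(too_short, na.rm = TRUE)) {
    bad <- c(bad, sprintf(
      "trip distance below the %.4f-mile recording threshold: %s",
      x$trip_distance_min, id_list(trips$trip_id[too_short])
    ))
  }
  if (any(trips$duration_min <= 0, na.rm = TRUE)) {
    bad <- c(bad, sprintf(
      "non-positive duration for trips: %s",
      id_list(trips$trip_id[trips$duration_min <= 0])
    ))
  }
  if (any(!trips$day_index %in% 1:7)) {
    bad <- c(bad, sprintf(
      "day_index outside 1-7 for trips: %s",
      id_list(trips$trip_id[!trips$day_index %in% 1:7])
    ))
  }
  ptw_pos <- trips$pt_walk_minutes > 0 & !trips$main_mode %in% pt_modes()
  if (any(ptw_pos, na.rm = TRUE)) {
    bad <- c(bad, sprintf(
      "pt_walk_minutes > 0 on non-public-transport trips: %s",
      id_list(trips$trip_id[ptw_pos])
    ))
  }
  ptw_over <- trips$pt_walk_minutes > trips$duration_min
  if (any(ptw_over, na.rm = TRUE)) {
    bad <- c(bad, sprintf(
      "pt_walk_minutes exceeds trip duration for: %s",
      id_list(trips$trip_id[ptw_over])
    ))
  }
  if (length(bad) > 0) {
    abort(
      paste0("invalid survey rows:\n  - ", paste(bad, collapse = "\n  - ")),
      "cycleimpacts_validation_error"
    )
  }

  orphan <- !trips$person_id %in% persons$person_id
  if (any(orphan)) {
    abort(
      sprintf(
        "trips reference unknown person_id(s); trip_ids: %s",
        id_list(trips$trip_id[orphan])
      ),
      "cycleimpacts_integrity_error"
    )
  }
  rep_bad <- !is.na(trips$replicate_of) & !trips$replicate_of %in% trips$trip_id
  if (any(rep_bad)) {
    abort(
      sprintf(
        "replicate_of references unknown trip_id(s); trip_ids: %s",
        id_list(trips$trip_id[rep_bad])
      ),
      "cycleimpacts_integrity_error"
    )
  }

  if (!is.null(x$stages)) {
    stages <- x$stages
    miss_s <- setdiff(stage_columns(), names(stages))
    if (length(miss_s) > 0) {
      abort(
        sprintf("stages table is missing mandatory column(s): %s", paste(miss_s, collapse = ", ")),
        "cycleimpacts_schema_error"
      )
    }
    s_orphan <- !stages$trip_id %in% trips$trip_id
    if (any(s_orphan)) {
      abort(
        sprintf(
          "stages reference unknown trip_id(s); stage_ids: %s",
          id_list(stages$stage_id[s_orphan])
        ),
        "cycleimpacts_integrity_error"
      )
    }
    stage_sum <- tapply(stages$duration_min, stages$trip_id, sum)
    trip_dur <- trips$duration_min[match(names(stage_sum), trips$trip_id)]
    over <- stage_sum > trip_dur + stage_tolerance_min
    if (any(over)) {
      abort(
        sprintf(
          "stage durations exceed trip duration (+%g min tolerance) for trip(s): %s",
          stage_tolerance_min, id_list(names(stage_sum)[over])
        ),
        "cycleimpacts_validation_error"
      )
    }
  }
  x$persons$age_band <- band
  invisible(x)
}

#' Read a travel survey from CSV files
#'
#' Reads the persons, trips and (optionally) stages tables from UTF-8
#' CSV files with the documented headers and returns a validated
#' [travel_survey()].
#'
#' @param person_path,trip_path,stage_path file paths; `stage_path` may
#'   be `NULL`.
#' @inheritParams travel_survey
#' @return a validated `travel_survey`.
#' @export
read_survey <- function(person_path, trip_path, stage_path = NULL,
                        geography = "England", trip_distance_min = 0.1) {
  persons <- utils::read.csv(person_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trips <- utils::read.csv(trip_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  stages <- if (!is.null(stage_path)) {
    utils::read.csv(stage_path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  if ("car_access" %in% names(persons)) {
    persons$car_access <- as.logical(persons$car_access)
  }
  if ("replicate_of" %in% names(trips)) {
    trips$replicate_of <- as.character(trips$replicate_of)
    trips$replicate_of[trips$replicate_of %in% c("", "NA")] <- NA_character_
  }
  for (col in c("person_id", "trip_id")) {
    if (col %in% names(persons)) persons[[col]] <- as.character(persons[[col]])
    if (col %in% names(trips)) trips[[col]] <- as.character(trips[[col]])
  }
  if (!is.null(stages)) {
    stages$stage_id <- as.character(stages$stage_id)
    stages$trip_id <- as.character(stages$trip_id)
  }
  travel_survey(persons, trips, stages,
    geography = geography,
    trip_distance_min = trip_distance_min
  )
}

#' Write a travel survey to CSV files
#'
#' Inverse of [read_survey()]: writes `persons.csv`, `trips.csv` and,
#' when stages are present, `stages.csv` under `dir`.
#'
#' @param survey a `travel_survey`.
#' @param dir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "travel_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    persons = file.path(dir, "persons.csv"),
    trips = file.path(dir, "trips.csv")
  )
  persons <- survey$persons
  persons$age_band <- NULL # derived on read
  utils::write.csv(persons, paths[["persons"]], row.names = FALSE, na = "")
  utils::write.csv(survey$trips, paths[["trips"]], row.names = FALSE, na = "")
  if (!is.null(survey$stages)) {
    paths <- c(paths, stages = file.path(dir, "stages.csv"))
    utils::write.csv(survey$stages, paths[["stages"]], row.names = FALSE, na = "")
  }
  invisible(paths)
}

#' Derive public-transport walking minutes from stage data
#'
#' For every trip whose main mode is bus or rail, sets
#' `pt_walk_minutes` to the summed duration of that trip's walking
#' stages; all other trips get 0. Walking embedded in motorised trips is
#' what makes public-transport users' activity visible to the physical
#' activity accounting.
#'
#' @param survey a `travel_survey` with stages.
#' @return the survey with `pt_walk_minutes` populated. If no stage
#'   table is present the survey is returned unchanged with a warning.
#' @export
derive_pt_walk_minutes <- function(survey) {
  stopifnot(inherits(survey, "travel_survey"))
  if (is.null(survey$stages)) {
    warning("no stage table present; pt_walk_minutes left as loaded")
    return(survey)
  }
  walk_stages <- survey$stages[survey$stages$mode == "walk", , drop = FALSE]
  walk_min <- tapply(walk_stages$duration_min, walk_stages$trip_id, sum)
  trips <- survey$trips
  trips$pt_walk_minutes <- 0
  is_pt <- trips$main_mode %in% pt_modes()
  m <- match(trips$trip_id[is_pt], names(walk_min))
  mins <- unname(walk_min[m])
  mins[is.na(mins)] <- 0
  trips$pt_walk_minutes[is_pt] <- pmin(mins, trips$duration_min[is_pt])
  survey$trips <- trips
  survey
}

#' Replicate short walking trips recorded on the diary's final day
#'
#' One-week diaries record short walks (under `threshold_miles`) only on
#' the final diary day; to avoid under-counting walking, each such walk
#' is replicated six additional times (one per remaining day of the
#' week). Copies carry fresh trip ids and `replicate_of` set to the
#' original trip id; all other trips are untouched. The operation is
#' idempotent: originals that already have replicates are skipped, so a
#' second call is a no-op.
#'
#' @param survey a `travel_survey`.
#' @param threshold_miles short-walk threshold (default 1 mile).
#' @param final_day diary day on which short walks are recorded
#'   (default 7).
#' @param n_copies number of additional copies (default 6, giving 7
#'   walk trips in total per qualifying walk).
#' @return the survey with replicated walk trips appended.
#' @export
replicate_short_walks <- function(survey, threshold_miles = 1, final_day = 7L,
                                  n_copies = 6L) {
  stopifnot(inherits(survey, "travel_survey"))
  trips <- survey$trips
  already <- unique(trips$replicate_of[!is.na(trips$replicate_of)])
  qualifies <- trips$main_mode == "walk" &
    trips$distance_miles < threshold_miles &
    trips$day_index == final_day &
    is.na(trips$replicate_of) &
    !trips$trip_id %in% already
  if (!any(qualifies)) {
    return(survey)
  }
  originals <- trips[qualifies, , drop = FALSE]
  copies <- originals[rep(seq_len(nrow(originals)), each = n_copies), , drop = FALSE]
  copies$replicate_of <- copies$trip_id
  copies$trip_id <- paste0(copies$trip_id, "_r", rep(seq_len(n_copies), times = nrow(originals)))
  rownames(copies) <- NULL
  survey$trips <- rbind(trips, copies)
  survey
}

#' Identify current cyclists
#'
#' A current cyclist is a person reporting at least one cycle (or
#' e-bike) trip in their diary week.
#'
#' @param survey a `travel_survey`.
#' @return character vector of `person_id`s.
#' @export
classify_current_cyclists <- function(survey) {
  stopifnot(inherits(survey, "travel_survey"))
  trips <- survey$trips
  sort(unique(trips$person_id[trips$main_mode %in% cycling_modes()]))
}

#' Baseline cyclist prevalence
#'
#' Share of the adult population who are current cyclists.
#'
#' @param survey a `travel_survey`.
#' @param weighted use survey weights (default `FALSE`: the quota
#'   scenario arithmetic is defined on person counts).
#' @return proportion in `[0, 1]`.
#' @export
baseline_prevalence <- function(survey, weighted = FALSE) {
  cyclists <- classify_current_cyclists(survey)
  persons <- survey$persons
  if (weighted) {
    sum(persons$survey_weight[persons$person_id %in% cyclists]) /
      sum(persons$survey_weight)
  } else {
    length(cyclists) / nrow(persons)
  }
}
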