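# Diary data model: registrations, nightly records, and the cohort container.

# Enumerated levels of the 16 registration questions. Field order matches the
# registration questionnaire; every record carries exactly these fields.
registration_fields <- function() {
  c(
    "age", "sex", "alarm_type", "sleep_depth", "enuresis_frequency",
    "wets_once_or_twice", "motivation", "daytime_urgency", "daytime_wetting",
    "prior_alarm_treatment", "prior_medication", "bladder_relaxant",
    "nurse_contact", "weak_stream", "thirsty_at_night", "previously_dry"
  )
}

alarm_type_levels <- function() {
  c("alarm_with_pants", "pjama_connect", "alarm_with_underwear",
    "other_alarm", "no_or_unknown")
}

sleep_depth_levels <- function() {
  c("almost_impossible", "difficult", "neither", "easy", "dont_know")
}

yes_no_fields <- function() {
  c("daytime_urgency", "daytime_wetting", "prior_alarm_treatment",
    "prior_medication", "bladder_relaxant", "nurse_contact", "weak_stream",
    "thirsty_at_night", "previously_dry")
}

awakening_levels <- function() c("alarm", "parent", "not_awakened")

#' Construct a diary cohort
#'
#' A cohort bundles one registration row per patient with one nightly diary
#' row per patient-day, the two tables the alarm-treatment app collects.
#' Nights are densified on construction: any unrecorded interior day up to a
#' patient's last recorded day is materialized as an explicit `status =
#' "missing"` night, so downstream window operations always see a gap-free
#' calendar with `day_index` running 1..n.
#'
#' @param registrations Tibble with one row per patient: `patient_id` plus
#'   the 16 registration questions (`age`, `sex`, `alarm_type`,
#'   `sleep_depth`, `enuresis_frequency`, `wets_once_or_twice`,
#'   `motivation`, and nine yes/no questions). Missing answers are `NA`.
#' @param nights Tibble with columns `patient_id`, `day_index` (1-based),
#'   `status` (`wet`/`dry`/`missing`), `severity` (0--3 or `NA`),
#'   `awakening` (`alarm`/`parent`/`not_awakened`/`NA`), `repeat_wetting`
#'   (`yes`/`no`/`NA`), `woke_to_void` (`yes`/`no`/`NA`, dry nights only)
#'   and `event_times` (list column of integer minutes after sleep onset;
#'   empty on a wet night means the time was not recorded).
#' @param latent_classes Optional tibble (`patient_id`, `latent_class`);
#'   simulation ground truth only, never used by the analysis itself.
#' @param validate Run the full invariant checks (default `TRUE`).
#'
#' @return An object of class `enuresis_cohort`: a list with elements
#'   `registrations`, `nights` and (possibly `NULL`) `latent_classes`.
#' @export
enuresis_cohort <- function(registrations, nights, latent_classes = NULL,
                            validate = TRUE) {
  registrations <- as_tibble(registrations)
  nights <- as_tibble(nights)
  for (col in c("patient_id", "day_index", "status")) {
    if (!col %in% names(nights)) abort(sprintf("nights lack column '%s'", col))
  }
  if (!"severity" %in% names(nights)) nights$severity <- NA_integer_
  for (col in c("awakening", "repeat_wetting", "woke_to_void")) {
    if (!col %in% names(nights)) nights[[col]] <- NA_character_
  }
  if (!"event_times" %in% names(nights)) {
    nights$event_times <- rep(list(integer(0)), nrow(nights))
  }
  nights$day_index <- as.integer(nights$day_index)
  nights$event_times <- lapply(nights$event_times, function(x) {
    if (is.null(x) || length(x) == 0 || all(is.na(x))) integer(0) else as.integer(x)
  })
  for (col in c("severity")) {
    if (col %in% names(nights)) nights[[col]] <- as.integer(nights[[col]])
  }
  registrations <- arrange(registrations, .data$patient_id)
  nights <- densify_nights(nights, registrations$patient_id)
  if (!is.null(latent_classes)) {
    latent_classes <- arrange(as_tibble(latent_classes), .data$patient_id)
  }
  x <- structure(
    list(registrations = registrations, nights = nights,
         latent_classes = latent_classes),
    class = "enuresis_cohort"
  )
  if (validate) validate_cohort(x)
  x
}

# Materialize unrecorded interior days as explicit missing nights and order
# rows (patient_id, day_index). Recorded rows are passed through unchanged.
densify_nights <- function(nights, patient_ids) {
  dup <- nights %>%
    count(.data$patient_id, .data$day_index) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate (patient_id, day_index): %s day %d",
                  dup$patient_id[1], dup$day_index[1]))
  }
  extra <- setdiff(unique(nights$patient_id), patient_ids)
  if (length(extra) > 0) {
    abort(sprintf("nights reference unknown patient_id '%s'", extra[1]))
  }
  if (nrow(nights) == 0) {
    return(arrange(nights, .data$patient_id, .data$day_index))
  }
  span <- nights %>%
    group_by(.data$patient_id) %>%
    summarise(n_days = max(.data$day_index), .groups = "drop")
  full <- span %>%
    reframe(day_index = seq_len(.data$n_days), .by = "patient_id")
  out <- full %>%
    left_join(nights, by = c("patient_id", "day_index")) %>%
    mutate(
      status = ifelse(is.na(.data$status), "missing", .data$status),
      event_times = lapply(.data$event_times,
                           function(x) if (is.null(x)) integer(0) else x)
    ) %>%
    arrange(.data$patient_id, .data$day_index)
  out
}

#' Validate a diary cohort
#'
#' Checks the registration ranges (age 3--30, motivation 1--5, enuresis
#' frequency 0--7, enumerated categorical levels) and the nightly record
#' invariants (missing nights carry no detail, dry nights carry no wetness
#' detail, repeat wetting with recorded times implies at least two event
#' times). Errors name the offending patient and field.
#'
#' @param cohort An `enuresis_cohort`.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "enuresis_cohort"))
  reg <- cohort$registrations
  nts <- cohort$nights

  need <- c("patient_id", registration_fields())
  miss <- setdiff(need, names(reg))
  if (length(miss) > 0) {
    abort(sprintf("registrations lack column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(reg$patient_id)) {
    abort("duplicate patient_id in registrations")
  }

  check_range <- function(field, lo, hi) {
    v <- reg[[field]]
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad) > 0) {
      abort(sprintf("patient %s: %s = %s outside [%s, %s]",
                    reg$patient_id[bad[1]], field, v[bad[1]], lo, hi))
    }
  }
  check_range("age", 3, 30)
  check_range("enuresis_frequency", 0, 7)
  check_range("motivation", 1, 5)
  bad_mot <- which(!is.na(reg$motivation) & reg$motivation %% 1 != 0)
  if (length(bad_mot) > 0) {
    abort(sprintf("patient %s: motivation must be an integer 1-5",
                  reg$patient_id[bad_mot[1]]))
  }

  check_levels <- function(field, levels) {
    v <- reg[[field]]
    bad <- which(!is.na(v) & !v %in% levels)
    if (length(bad) > 0) {
      abort(sprintf("patient %s: %s = '%s' not one of {%s}",
                    reg$patient_id[bad[1]], field, v[bad[1]],
                    paste(levels, collapse = ", ")))
    }
  }
  check_levels("sex", c("male", "female"))
  check_levels("alarm_type", alarm_type_levels())
  check_levels("sleep_depth", sleep_depth_levels())
  check_levels("wets_once_or_twice", c("once", "twice"))
  for (f in yes_no_fields()) check_levels(f, c("yes", "no"))

  # nights ---------------------------------------------------------------
  bad <- which(!nts$status %in% night_status_levels())
  if (length(bad) > 0) {
    abort(sprintf("patient %s day %d: status '%s' invalid",
                  nts$patient_id[bad[1]], nts$day_index[bad[1]],
                  nts$status[bad[1]]))
  }
  bad <- which(!is.na(nts$severity) & (nts$severity < 0 | nts$severity > 3))
  if (length(bad) > 0) {
    abort(sprintf("patient %s day %d: severity outside 0-3",
                  nts$patient_id[bad[1]], nts$day_index[bad[1]]))
  }
  bad <- which(!is.na(nts$awakening) & !nts$awakening %in% awakening_levels())
  if (length(bad) > 0) {
    abort(sprintf("patient %s day %d: awakening '%s' invalid",
                  nts$patient_id[bad[1]], nts$day_index[bad[1]],
                  nts$awakening[bad[1]]))
  }
  n_times <- lengths(nts$event_times)
  neg <- which(vapply(nts$event_times,
                      function(x) length(x) > 0 && any(x < 0), logical(1)))
  if (length(neg) > 0) {
    abort(sprintf("patient %s day %d: negative event time",
                  nts$patient_id[neg[1]], nts$day_index[neg[1]]))
  }

  is_missing <- nts$status == "missing"
  detail_present <- !is.na(nts$severity) | !is.na(nts$awakening) |
    !is.na(nts$repeat_wetting) | !is.na(nts$woke_to_void) | n_times > 0
  bad <- which(is_missing & detail_present)
  if (length(bad) > 0) {
    abort(sprintf("patient %s day %d: missing night carries detail fields",
                  nts$patient_id[bad[1]], nts$day_index[bad[1]]))
  }
  is_dry <- nts$status == "dry"
  bad <- which(is_dry & (!is.na(nts$severity) | n_times > 0 |
                           (!is.na(nts$repeat_wetting) &
                              nts$repeat_wetting == "yes")))
  if (length(bad) > 0) {
    abort(sprintf("patient %s day %d: dry night carries wetness detail",
                  nts$patient_id[bad[1]], nts$day_index[bad[1]]))
  }
  is_wet <- nts$status == "wet"
  bad <- which(is_wet & !is.na(nts$repeat_wetting) &
                 nts$repeat_wetting == "yes" & n_times == 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "patient %s day %d: repeat_wetting = yes but only one event time",
      nts$patient_id[bad[1]], nts$day_index[bad[1]]))
  }
  bad <- which(is_wet & !is.na(nts$woke_to_void) & nts$woke_to_void == "yes")
  if (length(bad) > 0) {
    abort(sprintf("patient %s day %d: woke_to_void applies to dry nights",
                  nts$patient_id[bad[1]], nts$day_index[bad[1]]))
  }

  if (!is.null(cohort$latent_classes)) {
    lc <- cohort$latent_classes
    bad <- which(!lc$latent_class %in% outcome_levels())
    if (length(bad) > 0) {
      abort(sprintf("patient %s: latent_class '%s' invalid",
                    lc$patient_id[bad[1]], lc$latent_class[bad[1]]))
    }
  }
  invisible(cohort)
}

#' @export
print.enuresis_cohort <- function(x, ...) {
  n <- nrow(x$registrations)
  days <- if (n > 0) {
    x$nights %>% count(.data$patient_id) %>% pull(.data$n)
  } else integer(0)
  cat(sprintf("<enuresis_cohort> %d patients, %s nights/patient\n", n,
              if (n > 0) paste0(min(days), "-", max(days)) else "0"))
  wet <- mean(x$nights$status == "wet")
  mis <- mean(x$nights$status == "missing")
  if (n > 0) {
    cat(sprintf("  nightly status: %.1f%% wet, %.1f%% missing\n",
                100 * wet, 100 * mis))
  }
  if (!is.null(x$latent_classes)) cat("  latent classes attached\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort An `enuresis_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$registrations)

#' Subset a cohort by patient id
#'
#' @param cohort An `enuresis_cohort`.
#' @param patient_ids Character vector of patient ids to keep.
#' @return A new `enuresis_cohort` restricted to those patients.
#' @export
subset_cohort <- function(cohort, patient_ids) {
  missing_ids <- setdiff(patient_ids, cohort$registrations$patient_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("unknown patient_id '%s'", missing_ids[1]))
  }
  lc <- cohort$latent_classes
  enuresis_cohort(
    filter(cohort$registrations, .data$patient_id %in% patient_ids),
    filter(cohort$nights, .data$patient_id %in% patient_ids),
    latent_classes = if (is.null(lc)) NULL else
      filter(lc, .data$patient_id %in% patient_ids),
    validate = FALSE
  )
}

#' Nights of one patient
#'
#' @param cohort An `enuresis_cohort`.
#' @param patient_id One patient id.
#' @return Tibble of that patient's nights ordered by `day_index`.
#' @export
patient_nights <- function(cohort, patient_id) {
  pid <- patient_id
  out <- filter(cohort$nights, .data$patient_id == pid)
  if (nrow(out) == 0) abort(sprintf("unknown patient_id '%s'", pid))
  out
}
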