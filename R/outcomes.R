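# ICCS-style outcome labeling after 8 weeks of alarm treatment.
#
# A patient is successful on reaching 14 consecutive dry nights (up to 2
# missing diary days tolerated provided the remaining 12 are dry), a dropout
# on stopping before 6 weeks or on a 14-day missing run before week 8
# without prior success, partially successful when wet nights in the last
# two weeks fell to half (or less) of the first two weeks, and unsuccessful
# otherwise.

#' Dry-streak rule
#'
#' @param streak_len Window length in nights (default 14).
#' @param max_missing Missing nights tolerated inside the window (default 2).
#' @param min_dry Dry nights required inside the window (default 12).
#'   `min_dry + max_missing` must equal `streak_len`.
#' @return A `streak_rule` list.
#' @export
streak_rule <- function(streak_len = 14, max_missing = 2,
                        min_dry = streak_len - max_missing) {
  if (streak_len < 1 || min_dry < 1 || max_missing < 0) {
    abort("streak_len and min_dry must be positive, max_missing >= 0")
  }
  if (min_dry + max_missing != streak_len) {
    abort("min_dry + max_missing must equal streak_len")
  }
  structure(list(streak_len = as.integer(streak_len),
                 max_missing = as.integer(max_missing),
                 min_dry = as.integer(min_dry)),
            class = "streak_rule")
}

# Accept either a nights tibble or a bare status vector.
as_status <- function(nights) {
  if (is.character(nights)) return(nights)
  if (is.data.frame(nights)) return(nights$status)
  abort("expected a nights tibble or a status character vector")
}

pad_status <- function(status, to = 56L) {
  if (length(status) >= to) status else
    c(status, rep("missing", to - length(status)))
}

#' Find the earliest qualifying dry streak
#'
#' Scans windows of `rule$streak_len` consecutive nights and returns the
#' day on which the first qualifying window ends: no wet nights, at most
#' `rule$max_missing` missing nights, at least `rule$min_dry` dry nights.
#'
#' @param nights A nights tibble (or bare status vector) for one patient.
#' @param rule A [streak_rule()].
#' @param search_end Last window end considered (default: calendar length).
#' @return The success day (integer) or `NA` if no window qualifies (in
#'   particular whenever `search_end < rule$streak_len`).
#' @export
find_dry_streak <- function(nights, rule = streak_rule(),
                            search_end = NULL) {
  status <- as_status(nights)
  n <- length(status)
  if (is.null(search_end)) search_end <- n
  if (search_end > n) abort("search_end exceeds calendar length")
  L <- rule$streak_len
  if (search_end < L) return(NA_integer_)
  cw <- cumsum(status == "wet")
  cm <- cumsum(status == "missing")
  ends <- L:search_end
  wet_in <- cw[ends] - c(0, cw)[ends - L + 1]
  mis_in <- cm[ends] - c(0, cm)[ends - L + 1]
  dry_in <- L - wet_in - mis_in
  ok <- wet_in == 0 & mis_in <= rule$max_missing & dry_in >= rule$min_dry
  if (!any(ok)) NA_integer_ else ends[which(ok)[1]]
}

#' Dropout test
#'
#' A patient drops out by stopping the diary before six weeks of treatment
#' (last non-missing night before day 42) without a prior qualifying dry
#' streak, or by a run of 14 or more consecutive missing nights before the
#' end of week 8 that is not preceded by success. A streak achieved before
#' the disqualifying event always takes precedence.
#'
#' @param nights Nights tibble or status vector for one patient; padded
#'   with missing nights to `search_end` if shorter.
#' @param rule A [streak_rule()].
#' @param search_end Horizon of the assessment (default 56).
#' @return A list with elements `dropout` (logical) and `reason`
#'   (`"short_treatment"`, `"missing_run"`, or `NA`).
#' @export
is_dropout <- function(nights, rule = streak_rule(), search_end = 56L) {
  status <- pad_status(as_status(nights), search_end)[seq_len(search_end)]
  success_day <- find_dry_streak(status, rule, search_end)

  recorded <- which(status != "missing")
  last_rec <- if (length(recorded) > 0) max(recorded) else 0L
  if (last_rec < 42) {
    streak_to_last <- if (last_rec >= rule$streak_len) {
      find_dry_streak(status, rule, last_rec)
    } else {
      NA_integer_
    }
    if (is.na(streak_to_last)) {
      return(list(dropout = TRUE, reason = "short_treatment"))
    }
  }

  r <- rle(status == "missing")
  run_ends <- cumsum(r$lengths)
  run_starts <- run_ends - r$lengths + 1L
  long <- r$values & r$lengths >= 14
  if (any(long)) {
    starts <- run_starts[long]
    disqualifies <- is.na(success_day) | success_day > starts
    if (any(disqualifies)) {
      return(list(dropout = TRUE, reason = "missing_run"))
    }
  }
  list(dropout = FALSE, reason = NA_character_)
}

#' Wet-night reduction ratio
#'
#' Compares the last two treatment weeks (days 43--56) with the first two
#' (days 1--14): `expected_wet_count(days 43-56) / max(expected_wet_count
#' (days 1-14), 1)`. Missing nights contribute their expected value so a
#' patchy diary is neither rewarded nor punished.
#'
#' @param nights Nights tibble or status vector for one patient (padded
#'   with missing nights to 56 if shorter).
#' @param baseline_rate Prior nightly wetting probability used when a
#'   missing night has no recorded history (registration enuresis
#'   frequency / 7).
#' @return A non-negative ratio.
#' @export
reduction_ratio <- function(nights, baseline_rate = 0.5) {
  status <- pad_status(as_status(nights), 56L)
  first2 <- expected_wet_count(status, 1:14, baseline_rate)
  last2 <- expected_wet_count(status, 43:56, baseline_rate)
  last2 / max(first2, 1)
}

#' Label one calendar
#'
#' Applies the response rules in order of precedence: successful if a
#' qualifying dry streak ends by day 56; otherwise dropout; otherwise
#' partially successful if the wet-night reduction ratio is at most 0.5
#' (the "decreased by 50% or more" boundary is inclusive); otherwise
#' unsuccessful.
#'
#' @inheritParams reduction_ratio
#' @param rule A [streak_rule()].
#' @return A one-row tibble: `label`, `success_day`, `reduction_ratio`,
#'   `dropout_reason` (exactly one metadata field populated).
#' @export
label_outcome <- function(nights, rule = streak_rule(),
                          baseline_rate = 0.5) {
  status <- pad_status(as_status(nights), 56L)
  success_day <- find_dry_streak(status, rule, 56L)
  if (!is.na(success_day)) {
    return(tibble(label = "successful", success_day = success_day,
                  reduction_ratio = NA_real_,
                  dropout_reason = NA_character_))
  }
  drop <- is_dropout(status, rule, 56L)
  if (drop$dropout) {
    return(tibble(label = "dropout", success_day = NA_integer_,
                  reduction_ratio = NA_real_, dropout_reason = drop$reason))
  }
  ratio <- reduction_ratio(status, baseline_rate)
  tibble(
    label = if (ratio <= 0.5) "partially_successful" else "unsuccessful",
    success_day = NA_integer_, reduction_ratio = ratio,
    dropout_reason = NA_character_
  )
}

#' Label every patient in a cohort
#'
#' @param cohort An [enuresis_cohort()].
#' @param rule A [streak_rule()].
#' @return Tibble with one row per patient: `patient_id`, `label`,
#'   `success_day`, `reduction_ratio`, `dropout_reason`.
#' @export
label_outcomes <- function(cohort, rule = streak_rule()) {
  stopifnot(inherits(cohort, "enuresis_cohort"))
  reg <- cohort$registrations
  baseline <- ifelse(is.na(reg$enuresis_frequency), 0.5,
                     reg$enuresis_frequency / 7)
  status_by <- split(cohort$nights$status, cohort$nights$patient_id)
  map(seq_len(nrow(reg)), function(i) {
    pid <- reg$patient_id[i]
    out <- label_outcome(status_by[[pid]], rule, baseline[i])
    mutate(out, patient_id = pid, .before = 1)
  }) %>% list_rbind()
}
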