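# Feature engineering: 26 registration variables, 12 nightly variables and
# 14 rolling computational variables per treatment day, with cohort-level
# imputation and event-time sanitization. All imputation statistics come
# from a cohort_statistics object so that, inside model training, they can
# be computed from the training split only.

reg_feature_names <- function() {
  c("age", "motivation", "enuresis_frequency",
    paste0("alarm_", alarm_type_levels()),
    paste0("sleep_", sleep_depth_levels()),
    "sex_male", "sex_female",
    "wets_twice", yes_no_fields(), "any_daytime_symptom")
}

night_feature_names <- function() {
  c("night_is_wet", "night_is_dry", "night_is_missing", "night_severity",
    "night_awakened_by_alarm", "night_awakened_by_parent",
    "night_not_awakened", "night_repeat_wetting", "night_woke_to_void",
    "night_first_event_time", "night_n_events", "night_event_before_180")
}

rolling_feature_names <- function() {
  c("roll_wet_last_7", "roll_wet_last_14", "roll_expected_wet_last_14",
    "roll_missing_last_7", "roll_missing_last_14",
    "roll_current_dry_streak", "roll_longest_dry_streak",
    "roll_week_wet_ratio", "roll_days_elapsed", "roll_cumulative_wet",
    "roll_cumulative_missing", "roll_mean_first_event_time_14",
    "roll_repeat_wet_last_14", "roll_alarm_wake_fraction_14")
}

#' Names of the 52 per-day features
#'
#' Registration block (26), nightly block (12), rolling block (14), in the
#' fixed column order used by [build_feature_matrix()].
#' @return Character vector of length 52.
#' @export
feature_names <- function() {
  c(reg_feature_names(), night_feature_names(), rolling_feature_names())
}

stat_mode <- function(x, levels) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(levels[1])
  counts <- table(factor(x, levels = levels))
  levels[which.max(counts)]
}

#' Cohort imputation statistics
#'
#' Medians of the numeric registration answers, modes of the categorical
#' ones, the modal wet-night severity and the median plausible first-event
#' time, all computed over patients with recorded values. Compute these on
#' the training split only when used inside model training, so no test
#' information leaks into imputation.
#'
#' @param cohort An [enuresis_cohort()].
#' @param time_cutoff Event times above this (minutes after sleep onset)
#'   are considered implausible and excluded from the median (default 720,
#'   i.e. 12 h).
#' @return A `cohort_statistics` list.
#' @export
cohort_statistics <- function(cohort, time_cutoff = 720) {
  stopifnot(inherits(cohort, "enuresis_cohort"))
  reg <- cohort$registrations
  if (nrow(reg) == 0) abort("cannot compute statistics on an empty cohort")
  med <- function(x, fallback) {
    x <- x[!is.na(x)]
    if (length(x) == 0) fallback else median(x)
  }
  modes <- c(
    sex = stat_mode(reg$sex, c("male", "female")),
    wets_once_or_twice = stat_mode(reg$wets_once_or_twice, c("once", "twice"))
  )
  for (f in yes_no_fields()) {
    modes[[f]] <- stat_mode(reg[[f]], c("no", "yes"))
  }
  wet <- filter(cohort$nights, .data$status == "wet")
  first_times <- map_dbl(wet$event_times, function(x) {
    if (length(x) == 0) NA_real_ else min(x)
  })
  plausible <- first_times[!is.na(first_times) & first_times <= time_cutoff]
  structure(
    list(
      age_median = med(reg$age, 9),
      motivation_median = med(reg$motivation, 4),
      enuresis_frequency_median = med(reg$enuresis_frequency, 5),
      modes = modes,
      severity_mode = if (any(!is.na(wet$severity))) {
        as.integer(stat_mode(wet$severity, 0:3))
      } else {
        2L
      },
      event_time_median = if (length(plausible) > 0) {
        median(plausible)
      } else {
        240
      },
      time_cutoff = time_cutoff
    ),
    class = "cohort_statistics"
  )
}

#' Sanitize an event time
#'
#' Diary event times beyond a plausible sleep duration (e.g. a reported
#' wetting 17 hours after going to sleep) are replaced by the cohort median
#' event time; plausible times pass through unchanged. The cutoff is
#' inclusive: exactly 720 minutes is kept.
#'
#' @param t Minutes after sleep onset (vectorized, non-negative).
#' @param stats A [cohort_statistics()].
#' @return Sanitized times.
#' @export
sanitize_event_time <- function(t, stats) {
  if (any(t < 0, na.rm = TRUE)) abort("event times must be non-negative")
  ifelse(!is.na(t) & t > stats$time_cutoff, stats$event_time_median, t)
}

#' Expected wet-night count over a window
#'
#' Sums, over the window, 1 for each wet night, 0 for each dry night and,
#' for each missing night, the estimated wetting probability
#' `p(d) = wet recorded before day d / nights recorded before day d`
#' (falling back to `baseline_rate` when nothing was recorded yet). Missing
#' nights are thereby treated as neither wet nor dry but as their expected
#' value under the patient's own history.
#'
#' @param nights Nights tibble or status vector for one patient.
#' @param window Integer day range, within `1..length(nights)`.
#' @param baseline_rate Prior nightly wetting probability (registration
#'   enuresis frequency / 7) used before any night is recorded.
#' @return Expected count (double).
#' @export
expected_wet_count <- function(nights, window, baseline_rate = 0.5) {
  status <- as_status(nights)
  if (length(window) == 0) abort("window must be non-empty")
  if (min(window) < 1 || max(window) > length(status)) {
    abort("window outside the calendar")
  }
  wet <- status == "wet"
  rec <- status != "missing"
  cum_wet <- c(0, cumsum(wet))
  cum_rec <- c(0, cumsum(rec))
  p_hat <- ifelse(cum_rec[window] > 0, cum_wet[window] / cum_rec[window],
                  baseline_rate)
  contribution <- ifelse(wet[window], 1,
                         ifelse(rec[window], 0, p_hat))
  sum(contribution)
}

# -- registration encoding ---------------------------------------------------

one_hot <- function(x, levels, prefix) {
  m <- outer(x, levels, `==`) * 1
  colnames(m) <- paste0(prefix, levels)
  m
}

encode_registrations <- function(reg, stats) {
  impute_num <- function(x, m) ifelse(is.na(x), m, x)
  impute_cat <- function(x, fill) ifelse(is.na(x), fill, x)
  age <- impute_num(reg$age, stats$age_median)
  motivation <- impute_num(reg$motivation, stats$motivation_median)
  freq <- impute_num(reg$enuresis_frequency, stats$enuresis_frequency_median)
  alarm <- impute_cat(reg$alarm_type, "no_or_unknown")
  sleep <- impute_cat(reg$sleep_depth, "dont_know")
  sex <- impute_cat(reg$sex, stats$modes[["sex"]])
  once_twice <- impute_cat(reg$wets_once_or_twice,
                           stats$modes[["wets_once_or_twice"]])
  out <- cbind(
    age = age, motivation = motivation, enuresis_frequency = freq,
    one_hot(alarm, alarm_type_levels(), "alarm_"),
    one_hot(sleep, sleep_depth_levels(), "sleep_"),
    one_hot(sex, c("male", "female"), "sex_"),
    wets_twice = (once_twice == "twice") * 1
  )
  yn <- matrix(0, nrow(reg), length(yes_no_fields()),
               dimnames = list(NULL, yes_no_fields()))
  for (f in yes_no_fields()) {
    yn[, f] <- (impute_cat(reg[[f]], stats$modes[[f]]) == "yes") * 1
  }
  composite <- pmax(yn[, "daytime_wetting"], yn[, "daytime_urgency"])
  out <- cbind(out, yn, any_daytime_symptom = composite)
  out[, reg_feature_names(), drop = FALSE]
}

#' Encode one registration record as 26 numeric features
#'
#' Numeric answers (age, motivation, enuresis frequency) are kept as is,
#' alarm type / sleep depth / sex become one-hot blocks, the remaining
#' questions become binaries, and a composite flag marks any daytime
#' symptom (daytime wetting or urgency). Missing numerics are imputed by
#' the cohort median, missing binaries by the cohort mode, missing sleep
#' depth by the explicit "don't know" level and missing alarm type by the
#' "no or unknown" level, so the encoding is total.
#'
#' @param reg A one-row registration tibble.
#' @param stats A [cohort_statistics()].
#' @return Named numeric vector of length 26.
#' @export
encode_registration <- function(reg, stats) {
  encode_registrations(as_tibble(reg), stats)[1, ]
}

# -- nightly encoding --------------------------------------------------------

encode_nights <- function(nights, stats) {
  n <- nrow(nights)
  is_wet <- (nights$status == "wet") * 1
  is_dry <- (nights$status == "dry") * 1
  is_missing <- (nights$status == "missing") * 1
  severity <- ifelse(is_wet == 1,
                     ifelse(is.na(nights$severity), stats$severity_mode,
                            nights$severity),
                     0)
  awak <- ifelse(is.na(nights$awakening), "", nights$awakening)
  first_time <- map_dbl(seq_len(n), function(i) {
    if (is_wet[i] != 1) return(0)
    times <- nights$event_times[[i]]
    if (length(times) == 0) return(stats$event_time_median)
    sanitize_event_time(min(times), stats)
  })
  n_events <- lengths(nights$event_times)
  before_180 <- map_dbl(nights$event_times, function(x) {
    any(x[x <= stats$time_cutoff] < 180) * 1
  })
  out <- cbind(
    night_is_wet = is_wet, night_is_dry = is_dry,
    night_is_missing = is_missing, night_severity = severity,
    night_awakened_by_alarm = (awak == "alarm") * 1,
    night_awakened_by_parent = (awak == "parent") * 1,
    night_not_awakened = (awak == "not_awakened") * 1,
    night_repeat_wetting = (!is.na(nights$repeat_wetting) &
                              nights$repeat_wetting == "yes") * 1,
    night_woke_to_void = (!is.na(nights$woke_to_void) &
                            nights$woke_to_void == "yes") * 1,
    night_first_event_time = first_time,
    night_n_events = as.numeric(n_events),
    night_event_before_180 = before_180
  )
  out[, night_feature_names(), drop = FALSE]
}

#' Encode one night as 12 numeric features
#'
#' Status indicators, severity (imputed by the cohort mode when a wet
#' night's severity is unrecorded), awakening indicators, repeat-wetting
#' and woke-to-void flags, the sanitized first event time (0 on dry or
#' missing nights; the cohort median when a wet night has no recorded
#' time), the event count and a flag for any event before 180 minutes.
#'
#' @param night A one-row nights tibble.
#' @param stats A [cohort_statistics()].
#' @return Named numeric vector of length 12.
#' @export
encode_night <- function(night, stats) {
  encode_nights(as_tibble(night), stats)[1, ]
}

# -- rolling computational variables -----------------------------------------

#' Rolling computational features at a treatment day
#'
#' The 14 variables summarizing a patient's history up to (and including)
#' `day`: raw wet and missing counts over the trailing 7- and 14-night
#' windows, the expectation-compensated wet count over the trailing 14
#' nights, the current and longest dry streaks (nights since a wet night;
#' missing nights do not break a streak), the ratio of the
#' expectation-compensated wet count of the current week so far to that of
#' week 1 (denominator floored at 1), days elapsed, compensated cumulative
#' wet count, cumulative missing count, mean sanitized first event time
#' over the trailing 14 nights (cohort median when no wet night), the
#' repeat-wetting count and the alarm-awakening fraction of wet nights in
#' the window (0 when there are none). Windows truncate at day 1; nothing
#' after `day` is read.
#'
#' @param nights Nights tibble for one patient.
#' @param day Day index, `1..nrow(nights)`.
#' @param stats A [cohort_statistics()].
#' @param baseline_rate Prior nightly wetting probability for
#'   [expected_wet_count()].
#' @return Named numeric vector of length 14.
#' @export
compute_rolling <- function(nights, day, stats, baseline_rate = 0.5) {
  status <- as_status(nights)
  if (day < 1 || day > length(status)) abort("day outside the calendar")
  w7 <- max(1, day - 6):day
  w14 <- max(1, day - 13):day
  st7 <- status[w7]
  st14 <- status[w14]

  wet_days <- which(status[seq_len(day)] == "wet")
  if (length(wet_days) == 0) {
    current_streak <- day
    longest_streak <- day
  } else {
    current_streak <- day - max(wet_days)
    gaps <- diff(c(0L, wet_days)) - 1L
    longest_streak <- max(c(gaps, day - max(wet_days)))
  }

  week <- ceiling(day / 7)
  cur_week_window <- (7 * (week - 1) + 1):day
  num <- expected_wet_count(status, cur_week_window, baseline_rate)
  den <- max(expected_wet_count(status, 1:min(7, day), baseline_rate), 1)

  wet14_idx <- w14[st14 == "wet"]
  if (length(wet14_idx) > 0) {
    times <- map_dbl(wet14_idx, function(d) {
      ts <- nights$event_times[[d]]
      if (length(ts) == 0) stats$event_time_median else
        sanitize_event_time(min(ts), stats)
    })
    mean_first_time <- mean(times)
    alarm_frac <- mean(!is.na(nights$awakening[wet14_idx]) &
                         nights$awakening[wet14_idx] == "alarm")
  } else {
    mean_first_time <- stats$event_time_median
    alarm_frac <- 0
  }

  c(
    roll_wet_last_7 = sum(st7 == "wet"),
    roll_wet_last_14 = sum(st14 == "wet"),
    roll_expected_wet_last_14 =
      expected_wet_count(status, w14, baseline_rate),
    roll_missing_last_7 = sum(st7 == "missing"),
    roll_missing_last_14 = sum(st14 == "missing"),
    roll_current_dry_streak = current_streak,
    roll_longest_dry_streak = longest_streak,
    roll_week_wet_ratio = num / den,
    roll_days_elapsed = day,
    roll_cumulative_wet =
      expected_wet_count(status, seq_len(day), baseline_rate),
    roll_cumulative_missing = sum(status[seq_len(day)] == "missing"),
    roll_mean_first_event_time_14 = mean_first_time,
    roll_repeat_wet_last_14 = sum(!is.na(nights$repeat_wetting[w14]) &
                                    nights$repeat_wetting[w14] == "yes"),
    roll_alarm_wake_fraction_14 = alarm_frac
  )
}

#' Per-day feature matrix for a cohort
#'
#' One row per patient: the 26 registration features, the 12 nightly
#' features of `day`, and the 14 rolling features at `day`. All history
#' before `day` enters only through the rolling block; nothing after `day`
#' is read, so predictions made from this matrix use only information
#' available on that treatment day.
#'
#' @param cohort An [enuresis_cohort()] whose calendars all span `day`.
#' @param day Treatment day index.
#' @param stats A [cohort_statistics()] (compute it on the training split
#'   when the matrix feeds model training).
#' @return Tibble: `patient_id`, `day_index`, then the 52 features of
#'   [feature_names()].
#' @export
build_feature_matrix <- function(cohort, day, stats) {
  stopifnot(inherits(cohort, "enuresis_cohort"))
  reg <- cohort$registrations
  nights_by <- split(cohort$nights, cohort$nights$patient_id)
  short <- names(nights_by)[vapply(nights_by, nrow, integer(1)) < day]
  if (length(short) > 0) {
    abort(sprintf("calendar of patient %s is shorter than day %d",
                  short[1], day))
  }
  reg_block <- encode_registrations(reg, stats)
  day_rows <- cohort$nights %>% filter(.data$day_index == day)
  day_rows <- day_rows[match(reg$patient_id, day_rows$patient_id), ]
  night_block <- encode_nights(day_rows, stats)
  baseline <- ifelse(is.na(reg$enuresis_frequency),
                     stats$enuresis_frequency_median / 7,
                     reg$enuresis_frequency / 7)
  roll_block <- t(vapply(seq_len(nrow(reg)), function(i) {
    compute_rolling(nights_by[[reg$patient_id[i]]], day, stats, baseline[i])
  }, numeric(length(rolling_feature_names()))))
  out <- bind_cols(
    tibble(patient_id = reg$patient_id, day_index = day),
    as_tibble(reg_block), as_tibble(night_block),
    as_tibble(roll_block)
  )
  out
}
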