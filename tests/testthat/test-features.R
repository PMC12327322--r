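stats_with <- function(event_time_median = 240) {
  co <- cohort_from_status(list(rep("dry", 5)))
  st <- cohort_statistics(co)
  st$event_time_median <- event_time_median
  st
}

test_that("registration encoding one-hots, composites and imputes", {
  co <- small_sim()
  st <- cohort_statistics(co)
  reg <- co$registrations[1, ]
  reg$sleep_depth <- "difficult"
  v <- encode_registration(reg, st)
  expect_length(v, 26)
  expect_equal(unname(v[paste0("sleep_", c("almost_impossible", "difficult",
                                           "neither", "easy", "dont_know"))]),
               c(0, 1, 0, 0, 0))
  expect_equal(sum(v[grep("^alarm_", names(v))]), 1)
  expect_equal(sum(v[c("sex_male", "sex_female")]), 1)
  expect_equal(
    unname(v["any_daytime_symptom"]),
    max(v["daytime_wetting"], v["daytime_urgency"]))

  # missing numeric -> cohort median; missing sleep depth -> dont_know
  reg$age <- NA
  reg$sleep_depth <- NA
  v2 <- encode_registration(reg, st)
  expect_equal(unname(v2["age"]), st$age_median)
  expect_equal(unname(v2["sleep_dont_know"]), 1)
})

test_that("night encoding matches the slot definitions", {
  st <- stats_with()
  dry <- tibble::tibble(
    patient_id = "x", day_index = 1L, status = "dry", severity = NA_integer_,
    awakening = NA_character_, repeat_wetting = NA_character_,
    woke_to_void = "yes", event_times = list(integer(0))
  )
  expect_equal(unname(encode_night(dry, st)),
               c(0, 1, 0, 0, 0, 0, 0, 0, 1, 0, 0, 0))

  miss <- dry
  miss$status <- "missing"
  miss$woke_to_void <- NA_character_
  v <- encode_night(miss, st)
  expect_equal(unname(v["night_is_missing"]), 1)
  expect_equal(sum(v[setdiff(names(v), "night_is_missing")]), 0)

  wet <- dry
  wet$status <- "wet"
  wet$woke_to_void <- NA_character_
  wet$severity <- 3L
  wet$awakening <- "alarm"
  wet$repeat_wetting <- "no"
  wet$event_times <- list(1020L)
  v <- encode_night(wet, st)
  # the implausible 17-hour report is replaced by the cohort median
  expect_equal(unname(v["night_first_event_time"]), 240)
  expect_equal(unname(v["night_awakened_by_alarm"]), 1)

  # wet night with unrecorded severity takes the cohort mode
  wet$severity <- NA_integer_
  wet$event_times <- list(90L)
  v <- encode_night(wet, st)
  expect_equal(unname(v["night_severity"]), as.numeric(st$severity_mode))
  expect_equal(unname(v["night_event_before_180"]), 1)
})

test_that("event-time sanitization is inclusive at the 12-hour cutoff", {
  st <- stats_with(event_time_median = 240)
  expect_equal(sanitize_event_time(240, st), 240)
  expect_equal(sanitize_event_time(720, st), 720)
  expect_equal(sanitize_event_time(1020, st), 240)
  expect_error(sanitize_event_time(-5, st), "non-negative")
})

test_that("expected wet count compensates missing nights by history", {
  expect_equal(
    expected_wet_count(c(rep("wet", 5), rep("dry", 9)), 1:14), 5)
  # p(4) = 2 wet / 3 recorded
  expect_equal(
    expected_wet_count(c("wet", "wet", "dry", "missing"), 1:4), 2 + 2 / 3)
  # no history at all: the registration baseline carries the window
  expect_equal(
    expected_wet_count(rep("missing", 14), 1:14, baseline_rate = 1), 14)
  expect_error(expected_wet_count(rep("dry", 5), integer(0)), "non-empty")
  expect_error(expected_wet_count(rep("dry", 5), 4:6), "outside")
})

test_that("expected wet count equals the raw count on dense calendars", {
  set.seed(42)
  for (i in 1:25) {
    status <- sample(c("wet", "dry"), 56, replace = TRUE)
    window <- sort(sample(56, 2))
    window <- window[1]:window[2]
    expect_equal(expected_wet_count(status, window),
                 sum(status[window] == "wet"))
  }
})

test_that("flipping a missing night moves the expected count monotonically", {
  set.seed(7)
  for (i in 1:20) {
    status <- sample(c("wet", "dry", "missing"), 30, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    mis <- which(status == "missing")
    if (length(mis) == 0) next
    d <- sample(mis, 1)
    base <- expected_wet_count(status, 1:30, 0.5)
    up <- replace(status, d, "wet")
    down <- replace(status, d, "dry")
    expect_gte(expected_wet_count(up, 1:30, 0.5), base)
    expect_lte(expected_wet_count(down, 1:30, 0.5), base)
  }
})

test_that("rolling features match hand computations", {
  st <- stats_with()
  mk <- function(status) cohort_from_status(list(status))$nights

  # day 14, no missing, 6 wet in days 1-14
  status <- c(rep("wet", 6), rep("dry", 8))
  v <- compute_rolling(mk(status), 14, st)
  expect_equal(unname(v["roll_wet_last_14"]), 6)
  expect_equal(unname(v["roll_missing_last_14"]), 0)
  expect_equal(unname(v["roll_expected_wet_last_14"]), 6)

  # day 7 of an all-dry calendar
  v <- compute_rolling(mk(rep("dry", 7)), 7, st)
  expect_equal(unname(v["roll_current_dry_streak"]), 7)
  expect_equal(unname(v["roll_week_wet_ratio"]), 0)

  # week 1 fully wet, days 15-21 with 3 wet: ratio 3/7 at day 21
  status <- c(rep("wet", 7), rep("dry", 7), rep(c("wet", "dry"), c(3, 4)))
  v <- compute_rolling(mk(status), 21, st)
  expect_equal(unname(v["roll_week_wet_ratio"]), 3 / 7)
  expect_equal(unname(v["roll_days_elapsed"]), 21)

  expect_error(compute_rolling(mk(rep("dry", 7)), 9, st), "outside")
})

test_that("feature matrices are complete, finite and leakage-free", {
  co <- small_sim(seed = 5)
  st <- cohort_statistics(co)
  fm <- build_feature_matrix(co, 30, st)
  expect_equal(dim(fm), c(n_patients(co), 54))
  expect_equal(names(fm)[-(1:2)], feature_names())
  expect_true(all(is.finite(as.matrix(fm[, feature_names()]))))

  # registration block constant across days; later blocks may move
  fm29 <- build_feature_matrix(co, 29, st)
  reg_cols <- setdiff(feature_names(), feature_names()[27:52])
  expect_equal(fm[, reg_cols], fm29[, reg_cols])

  # rewriting the calendar after day d never changes the day-d features
  nights2 <- co$nights
  late <- nights2$day_index > 30
  nights2$status[late] <- "missing"
  nights2$severity[late] <- NA_integer_
  nights2$awakening[late] <- NA_character_
  nights2$repeat_wetting[late] <- NA_character_
  nights2$woke_to_void[late] <- NA_character_
  nights2$event_times[late] <- list(integer(0))
  co2 <- enuresis_cohort(co$registrations, nights2, co$latent_classes)
  expect_equal(build_feature_matrix(co2, 30, st), fm)

  short <- enuresis_cohort(co$registrations[1, ],
                           co$nights[co$nights$patient_id ==
                                       co$registrations$patient_id[1], ][1:10, ])
  expect_error(build_feature_matrix(short, 30, st), "shorter than day 30")
})
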