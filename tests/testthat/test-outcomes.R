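test_that("streak rule construction enforces its arithmetic", {
  r <- streak_rule()
  expect_equal(r$streak_len, 14L)
  expect_equal(r$max_missing, 2L)
  expect_equal(r$min_dry, 12L)
  expect_error(streak_rule(14, 2, 13), "must equal")
})

test_that("dry-streak detection follows the tolerated-missing rule", {
  expect_equal(find_dry_streak(rep("dry", 56)), 14)
  # 12 dry + 2 missing, 0 wet qualifies
  status <- c(rep("dry", 6), "missing", rep("dry", 3), "missing",
              rep("dry", 3), rep("wet", 42))
  expect_equal(find_dry_streak(status), 14)
  # 3 missing in the window does not
  status <- c(rep("dry", 5), rep("missing", 3), rep("dry", 6),
              rep("wet", 42))
  expect_true(is.na(find_dry_streak(status, search_end = 14)))
  expect_true(is.na(find_dry_streak(rep(c("wet", "dry"), 28))))
  expect_true(is.na(find_dry_streak(rep("dry", 10), search_end = 10)))
  expect_error(find_dry_streak(rep("dry", 10), search_end = 20), "exceeds")
})

test_that("dropout rules respect success precedence", {
  # stopped recording at day 30 with no streak
  status <- c(rep(c("wet", "dry"), 15), rep("missing", 26))
  d <- is_dropout(status)
  expect_true(d$dropout)
  expect_equal(d$reason, "short_treatment")

  # success in days 1-14 precedes the total missing run
  status <- c(rep("dry", 14), rep("missing", 42))
  d <- is_dropout(status)
  expect_false(d$dropout)

  # interior 14-day missing run without success
  status <- rep("wet", 56)
  status[20:33] <- "missing"
  d <- is_dropout(status)
  expect_true(d$dropout)
  expect_equal(d$reason, "missing_run")
})

test_that("reduction ratio compares first and last two weeks", {
  status <- c(rep("wet", 14), rep("dry", 28), rep("wet", 14))
  expect_equal(reduction_ratio(status), 1)
  status <- c(rep("wet", 14), rep("dry", 28), rep("wet", 6), rep("dry", 8))
  expect_equal(reduction_ratio(status), 6 / 14)
  expect_equal(reduction_ratio(rep("dry", 56)), 0)
})

test_that("outcome labels follow the rule precedence and boundaries", {
  lab <- label_outcome(rep("dry", 56))
  expect_equal(lab$label, "successful")
  expect_equal(lab$success_day, 14)
  expect_true(is.na(lab$reduction_ratio))

  # 7 wet per week throughout
  lab <- label_outcome(rep(c("wet"), 56))
  expect_equal(lab$label, "unsuccessful")
  expect_equal(lab$reduction_ratio, 1)

  # halving is inclusive: 12 wet in weeks 1-2, 6 wet in weeks 7-8
  status <- c(rep(c("wet", "wet", "wet", "wet", "wet", "wet", "dry"), 2),
              rep(c("wet", "dry"), 14),
              rep(c("wet", "wet", "wet", "dry", "dry", "dry", "dry"), 2))
  expect_equal(sum(status[1:14] == "wet"), 12)
  expect_equal(sum(status[43:56] == "wet"), 6)
  lab <- label_outcome(status)
  expect_equal(lab$label, "partially_successful")
  expect_equal(lab$reduction_ratio, 0.5)
})

test_that("every calendar gets exactly one label with matching metadata", {
  co <- small_sim(seed = 21)
  labels <- label_outcomes(co)
  expect_equal(nrow(labels), n_patients(co))
  expect_true(all(labels$label %in%
                    c("successful", "partially_successful", "unsuccessful",
                      "dropout")))
  populated <- (!is.na(labels$success_day)) +
    (!is.na(labels$reduction_ratio)) + (!is.na(labels$dropout_reason))
  expect_true(all(populated == 1))
  expect_true(all(is.na(labels$success_day) |
                    labels$label == "successful"))
  expect_true(all(is.na(labels$dropout_reason) |
                    labels$label == "dropout"))
  expect_true(all(labels$reduction_ratio >= 0, na.rm = TRUE))
})

test_that("labeling agrees with the literal rule transcription", {
  set.seed(13)
  for (i in 1:100) {
    status <- sample(c("wet", "dry", "missing"), 56, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    freq <- round(runif(1, 0, 7), 1)
    got <- label_outcome(status, baseline_rate = freq / 7)
    want <- oracle_label(status, freq)
    expect_equal(got$label, want$label)
  }
})
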