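mk_preds <- function(rows) {
  tibble::tibble(
    patient_id = rows$id, day_index = rows$day,
    p_successful = rows$ps, p_partial = rows$pp, p_unsuccessful = rows$pu
  )
}

test_that("daily accuracy counts argmax hits with a fixed tie-break", {
  labels <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                           label = c("successful", "successful",
                                     "unsuccessful", "partially_successful"))
  preds <- mk_preds(data.frame(
    id = c("a", "b", "c", "d"), day = 1,
    ps = c(0.8, 0.1, 0.2, 0.2), pp = c(0.1, 0.2, 0.3, 0.7),
    pu = c(0.1, 0.7, 0.5, 0.1)
  ))
  # a, c, d predicted correctly; b is called unsuccessful
  expect_equal(daily_accuracy(preds, labels)$accuracy, 0.75)

  # uniform probabilities resolve to the first class in the fixed order
  tie <- mk_preds(data.frame(id = "a", day = 1, ps = 1 / 3, pp = 1 / 3,
                             pu = 1 / 3))
  expect_equal(daily_accuracy(tie, labels[1, ])$accuracy, 1)

  expect_error(daily_accuracy(preds, labels[1:2, ]), "no label")
  expect_error(daily_accuracy(dplyr::bind_rows(preds, preds[1, ]), labels),
               "duplicate")
})

test_that("precision and recall use the zero-denominator convention", {
  labels <- tibble::tibble(patient_id = c("a", "b"),
                           label = c("successful", "unsuccessful"))
  perfect <- mk_preds(data.frame(id = c("a", "b"), day = 1,
                                 ps = c(0.9, 0.1), pp = 0,
                                 pu = c(0.1, 0.9)))
  pr <- precision_recall(perfect, labels)
  expect_equal(pr$precision[pr$class == "successful"], 1)
  expect_equal(pr$recall[pr$class == "unsuccessful"], 1)
  # nothing predicted as partial and no partial patients: both 0
  expect_equal(pr$precision[pr$class == "partially_successful"], 0)
  expect_equal(pr$recall[pr$class == "partially_successful"], 0)
})

test_that("micro-averaged recall equals daily accuracy", {
  rp <- random_predictions(n_patients = 25, days = 1:10, seed = 5)
  acc <- daily_accuracy(rp$preds, rp$labels)
  pr <- precision_recall(rp$preds, rp$labels)
  joined <- dplyr::inner_join(
    pr,
    dplyr::count(rp$labels, .data$label, name = "class_n"),
    by = c(class = "label"))
  micro <- joined |>
    dplyr::summarise(
      micro_recall = sum(recall * class_n) / sum(class_n),
      .by = day_index)
  expect_equal(micro$micro_recall, acc$accuracy, tolerance = 1e-12)
})

test_that("trend fitting recovers exact lines and degenerate series", {
  d <- tibble::tibble(day_index = 1:56, value = 0.5 + 0.0065 * 1:56)
  fit <- fit_trend(d)
  expect_equal(fit$slope, 0.0065, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  flat <- fit_trend(tibble::tibble(day_index = 1:10, value = rep(0.6, 10)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  three <- fit_trend(tibble::tibble(day_index = 1:3,
                                    value = c(0.4, 0.5, 0.7)))
  expect_equal(three$slope, 0.15)
  expect_equal(glance(three)$slope, 0.15)
  expect_equal(tidy(three)$estimate[2], 0.15)
  expect_error(fit_trend(d[1, ]), "at least 2")
})

test_that("threshold counts are exact and monotone in the threshold", {
  labels <- tibble::tibble(patient_id = c("a", "b"),
                           label = c("successful", "unsuccessful"))
  preds <- mk_preds(data.frame(id = c("a", "b"), day = 1,
                               ps = c(0.6, 0.55), pp = c(0.2, 0.15),
                               pu = c(0.2, 0.3)))
  tc <- threshold_counts(preds, labels, "successful", 0.5)
  expect_equal(tc$n[tc$true_label == "successful"], 1L)
  expect_equal(tc$n[tc$true_label == "unsuccessful"], 1L)
  none <- threshold_counts(preds, labels, "successful", 0.9)
  expect_true(all(none$n == 0))

  rp <- random_predictions(n_patients = 30, days = 1:8, seed = 9)
  prev <- NULL
  for (t in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- threshold_counts(rp$preds, rp$labels, "unsuccessful", t)
    if (!is.null(prev)) expect_true(all(cur$n <= prev$n))
    prev <- cur
  }
  expect_error(threshold_counts(preds, labels, "successful", 1.5),
               "strictly between")
})

test_that("threshold optimization maximizes the summed TP/FP quotient", {
  labels <- tibble::tibble(patient_id = sprintf("p%d", 1:10),
                           label = rep(c("successful", "unsuccessful"),
                                       each = 5))
  # at 0.6 only true successes pass; at 0.5 five FPs join
  preds <- mk_preds(data.frame(
    id = sprintf("p%d", 1:10), day = 1,
    ps = c(rep(0.7, 5), rep(0.55, 5)), pp = 0.01,
    pu = 1 - 0.01 - c(rep(0.7, 5), rep(0.55, 5))
  ))
  pol <- optimize_threshold(preds, labels, "successful",
                            grid = c(0.5, 0.6), window = 1)
  expect_equal(pol$threshold, 0.6)
  expect_equal(pol$objective_value, 5 / 1)

  single <- optimize_threshold(preds, labels, "successful", grid = 0.5,
                               window = 1)
  expect_equal(single$threshold, 0.5)
  expect_equal(single$objective_value, 5 / (5 + 1))

  expect_error(optimize_threshold(preds, labels, "successful",
                                  grid = numeric(0), window = 1),
               "non-empty")
  expect_error(optimize_threshold(preds, labels, "successful",
                                  grid = 0.5, window = 2), "no predictions")
})

test_that("grid order does not matter and joint mode agrees per class", {
  rp <- random_predictions(n_patients = 20, days = 1:20, seed = 12)
  grid <- seq(0.5, 0.95, 0.05)
  a <- optimize_threshold(rp$preds, rp$labels, "successful", grid, 5:15)
  b <- optimize_threshold(rp$preds, rp$labels, "successful",
                          rev(grid), 5:15)
  expect_equal(a, b)
  sep <- optimize_thresholds(rp$preds, rp$labels, grid = grid,
                             window = 5:15)
  joint <- optimize_thresholds(rp$preds, rp$labels, grid = grid,
                               window = 5:15, joint = TRUE)
  expect_equal(as.data.frame(sep), as.data.frame(joint))
})
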