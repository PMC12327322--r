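test_that("the default search space spans 120 combinations", {
  sp <- search_space()
  expect_equal(nrow(drynights:::space_grid(sp)), 120)
  expect_error(search_space(n_trees = integer(0)), "non-empty")
  expect_error(search_space(n_folds = 1), "n_folds")
})

test_that("stratified split reproduces the 70/30 cohort flow", {
  labels <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:611),
    label = rep(c("successful", "partially_successful", "unsuccessful"),
                c(173, 151, 287))
  )
  split <- split_cohort(labels, 0.7, seed = 5)
  expect_equal(sum(split$split == "train"), 427)
  expect_equal(sum(split$split == "test"), 184)

  small <- tibble::tibble(
    patient_id = sprintf("Q%02d", 1:30),
    label = rep(c("successful", "partially_successful", "unsuccessful"),
                each = 10)
  )
  s <- split_cohort(small, 0.7, seed = 2)
  per_class <- table(s$label, s$split)
  expect_true(all(per_class[, "train"] == 7))
  expect_identical(split_cohort(small, 0.7, seed = 2),
                   split_cohort(small, 0.7, seed = 2))
  expect_error(split_cohort(dplyr::mutate(small, label = replace(
    label, 1, "dropout")), 0.7, 1), "dropout")
  expect_error(split_cohort(small[1:11, ], 0.7, 1), "fewer than 2")
})

test_that("SMOTE balances classes on interpolated segments", {
  set.seed(31)
  data <- tibble::tibble(
    f1 = c(rnorm(8, 0), rnorm(20, 5)),
    f2 = c(rnorm(8, 0), rnorm(20, 5)),
    label = rep(c("a", "b"), c(8, 20))
  )
  out <- oversample_smote(data, "label", k_neighbors = 5, seed = 1)
  expect_equal(as.vector(table(out$label)), c(20L, 20L))
  expect_equal(out[1:28, ], data)
  # balanced input passes through untouched
  bal <- data[c(1:8, 9:16), ]
  expect_equal(oversample_smote(bal, "label", seed = 1), bal)
  expect_error(oversample_smote(data[c(1:4, 9:20), ], "label", 5, 1),
               "smaller k_neighbors")

  # every synthetic row sits on a segment between a source and a
  # same-class nearest neighbour
  synth <- out[29:40, c("f1", "f2")]
  x <- as.matrix(data[data$label == "a", c("f1", "f2")])
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  for (i in seq_len(nrow(synth))) {
    s <- as.numeric(synth[i, ])
    ok <- FALSE
    for (j in seq_len(nrow(x))) {
      for (nb in order(d[j, ])[1:5]) {
        seg <- x[nb, ] - x[j, ]
        u <- sum((s - x[j, ]) * seg) / sum(seg^2)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((s - x[j, ] - u * seg)^2)) < 1e-9) {
          ok <- TRUE
          break
        }
      }
      if (ok) break
    }
    expect_true(ok)
  }
})

test_that("grid search evaluates the space and is deterministic", {
  set.seed(77)
  x <- data.frame(a = c(rnorm(20, 0), rnorm(20, 8)),
                  b = c(rnorm(20, 0), rnorm(20, 8)))
  y <- factor(rep(c("successful", "unsuccessful"), each = 20),
              levels = c("successful", "unsuccessful"))
  sp <- tiny_space(n_folds = 4L)
  gs <- grid_search_cv(x, y, sp, seed = 3)
  expect_equal(nrow(gs$results), 1)
  expect_equal(gs$best$n_trees, 50L)
  # well-separated blobs are classified perfectly in every fold
  expect_equal(gs$cv_mean_accuracy, 1)
  expect_equal(gs$cv_std_accuracy, 0)
  gs2 <- grid_search_cv(x, y, sp, seed = 3)
  expect_identical(gs$results, gs2$results)
  expect_error(grid_search_cv(x, factor(rep("a", 40)), sp, 1),
               "two classes")

  sp2 <- search_space(n_trees = c(50, 100), max_depth = c(25, 50),
                      max_features_rule = "sqrt",
                      split_criterion = c("gini", "entropy"), n_folds = 2)
  gs3 <- grid_search_cv(x, y, sp2, seed = 5)
  expect_equal(nrow(gs3$results), 8)
  # ties broken toward fewer trees, smaller depth, lexicographic criterion
  top <- gs3$results[gs3$results$cv_mean_accuracy ==
                       max(gs3$results$cv_mean_accuracy), ]
  expect_equal(gs3$best$n_trees, top$n_trees[1])
})

test_that("day models train, predict proper probabilities, and repeat", {
  co <- small_sim(n = c(successful = 10, partially_successful = 10,
                        unsuccessful = 10, dropout = 0), seed = 6)
  labels <- label_outcomes(co)
  labels <- labels[labels$label != "dropout", ]
  co <- subset_cohort(co, labels$patient_id)
  st <- cohort_statistics(co)
  m <- train_day_model(co, labels, 28, tiny_space(3L), st, seed = 2,
                       k_neighbors = 3L)
  expect_s3_class(m, "day_model")
  expect_equal(m$day_index, 28)
  expect_true(m$cv_mean_accuracy >= 0 && m$cv_mean_accuracy <= 1)
  m2 <- train_day_model(co, labels, 28, tiny_space(3L), st, seed = 2,
                        k_neighbors = 3L)
  expect_identical(m$manifest, m2$manifest)

  preds <- predict_day(m, co, st)
  expect_equal(nrow(preds), n_patients(co))
  sums <- preds$p_successful + preds$p_partial + preds$p_unsuccessful
  expect_equal(sums, rep(1, nrow(preds)), tolerance = 1e-9)
  # identical calendars produce identical probabilities
  dup <- subset_cohort(co, co$registrations$patient_id[c(1, 1:3)][c(1, 2)])
  p1 <- predict_day(m, dup, st)
  expect_identical(p1[1, -1], predict_day(m, dup, st)[1, -1])

  models <- train_all_days(co, labels, days = 1:3, space = tiny_space(3L),
                           stats = st, seed = 4, k_neighbors = 3L)
  expect_length(models, 3)
  expect_equal(tidy(models)$day_index, 1:3)
  long <- predict_days(models, co, st)
  expect_equal(nrow(long), 3 * n_patients(co))
})
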