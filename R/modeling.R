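# Per-day classifier cascade: stratified train/test split, SMOTE class
# balancing, five-fold cross-validated grid search over the random-forest
# hyperparameter space, and daily probability prediction.

#' Random-forest hyperparameter search space
#'
#' The default grid spans 4 tree counts x 5 depths x 2 feature rules x 3
#' split criteria = 120 combinations, evaluated with stratified five-fold
#' cross-validation. The backend forest (ranger) implements Gini-impurity
#' splitting for classification; the `split_criterion` axis is part of the
#' search-space interface and is recorded with each model, but its levels
#' (`entropy`, `gini`, `log_loss` — the latter two being the conventional
#' impurity pairing, with `log_loss` an alias of `entropy`) all use the
#' backend's impurity splitting.
#'
#' @param n_trees Integer set of forest sizes (default 50--200 by 50).
#' @param max_depth Integer set of maximal tree depths (default 25, 50,
#'   100, 150, 200).
#' @param max_features_rule Subset of `"sqrt"`, `"log2"`: features drawn
#'   per split as a function of the feature count.
#' @param split_criterion Subset of `"entropy"`, `"gini"`, `"log_loss"`.
#' @param n_folds Cross-validation folds (default 5).
#' @return A `search_space` list.
#' @export
search_space <- function(n_trees = c(50L, 100L, 150L, 200L),
                         max_depth = c(25L, 50L, 100L, 150L, 200L),
                         max_features_rule = c("sqrt", "log2"),
                         split_criterion = c("entropy", "gini", "log_loss"),
                         n_folds = 5L) {
  if (length(n_trees) == 0 || length(max_depth) == 0 ||
      length(max_features_rule) == 0 || length(split_criterion) == 0) {
    abort("all search-space dimensions must be non-empty")
  }
  if (!all(max_features_rule %in% c("sqrt", "log2"))) {
    abort("max_features_rule must be a subset of {sqrt, log2}")
  }
  if (!all(split_criterion %in% c("entropy", "gini", "log_loss"))) {
    abort("split_criterion must be a subset of {entropy, gini, log_loss}")
  }
  if (n_folds < 2) abort("n_folds must be >= 2")
  structure(
    list(n_trees = sort(as.integer(n_trees)),
         max_depth = sort(as.integer(max_depth)),
         max_features_rule = sort(max_features_rule),
         split_criterion = sort(split_criterion),
         n_folds = as.integer(n_folds)),
    class = "search_space"
  )
}

# All combinations, ordered by the deterministic tie-break priority:
# fewer trees, then smaller depth, then lexicographic criterion and rule.
space_grid <- function(space) {
  tidyr::expand_grid(
    n_trees = space$n_trees, max_depth = space$max_depth,
    split_criterion = space$split_criterion,
    max_features_rule = space$max_features_rule
  )
}

#' Stratified train/test split
#'
#' Assigns `floor(train_fraction * n)` patients to the training group,
#' apportioned across outcome classes by largest remainder so class
#' proportions carry over, with seeded sampling inside each class.
#'
#' @param labels Tibble (`patient_id`, `label`) of labeled non-dropout
#'   patients.
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return The `labels` tibble with an added `split` column
#'   (`"train"`/`"test"`).
#' @export
split_cohort <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (any(labels$label == "dropout")) {
    abort("dropouts must be excluded before splitting")
  }
  counts <- table(labels$label)
  if (any(counts < 2)) {
    abort(sprintf("class '%s' has fewer than 2 members",
                  names(counts)[which(counts < 2)[1]]))
  }
  classes <- sort(names(counts))
  n_train_total <- floor(train_fraction * nrow(labels))
  quota <- train_fraction * as.numeric(counts[classes])
  base <- floor(quota)
  remainder <- n_train_total - sum(base)
  frac_order <- order(-(quota - base), classes)
  extra <- integer(length(classes))
  if (remainder > 0) extra[frac_order[seq_len(remainder)]] <- 1L
  n_train <- setNames(base + extra, classes)

  set.seed(seed)
  train_ids <- character(0)
  for (cls in classes) {
    ids <- sort(labels$patient_id[labels$label == cls])
    train_ids <- c(train_ids, sample(ids, n_train[[cls]]))
  }
  mutate(labels,
         split = ifelse(.data$patient_id %in% train_ids, "train", "test"))
}

#' SMOTE class balancing
#'
#' Brings every class up to the majority-class count by synthesizing
#' minority-class rows on the segment between an existing row and one of
#' its `k_neighbors` nearest same-class neighbours (Euclidean distance on
#' the numeric features, uniform interpolation). Original rows pass
#' through unchanged; synthetic rows are appended after them.
#'
#' @param data Tibble with a label column and numeric feature columns
#'   (non-numeric columns other than the label, e.g. `patient_id`, are
#'   carried through; synthetic rows get a `syn_<class>_<i>` id).
#' @param label_col Name of the label column (default `"label"`).
#' @param k_neighbors Neighbours per source row (default 5).
#' @param seed Integer seed.
#' @return The balanced tibble; every class count equals the input
#'   majority count.
#' @export
oversample_smote <- function(data, label_col = "label", k_neighbors = 5L,
                             seed = 1L) {
  labels <- data[[label_col]]
  if (is.null(labels)) abort(sprintf("no column '%s'", label_col))
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, label_col)
  counts <- table(labels)
  target <- max(counts)
  minority <- names(counts)[counts < target]
  too_small <- minority[counts[minority] < k_neighbors + 1]
  if (length(too_small) > 0) {
    abort(sprintf(
      "class '%s' has %d rows but k_neighbors = %d needs at least %d; use a smaller k_neighbors",
      too_small[1], counts[[too_small[1]]], k_neighbors, k_neighbors + 1))
  }

  set.seed(seed)
  synth <- map(sort(minority), function(cls) {
    idx <- which(labels == cls)
    x <- as.matrix(data[idx, num_cols])
    n_new <- target - length(idx)
    d <- as.matrix(stats::dist(x))
    diag(d) <- Inf
    nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
    src <- sample.int(length(idx), n_new, replace = TRUE)
    nb <- nn[cbind(src, sample.int(k_neighbors, n_new, replace = TRUE))]
    u <- runif(n_new)
    newx <- x[src, , drop = FALSE] +
      u * (x[nb, , drop = FALSE] - x[src, , drop = FALSE])
    out <- as_tibble(newx)
    for (col in setdiff(names(data), c(num_cols, label_col))) {
      out[[col]] <- if (col == "patient_id") {
        sprintf("syn_%s_%04d", cls, seq_len(n_new))
      } else {
        NA
      }
    }
    out[[label_col]] <- cls
    out[, names(data)]
  })
  bind_rows(data, list_rbind(synth))
}

# mtry rules matching the conventional sqrt/log2 feature subsampling.
mtry_from_rule <- function(rule, p) {
  max(1L, floor(switch(rule, sqrt = sqrt(p), log2 = log2(p))))
}

fit_rf <- function(x, y, n_trees, max_depth, max_features_rule,
                   split_criterion, seed) {
  ranger::ranger(
    x = as.data.frame(x), y = y,
    num.trees = n_trees, max.depth = max_depth,
    mtry = mtry_from_rule(max_features_rule, ncol(x)),
    min.node.size = 1, probability = TRUE, splitrule = "gini",
    seed = seed, num.threads = 1
  )
}

predict_probs <- function(fit, x) {
  p <- predict(fit, data = as.data.frame(x), num.threads = 1)$predictions
  full <- matrix(0, nrow(p), length(analysis_classes()),
                 dimnames = list(NULL, analysis_classes()))
  full[, colnames(p)] <- p
  full
}

# Deterministic argmax: ties resolved by the fixed class order
# successful < partially_successful < unsuccessful.
argmax_class <- function(prob_matrix) {
  analysis_classes()[max.col(prob_matrix, ties.method = "first")]
}

stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in levels(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Cross-validated grid search
#'
#' Evaluates every hyperparameter combination of the space with stratified
#' `n_folds` cross-validation on accuracy and returns the combination with
#' the highest mean fold accuracy, ties broken toward fewer trees, then
#' smaller depth, then lexicographic criterion (a fixed order, so results
#' are reproducible).
#'
#' @param x Numeric feature data frame / matrix.
#' @param y Factor of class labels (>= `n_folds` rows per class).
#' @param space A [search_space()].
#' @param seed Integer seed (fold assignment and forest fits).
#' @return List: `best` (one-row tibble of hyperparameters),
#'   `cv_mean_accuracy`, `cv_std_accuracy`, and `results` (per-combination
#'   tibble).
#' @export
grid_search_cv <- function(x, y, space, seed = 1L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("grid search needs at least two classes")
  if (min(table(y)) < space$n_folds) {
    abort("every class needs at least n_folds rows")
  }
  set.seed(seed)
  k <- space$n_folds
  folds <- stratified_folds(y, k)
  combos <- space_grid(space)
  fit_seeds <- matrix(sample.int(.Machine$integer.max - 1, nrow(combos) * k),
                      nrow(combos), k)
  x <- as.data.frame(x)

  fold_acc <- matrix(NA_real_, nrow(combos), k)
  for (f in seq_len(k)) {
    in_train <- folds != f
    x_tr <- x[in_train, , drop = FALSE]
    y_tr <- y[in_train]
    x_va <- x[!in_train, , drop = FALSE]
    y_va <- as.character(y[!in_train])
    for (i in seq_len(nrow(combos))) {
      fit <- fit_rf(x_tr, y_tr, combos$n_trees[i], combos$max_depth[i],
                    combos$max_features_rule[i], combos$split_criterion[i],
                    seed = fit_seeds[i, f])
      pred <- argmax_class(predict_probs(fit, x_va))
      fold_acc[i, f] <- mean(pred == y_va)
    }
  }
  results <- combos %>%
    mutate(cv_mean_accuracy = rowMeans(fold_acc),
           cv_std_accuracy = apply(fold_acc, 1, sd))
  best_i <- which.max(results$cv_mean_accuracy)
  list(
    best = combos[best_i, ],
    cv_mean_accuracy = results$cv_mean_accuracy[best_i],
    cv_std_accuracy = results$cv_std_accuracy[best_i],
    results = results
  )
}

#' Train the classifier for one treatment day
#'
#' Builds the day's feature matrix from the training cohort, balances
#' classes with SMOTE, runs the cross-validated grid search, and refits a
#' random forest with the winning hyperparameters on the full oversampled
#' set. Only training patients (and training-derived `stats`) are touched.
#'
#' @param train_cohort Training [enuresis_cohort()].
#' @param labels Tibble (`patient_id`, `label`) covering the training
#'   patients; no dropouts.
#' @param day Treatment day index.
#' @param space A [search_space()].
#' @param stats Training-split [cohort_statistics()].
#' @param seed Integer seed for this day's SMOTE, folds and fits.
#' @param k_neighbors SMOTE neighbours (default 5).
#' @return A `day_model` object.
#' @export
train_day_model <- function(train_cohort, labels, day, space, stats,
                            seed = 1L, k_neighbors = 5L) {
  fm <- build_feature_matrix(train_cohort, day, stats)
  df <- inner_join(fm, labels[, c("patient_id", "label")], by = "patient_id")
  if (nrow(df) < nrow(fm)) abort("labels do not cover all training patients")
  if (any(df$label == "dropout")) abort("dropouts cannot be used in training")

  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1, 3)
  over <- oversample_smote(select(df, -"day_index"), "label",
                           k_neighbors = k_neighbors, seed = seeds[1])
  x <- over[, feature_names()]
  y <- factor(over$label,
              levels = intersect(analysis_classes(), unique(over$label)))
  gs <- grid_search_cv(x, y, space, seed = seeds[2])
  fit <- fit_rf(x, y, gs$best$n_trees, gs$best$max_depth,
                gs$best$max_features_rule, gs$best$split_criterion,
                seed = seeds[3])
  manifest <- list(
    day_index = as.integer(day),
    hyperparameters = as.list(gs$best),
    cv_mean_accuracy = gs$cv_mean_accuracy,
    cv_std_accuracy = gs$cv_std_accuracy,
    training_seed = as.integer(seed),
    n_train = nrow(df),
    n_oversampled = nrow(over),
    class_counts = as.list(table(df$label)),
    feature_hash = rlang::hash(list(as.matrix(x), as.character(y)))
  )
  structure(
    list(day_index = as.integer(day), fit = fit,
         hyperparameters = gs$best,
         cv_mean_accuracy = gs$cv_mean_accuracy,
         cv_std_accuracy = gs$cv_std_accuracy,
         cv_results = gs$results,
         training_seed = as.integer(seed), classes = levels(y),
         manifest = manifest),
    class = "day_model"
  )
}

#' @export
print.day_model <- function(x, ...) {
  cat(sprintf(
    "<day_model> day %d: %d trees, depth %d, %s/%s; CV accuracy %.3f +/- %.3f\n",
    x$day_index, x$hyperparameters$n_trees, x$hyperparameters$max_depth,
    x$hyperparameters$max_features_rule, x$hyperparameters$split_criterion,
    x$cv_mean_accuracy, x$cv_std_accuracy))
  invisible(x)
}

#' Train the full day-indexed cascade
#'
#' One classifier per treatment day, each trained on the features available
#' up to that day. Per-day seeds are derived deterministically from the
#' master seed, so the cascade is a pure function of (cohort, labels,
#' space, stats, seed).
#'
#' @inheritParams train_day_model
#' @param days Integer vector of treatment days (default `1:56`).
#' @return A `day_model_list` (list of `day_model`).
#' @export
train_all_days <- function(train_cohort, labels, days = 1:56,
                           space = search_space(), stats, seed = 1L,
                           k_neighbors = 5L) {
  set.seed(seed)
  day_seeds <- sample.int(.Machine$integer.max - 1, length(days))
  models <- map(seq_along(days), function(i) {
    train_day_model(train_cohort, labels, days[i], space, stats,
                    seed = day_seeds[i], k_neighbors = k_neighbors)
  })
  structure(models, class = "day_model_list")
}

#' Predict one day's outcome probabilities
#'
#' @param model A `day_model`.
#' @param cohort Cohort to predict for (calendars must span the model's
#'   day).
#' @param stats The [cohort_statistics()] used at training time.
#' @return Tibble: `patient_id`, `day_index`, `p_successful`, `p_partial`,
#'   `p_unsuccessful` (each row sums to 1).
#' @export
predict_day <- function(model, cohort, stats) {
  stopifnot(inherits(model, "day_model"))
  fm <- build_feature_matrix(cohort, model$day_index, stats)
  x <- fm[, feature_names()]
  probs <- predict_probs(model$fit, x)
  tibble(
    patient_id = fm$patient_id, day_index = model$day_index,
    p_successful = probs[, "successful"],
    p_partial = probs[, "partially_successful"],
    p_unsuccessful = probs[, "unsuccessful"]
  )
}

#' Predict all days of a cascade
#'
#' @param models A `day_model_list`.
#' @inheritParams predict_day
#' @return Long tibble of [predict_day()] results over all days.
#' @export
predict_days <- function(models, cohort, stats) {
  map(models, predict_day, cohort = cohort, stats = stats) %>% list_rbind()
}

#' @export
glance.day_model <- function(x, ...) {
  bind_cols(tibble(day_index = x$day_index), x$hyperparameters,
            tibble(cv_mean_accuracy = x$cv_mean_accuracy,
                   cv_std_accuracy = x$cv_std_accuracy,
                   training_seed = x$training_seed))
}

#' @export
tidy.day_model <- function(x, ...) {
  tibble(
    term = names(x$hyperparameters),
    value = as.character(unlist(x$hyperparameters))
  )
}

#' @export
tidy.day_model_list <- function(x, ...) {
  map(x, glance) %>% list_rbind()
}
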