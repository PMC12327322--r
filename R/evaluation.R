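# Evaluation of daily predictions: accuracy, per-class precision/recall,
# trend lines, threshold-based patient counts, and threshold optimization
# by the summed true-positive / false-positive quotient.

prob_col <- function(target_class) {
  switch(target_class,
         successful = "p_successful",
         partially_successful = "p_partial",
         unsuccessful = "p_unsuccessful",
         abort(sprintf("unknown target class '%s'", target_class)))
}

check_predictions <- function(preds, labels) {
  need <- c("patient_id", "day_index", "p_successful", "p_partial",
            "p_unsuccessful")
  miss <- setdiff(need, names(preds))
  if (length(miss) > 0) {
    abort(sprintf("predictions lack column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(preds[, c("patient_id", "day_index")])) {
    abort("duplicate (patient_id, day_index) in predictions")
  }
  unlabeled <- setdiff(unique(preds$patient_id), labels$patient_id)
  if (length(unlabeled) > 0) {
    abort(sprintf("no label for patient '%s'", unlabeled[1]))
  }
  invisible(TRUE)
}

joined_predictions <- function(preds, labels) {
  check_predictions(preds, labels)
  preds %>%
    inner_join(labels[, c("patient_id", "label")], by = "patient_id") %>%
    mutate(predicted = argmax_class(
      cbind(.data$p_successful, .data$p_partial, .data$p_unsuccessful)))
}

#' Daily prediction accuracy
#'
#' Per day, the fraction of patients whose highest-probability class equals
#' the true label; probability ties resolve by the fixed class order
#' (successful, partially successful, unsuccessful).
#'
#' @param preds Long prediction tibble (`patient_id`, `day_index`,
#'   `p_successful`, `p_partial`, `p_unsuccessful`).
#' @param labels Tibble (`patient_id`, `label`).
#' @return Tibble (`day_index`, `accuracy`), days increasing.
#' @export
daily_accuracy <- function(preds, labels) {
  joined_predictions(preds, labels) %>%
    group_by(.data$day_index) %>%
    summarise(accuracy = mean(.data$predicted == .data$label),
              .groups = "drop") %>%
    arrange(.data$day_index)
}

#' Daily per-class precision and recall
#'
#' Under argmax classification: `precision = TP / (TP + FP)` and
#' `recall = TP / (TP + FN)` per day and class, defined as 0 when the
#' denominator is 0.
#'
#' @inheritParams daily_accuracy
#' @return Tibble (`day_index`, `class`, `precision`, `recall`).
#' @export
precision_recall <- function(preds, labels) {
  joined <- joined_predictions(preds, labels)
  grid <- tidyr::expand_grid(day_index = sort(unique(joined$day_index)),
                             class = analysis_classes())
  grid %>%
    rowwise() %>%
    mutate(
      tp = sum(joined$day_index == .data$day_index &
                 joined$predicted == .data$class &
                 joined$label == .data$class),
      fp = sum(joined$day_index == .data$day_index &
                 joined$predicted == .data$class &
                 joined$label != .data$class),
      fn = sum(joined$day_index == .data$day_index &
                 joined$predicted != .data$class &
                 joined$label == .data$class)
    ) %>%
    ungroup() %>%
    mutate(
      precision = ifelse(.data$tp + .data$fp == 0, 0,
                         .data$tp / (.data$tp + .data$fp)),
      recall = ifelse(.data$tp + .data$fn == 0, 0,
                      .data$tp / (.data$tp + .data$fn))
    ) %>%
    select("day_index", "class", "precision", "recall")
}

#' Least-squares trend of a daily metric
#'
#' Ordinary least squares of the metric on the day index, as used to
#' summarize the day-on-day improvement of accuracy series.
#'
#' @param series Tibble whose first column is `day_index` and second column
#'   the metric value (at least 2 points).
#' @return A `trend_fit`: `slope` (per-day change), `intercept`,
#'   `r_squared` (defined as 0 for a constant series), `n`.
#' @export
fit_trend <- function(series) {
  if (nrow(series) < 2) abort("need at least 2 points to fit a trend")
  x <- series[[1]]
  y <- series[[2]]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r_squared <- if (ss_tot == 0) 0 else max(0, 1 - ss_res / ss_tot)
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n = length(x), metric = names(series)[2]),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s: slope %.4f per day, R^2 %.3f (n = %d)\n",
              x$metric, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
glance.trend_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, n = x$n)
}

#' @export
tidy.trend_fit <- function(x, ...) {
  tibble(term = c("intercept", "day_index"),
         estimate = c(x$intercept, x$slope))
}

#' Patients above a probability threshold, by true label
#'
#' Counts, separately for each true outcome label, the patients whose
#' predicted probability for `target_class` strictly exceeds `threshold`
#' on each day — the stacked-bar view of daily predictions.
#'
#' @inheritParams daily_accuracy
#' @param target_class Outcome whose probability is thresholded.
#' @param threshold Probability threshold in (0, 1); strict inequality.
#' @param days Days to count (default: all days present).
#' @return Tibble (`day_index`, `target_class`, `threshold`, `true_label`,
#'   `n`), complete over true labels with zero counts.
#' @export
threshold_counts <- function(preds, labels, target_class, threshold,
                             days = NULL) {
  if (threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly between 0 and 1")
  }
  check_predictions(preds, labels)
  col <- prob_col(target_class)
  joined <- preds %>%
    inner_join(labels[, c("patient_id", "label")], by = "patient_id")
  if (!is.null(days)) joined <- filter(joined, .data$day_index %in% days)
  joined %>%
    filter(.data[[col]] > threshold) %>%
    count(.data$day_index, true_label = .data$label) %>%
    tidyr::complete(
      day_index = if (is.null(days)) sort(unique(preds$day_index)) else
        sort(days),
      true_label = sort(unique(labels$label)), fill = list(n = 0L)
    ) %>%
    mutate(target_class = target_class, threshold = threshold) %>%
    select("day_index", "target_class", "threshold", "true_label", "n") %>%
    arrange(.data$day_index, .data$true_label)
}

threshold_objective <- function(joined, col, target_class, threshold,
                                window, fp_handling) {
  per_day <- joined %>%
    filter(.data$day_index %in% window) %>%
    group_by(.data$day_index) %>%
    summarise(
      tp = sum(.data[[col]] > threshold & .data$label == target_class),
      fp = sum(.data[[col]] > threshold & .data$label != target_class),
      .groups = "drop"
    )
  if (fp_handling == "add_one") {
    sum(per_day$tp / (per_day$fp + 1))
  } else {
    keep <- per_day$fp > 0
    sum(per_day$tp[keep] / per_day$fp[keep])
  }
}

#' Optimize a decision threshold by the TP/FP quotient
#'
#' For each candidate threshold, computes per day in the window the number
#' of true positives (patients of `target_class` whose predicted
#' probability exceeds the threshold) and false positives (other patients
#' above it), sums the daily quotients, and returns the threshold with the
#' highest sum — the threshold giving the most true positives per false
#' positive over the window. Because the raw quotient is undefined on
#' zero-false-positive days, the default objective is
#' `sum(TP / (FP + 1))`; `fp_handling = "skip_zero"` instead uses the raw
#' `TP / FP` and skips days with no false positives. Ties break toward the
#' larger (more conservative) threshold.
#'
#' @inheritParams daily_accuracy
#' @param target_class Outcome to optimize for.
#' @param grid Candidate thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param window Day range of the objective (default days 15--35, week 3
#'   through week 5; use `1:56` for the full treatment).
#' @param fp_handling `"add_one"` (default) or `"skip_zero"`.
#' @return A one-row `threshold_policy` tibble: `target_class`,
#'   `threshold`, `objective_value`, `window_start`, `window_end`.
#' @export
optimize_threshold <- function(preds, labels, target_class,
                               grid = seq(0.5, 0.95, by = 0.05),
                               window = 15:35,
                               fp_handling = c("add_one", "skip_zero")) {
  fp_handling <- match.arg(fp_handling)
  if (length(grid) == 0) abort("threshold grid must be non-empty")
  if (length(window) == 0) abort("optimization window must be non-empty")
  if (any(grid <= 0 | grid >= 1)) {
    abort("thresholds must lie strictly between 0 and 1")
  }
  check_predictions(preds, labels)
  missing_days <- setdiff(window, unique(preds$day_index))
  if (length(missing_days) > 0) {
    abort(sprintf("no predictions for day %d in the window",
                  missing_days[1]))
  }
  col <- prob_col(target_class)
  joined <- preds %>%
    inner_join(labels[, c("patient_id", "label")], by = "patient_id")
  grid <- sort(grid)
  obj <- map_dbl(grid, function(t) {
    threshold_objective(joined, col, target_class, t, window, fp_handling)
  })
  best <- max(which(obj == max(obj)))
  out <- tibble(
    target_class = target_class, threshold = grid[best],
    objective_value = obj[best],
    window_start = min(window), window_end = max(window)
  )
  class(out) <- c("threshold_policy", class(out))
  out
}

#' Optimize thresholds for several target classes
#'
#' Per-class optimization by default (the per-class objectives share no
#' terms). With `joint = TRUE` every combination of thresholds across the
#' classes is enumerated and the combination maximizing the summed
#' objective is returned — equivalent to the per-class optimum because the
#' objective is separable, but computed by explicit enumeration.
#'
#' @inheritParams optimize_threshold
#' @param target_classes Classes to optimize (default successful and
#'   unsuccessful).
#' @param joint Enumerate joint combinations (default `FALSE`).
#' @return A `threshold_policy` tibble, one row per target class.
#' @export
optimize_thresholds <- function(preds, labels,
                                target_classes = c("successful",
                                                   "unsuccessful"),
                                grid = seq(0.5, 0.95, by = 0.05),
                                window = 15:35,
                                fp_handling = c("add_one", "skip_zero"),
                                joint = FALSE) {
  fp_handling <- match.arg(fp_handling)
  per_class <- map(target_classes, function(cls) {
    optimize_threshold(preds, labels, cls, grid, window, fp_handling)
  }) %>% list_rbind()
  if (!joint) {
    class(per_class) <- c("threshold_policy", class(per_class))
    return(per_class)
  }
  check_predictions(preds, labels)
  joined <- preds %>%
    inner_join(labels[, c("patient_id", "label")], by = "patient_id")
  grid <- sort(grid)
  combos <- tidyr::expand_grid(!!!setNames(rep(list(grid),
                                               length(target_classes)),
                                           target_classes))
  totals <- map_dbl(seq_len(nrow(combos)), function(i) {
    sum(map_dbl(target_classes, function(cls) {
      threshold_objective(joined, prob_col(cls), cls,
                          combos[[cls]][i], window, fp_handling)
    }))
  })
  best <- max(which(totals == max(totals)))
  out <- map(target_classes, function(cls) {
    tibble(target_class = cls, threshold = combos[[cls]][best],
           objective_value = threshold_objective(
             joined, prob_col(cls), cls, combos[[cls]][best], window,
             fp_handling),
           window_start = min(window), window_end = max(window))
  }) %>% list_rbind()
  class(out) <- c("threshold_policy", class(out))
  out
}
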