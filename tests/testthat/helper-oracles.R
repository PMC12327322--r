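# Independent oracles and fixture builders shared across the test files.
# The oracles are literal loop-based transcriptions of the response rules
# and objectives, kept free of the package's vectorized implementations.

# Exhaustive sliding-window streak scan.
oracle_streak <- function(status, streak_len, max_missing, min_dry,
                          search_end = length(status)) {
  if (search_end < streak_len) return(NA_integer_)
  for (e in streak_len:search_end) {
    win <- status[(e - streak_len + 1):e]
    if (sum(win == "wet") == 0 && sum(win == "missing") <= max_missing &&
        sum(win == "dry") >= min_dry) {
      return(e)
    }
  }
  NA_integer_
}

# Literal transcription of the labeling rules: 14-night dry streak with up
# to 2 missing tolerated; dropout on <6 recorded weeks or a 14-night
# missing run without prior success; partial success on a >= 50% wet-night
# reduction (missing nights entering at their expected value).
oracle_label <- function(status, freq) {
  status <- c(status, rep("missing", max(0, 56 - length(status))))[1:56]
  for (e in 14:56) {
    win <- status[(e - 13):e]
    if (sum(win == "wet") == 0 && sum(win == "missing") <= 2 &&
        sum(win == "dry") >= 12) {
      return(list(label = "successful", success_day = e,
                  reason = NA_character_))
    }
  }
  last_rec <- 0
  for (d in 1:56) if (status[d] != "missing") last_rec <- d
  if (last_rec < 42) {
    return(list(label = "dropout", success_day = NA_integer_,
                reason = "short_treatment"))
  }
  run <- 0
  for (d in 1:56) {
    run <- if (status[d] == "missing") run + 1 else 0
    if (run >= 14) {
      return(list(label = "dropout", success_day = NA_integer_,
                  reason = "missing_run"))
    }
  }
  expected_count <- function(days) {
    total <- 0
    for (d in days) {
      if (status[d] == "wet") {
        total <- total + 1
      } else if (status[d] == "missing") {
        n_wet <- 0
        n_rec <- 0
        for (q in seq_len(d - 1)) {
          if (status[q] != "missing") {
            n_rec <- n_rec + 1
            if (status[q] == "wet") n_wet <- n_wet + 1
          }
        }
        total <- total + if (n_rec > 0) n_wet / n_rec else freq / 7
      }
    }
    total
  }
  ratio <- expected_count(43:56) / max(expected_count(1:14), 1)
  list(label = if (ratio <= 0.5) "partially_successful" else "unsuccessful",
       success_day = NA_integer_, reason = NA_character_)
}

# Loop-based TP/FP-quotient objective and grid enumeration.
oracle_threshold <- function(preds, labels, target_class, grid, window,
                             fp_handling = "add_one") {
  col <- switch(target_class, successful = "p_successful",
                partially_successful = "p_partial",
                unsuccessful = "p_unsuccessful")
  lab <- labels$label[match(preds$patient_id, labels$patient_id)]
  objective <- numeric(length(grid))
  for (g in seq_along(grid)) {
    total <- 0
    for (d in window) {
      rows <- preds$day_index == d
      pos <- preds[[col]][rows] > grid[g]
      tp <- sum(pos & lab[rows] == target_class)
      fp <- sum(pos & lab[rows] != target_class)
      if (fp_handling == "add_one") {
        total <- total + tp / (fp + 1)
      } else if (fp > 0) {
        total <- total + tp / fp
      }
    }
    objective[g] <- total
  }
  best <- max(which(objective == max(objective)))
  list(threshold = sort(grid)[best], objective = objective[best],
       all = objective)
}

# Random prediction set: n_patients x days rows of normalized probability
# triples plus random true labels.
random_predictions <- function(n_patients = 60, days = 1:56, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_patients))
  grid <- tidyr::expand_grid(patient_id = ids, day_index = days)
  raw <- matrix(runif(nrow(grid) * 3), ncol = 3)
  p <- raw / rowSums(raw)
  preds <- dplyr::mutate(grid, p_successful = p[, 1], p_partial = p[, 2],
                         p_unsuccessful = p[, 3])
  labels <- tibble::tibble(
    patient_id = ids,
    label = sample(c("successful", "partially_successful", "unsuccessful"),
                   n_patients, replace = TRUE)
  )
  list(preds = preds, labels = labels)
}

# Minimal valid cohort from a list of status vectors (details left blank;
# wet nights use the explicit time-missing marker).
cohort_from_status <- function(status_list, freq = NULL) {
  n <- length(status_list)
  ids <- sprintf("C%04d", seq_len(n))
  if (is.null(freq)) freq <- rep(4, n)
  reg <- tibble::tibble(
    patient_id = ids, age = 8, sex = "male",
    alarm_type = "alarm_with_pants", sleep_depth = "difficult",
    enuresis_frequency = freq, wets_once_or_twice = "once", motivation = 4,
    daytime_urgency = "no", daytime_wetting = "no",
    prior_alarm_treatment = "no", prior_medication = "no",
    bladder_relaxant = "no", nurse_contact = "no", weak_stream = "no",
    thirsty_at_night = "no", previously_dry = "no"
  )
  nights <- purrr::map2(status_list, ids, function(st, id) {
    tibble::tibble(
      patient_id = id, day_index = seq_along(st), status = st,
      severity = NA_integer_, awakening = NA_character_,
      repeat_wetting = NA_character_, woke_to_void = NA_character_,
      event_times = rep(list(integer(0)), length(st))
    )
  }) |> purrr::list_rbind()
  enuresis_cohort(reg, nights)
}

small_sim <- function(n = c(successful = 8, partially_successful = 8,
                            unsuccessful = 8, dropout = 4), seed = 11,
                      ...) {
  simulate_cohort(sim_config(n_per_class = n, seed = seed, ...))
}

tiny_space <- function(n_folds = 5L) {
  search_space(n_trees = 50L, max_depth = 25L, max_features_rule = "sqrt",
               split_criterion = "gini", n_folds = n_folds)
}
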