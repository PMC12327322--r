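# End-to-end orchestration: simulate (or read) -> label -> split -> train
# cascade -> predict -> evaluate -> optimize thresholds, with every stage
# seeded from one master seed and all reports written as CSV/JSON.

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. A single master `seed`
#' deterministically derives the simulation, split and training seeds, so
#' two runs of the same config produce identical reports.
#'
#' @param out_dir Report directory (created if needed).
#' @param cohort_path Path to an existing cohort (`csv_pair` directory or
#'   JSON file); `NULL` to simulate.
#' @param cohort_format Format at `cohort_path`.
#' @param simulate Simulate a cohort instead of reading one (default: no
#'   `cohort_path` given).
#' @param sim A [sim_config()] (its own seed is overridden by the derived
#'   seed).
#' @param rule A [streak_rule()].
#' @param space A [search_space()].
#' @param days Treatment days to train and predict (default `1:56`).
#' @param train_fraction Training fraction of the 70/30 split.
#' @param threshold_grid Candidate decision thresholds.
#' @param threshold_window Days of the threshold objective (must lie
#'   within `days`; default 15--35, weeks 3--5).
#' @param fixed_thresholds Fixed thresholds for the stacked-count tables
#'   (default 0.5 and 0.7).
#' @param fp_handling `"add_one"` or `"skip_zero"` (see
#'   [optimize_threshold()]).
#' @param k_neighbors SMOTE neighbours.
#' @param seed Master seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort_path = NULL,
                            cohort_format = c("csv_pair", "json"),
                            simulate = is.null(cohort_path),
                            sim = sim_config(),
                            rule = streak_rule(),
                            space = search_space(),
                            days = 1:56,
                            train_fraction = 0.7,
                            threshold_grid = seq(0.5, 0.95, by = 0.05),
                            threshold_window = 15:35,
                            fixed_thresholds = c(0.5, 0.7),
                            fp_handling = c("add_one", "skip_zero"),
                            k_neighbors = 5L,
                            seed = 1L,
                            log_level = c("info", "quiet")) {
  cohort_format <- match.arg(cohort_format)
  fp_handling <- match.arg(fp_handling)
  log_level <- match.arg(log_level)
  if (!simulate && is.null(cohort_path)) {
    abort("either enable simulate or provide cohort_path")
  }
  stopifnot(inherits(sim, "sim_config"), inherits(rule, "streak_rule"),
            inherits(space, "search_space"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must lie strictly between 0 and 1")
  }
  if (!all(threshold_window %in% days)) {
    abort("threshold_window must lie within the trained days")
  }
  structure(
    list(out_dir = out_dir, cohort_path = cohort_path,
         cohort_format = cohort_format, simulate = simulate, sim = sim,
         rule = rule, space = space, days = as.integer(days),
         train_fraction = train_fraction, threshold_grid = threshold_grid,
         threshold_window = as.integer(threshold_window),
         fixed_thresholds = fixed_thresholds, fp_handling = fp_handling,
         k_neighbors = as.integer(k_neighbors), seed = as.integer(seed),
         log_level = log_level),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; the nested
#' `sim`, `rule` and `space` mappings mirror [sim_config()],
#' [streak_rule()] and [search_space()]. Integer ranges may be written as
#' `"a:b"` strings. Omitted keys take their defaults.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured report directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  parse_range <- function(x) {
    if (is.character(x) && length(x) == 1 && grepl("^\\d+:\\d+$", x)) {
      parts <- as.integer(strsplit(x, ":")[[1]])
      return(parts[1]:parts[2])
    }
    x
  }
  args <- raw
  for (f in c("days", "threshold_window")) {
    if (!is.null(args[[f]])) args[[f]] <- parse_range(args[[f]])
  }
  for (nested in c("sim", "rule", "space")) {
    if (!is.null(args[[nested]])) {
      ctor <- switch(nested, sim = sim_config, rule = streak_rule,
                     space = search_space)
      sub <- args[[nested]]
      for (f in c("n_per_class", "wet_prob_start", "wet_prob_decay")) {
        if (!is.null(sub[[f]])) sub[[f]] <- unlist(sub[[f]])
      }
      args[[nested]] <- do.call(ctor, sub)
    }
  }
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

log_info <- function(config, fmt, ...) {
  if (config$log_level == "info") inform(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Simulates or reads a cohort, labels outcomes, splits patients 70/30,
#' trains the per-day classifier cascade, predicts daily outcome
#' probabilities for the test group, evaluates them, and optimizes the
#' decision thresholds. All numeric reports are written under
#' `config$out_dir`; rerunning the same config reproduces them byte for
#' byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `labels`, `split`, `models`, `predictions`, `accuracy`,
#'   `precision_recall`, `trends`, `thresholds`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  derived <- sample.int(.Machine$integer.max - 1, 3)

  # -- cohort ------------------------------------------------------------
  if (config$simulate) {
    sim <- config$sim
    sim$seed <- derived[1]
    cohort <- simulate_cohort(sim)
    write_cohort(cohort, file.path(config$out_dir, "cohort"), "csv_pair")
    log_info(config, "simulated %d patients", n_patients(cohort))
  } else {
    if (!file.exists(config$cohort_path)) {
      abort(sprintf("cohort path not found: %s", config$cohort_path))
    }
    cohort <- read_cohort(config$cohort_path, config$cohort_format)
    log_info(config, "read %d patients from %s", n_patients(cohort),
             config$cohort_path)
  }

  reg <- cohort$registrations
  n_missing_reg <- sum(is.na(reg[, registration_fields()]))
  n_implausible <- sum(map_int(cohort$nights$event_times,
                               function(x) sum(x > 720)))
  n_missing_nights <- sum(cohort$nights$status == "missing")
  log_info(config,
           "missing-data audit: %d blank registration answers, %d missing nights, %d implausible event times",
           n_missing_reg, n_missing_nights, n_implausible)

  # -- label and split ---------------------------------------------------
  labels <- label_outcomes(cohort, config$rule)
  readr::write_csv(labels, file.path(config$out_dir, "labels.csv"), na = "")
  analysis <- filter(labels, .data$label != "dropout")
  log_info(config, "labels: %s",
           paste(names(table(labels$label)), table(labels$label),
                 sep = "=", collapse = ", "))
  split <- split_cohort(analysis[, c("patient_id", "label")],
                        config$train_fraction, seed = derived[2])
  readr::write_csv(split, file.path(config$out_dir, "split.csv"), na = "")
  train_ids <- split$patient_id[split$split == "train"]
  test_ids <- split$patient_id[split$split == "test"]
  train_cohort <- subset_cohort(cohort, train_ids)
  test_cohort <- subset_cohort(cohort, test_ids)
  stats <- cohort_statistics(train_cohort)

  # -- train and predict -------------------------------------------------
  models <- train_all_days(
    train_cohort, filter(split, .data$split == "train"),
    days = config$days, space = config$space, stats = stats,
    seed = derived[3], k_neighbors = config$k_neighbors
  )
  jsonlite::write_json(map(models, "manifest"),
                       file.path(config$out_dir, "models_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  preds <- predict_days(models, test_cohort, stats)
  readr::write_csv(preds, file.path(config$out_dir, "predictions.csv"),
                   na = "")

  # -- evaluate ----------------------------------------------------------
  test_labels <- filter(split, .data$split == "test")
  acc <- daily_accuracy(preds, test_labels)
  readr::write_csv(acc, file.path(config$out_dir, "accuracy.csv"), na = "")
  pr <- precision_recall(preds, test_labels)
  readr::write_csv(pr, file.path(config$out_dir, "precision_recall.csv"),
                   na = "")
  cv_series <- tidy(models)[, c("day_index", "cv_mean_accuracy")]
  trends <- list(
    test_accuracy = glance(fit_trend(acc)),
    cv_mean_accuracy = glance(fit_trend(cv_series))
  )
  jsonlite::write_json(trends, file.path(config$out_dir, "trend.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  counts <- tidyr::expand_grid(
    target_class = c("successful", "unsuccessful"),
    threshold = config$fixed_thresholds
  )
  count_tables <- map(seq_len(nrow(counts)), function(i) {
    threshold_counts(preds, test_labels, counts$target_class[i],
                     counts$threshold[i], days = config$days)
  }) %>% list_rbind()
  readr::write_csv(count_tables,
                   file.path(config$out_dir, "threshold_counts.csv"),
                   na = "")
  policies <- optimize_thresholds(
    preds, test_labels, grid = config$threshold_grid,
    window = config$threshold_window, fp_handling = config$fp_handling
  )
  jsonlite::write_json(policies,
                       file.path(config$out_dir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_info(config, "optimized thresholds: %s",
           paste(policies$target_class, policies$threshold,
                 sep = "=", collapse = ", "))

  manifest <- list(
    package_version = as.character(utils::packageVersion("drynights")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_patients = n_patients(cohort),
    label_counts = as.list(table(labels$label)),
    n_train = length(train_ids), n_test = length(test_ids),
    missing_data = list(
      blank_registration_answers = n_missing_reg,
      missing_nights = n_missing_nights,
      implausible_event_times = n_implausible
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    cohort = cohort, labels = labels, split = split, stats = stats,
    models = models, predictions = preds, accuracy = acc,
    precision_recall = pr, trends = trends,
    threshold_counts = count_tables, thresholds = policies,
    manifest = manifest
  ))
}
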