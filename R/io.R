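# Cohort persistence: csv_pair (registrations.csv + nights.csv) and JSON.
# Missing sentinel in CSV is the empty cell; event times are ";"-joined.

night_columns <- function() {
  c("patient_id", "day_index", "status", "severity", "awakening",
    "repeat_wetting", "woke_to_void", "event_times")
}

empty_nights <- function() {
  tibble(
    patient_id = character(0), day_index = integer(0), status = character(0),
    severity = integer(0), awakening = character(0),
    repeat_wetting = character(0), woke_to_void = character(0),
    event_times = list()
  )
}

empty_registrations <- function() {
  out <- tibble(patient_id = character(0))
  for (f in registration_fields()) {
    out[[f]] <- if (f %in% c("age", "enuresis_frequency", "motivation")) {
      numeric(0)
    } else {
      character(0)
    }
  }
  out
}

#' Read a diary cohort from disk
#'
#' @param path For `csv_pair`, a directory containing `registrations.csv`
#'   and `nights.csv`; for `json`, a single JSON file.
#' @param format `"csv_pair"` or `"json"`.
#' @return A validated [enuresis_cohort()]. Unrecorded interior days are
#'   materialized as missing nights.
#' @export
read_cohort <- function(path, format = c("csv_pair", "json")) {
  format <- match.arg(format)
  if (format == "csv_pair") {
    reg_path <- file.path(path, "registrations.csv")
    nts_path <- file.path(path, "nights.csv")
    for (p in c(reg_path, nts_path)) {
      if (!file.exists(p)) abort(sprintf("file not found: %s", p))
    }
    reg <- readr::read_csv(
      reg_path, na = "", show_col_types = FALSE,
      col_types = readr::cols(
        patient_id = "c", age = "d", enuresis_frequency = "d",
        motivation = "d", .default = "c"
      )
    )
    nts <- readr::read_csv(
      nts_path, na = "", show_col_types = FALSE,
      col_types = readr::cols(
        patient_id = "c", day_index = "i", severity = "i",
        event_times = "c", .default = "c"
      )
    )
    nts$event_times <- lapply(nts$event_times, function(s) {
      if (is.na(s) || s == "") integer(0) else as.integer(strsplit(s, ";")[[1]])
    })
    lc_path <- file.path(path, "latent_classes.csv")
    lc <- if (file.exists(lc_path)) {
      readr::read_csv(lc_path, na = "", show_col_types = FALSE,
                      col_types = readr::cols(.default = "c"))
    } else {
      NULL
    }
    return(enuresis_cohort(reg, nts, latent_classes = lc))
  }

  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  reg <- map(raw, function(p) {
    r <- p$registration
    r[vapply(r, is.null, logical(1))] <- NA
    as_tibble(r)
  }) %>% list_rbind()
  nts <- map(raw, function(p) {
    map(p$nights, function(nt) {
      times <- if (is.null(nt$event_times)) integer(0) else
        as.integer(unlist(nt$event_times))
      nt_scalar <- nt[setdiff(names(nt), "event_times")]
      nt_scalar[vapply(nt_scalar, is.null, logical(1))] <- NA
      row <- as_tibble(nt_scalar)
      row$patient_id <- p$registration$patient_id
      row$event_times <- list(times)
      row
    }) %>% list_rbind()
  }) %>% list_rbind()
  lc <- map(raw, function(p) {
    if (is.null(p$latent_class)) return(NULL)
    tibble(patient_id = p$registration$patient_id,
           latent_class = p$latent_class)
  }) %>% list_rbind()
  if (!is.null(lc) && nrow(lc) == 0) lc <- NULL
  if (nrow(nts) > 0) {
    nts$day_index <- as.integer(nts$day_index)
    nts$severity <- if ("severity" %in% names(nts)) {
      as.integer(nts$severity)
    } else {
      NA_integer_
    }
  } else {
    nts <- empty_nights()
  }
  if (nrow(reg) == 0) reg <- empty_registrations()
  reg$age <- as.numeric(reg$age)
  reg$enuresis_frequency <- as.numeric(reg$enuresis_frequency)
  reg$motivation <- as.numeric(reg$motivation)
  enuresis_cohort(reg, nts, latent_classes = lc)
}

#' Write a diary cohort to disk
#'
#' @param cohort A validated [enuresis_cohort()].
#' @param path Directory (`csv_pair`) or file path (`json`).
#' @param format `"csv_pair"` or `"json"`.
#' @return `path`, invisibly. `read_cohort()` on the output reproduces the
#'   cohort exactly.
#' @export
write_cohort <- function(cohort, path, format = c("csv_pair", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "enuresis_cohort"))
  if (format == "csv_pair") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    reg <- cohort$registrations[, c("patient_id", registration_fields())]
    readr::write_csv(reg, file.path(path, "registrations.csv"), na = "")
    nts <- cohort$nights %>%
      mutate(event_times = map_chr(.data$event_times,
                                   function(x) paste(x, collapse = ";"))) %>%
      select(all_of(night_columns()))
    readr::write_csv(nts, file.path(path, "nights.csv"), na = "")
    if (!is.null(cohort$latent_classes)) {
      readr::write_csv(cohort$latent_classes,
                       file.path(path, "latent_classes.csv"), na = "")
    }
    return(invisible(path))
  }

  nights_by <- split(cohort$nights, cohort$nights$patient_id)
  lc <- cohort$latent_classes
  patients <- map(seq_len(nrow(cohort$registrations)), function(i) {
    reg <- as.list(cohort$registrations[i, c("patient_id",
                                             registration_fields())])
    pid <- reg$patient_id
    nts <- nights_by[[pid]]
    nights <- map(seq_len(nrow(nts)), function(j) {
      list(
        day_index = nts$day_index[j], status = nts$status[j],
        severity = nts$severity[j], awakening = nts$awakening[j],
        repeat_wetting = nts$repeat_wetting[j],
        woke_to_void = nts$woke_to_void[j],
        event_times = nts$event_times[[j]]
      )
    })
    out <- list(registration = reg, nights = nights)
    if (!is.null(lc)) {
      out$latent_class <- lc$latent_class[match(pid, lc$patient_id)]
    }
    out
  })
  jsonlite::write_json(patients, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}
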