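# Synthetic diary cohorts: a stand-in for proprietary alarm-treatment data.
# Registration answers follow published cohort marginals; nightly wetting
# follows per-class probability trajectories with weekly multiplicative
# decay, overlaid with a missingness process and (for the dropout class) a
# weekly hazard of stopping the diary entirely.

# Marginal distributions of the registration questions (cohort totals of the
# source population; independent across fields).
registration_marginals <- function() {
  list(
    age = list(mean = 8.55, sd = 4.32, min = 3, max = 30),
    sex = c(male = 0.7661, female = 0.2339),
    wets_once_or_twice = c(once = 0.9775, twice = 0.0225),
    motivation = list(mean = 4.05, sd = 0.47),
    alarm_type = c(
      alarm_with_pants = 0.5221, pjama_connect = 0.1702,
      alarm_with_underwear = 0.0557, other_alarm = 0.2406,
      no_or_unknown = 0.0114
    ),
    sleep_depth = c(
      almost_impossible = 0.0998, difficult = 0.5155, neither = 0.2357,
      easy = 0.0458, dont_know = 0.1032
    ),
    enuresis_frequency = list(mean = 5.09, sd = 1.91, min = 0, max = 7),
    yes_rates = c(
      daytime_urgency = 0.4778, daytime_wetting = 0.1433,
      prior_alarm_treatment = 0.2543, prior_medication = 0.4061,
      bladder_relaxant = 0.0376, nurse_contact = 0.5435,
      weak_stream = 0.0297, thirsty_at_night = 0.1023,
      previously_dry = 0.1551
    )
  )
}

#' Simulation configuration
#'
#' Defines the study conditions a simulated cohort emulates: class sizes,
#' the treatment horizon, per-class nightly wetting-probability
#' trajectories, the diary missingness process, and the event-time
#' distribution including occasional implausible values that exercise the
#' sanitization rule.
#'
#' The wetting probability of a patient in latent class `c` on treatment
#' day `d` is `wet_prob_start[c] * wet_prob_decay[c]^(week(d) - 1)` with
#' `week(d) = ceiling(d / 7)`: the successful class decays fast enough to
#' reach a stable dry regime before day 56, the partial class halves its
#' wetting rate slowly, and the unsuccessful (and dropout) classes stay
#' flat.
#'
#' @param n_per_class Named integer vector of patients per latent class
#'   (`successful`, `partially_successful`, `unsuccessful`, `dropout`).
#' @param horizon_days Calendar length per patient (>= 56; default 70).
#' @param wet_prob_start Named per-class initial nightly wetting
#'   probability.
#' @param wet_prob_decay Named per-class multiplicative weekly decay of the
#'   wetting probability.
#' @param missing_prob Per-night probability a night goes unrecorded
#'   (default 0.05).
#' @param dropout_hazard Per-week probability a dropout-class patient stops
#'   recording entirely (default 0.30).
#' @param repeat_wet_prob Probability a wet night has two or more wetting
#'   events (default 0.25).
#' @param implausible_time_prob Probability an event time is drawn from an
#'   implausible range (720--1100 min, i.e. beyond a plausible sleep
#'   duration; default 0.02).
#' @param seed Integer seed; identical config + seed gives an identical
#'   cohort.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_per_class = c(successful = 170,
                                       partially_successful = 150,
                                       unsuccessful = 290, dropout = 90),
                       horizon_days = 70,
                       wet_prob_start = c(successful = 0.70,
                                          partially_successful = 0.75,
                                          unsuccessful = 0.80,
                                          dropout = 0.80),
                       wet_prob_decay = c(successful = 0.45,
                                          partially_successful = 0.80,
                                          unsuccessful = 1.00,
                                          dropout = 1.00),
                       missing_prob = 0.05,
                       dropout_hazard = 0.30,
                       repeat_wet_prob = 0.25,
                       implausible_time_prob = 0.02,
                       seed = 1L) {
  cls <- outcome_levels()
  for (nm in c("n_per_class", "wet_prob_start", "wet_prob_decay")) {
    v <- get(nm)
    if (!all(cls %in% names(v))) {
      abort(sprintf("%s must name all classes: %s", nm,
                    paste(cls, collapse = ", ")))
    }
  }
  if (any(n_per_class < 0)) abort("n_per_class values must be >= 0")
  if (horizon_days < 56) abort("horizon_days must be >= 56")
  probs <- c(wet_prob_start, wet_prob_decay, missing_prob, dropout_hazard,
             repeat_wet_prob, implausible_time_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  structure(
    list(
      n_per_class = n_per_class[cls], horizon_days = as.integer(horizon_days),
      wet_prob_start = wet_prob_start[cls], wet_prob_decay = wet_prob_decay[cls],
      missing_prob = missing_prob, dropout_hazard = dropout_hazard,
      repeat_wet_prob = repeat_wet_prob,
      implausible_time_prob = implausible_time_prob, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Nightly wetting probability of a latent class
#'
#' @param class One of the four latent classes.
#' @param day Treatment day (vectorized).
#' @param config A [sim_config()].
#' @return Probability vector, one per day.
#' @export
class_wet_prob <- function(class, day, config) {
  week <- ceiling(day / 7)
  unname(config$wet_prob_start[class] * config$wet_prob_decay[class]^(week - 1))
}

sample_registration <- function(patient_id) {
  m <- registration_marginals()
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  age <- round(clamp(rnorm(1, m$age$mean, m$age$sd), m$age$min, m$age$max), 1)
  freq <- round(clamp(rnorm(1, m$enuresis_frequency$mean,
                            m$enuresis_frequency$sd), 0, 7), 1)
  motivation <- clamp(round(rnorm(1, m$motivation$mean, m$motivation$sd)), 1, 5)
  draw <- function(p) sample(names(p), 1, prob = p)
  out <- tibble(
    patient_id = patient_id, age = age,
    sex = draw(m$sex), alarm_type = draw(m$alarm_type),
    sleep_depth = draw(m$sleep_depth), enuresis_frequency = freq,
    wets_once_or_twice = draw(m$wets_once_or_twice), motivation = motivation
  )
  for (f in names(m$yes_rates)) {
    out[[f]] <- if (runif(1) < m$yes_rates[[f]]) "yes" else "no"
  }
  out[, c("patient_id", registration_fields())]
}

sample_event_time <- function(config) {
  if (runif(1) < config$implausible_time_prob) {
    as.integer(round(runif(1, 720, 1100)))
  } else {
    as.integer(round(pmin(pmax(rnorm(1, 150, 90), 30), 600)))
  }
}

#' Simulate one patient calendar
#'
#' Draws a registration record from the cohort marginals and a nightly
#' diary from the class trajectory, using the current RNG state (seed the
#' stream, or call via [simulate_cohort()], for reproducibility).
#'
#' @param class Latent class of the patient.
#' @param config A [sim_config()].
#' @param patient_id Id to assign (default `"P1"`).
#' @return A list with elements `registration` (one-row tibble), `nights`
#'   (tibble of `horizon_days` rows) and `latent_class`.
#' @export
simulate_patient <- function(class, config, patient_id = "P1") {
  stopifnot(class %in% outcome_levels())
  reg <- sample_registration(patient_id)
  horizon <- config$horizon_days

  # Dropout-class patients stop recording at the end of a geometric week.
  stop_day <- Inf
  if (class == "dropout" && config$dropout_hazard > 0) {
    stop_week <- rgeom(1, config$dropout_hazard) + 1
    stop_day <- 7 * stop_week
  }

  status <- character(horizon)
  severity <- rep(NA_integer_, horizon)
  awakening <- rep(NA_character_, horizon)
  repeat_wetting <- rep(NA_character_, horizon)
  woke_to_void <- rep(NA_character_, horizon)
  event_times <- rep(list(integer(0)), horizon)
  for (d in seq_len(horizon)) {
    if (d > stop_day || runif(1) < config$missing_prob) {
      status[d] <- "missing"
      next
    }
    wet <- runif(1) < class_wet_prob(class, d, config)
    if (wet) {
      status[d] <- "wet"
      repeat_wet <- runif(1) < config$repeat_wet_prob
      t1 <- sample_event_time(config)
      event_times[[d]] <- if (repeat_wet) {
        sort(c(t1, t1 + as.integer(round(runif(1, 30, 180)))))
      } else {
        t1
      }
      severity[d] <- sample(0:3, 1, prob = c(0.1, 0.3, 0.4, 0.2))
      awakening[d] <- sample(awakening_levels(), 1, prob = c(0.6, 0.3, 0.1))
      repeat_wetting[d] <- if (repeat_wet) "yes" else "no"
    } else {
      status[d] <- "dry"
      woke_to_void[d] <- if (runif(1) < 0.2) "yes" else "no"
    }
  }
  nights <- tibble(
    patient_id = patient_id, day_index = seq_len(horizon), status = status,
    severity = severity, awakening = awakening,
    repeat_wetting = repeat_wetting, woke_to_void = woke_to_void,
    event_times = event_times
  )
  list(registration = reg, nights = nights, latent_class = class)
}

#' Simulate a diary cohort
#'
#' Generates `sum(n_per_class)` patient calendars with latent classes
#' attached as ground truth. The cohort is a pure function of
#' `(config, config$seed)`.
#'
#' @param config A [sim_config()].
#' @return An [enuresis_cohort()] with `latent_classes` populated.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_total <- sum(config$n_per_class)
  if (n_total == 0) {
    return(enuresis_cohort(empty_registrations(), empty_nights(),
                           latent_classes = NULL, validate = FALSE))
  }
  width <- max(4, nchar(as.character(n_total)))
  i <- 0L
  patients <- vector("list", n_total)
  for (cls in outcome_levels()) {
    for (k in seq_len(config$n_per_class[[cls]])) {
      i <- i + 1L
      pid <- sprintf(paste0("P%0", width, "d"), i)
      patients[[i]] <- simulate_patient(cls, config, patient_id = pid)
    }
  }
  enuresis_cohort(
    list_rbind(map(patients, "registration")),
    list_rbind(map(patients, "nights")),
    latent_classes = tibble(
      patient_id = map_chr(patients, ~ .x$registration$patient_id),
      latent_class = map_chr(patients, "latent_class")
    )
  )
}
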