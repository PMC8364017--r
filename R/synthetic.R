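#' Synthetic scenario configuration
#'
#' Defines the study conditions a synthetic scenario is generated under.
#' Defaults mirror the packaged Lahj configuration: its total under-five
#' population and initial state distribution, the observed per-program
#' monthly admission-probability ranges, the treatment-outcome profile,
#' and a 14-month (August to October of the following year) horizon. The
#' true incidence probabilities default to values of the magnitude implied
#' by the Lahj calibration (annual incident cases around three times the
#' severe pool and two to three times the moderate pool).
#'
#' @param seed Integer seed; the whole bundle is reproducible from it.
#' @param n_months Simulation horizon in months.
#' @param population Total under-five population.
#' @param true_p_ms True monthly ModeratelyWasted -> SeverelyWasted
#'   probability.
#' @param true_p_hm True monthly Healthy -> ModeratelyWasted probability.
#' @param admission_ranges Named list of \code{c(low, high)} per program.
#' @param outcome_profile Named list per program of monthly outcome
#'   probabilities (see the packaged configuration for the layout).
#' @param seasonal_amplitude Sinusoidal seasonal amplitude as a fraction
#'   of each range's half-width, in [0, 1].
#' @param survey_noise_sd Additive Gaussian noise on the end-survey
#'   prevalence proportion (0 = noise-free), truncated at 0.
#' @return Object of class \code{scenario_config}.
#' @export
scenario_config <- function(seed, n_months = 14L, population = NULL,
                            true_p_ms = 0.06, true_p_hm = 0.032,
                            admission_ranges = NULL, outcome_profile = NULL,
                            seasonal_amplitude = 0.6, survey_noise_sd = 0) {
  fx <- lahj_fixture()
  if (is.null(population)) population <- fx$population
  if (is.null(admission_ranges)) admission_ranges <- fx$admission_ranges
  if (is.null(outcome_profile)) outcome_profile <- fx$outcome_profile
  seed <- as.integer(seed)
  stopifnot(!is.na(seed), n_months >= 2L, population > 0,
            true_p_ms >= 0, true_p_ms <= 1, true_p_hm >= 0, true_p_hm <= 1,
            seasonal_amplitude >= 0, seasonal_amplitude <= 1,
            survey_noise_sd >= 0)
  for (p in .PROGRAMS) {
    r <- admission_ranges[[p]]
    if (is.null(r) || length(r) != 2L || r[1L] > r[2L] ||
        any(r < 0) || any(r > 1)) {
      stop("admission_ranges['", p, "'] must be [low, high] within [0, 1]",
           call. = FALSE)
    }
  }
  structure(list(seed = seed, n_months = as.integer(n_months),
                 population = population, true_p_ms = true_p_ms,
                 true_p_hm = true_p_hm, admission_ranges = admission_ranges,
                 outcome_profile = outcome_profile,
                 seasonal_amplitude = seasonal_amplitude,
                 survey_noise_sd = survey_noise_sd),
            class = "scenario_config")
}

## internal: integerise outcome counts so their sum never exceeds the
## enrolled count (round-half-even, then trim the largest outcomes).
.integerise_outcomes <- function(expected, enrolled) {
  counts <- round(expected)
  excess <- sum(counts) - enrolled
  while (excess > 0) {
    i <- which.max(counts)
    take <- min(counts[i], excess)
    counts[i] <- counts[i] - take
    excess <- excess - take
  }
  counts
}

#' Generate a seeded synthetic scenario
#'
#' Simulates the true model forward under seasonal admission-probability
#' series drawn inside the configured ranges, then derives the artefacts a
#' real program would record: integer monthly admission and outcome counts
#' per program (rounded expected flows), start and end survey summaries,
#' and the admission-probability series a records-based analysis would
#' recover. The ground truth (incidence probabilities and full trajectory)
#' is kept alongside so parameter-recovery can be checked.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return Object of class \code{scenario_bundle}: list with
#'   \code{config}, \code{initial} (\code{state_census}), \code{records}
#'   (long data frame of monthly program records),
#'   \code{derived_admission_series}, \code{surveys} (start/end
#'   \code{survey_summary}), \code{targets} (calibration targets built
#'   from the end survey) and \code{truth} (\code{p_ms}, \code{p_hm},
#'   \code{admission_series}, \code{trajectory}).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  fx <- lahj_fixture()
  n <- config$n_months

  scale <- config$population / fx$population
  initial <- new_state_census(fx$initial$census$counts * scale, month = 0L)

  series <- seasonal_admission_series(config$admission_ranges, n,
                                      amplitude = config$seasonal_amplitude)
  stationary <- fx$stationary
  stationary[["ModeratelyWasted->SeverelyWasted"]] <- config$true_p_ms
  stationary[["Healthy->ModeratelyWasted"]] <- config$true_p_hm
  matrices <- build_matrix_sequence(stationary, series)
  traj <- simulate_cohort(initial, matrices, n)

  outcome_cols <- c("cured", "defaulted", "non_response", "referred_tsfp",
                    "referred_otp", "referred_tfc", "died")
  records <- list()
  derived <- matrix(0, n, 3L, dimnames = list(month = 0:(n - 1L),
                                              program = .PROGRAMS))
  for (p in .PROGRAMS) {
    src <- .PROGRAM_SOURCE_STATE[[p]]
    ts <- .PROGRAM_TREATMENT_STATE[[p]]
    profile <- unlist(config$outcome_profile[[p]])[outcome_cols]
    profile[is.na(profile)] <- 0
    for (t in seq_len(n)) {
      pool <- traj$counts[t, src]           # month-start source pool
      enrolled <- round(traj$counts[t, ts]) # month-start program census
      admissions <- round(series[t, p] * pool)
      outcomes <- .integerise_outcomes(profile * traj$counts[t, ts], enrolled)
      derived[t, p] <- if (pool > 0) min(1, admissions / pool) else 0
      records[[length(records) + 1L]] <- data.frame(
        program = p, month = t - 1L, admissions = admissions,
        enrolled = enrolled, as.list(outcomes)
      )
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  obs_sev <- observed_prevalence(traj, n, "severe")
  obs_mod <- observed_prevalence(traj, n, "moderate")
  noise <- function(x) {
    if (config$survey_noise_sd <= 0) return(x)
    max(0, x + stats::rnorm(1L, 0, config$survey_noise_sd))
  }
  end_mod_prev <- noise(obs_mod / config$population)
  end_sev_prev <- noise(obs_sev / config$population)
  mortality <- fx$stationary[["Healthy->Deceased"]]
  start_survey <- survey_summary(
    region = "synthetic", under5_population = config$population,
    moderate_prevalence = (initial$counts[["ModeratelyWasted"]] ) /
      config$population,
    severe_prevalence = (initial$counts[["SeverelyWasted"]] +
                           initial$counts[["SeverelyWastedComplicated"]]) /
      config$population,
    under5_mortality_monthly = mortality, survey_month = "month-0"
  )
  end_survey <- survey_summary(
    region = "synthetic", under5_population = config$population,
    moderate_prevalence = end_mod_prev, severe_prevalence = end_sev_prev,
    under5_mortality_monthly = mortality,
    survey_month = paste0("month-", n)
  )
  targets <- list(
    severe = calibration_target("severe", end_sev_prev * config$population,
                                n),
    moderate = calibration_target("moderate",
                                  end_mod_prev * config$population, n)
  )
  structure(list(
    config = config,
    initial = initial,
    records = records,
    derived_admission_series = derived,
    surveys = list(start = start_survey, end = end_survey),
    targets = targets,
    truth = list(p_ms = config$true_p_ms, p_hm = config$true_p_hm,
                 admission_series = series, trajectory = traj)
  ), class = "scenario_bundle")
}

#' Calibrate a synthetic scenario as the pipeline would
#'
#' Runs the sequential severe-then-moderate calibration using only the
#' bundle's observable artefacts: the initial census, the stationary rates
#' (without the incidence unknowns), the records-derived admission series
#' and the end-survey targets.
#'
#' @param bundle A \code{scenario_bundle}.
#' @param ... Passed to \code{\link{calibrate_incidence}}.
#' @return List with \code{severe} and \code{moderate}
#'   \code{calibration_result}s.
#' @export
calibrate_scenario <- function(bundle, ...) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  fx <- lahj_fixture()
  inputs <- list(initial = bundle$initial,
                 stationary = fx$stationary,
                 admission_series = bundle$derived_admission_series)
  sequential_calibration(inputs, bundle$targets$severe,
                         bundle$targets$moderate, ...)
}
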