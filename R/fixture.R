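#' Packaged Lahj (Yemen) model configuration
#'
#' Loads the packaged configuration for the Lahj governorate: the August
#' 2018 initial state census, the stationary transition rates, the observed
#' monthly admission-probability ranges per program, the treatment-outcome
#' profile used by the synthetic generator, and the October 2019 survey
#' counts used as calibration targets.
#'
#' @param path Path to a YAML configuration; defaults to the packaged Lahj
#'   file.
#' @return List with elements \code{region}, \code{initial}
#'   (\code{initial_census_spec}), \code{stationary} (named rate vector),
#'   \code{printed_complements}, \code{admission_ranges},
#'   \code{outcome_profile}, \code{validation_targets},
#'   \code{validation_month}, \code{population}.
#' @export
#' @examples
#' fx <- lahj_fixture()
#' fx$initial
lahj_fixture <- function(path = system.file("extdata", "lahj.yaml",
                                            package = "wastingMarkov")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("configuration file not found: '", path, "'", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  for (field in c("initial_census", "stationary_rates", "admission_ranges",
                  "validation_targets", "validation_month")) {
    if (is.null(cfg[[field]])) {
      stop("configuration is missing field '", field, "'", call. = FALSE)
    }
  }
  census <- new_state_census(unlist(cfg$initial_census), month = 0L)
  ranges <- lapply(cfg$admission_ranges, as.numeric)
  for (p in names(ranges)) {
    r <- ranges[[p]]
    if (length(r) != 2L || any(r < 0) || any(r > 1) || r[1L] > r[2L]) {
      stop("admission_ranges['", p, "'] must be [low, high] within [0, 1]",
           call. = FALSE)
    }
  }
  list(
    region = cfg$region,
    initial = initial_census_spec(census),
    stationary = as_rate_vector(cfg$stationary_rates),
    printed_complements = cfg$printed_complements,
    admission_ranges = ranges,
    outcome_profile = cfg$outcome_profile,
    validation_targets = lapply(cfg$validation_targets, as.numeric),
    validation_month = as.integer(cfg$validation_month),
    population = census_total(census)
  )
}

#' Consistency diagnostic for published remain-in-state terms
#'
#' The model computes every self-transition as the exact complement of its
#' row's off-diagonal sum. This diagnostic compares that construction with
#' the published remain-in-state terms. For rows published as a full self
#' probability, it reports |(1 - off-diagonal sum) - published|. For rows
#' published as "1 minus the unknown/time-varying terms minus a constant",
#' it reports |sum of constant off-diagonals - published constant|. The
#' SeverelyWasted row is knowingly inconsistent in the source material
#' (published constant 0.0724 vs off-diagonal constants summing 0.11038)
#' and is flagged.
#'
#' @param fixture A configuration list from \code{\link{lahj_fixture}}.
#' @return Data frame with one row per published term: \code{state},
#'   \code{kind}, \code{published}, \code{reconstructed},
#'   \code{discrepancy}, \code{consistent} (within 5e-3).
#' @export
printed_complement_diagnostic <- function(fixture = lahj_fixture()) {
  pc <- fixture$printed_complements
  if (is.null(pc)) stop("fixture has no printed_complements", call. = FALSE)
  rates <- fixture$stationary
  edges <- do.call(rbind, lapply(names(rates), .parse_edge))
  rows <- lapply(names(pc), function(state) {
    kind <- pc[[state]]$kind
    published <- as.numeric(pc[[state]]$value)
    const_sum <- sum(rates[edges[, 1L] == state])
    reconstructed <- switch(
      kind,
      self_probability = 1 - const_sum,
      constant_part = const_sum,
      stop("unknown printed-complement kind '", kind, "'", call. = FALSE)
    )
    data.frame(state = state, kind = kind, published = published,
               reconstructed = reconstructed,
               discrepancy = abs(reconstructed - published))
  })
  out <- do.call(rbind, rows)
  out$consistent <- out$discrepancy <= 5e-3
  out[order(out$state), , drop = FALSE]
}

#' Seasonal monthly admission-probability series
#'
#' Generates one monthly admission-probability series per program: a
#' 12-month sinusoid centred on the midpoint of the program's observed
#' range with random phase and small Gaussian month-to-month jitter,
#' clipped to the range so every monthly value stays inside it. Uses the
#' current RNG state; callers control reproducibility with
#' \code{set.seed}.
#'
#' @param ranges Named list of \code{c(low, high)} per program
#'   (\code{tsfp}, \code{otp}, \code{tfc}).
#' @param n_months Number of months.
#' @param amplitude Seasonal amplitude as a fraction of the half-range,
#'   in [0, 1].
#' @param jitter_sd Month-to-month jitter, as a fraction of the half-range.
#' @return Numeric matrix \code{n_months x 3} with columns \code{tsfp},
#'   \code{otp}, \code{tfc}; rows are months 0, 1, ...
#' @export
seasonal_admission_series <- function(ranges, n_months, amplitude = 0.6,
                                      jitter_sd = 0.1) {
  stopifnot(n_months >= 1, amplitude >= 0, amplitude <= 1, jitter_sd >= 0)
  miss <- setdiff(.PROGRAMS, names(ranges))
  if (length(miss)) {
    stop("ranges missing program(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  t <- seq_len(n_months) - 1L
  out <- vapply(.PROGRAMS, function(p) {
    r <- ranges[[p]]
    mid <- mean(r)
    half <- diff(r) / 2
    phase <- stats::runif(1L, 0, 12)
    x <- mid + half * (amplitude * sin(2 * pi * (t + phase) / 12) +
                         stats::rnorm(n_months, 0, jitter_sd))
    pmin(pmax(x, r[1L]), r[2L])
  }, numeric(n_months))
  out <- matrix(out, nrow = n_months,
                dimnames = list(month = t, program = .PROGRAMS))
  out
}

#' Calibration inputs for the Lahj configuration
#'
#' Bundles the packaged Lahj census and stationary rates with a seeded
#' synthetic monthly admission series drawn inside the observed
#' per-program ranges (the real monthly Nutrition Cluster series is not
#' public), ready for \code{\link{calibrate_incidence}} /
#' \code{\link{sequential_calibration}}.
#'
#' @param seed Integer seed for the admission series.
#' @param n_months Simulation horizon in months (default: the packaged
#'   validation month, 14 = August 2018 to October 2019).
#' @param fixture Configuration list from \code{\link{lahj_fixture}}.
#' @return List with \code{inputs} (list of \code{initial},
#'   \code{stationary}, \code{admission_series}) and \code{targets}
#'   (\code{\link{calibration_target}} per tier).
#' @export
lahj_calibration_inputs <- function(seed = 1L, n_months = NULL,
                                    fixture = lahj_fixture()) {
  if (is.null(n_months)) n_months <- fixture$validation_month
  set.seed(as.integer(seed))
  series <- seasonal_admission_series(fixture$admission_ranges, n_months)
  inputs <- list(initial = fixture$initial$census,
                 stationary = fixture$stationary,
                 admission_series = series)
  targets <- list(
    severe = calibration_target("severe",
                                fixture$validation_targets$severe, n_months),
    moderate = calibration_target("moderate",
                                  fixture$validation_targets$moderate,
                                  n_months)
  )
  list(inputs = inputs, targets = targets)
}
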