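#' Calibration target
#'
#' The survey-observed wasting count (untreated cases plus the past
#' month's treatment admissions) the simulated observed prevalence must
#' match at the validation month.
#'
#' @param tier \code{"severe"} or \code{"moderate"}.
#' @param observed_prevalence Target expected count, >= 0.
#' @param month Validation month, >= 1 (14 for an August -> October of the
#'   following year run).
#' @return Object of class \code{calibration_target}.
#' @export
calibration_target <- function(tier = c("severe", "moderate"),
                               observed_prevalence, month = 14L) {
  tier <- match.arg(tier)
  observed_prevalence <- as.numeric(observed_prevalence)
  month <- as.integer(month)
  if (!is.finite(observed_prevalence) || observed_prevalence < 0) {
    stop("observed_prevalence must be a non-negative count", call. = FALSE)
  }
  if (is.na(month) || month < 1L) stop("month must be >= 1", call. = FALSE)
  structure(list(tier = tier, observed_prevalence = observed_prevalence,
                 month = month),
            class = "calibration_target")
}

## internal: insert a candidate incidence into the stationary rates and
## simulate; returns the trajectory.
.forward_trajectory <- function(candidate, tier, inputs, target_month) {
  stationary <- as_rate_vector(inputs$stationary)
  if (tier == "moderate" &&
      !("ModeratelyWasted->SeverelyWasted" %in% names(stationary))) {
    stop("moderate calibration requires the severe incidence ",
         "('ModeratelyWasted->SeverelyWasted') to be fixed in the ",
         "stationary rates first; run the severe calibration and freeze ",
         "its result (see sequential_calibration)", call. = FALSE)
  }
  stationary[[.TIER_INCIDENCE_EDGE[[tier]]]] <- candidate
  series <- as.matrix(inputs$admission_series)
  if (nrow(series) < target_month) {
    stop("admission_series has ", nrow(series), " months; need ",
         target_month, call. = FALSE)
  }
  matrices <- build_matrix_sequence(stationary, series[seq_len(target_month), ,
                                                       drop = FALSE])
  simulate_cohort(inputs$initial, matrices, target_month)
}

#' Simulated observed prevalence under a candidate incidence
#'
#' Runs the cohort model with the candidate incidence probability
#' substituted for the tier's unknown transition (ModeratelyWasted ->
#' SeverelyWasted for severe, Healthy -> ModeratelyWasted for moderate)
#' and returns the survey-comparable observed prevalence at the target
#' month. Strictly increasing in the candidate, which is what makes
#' bisection calibration valid.
#'
#' @param candidate Candidate monthly incidence probability.
#' @param tier \code{"severe"} or \code{"moderate"}. Moderate requires the
#'   severe incidence to be present in \code{inputs$stationary}.
#' @param inputs List with \code{initial} (\code{state_census} at month 0),
#'   \code{stationary} (rates without the tier's unknown) and
#'   \code{admission_series} (months x programs matrix).
#' @param target_month Month at which the observed prevalence is taken.
#' @return Expected observed count (state count plus prior-month treatment
#'   admissions).
#' @export
forward_prevalence <- function(candidate, tier = c("severe", "moderate"),
                               inputs, target_month) {
  tier <- match.arg(tier)
  traj <- .forward_trajectory(candidate, tier, inputs, target_month)
  observed_prevalence(traj, target_month, tier)
}

## internal: largest feasible candidate for the tier's incidence row
.candidate_upper_bound <- function(tier, inputs, target_month) {
  stationary <- as_rate_vector(inputs$stationary)
  edges <- do.call(rbind, lapply(names(stationary), .parse_edge))
  row_state <- .TIER_SOURCE_STATE[[tier]]
  keep <- edges[, 1L] == row_state &
    names(stationary) != .TIER_INCIDENCE_EDGE[[tier]]
  fixed <- sum(stationary[keep])
  series <- as.matrix(inputs$admission_series)[seq_len(target_month), ,
                                               drop = FALSE]
  adm_max <- switch(tier,
                    severe = max(series[, "tsfp"]),  # row ModeratelyWasted
                    moderate = 0)                    # row Healthy: no admission
  max(0, 1 - fixed - adm_max)
}

#' Calibrate one incidence probability against a prevalence target
#'
#' Bisection root-finding on the monotone map from candidate incidence to
#' simulated observed prevalence: the bracket is [0, largest feasible
#' candidate for the affected matrix row], and iteration stops when the
#' achieved observed prevalence is within \code{solver_tol} children of
#' the target. The converged run is then summarised into the annual
#' incidence quantities: annual incident cases (candidate times the source
#' state's expected count at each month start, summed over months
#' 1..\code{annual_months}), the incidence correction factor
#' k = incident cases / baseline prevalence, and the mean episode duration
#' 12 / k.
#'
#' @param target A \code{\link{calibration_target}}.
#' @param inputs As in \code{\link{forward_prevalence}}.
#' @param solver_tol Tolerance on |achieved - target| in expected children
#'   (default 1e-3).
#' @param max_iter Maximum bisection iterations (default 200).
#' @param annual_months Months summed for the annual incident cases
#'   (default 12).
#' @return Object of class \code{calibration_result} with fields
#'   \code{tier}, \code{probability}, \code{annual_incident_cases},
#'   \code{baseline_prevalence}, \code{k},
#'   \code{mean_episode_duration_months}, \code{achieved_prevalence},
#'   \code{target_prevalence}, \code{target_month}, \code{iterations} and
#'   the converged \code{trajectory}.
#' @export
calibrate_incidence <- function(target, inputs, solver_tol = 1e-3,
                                max_iter = 200L, annual_months = 12L) {
  stopifnot(inherits(target, "calibration_target"))
  tier <- target$tier
  month <- target$month
  f <- function(p) forward_prevalence(p, tier, inputs, month)
  lo <- 0
  hi <- .candidate_upper_bound(tier, inputs, month)
  f_lo <- f(lo)
  f_hi <- f(hi)
  tgt <- target$observed_prevalence
  if (tgt < f_lo - solver_tol || tgt > f_hi + solver_tol) {
    stop(sprintf(
      paste0("target observed prevalence %.3f is outside the attainable ",
             "bracket [%.3f, %.3f] (candidates 0 and %.6f)"),
      tgt, f_lo, f_hi, hi), call. = FALSE)
  }
  iterations <- 0L
  if (abs(f_lo - tgt) <= solver_tol) {
    sol <- lo; achieved <- f_lo
  } else if (abs(f_hi - tgt) <= solver_tol) {
    sol <- hi; achieved <- f_hi
  } else {
    sol <- NA_real_; achieved <- NA_real_
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      f_mid <- f(mid)
      iterations <- i
      if (abs(f_mid - tgt) <= solver_tol) {
        sol <- mid; achieved <- f_mid
        break
      }
      if (f_mid < tgt) lo <- mid else hi <- mid
    }
    if (is.na(sol)) {  # tolerance not reached; return the midpoint anyway
      sol <- (lo + hi) / 2
      achieved <- f(sol)
      warning("bisection stopped after ", max_iter,
              " iterations; |achieved - target| = ",
              format(abs(achieved - tgt)), call. = FALSE)
    }
  }
  traj <- .forward_trajectory(sol, tier, inputs, month)
  src <- .TIER_SOURCE_STATE[[tier]]
  months_used <- min(annual_months, traj$horizon)
  annual <- sol * sum(traj$counts[seq_len(months_used), src])
  baseline <- inputs$initial$counts[[.TIER_UNTREATED_STATE[[tier]]]]
  k <- k_from_incidence(annual, baseline)
  structure(list(
    tier = tier,
    probability = sol,
    annual_incident_cases = annual,
    baseline_prevalence = baseline,
    k = k,
    ## a zero calibrated incidence has no finite episode duration
    mean_episode_duration_months = if (k > 0) duration_from_k(k) else Inf,
    achieved_prevalence = achieved,
    target_prevalence = tgt,
    target_month = month,
    iterations = iterations,
    trajectory = traj
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    paste0("<calibration_result> tier %s\n",
           "  incidence probability : %.6f /month\n",
           "  annual incident cases : %.1f\n",
           "  baseline prevalence   : %.0f\n",
           "  k                     : %.2f\n",
           "  episode duration      : %.2f months\n",
           "  achieved vs target    : %.3f vs %.3f (month %d, %d iterations)\n"),
    x$tier, x$probability, x$annual_incident_cases, x$baseline_prevalence,
    x$k, x$mean_episode_duration_months, x$achieved_prevalence,
    x$target_prevalence, x$target_month, x$iterations))
  invisible(x)
}

#' Incidence correction factor from annual incident cases
#'
#' k converts a point prevalence into expected annual incident cases:
#' incidence = prevalence x k.
#'
#' @param annual_incident_cases Expected incident cases over the year.
#' @param baseline_prevalence Point prevalence at the start of the year
#'   (> 0).
#' @return Dimensionless k.
#' @export
k_from_incidence <- function(annual_incident_cases, baseline_prevalence) {
  if (!is.finite(baseline_prevalence) || baseline_prevalence <= 0) {
    stop("baseline_prevalence must be > 0", call. = FALSE)
  }
  if (annual_incident_cases < 0) {
    stop("annual_incident_cases must be >= 0", call. = FALSE)
  }
  annual_incident_cases / baseline_prevalence
}

#' Mean episode duration from k
#'
#' Inverts incidence = prevalence x 12 / duration: duration = 12 / k
#' months. The conventional global value k = 1.6 corresponds to 7.5
#' months.
#'
#' @param k Incidence correction factor, > 0.
#' @return Mean episode duration in months.
#' @export
#' @examples
#' duration_from_k(1.6)   # 7.5
#' duration_from_k(3.11)  # 3.86
duration_from_k <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0)) stop("k must be > 0", call. = FALSE)
  12 / k
}

#' Sequential calibration of severe then moderate incidence
#'
#' Within each round the severe incidence is calibrated first and frozen
#' into the stationary rates before the moderate calibration runs; calling
#' the moderate step without a severe result is impossible through this
#' interface. Because the severe prevalence over a year-long horizon also
#' depends on the moderate incidence (which replenishes the moderate pool
#' that progression draws from), the severe-then-moderate sequence is
#' iterated to a fixed point: each round re-runs the pair with the other
#' tier's latest estimate frozen, until neither incidence moves by more
#' than \code{rel_tol} relative. If the stationary rates carry no starting
#' value for the moderate incidence, it is bootstrapped by a moderate
#' calibration with the progression probability set to 0.
#'
#' @param inputs As in \code{\link{forward_prevalence}}; the stationary
#'   rates may contain a starting moderate incidence but not the severe
#'   one.
#' @param severe_target,moderate_target \code{\link{calibration_target}}s
#'   of the matching tiers.
#' @param rel_tol Relative fixed-point tolerance on both incidence
#'   probabilities (default 1e-6).
#' @param max_rounds Maximum severe/moderate rounds (default 50).
#' @param ... Passed on to \code{\link{calibrate_incidence}}.
#' @return List with elements \code{severe} and \code{moderate}
#'   (\code{calibration_result}s) and \code{rounds}.
#' @export
sequential_calibration <- function(inputs, severe_target, moderate_target,
                                   rel_tol = 1e-6, max_rounds = 50L, ...) {
  stopifnot(inherits(severe_target, "calibration_target"),
            inherits(moderate_target, "calibration_target"))
  if (severe_target$tier != "severe" || moderate_target$tier != "moderate") {
    stop("targets must be, in order, the severe and the moderate target",
         call. = FALSE)
  }
  inputs$stationary <- as_rate_vector(inputs$stationary)
  if ("ModeratelyWasted->SeverelyWasted" %in% names(inputs$stationary)) {
    stop("the severe incidence ('ModeratelyWasted->SeverelyWasted') is the ",
         "calibrated unknown and must not be present in the stationary ",
         "rates", call. = FALSE)
  }
  p_hm <- inputs$stationary["Healthy->ModeratelyWasted"]
  if (is.na(p_hm)) {
    ## bootstrap the moderate incidence with progression switched off
    boot <- inputs
    boot$stationary[["ModeratelyWasted->SeverelyWasted"]] <- 0
    p_hm <- calibrate_incidence(moderate_target, boot, ...)$probability
  } else {
    p_hm <- as.numeric(p_hm)
  }
  severe <- moderate <- NULL
  rounds <- 0L
  for (r in seq_len(max_rounds)) {
    rounds <- r
    cur <- inputs
    cur$stationary[["Healthy->ModeratelyWasted"]] <- p_hm
    severe_new <- calibrate_incidence(severe_target, cur, ...)
    cur$stationary[["ModeratelyWasted->SeverelyWasted"]] <-
      severe_new$probability
    moderate_new <- calibrate_incidence(moderate_target, cur, ...)
    p_hm_new <- moderate_new$probability
    done <- !is.null(severe) &&
      abs(severe_new$probability - severe$probability) <=
        rel_tol * max(severe$probability, 1e-12) &&
      abs(p_hm_new - p_hm) <= rel_tol * max(p_hm, 1e-12)
    severe <- severe_new
    moderate <- moderate_new
    p_hm <- p_hm_new
    if (done) break
  }
  if (rounds == max_rounds) {
    warning("sequential calibration did not reach the fixed-point ",
            "tolerance within ", max_rounds, " rounds", call. = FALSE)
  }
  list(severe = severe, moderate = moderate, rounds = rounds)
}
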