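#' Advance a census by one month
#'
#' Deterministic expected-count update: the returned counts are the
#' matrix-weighted redistribution of the input counts. Total population
#' (Deceased included) is conserved.
#'
#' @param census A \code{state_census} whose month equals the matrix month.
#' @param tmat A \code{transition_matrix} for that month.
#' @return A \code{state_census} at \code{month + 1}.
#' @export
step_census <- function(census, tmat) {
  stopifnot(inherits(census, "state_census"))
  m <- attr(tmat, "month")
  if (!identical(as.integer(m), census$month)) {
    stop("census month (", census$month, ") does not match matrix month (",
         m, ")", call. = FALSE)
  }
  new <- drop(census$counts %*% unclass(tmat))
  new_state_census(new, census$month + 1L)
}

#' Run the cohort simulation
#'
#' Propagates the initial expected census forward month by month under the
#' supplied matrix sequence, recording for every month the inflow of
#' children newly entering each state (mass arriving from *other* states
#' during that month). The treatment-state inflows implement the
#' "admitted to treatment within the past month" accounting used for the
#' survey-comparable observed prevalence.
#'
#' @param initial \code{state_census} at month 0.
#' @param matrices List of \code{transition_matrix} with consecutive months
#'   starting at 0; at least \code{horizon} of them.
#' @param horizon Integer number of months to simulate (>= 1).
#' @return Object of class \code{wasting_trajectory}: list with
#'   \code{counts} ((horizon+1) x 8 matrix, row \code{t+1} = month t),
#'   \code{inflows} (horizon x 8 matrix, row t = mass entering each state
#'   during month t, i.e. over the step t-1 -> t) and \code{horizon}.
#' @export
simulate_cohort <- function(initial, matrices, horizon = length(matrices)) {
  stopifnot(inherits(initial, "state_census"))
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1L) {
    stop("horizon must be an integer >= 1", call. = FALSE)
  }
  if (length(matrices) < horizon) {
    stop("need at least ", horizon, " monthly matrices; got ",
         length(matrices), call. = FALSE)
  }
  if (initial$month != 0L) {
    stop("initial census must be at month 0", call. = FALSE)
  }
  counts <- matrix(0, horizon + 1L, 8L,
                   dimnames = list(month = 0:horizon, state = .WASTING_STATES))
  inflows <- matrix(0, horizon, 8L,
                    dimnames = list(month = seq_len(horizon),
                                    state = .WASTING_STATES))
  counts[1L, ] <- initial$counts
  total0 <- sum(initial$counts)
  cur <- initial
  for (t in seq_len(horizon)) {
    P <- matrices[[t]]
    nxt <- step_census(cur, P)
    ## inflow into state j = new mass minus the mass that stayed put
    inflows[t, ] <- nxt$counts - cur$counts * diag(unclass(P))
    counts[t + 1L, ] <- nxt$counts
    if (abs(sum(nxt$counts) - total0) > 1e-6 * max(total0, 1)) {
      stop("population not conserved at month ", t, call. = FALSE)
    }
    cur <- nxt
  }
  structure(list(counts = counts, inflows = inflows, horizon = horizon),
            class = "wasting_trajectory")
}

#' @export
print.wasting_trajectory <- function(x, ...) {
  cat("<wasting_trajectory> months 0-", x$horizon, "\n", sep = "")
  print(round(x$counts, 1))
  invisible(x)
}

## internal: census counts row for a given month (0-based)
.traj_counts <- function(trajectory, month) {
  trajectory$counts[month + 1L, ]
}

#' Survey-comparable observed prevalence
#'
#' A cross-sectional survey classifies as wasted both the children in the
#' untreated state and those admitted to the corresponding treatment
#' program within the past month (who still meet the anthropometric case
#' definition). The observed prevalence at month \code{m} is therefore the
#' untreated-state count at \code{m} plus the inflow into the tier's
#' treatment state during month \code{m}.
#'
#' @param trajectory A \code{wasting_trajectory}.
#' @param month Integer in \code{1 .. horizon}. Month 0 has no preceding
#'   admission inflow and is an error (the initial observed prevalence
#'   comes from the survey inputs, not the model).
#' @param tier \code{"moderate"} or \code{"severe"}.
#' @return Expected number of children a survey at that month would
#'   classify as wasted at the given tier.
#' @export
observed_prevalence <- function(trajectory, month, tier = c("severe", "moderate")) {
  stopifnot(inherits(trajectory, "wasting_trajectory"))
  tier <- match.arg(tier)
  month <- as.integer(month)
  if (is.na(month) || month < 1L || month > trajectory$horizon) {
    if (!is.na(month) && month == 0L) {
      stop("observed prevalence is undefined at month 0 (no preceding ",
           "admission inflow); use the survey inputs instead", call. = FALSE)
    }
    stop("month must be in 1..", trajectory$horizon, call. = FALSE)
  }
  state <- .TIER_UNTREATED_STATE[[tier]]
  treat <- .TIER_TREATMENT_STATE[[tier]]
  .traj_counts(trajectory, month)[[state]] + trajectory$inflows[month, treat]
}
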