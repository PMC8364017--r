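## One-way deterministic sensitivity analysis: each transition probability
## is scaled through a range of multipliers while all others stay at their
## base values, the incidence calibration is re-run at each point, and the
## induced change in the calibrated incidence is reported.

.ADMISSION_PARAMS <- c("tsfp_admission", "otp_admission", "tfc_admission")

#' Parameter names available for sensitivity sweeps
#'
#' All stationary transition edges present in the inputs plus the three
#' admission-probability series. The tier's own calibrated incidence edge
#' is excluded (it is the unknown being recalibrated).
#'
#' @param inputs Calibration inputs (see \code{\link{forward_prevalence}}).
#' @param tier Tier whose calibration the sweep re-runs.
#' @return Character vector of valid parameter names.
#' @export
sweepable_parameters <- function(inputs, tier = c("severe", "moderate")) {
  tier <- match.arg(tier)
  stationary <- as_rate_vector(inputs$stationary)
  setdiff(c(sort(names(stationary)), .ADMISSION_PARAMS),
          .TIER_INCIDENCE_EDGE[[tier]])
}

## internal: scale one parameter in the inputs by a multiplier.
## Returns list(inputs, perturbed_value, clamped) or NULL if infeasible.
.perturb_inputs <- function(inputs, parameter, multiplier) {
  clamped <- FALSE
  if (parameter %in% .ADMISSION_PARAMS) {
    prog <- sub("_admission$", "", parameter)
    series <- as.matrix(inputs$admission_series)
    scaled <- series[, prog] * multiplier
    ## cap each month at the feasibility limit of the source-state row
    stationary <- as_rate_vector(inputs$stationary)
    edges <- do.call(rbind, lapply(names(stationary), .parse_edge))
    row_state <- .PROGRAM_SOURCE_STATE[[prog]]
    cap <- 1 - sum(stationary[edges[, 1L] == row_state])
    if (any(scaled > cap)) {
      clamped <- TRUE
      scaled <- pmin(scaled, cap)
    }
    scaled <- pmin(scaled, 1)
    series[, prog] <- scaled
    inputs$admission_series <- series
    value <- mean(scaled)
  } else {
    stationary <- as_rate_vector(inputs$stationary)
    value <- stationary[[parameter]] * multiplier
    if (value > 1) return(NULL)
    stationary[[parameter]] <- value
    inputs$stationary <- stationary
  }
  list(inputs = inputs, perturbed_value = value, clamped = clamped)
}

#' One-way sensitivity sweep of a single parameter
#'
#' Scales the named parameter through the multiplier grid (1.0 is always
#' included), re-runs the incidence calibration at every feasible point
#' and records the recalibrated incidence probability, k and episode
#' duration. Multipliers that make a matrix row infeasible are skipped
#' with a warning; admission-series multipliers are clamped at row
#' feasibility (also with a warning). The sweep is fully deterministic.
#'
#' @param parameter One of \code{\link{sweepable_parameters}}.
#' @param inputs Calibration inputs (see \code{\link{forward_prevalence}});
#'   for a moderate-tier sweep the stationary rates must already contain
#'   the calibrated severe incidence.
#' @param target A \code{\link{calibration_target}} for the tier being
#'   recalibrated.
#' @param multipliers Ordered positive factors (default
#'   \code{c(0.5, 0.75, 1, 1.25, 1.5)}).
#' @param ... Passed to \code{\link{calibrate_incidence}}.
#' @return Data frame with columns \code{parameter}, \code{multiplier},
#'   \code{perturbed_value}, \code{incidence}, \code{k},
#'   \code{duration_months}; attribute \code{"multipliers"} records the
#'   attempted grid.
#' @export
one_way_sweep <- function(parameter, inputs, target,
                          multipliers = c(0.5, 0.75, 1, 1.25, 1.5), ...) {
  stopifnot(inherits(target, "calibration_target"))
  valid <- sweepable_parameters(inputs, target$tier)
  if (!parameter %in% valid) {
    stop("unknown or unsweepable parameter '", parameter,
         "'; valid parameters: ", paste(valid, collapse = ", "),
         call. = FALSE)
  }
  if (any(multipliers <= 0)) stop("multipliers must be > 0", call. = FALSE)
  grid <- sort(unique(c(as.numeric(multipliers), 1)))
  rows <- lapply(grid, function(m) {
    pert <- .perturb_inputs(inputs, parameter, m)
    if (is.null(pert)) {
      warning("parameter '", parameter, "' at multiplier ", m,
              " exceeds 1; skipped", call. = FALSE)
      return(NULL)
    }
    if (pert$clamped) {
      warning("admission series '", parameter, "' at multiplier ", m,
              " clamped at row feasibility", call. = FALSE)
    }
    res <- tryCatch(calibrate_incidence(target, pert$inputs, ...),
                    error = function(e) {
                      warning("multiplier ", m, " for '", parameter,
                              "' skipped: ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (is.null(res)) return(NULL)
    data.frame(parameter = parameter, multiplier = m,
               perturbed_value = pert$perturbed_value,
               incidence = res$probability, k = res$k,
               duration_months = res$mean_episode_duration_months)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parameter = character(), multiplier = numeric(),
                      perturbed_value = numeric(), incidence = numeric(),
                      k = numeric(), duration_months = numeric())
  }
  rownames(out) <- NULL
  attr(out, "multipliers") <- grid
  out
}

#' Rank parameters by their impact on calibrated incidence
#'
#' Impact is the spread (max - min) of the recalibrated incidence
#' probability across a parameter's sweep. Parameters are ordered by
#' decreasing impact, ties broken alphabetically.
#'
#' @param results List of sweep data frames from
#'   \code{\link{one_way_sweep}}, all run over the same multiplier grid.
#' @return Data frame with columns \code{parameter}, \code{impact},
#'   ordered by rank.
#' @export
rank_impacts <- function(results) {
  if (!length(results)) stop("no sweep results supplied", call. = FALSE)
  grids <- lapply(results, attr, "multipliers")
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) > 1L) {
    stop("inconsistent multiplier grids across parameters", call. = FALSE)
  }
  rows <- lapply(results, function(df) {
    if (!nrow(df)) return(NULL)
    data.frame(parameter = df$parameter[1L],
               impact = max(df$incidence) - min(df$incidence))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$impact, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a full one-way sensitivity analysis
#'
#' Sweeps every requested parameter and returns the long-format table plus
#' the impact ranking.
#'
#' @param inputs,target As in \code{\link{one_way_sweep}}.
#' @param parameters Parameter names (default: all sweepable).
#' @param multipliers Multiplier grid.
#' @param ... Passed to \code{\link{calibrate_incidence}}.
#' @return List with \code{sweeps} (long data frame) and \code{ranking}.
#' @export
run_sensitivity <- function(inputs, target,
                            parameters = sweepable_parameters(inputs,
                                                              target$tier),
                            multipliers = c(0.5, 0.75, 1, 1.25, 1.5), ...) {
  results <- lapply(parameters, one_way_sweep, inputs = inputs,
                    target = target, multipliers = multipliers, ...)
  names(results) <- parameters
  sweeps <- do.call(rbind, results)
  rownames(sweeps) <- NULL
  list(sweeps = sweeps, ranking = rank_impacts(results))
}
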