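#' Annual treatment caseload
#'
#' Caseload = prevalent cases at the start of the year plus incident cases
#' over the year = prevalence x (1 + k). With the conventional k = 1.6
#' this is 2.6 x prevalence.
#'
#' @param baseline_prevalence Point prevalence count at the start of the
#'   year, >= 0.
#' @param k Incidence correction factor, >= 0.
#' @return Expected annual caseload.
#' @export
#' @examples
#' annual_caseload(4199, 1.6)   # conventional
#' annual_caseload(4199, 3.11)  # context-specific
annual_caseload <- function(baseline_prevalence, k) {
  if (any(baseline_prevalence < 0) || any(k < 0)) {
    stop("baseline_prevalence and k must be non-negative", call. = FALSE)
  }
  baseline_prevalence * (1 + k)
}

#' Percent increase between two caseloads
#'
#' @param caseload_original Caseload under the conventional k (> 0).
#' @param caseload_context Caseload under the context-specific k.
#' @return Percent change, 100 x (context / original - 1).
#' @export
percent_increase <- function(caseload_original, caseload_context) {
  if (any(caseload_original <= 0)) {
    stop("caseload_original must be > 0", call. = FALSE)
  }
  100 * (caseload_context / caseload_original - 1)
}

#' Fraction of moderately wasted children who progress to severe wasting
#'
#' Progression events over the run are the monthly progression probability
#' times the moderate pool at each month start, summed. The denominator is
#' the cumulative mass ever moderately wasted: the initial moderate pool
#' plus every inflow into the ModeratelyWasted state over the run. The
#' source material does not define this denominator, so the number should
#' be read as approximate.
#'
#' @param trajectory A \code{wasting_trajectory} from a calibrated run.
#' @param p_ms Monthly ModeratelyWasted -> SeverelyWasted probability used
#'   in that run.
#' @return Percentage in [0, 100].
#' @export
progression_fraction <- function(trajectory, p_ms) {
  stopifnot(inherits(trajectory, "wasting_trajectory"))
  if (!is.finite(p_ms) || p_ms < 0 || p_ms > 1) {
    stop("p_ms must be a probability", call. = FALSE)
  }
  h <- trajectory$horizon
  if (h < 1L) stop("trajectory is empty", call. = FALSE)
  moderate_at_start <- trajectory$counts[seq_len(h), "ModeratelyWasted"]
  progressed <- p_ms * sum(moderate_at_start)
  ever_moderate <- trajectory$counts[1L, "ModeratelyWasted"] +
    sum(trajectory$inflows[, "ModeratelyWasted"])
  if (ever_moderate <= 0) return(0)
  100 * progressed / ever_moderate
}

#' Caseload comparison report for one tier
#'
#' Compares the annual caseload under the conventional correction factor
#' with the context-specific (model-calibrated) one.
#'
#' @param tier \code{"severe"} or \code{"moderate"}.
#' @param baseline_prevalence Point prevalence at the start of the year.
#' @param k_context Context-specific k.
#' @param k_original Conventional k (default 1.6, i.e. a 7.5-month
#'   episode).
#' @return Object of class \code{caseload_report}: list with the inputs,
#'   both caseloads and \code{percent_increase}.
#' @export
caseload_report <- function(tier = c("severe", "moderate"),
                            baseline_prevalence, k_context,
                            k_original = 1.6) {
  tier <- match.arg(tier)
  orig <- annual_caseload(baseline_prevalence, k_original)
  ctx <- annual_caseload(baseline_prevalence, k_context)
  structure(list(
    tier = tier,
    baseline_prevalence = baseline_prevalence,
    k_original = k_original,
    k_context = k_context,
    caseload_original = orig,
    caseload_context = ctx,
    percent_increase = percent_increase(orig, ctx)
  ), class = "caseload_report")
}

#' @export
print.caseload_report <- function(x, ...) {
  cat(sprintf(
    paste0("<caseload_report> tier %s (baseline prevalence %.0f)\n",
           "  k %.2f -> caseload %.0f (conventional)\n",
           "  k %.2f -> caseload %.0f (context-specific)\n",
           "  increase: %.1f%%\n"),
    x$tier, x$baseline_prevalence, x$k_original, x$caseload_original,
    x$k_context, x$caseload_context, x$percent_increase))
  invisible(x)
}
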