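#' SMART-style survey summary
#'
#' @param region Region label.
#' @param under5_population Positive under-five population count.
#' @param moderate_prevalence,severe_prevalence Point prevalences as
#'   proportions in [0, 1]; their sum must not exceed 1.
#' @param under5_mortality_monthly Monthly under-five mortality as a
#'   proportion (the model's Healthy -> Deceased rate source).
#' @param survey_month Calendar-month identifier, e.g. \code{"2018-08"}.
#' @return Object of class \code{survey_summary}.
#' @export
survey_summary <- function(region, under5_population, moderate_prevalence,
                           severe_prevalence, under5_mortality_monthly,
                           survey_month) {
  under5_population <- as.numeric(under5_population)
  if (!is.finite(under5_population) || under5_population <= 0) {
    stop("under5_population must be > 0", call. = FALSE)
  }
  for (nm in c("moderate_prevalence", "severe_prevalence",
               "under5_mortality_monthly")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) {
      stop(nm, " must be a proportion in [0, 1]; got ", v, call. = FALSE)
    }
  }
  if (moderate_prevalence + severe_prevalence > 1) {
    stop("moderate_prevalence + severe_prevalence exceeds 1", call. = FALSE)
  }
  structure(list(region = as.character(region),
                 under5_population = under5_population,
                 moderate_prevalence = moderate_prevalence,
                 severe_prevalence = severe_prevalence,
                 under5_mortality_monthly = under5_mortality_monthly,
                 survey_month = as.character(survey_month)),
            class = "survey_summary")
}

#' Combine regional surveys into a governorate summary
#'
#' Population-weighted mean of each prevalence and mortality field;
#' populations are summed. Invariant to the ordering of the surveys.
#'
#' @param surveys Non-empty list of \code{survey_summary} sharing the same
#'   \code{survey_month}.
#' @return A combined \code{survey_summary}.
#' @export
combine_surveys <- function(surveys) {
  if (inherits(surveys, "survey_summary")) surveys <- list(surveys)
  if (!length(surveys)) stop("need at least one survey", call. = FALSE)
  stopifnot(all(vapply(surveys, inherits, logical(1), "survey_summary")))
  months <- unique(vapply(surveys, `[[`, character(1), "survey_month"))
  if (length(months) != 1L) {
    stop("surveys have inconsistent survey_month: ",
         paste(months, collapse = ", "), call. = FALSE)
  }
  pop <- vapply(surveys, `[[`, numeric(1), "under5_population")
  w <- pop / sum(pop)
  wmean <- function(field) {
    sum(w * vapply(surveys, `[[`, numeric(1), field))
  }
  survey_summary(
    region = paste(sort(vapply(surveys, `[[`, character(1), "region")),
                   collapse = "+"),
    under5_population = sum(pop),
    moderate_prevalence = wmean("moderate_prevalence"),
    severe_prevalence = wmean("severe_prevalence"),
    under5_mortality_monthly = wmean("under5_mortality_monthly"),
    survey_month = months
  )
}

#' Split untreated severe cases into uncomplicated and complicated
#'
#' In the absence of a direct prevalence estimate for complicated severe
#' wasting, the ratio of complicated to uncomplicated untreated cases is
#' assumed equal to the ratio of inpatient (TFC) to outpatient (OTP)
#' treatment admissions.
#'
#' @param total_untreated_severe Total untreated severe count to split.
#' @param uncomplicated_admissions,complicated_admissions Cumulative OTP
#'   and TFC admission counts; not both zero.
#' @return Named numeric: \code{uncomplicated}, \code{complicated};
#'   the two parts sum to the input total.
#' @export
complication_split <- function(total_untreated_severe,
                               uncomplicated_admissions,
                               complicated_admissions) {
  if (total_untreated_severe < 0 || uncomplicated_admissions < 0 ||
      complicated_admissions < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  denom <- uncomplicated_admissions + complicated_admissions
  if (denom == 0) {
    stop("complication ratio undefined: both admission counts are zero",
         call. = FALSE)
  }
  unc <- total_untreated_severe * uncomplicated_admissions / denom
  c(uncomplicated = unc, complicated = total_untreated_severe - unc)
}

#' Construct the month-0 state census from survey and program data
#'
#' Children enrolled in treatment for at least one month no longer meet the
#' anthropometric case definition, so the surveyed prevalence covers the
#' untreated pool plus the past month's admissions; both are placed in the
#' untreated model state. The treatment states start with the enrolment
#' carried over from earlier months (enrolment minus the last month's
#' admissions). Untreated severe cases are split into uncomplicated and
#' complicated via \code{\link{complication_split}}. TreatmentSC and
#' Deceased start at 0 (inpatient stays are shorter than one month).
#'
#' @param combined Combined \code{survey_summary} for the region.
#' @param treatment_enrolled Named numeric, average monthly enrolment per
#'   program: elements \code{tsfp}, \code{otp}.
#' @param last_month_admissions Named numeric, admissions during the survey
#'   month per program: elements \code{tsfp}, \code{otp}.
#' @param otp_admissions_total,tfc_admissions_total Cumulative admission
#'   counts used for the complication split.
#' @return Object of class \code{initial_census_spec}: list with
#'   \code{census} (\code{state_census} at month 0) and
#'   \code{probabilities} (counts / population, summing to 1).
#' @export
build_initial_census <- function(combined, treatment_enrolled,
                                 last_month_admissions,
                                 otp_admissions_total, tfc_admissions_total) {
  stopifnot(inherits(combined, "survey_summary"))
  for (prog in c("tsfp", "otp")) {
    if (!prog %in% names(treatment_enrolled) ||
        !prog %in% names(last_month_admissions)) {
      stop("treatment_enrolled and last_month_admissions need elements ",
           "'tsfp' and 'otp'", call. = FALSE)
    }
    if (treatment_enrolled[[prog]] < last_month_admissions[[prog]]) {
      stop("program '", prog, "': last-month admissions (",
           last_month_admissions[[prog]], ") exceed enrolment (",
           treatment_enrolled[[prog]], ")", call. = FALSE)
    }
  }
  pop <- combined$under5_population
  m0 <- combined$moderate_prevalence * pop
  severe_total <- combined$severe_prevalence * pop
  split <- complication_split(severe_total, otp_admissions_total,
                              tfc_admissions_total)
  tm0 <- treatment_enrolled[["tsfp"]] - last_month_admissions[["tsfp"]]
  ts0 <- treatment_enrolled[["otp"]] - last_month_admissions[["otp"]]
  h0 <- pop - m0 - severe_total - tm0 - ts0
  if (h0 < 0) {
    stop("derived Healthy count is negative (", round(h0, 1),
         "): surveyed prevalence plus enrolment exceeds the population",
         call. = FALSE)
  }
  census <- new_state_census(c(
    Healthy = h0,
    ModeratelyWasted = m0,
    SeverelyWasted = split[["uncomplicated"]],
    SeverelyWastedComplicated = split[["complicated"]],
    TreatmentM = tm0,
    TreatmentS = ts0,
    TreatmentSC = 0,
    Deceased = 0
  ), month = 0L)
  initial_census_spec(census)
}

#' @rdname build_initial_census
#' @param census A \code{state_census} at month 0 (direct construction,
#'   e.g. from a packaged table of counts).
#' @export
initial_census_spec <- function(census) {
  stopifnot(inherits(census, "state_census"), census$month == 0L)
  total <- census_total(census)
  if (total <= 0) stop("initial census must have positive total", call. = FALSE)
  p <- census$counts / total
  stopifnot(abs(sum(p) - 1) <= 1e-6)
  structure(list(census = census, probabilities = p),
            class = "initial_census_spec")
}

#' @export
print.initial_census_spec <- function(x, ...) {
  cat("<initial_census_spec> total",
      format(census_total(x$census), big.mark = ","), "\n")
  print(data.frame(count = round(x$census$counts, 1),
                   probability = signif(x$probabilities, 4)))
  invisible(x)
}

#' Stationary treatment-outcome probabilities from monthly records
#'
#' Pools admissions and outcome counts over all months of one program and
#' divides each pooled outcome count by the pooled enrolment; the
#' remain-in-treatment probability is the complement, so the returned
#' probabilities sum to exactly 1.
#'
#' @param records Data frame of monthly records for a single program with
#'   columns \code{enrolled}, \code{cured}, \code{defaulted},
#'   \code{non_response}, \code{referred_tsfp}, \code{referred_otp},
#'   \code{referred_tfc}, \code{died}.
#' @return Named numeric vector of monthly probabilities: the outcomes
#'   above plus \code{remain}.
#' @export
outcome_probabilities <- function(records) {
  records <- as.data.frame(records)
  outcome_cols <- c("cured", "defaulted", "non_response", "referred_tsfp",
                    "referred_otp", "referred_tfc", "died")
  need <- c("enrolled", outcome_cols)
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(records$program %||% "one")) > 1L) {
    stop("records must belong to a single program", call. = FALSE)
  }
  enrol <- sum(records$enrolled)
  if (enrol <= 0) stop("total enrolment must be > 0", call. = FALSE)
  row_out <- rowSums(records[outcome_cols])
  if (any(row_out > records$enrolled)) {
    bad <- which(row_out > records$enrolled)[1L]
    stop("record row ", bad, ": outcome counts (", row_out[bad],
         ") exceed enrolment (", records$enrolled[bad], ")", call. = FALSE)
  }
  p <- colSums(records[outcome_cols]) / enrol
  c(p, remain = 1 - sum(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Monthly treatment-admission probability
#'
#' Admissions divided by the eligible pool — the expected count in the
#' untreated source state at the start of the month, the only state the
#' admission transition departs from. Values above 1 are clamped to 1 with
#' a warning.
#'
#' @param admissions Non-negative admission count(s).
#' @param eligible_pool Positive expected count(s) in the source state.
#' @return Proportion(s) in [0, 1]; vectorised.
#' @export
admission_probability <- function(admissions, eligible_pool) {
  if (any(!is.finite(eligible_pool)) || any(eligible_pool <= 0)) {
    stop("eligible_pool must be > 0", call. = FALSE)
  }
  if (any(admissions < 0)) stop("admissions must be >= 0", call. = FALSE)
  p <- admissions / eligible_pool
  if (any(p > 1)) {
    warning("admission probability exceeded 1 for ", sum(p > 1),
            " month(s); clamped to 1", call. = FALSE)
    p <- pmin(p, 1)
  }
  p
}
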