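## State space for the child-wasting Markov cohort model.
##
## The model distinguishes three untreated wasting tiers (moderate, severe,
## severe-with-medical-complications), their respective CMAM treatment
## programs (TSFP, OTP, TFC), a Healthy state and an absorbing Deceased
## state. The ordering below is canonical: every matrix, census and report
## in the package uses it.

.WASTING_STATES <- c(
  "Healthy",
  "ModeratelyWasted",
  "SeverelyWasted",
  "SeverelyWastedComplicated",
  "TreatmentM",
  "TreatmentS",
  "TreatmentSC",
  "Deceased"
)

## treatment program <-> state/source-state bookkeeping
.PROGRAMS <- c("tsfp", "otp", "tfc")
.PROGRAM_TREATMENT_STATE <- c(
  tsfp = "TreatmentM", otp = "TreatmentS", tfc = "TreatmentSC"
)
.PROGRAM_SOURCE_STATE <- c(
  tsfp = "ModeratelyWasted", otp = "SeverelyWasted",
  tfc = "SeverelyWastedComplicated"
)

## tier (survey case definition) <-> model state bookkeeping
.TIER_UNTREATED_STATE <- c(
  moderate = "ModeratelyWasted", severe = "SeverelyWasted"
)
.TIER_TREATMENT_STATE <- c(moderate = "TreatmentM", severe = "TreatmentS")
.TIER_SOURCE_STATE <- c(moderate = "Healthy", severe = "ModeratelyWasted")
.TIER_INCIDENCE_EDGE <- c(
  moderate = "Healthy->ModeratelyWasted",
  severe = "ModeratelyWasted->SeverelyWasted"
)

#' Canonical state ordering of the wasting model
#'
#' Returns the eight nutritional states in the fixed canonical order used by
#' every matrix, census and report in the package: Healthy, ModeratelyWasted,
#' SeverelyWasted, SeverelyWastedComplicated, TreatmentM (TSFP), TreatmentS
#' (OTP), TreatmentSC (TFC), Deceased.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' wasting_states()
wasting_states <- function() .WASTING_STATES

#' Structurally allowed monthly transitions
#'
#' Logical 8x8 matrix marking the transitions permitted by the model's
#' structural assumptions: a child must be moderately wasted before becoming
#' severely wasted, a severely wasted child cannot recover directly to
#' Healthy, treatment exits (cure, default, referral, death) follow the CMAM
#' program pathways, and Deceased is absorbing. Every transition outside
#' this set is an exact structural zero in any constructed matrix.
#'
#' @return Logical matrix with dimnames \code{wasting_states()}.
#' @export
allowed_transitions <- function() {
  s <- .WASTING_STATES
  A <- matrix(FALSE, 8L, 8L, dimnames = list(from = s, to = s))
  allow <- function(from, to) A[from, to] <<- TRUE
  allow("Healthy", c("Healthy", "ModeratelyWasted", "Deceased"))
  allow("ModeratelyWasted",
        c("Healthy", "ModeratelyWasted", "SeverelyWasted", "TreatmentM",
          "Deceased"))
  allow("SeverelyWasted",
        c("ModeratelyWasted", "SeverelyWasted", "SeverelyWastedComplicated",
          "TreatmentS", "Deceased"))
  allow("SeverelyWastedComplicated",
        c("SeverelyWastedComplicated", "TreatmentSC", "Deceased"))
  allow("TreatmentM",
        c("Healthy", "ModeratelyWasted", "TreatmentM", "TreatmentS",
          "Deceased"))
  allow("TreatmentS",
        c("Healthy", "SeverelyWasted", "TreatmentM", "TreatmentS",
          "TreatmentSC", "Deceased"))
  allow("TreatmentSC",
        c("Healthy", "TreatmentM", "TreatmentS", "TreatmentSC", "Deceased"))
  allow("Deceased", "Deceased")
  A
}

## internal: split "From->To" keys, with validation
.parse_edge <- function(key) {
  parts <- strsplit(key, "->", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !all(parts %in% .WASTING_STATES)) {
    stop("invalid transition key '", key,
         "'; expected '<FromState>-><ToState>' with states among: ",
         paste(.WASTING_STATES, collapse = ", "), call. = FALSE)
  }
  parts
}

## internal: normalise a nested list (from -> to -> value) or a flat named
## numeric vector of "From->To" rates to the flat named-numeric form.
as_rate_vector <- function(rates) {
  if (is.numeric(rates)) {
    if (length(rates) == 0L) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
      stop("stationary rates must be named 'From->To'", call. = FALSE)
    }
    return(rates)
  }
  if (!is.list(rates)) {
    stop("stationary rates must be a named numeric vector or a nested list",
         call. = FALSE)
  }
  out <- numeric(0)
  for (from in names(rates)) {
    row <- rates[[from]]
    if (!length(row)) next
    vals <- unlist(row)
    names(vals) <- paste0(from, "->", names(row))
    out <- c(out, vals)
  }
  out
}
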