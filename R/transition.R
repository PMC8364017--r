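#' Build one monthly transition matrix
#'
#' Assembles the 8x8 row-stochastic monthly transition matrix from a set of
#' stationary off-diagonal transition probabilities and the three (possibly
#' time-varying) treatment-admission probabilities. Self-transition entries
#' are always computed as the exact complement of the row's off-diagonal
#' sum, which guarantees row-stochasticity by construction; published
#' remain-in-state constants are never used here (see
#' \code{\link{printed_complement_diagnostic}}).
#'
#' @param stationary Stationary off-diagonal rates, either a named numeric
#'   vector with names \code{"From->To"} or a nested list
#'   (\code{from = list(to = value)}). Must not contain self-transitions or
#'   the admission edges (those come from \code{admissions}); every edge
#'   must be in \code{\link{allowed_transitions}()}.
#' @param admissions Named numeric vector with elements \code{tsfp}
#'   (ModeratelyWasted -> TreatmentM), \code{otp} (SeverelyWasted ->
#'   TreatmentS) and \code{tfc} (SeverelyWastedComplicated -> TreatmentSC).
#'   Missing elements default to 0.
#' @param month Integer month index the matrix applies to: the matrix maps
#'   the census at \code{month} to the census at \code{month + 1}.
#' @return An 8x8 matrix of class \code{transition_matrix} with a
#'   \code{month} attribute. Rows sum to 1 exactly; Deceased is absorbing.
#' @export
#' @examples
#' m <- build_transition_matrix(
#'   c("ModeratelyWasted->Healthy" = 0.07814,
#'     "ModeratelyWasted->Deceased" = 0.00260),
#'   admissions = c(tsfp = 0.0529))
#' rowSums(m)
build_transition_matrix <- function(stationary, admissions = c(tsfp = 0, otp = 0, tfc = 0),
                                    month = 0L) {
  rates <- as_rate_vector(stationary)
  adm <- stats::setNames(numeric(3L), .PROGRAMS)
  if (length(admissions)) {
    if (is.null(names(admissions)) || !all(names(admissions) %in% .PROGRAMS)) {
      stop("admissions must be named among: ",
           paste(.PROGRAMS, collapse = ", "), call. = FALSE)
    }
    adm[names(admissions)] <- as.numeric(admissions)
  }
  if (any(!is.finite(adm)) || any(adm < 0) || any(adm > 1)) {
    stop("admission probabilities must be in [0, 1]", call. = FALSE)
  }

  allowed <- allowed_transitions()
  admission_edges <- paste0(.PROGRAM_SOURCE_STATE, "->", .PROGRAM_TREATMENT_STATE)
  P <- matrix(0, 8L, 8L,
              dimnames = list(from = .WASTING_STATES, to = .WASTING_STATES))
  for (key in names(rates)) {
    edge <- .parse_edge(key)
    v <- rates[[key]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("transition probability '", key, "' must be in [0, 1]; got ", v,
           call. = FALSE)
    }
    if (edge[1L] == edge[2L]) {
      stop("self-transition '", key, "' may not be supplied; ",
           "self-transitions are computed as row complements", call. = FALSE)
    }
    if (key %in% admission_edges) {
      stop("admission edge '", key,
           "' must be supplied via the 'admissions' argument", call. = FALSE)
    }
    if (!allowed[edge[1L], edge[2L]]) {
      stop("transition '", key, "' is structurally forbidden by the model",
           call. = FALSE)
    }
    P[edge[1L], edge[2L]] <- v
  }
  P["ModeratelyWasted", "TreatmentM"] <- adm[["tsfp"]]
  P["SeverelyWasted", "TreatmentS"] <- adm[["otp"]]
  P["SeverelyWastedComplicated", "TreatmentSC"] <- adm[["tfc"]]

  off <- rowSums(P)
  if (any(off > 1 + 1e-12)) {
    bad <- .WASTING_STATES[off > 1 + 1e-12]
    stop("off-diagonal transition probabilities for state(s) ",
         paste(bad, collapse = ", "), " sum to ",
         paste(format(off[off > 1 + 1e-12], digits = 6), collapse = ", "),
         ", exceeding 1", call. = FALSE)
  }
  diag(P) <- pmax(0, 1 - off)
  structure(P, month = as.integer(month),
            class = c("transition_matrix", "matrix", "array"))
}

#' Row-stochasticity check
#'
#' @param tmat A \code{transition_matrix}.
#' @param tol Tolerance on |row sum - 1| (default 1e-9).
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_transition_matrix <- function(tmat, tol = 1e-9) {
  stopifnot(is.matrix(tmat), all(dim(tmat) == 8L))
  if (any(tmat < 0) || any(tmat > 1)) {
    stop("transition matrix entries must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(tmat)
  if (any(abs(rs - 1) > tol)) {
    bad <- .WASTING_STATES[abs(rs - 1) > tol]
    stop("rows not stochastic within ", tol, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (tmat["Deceased", "Deceased"] != 1) {
    stop("Deceased row must be the identity row (absorbing state)",
         call. = FALSE)
  }
  forbidden <- !allowed_transitions()
  if (any(unclass(tmat)[forbidden] != 0)) {
    stop("structurally forbidden transitions must be exactly 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Build the monthly matrix sequence for a simulation
#'
#' One matrix per simulated month, combining the stationary rates with that
#' month's row of the admission-probability series.
#'
#' @param stationary Stationary rates as in
#'   \code{\link{build_transition_matrix}}.
#' @param admission_series Matrix or data frame with one row per simulated
#'   month (month 0 first) and columns \code{tsfp}, \code{otp}, \code{tfc}.
#' @return List of \code{transition_matrix}, months \code{0 .. nrow - 1}.
#' @export
build_matrix_sequence <- function(stationary, admission_series) {
  admission_series <- as.matrix(admission_series)
  if (!all(.PROGRAMS %in% colnames(admission_series))) {
    stop("admission_series must have columns: ",
         paste(.PROGRAMS, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(admission_series)), function(i) {
    build_transition_matrix(
      stationary,
      admissions = admission_series[i, .PROGRAMS],
      month = i - 1L
    )
  })
}
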