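#' Expected state census at one month
#'
#' A state census holds the expected (real-valued, not sampled) number of
#' children residing in each of the eight model states at a given month of
#' the simulation. Month 0 is the month of the initialising survey
#' (August 2018 for the packaged Lahj configuration).
#'
#' @param counts Named non-negative numeric vector. Names must be a subset
#'   of \code{wasting_states()}; omitted states default to 0.
#' @param month Integer month index, >= 0.
#' @return Object of class \code{state_census}: a list with elements
#'   \code{counts} (full named vector in canonical order) and \code{month}.
#' @export
#' @examples
#' new_state_census(c(Healthy = 1000, ModeratelyWasted = 50))
new_state_census <- function(counts, month = 0L) {
  if (is.null(names(counts)) || !all(names(counts) %in% .WASTING_STATES)) {
    bad <- setdiff(names(counts), .WASTING_STATES)
    stop("census counts must be named by model states; unknown: ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(numeric(8L), .WASTING_STATES)
  full[names(counts)] <- as.numeric(counts)
  if (any(!is.finite(full))) stop("census counts must be finite", call. = FALSE)
  if (any(full < 0)) {
    stop("census counts must be non-negative; negative count for state(s): ",
         paste(names(full)[full < 0], collapse = ", "), call. = FALSE)
  }
  month <- as.integer(month)
  if (length(month) != 1L || is.na(month) || month < 0L) {
    stop("month must be a single integer >= 0", call. = FALSE)
  }
  structure(list(counts = full, month = month), class = "state_census")
}

#' @export
print.state_census <- function(x, ...) {
  cat("<state_census> month", x$month,
      "| total", format(sum(x$counts), big.mark = ","), "\n")
  print(round(x$counts, 2))
  invisible(x)
}

#' Total expected population of a census
#'
#' @param census A \code{state_census}.
#' @return Numeric total over all states (Deceased included).
#' @export
census_total <- function(census) {
  stopifnot(inherits(census, "state_census"))
  sum(census$counts)
}
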