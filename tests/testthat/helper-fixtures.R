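## Shared toy builders used across test files. All fixtures are built in
## code; nothing is read from disk except the packaged configuration.

states <- wasting_states()

## a feasible stationary rate set with both incidence edges fixed, handy
## for forward-model and sensitivity tests
toy_stationary <- function(p_hm = 0.032, p_ms = 0.06) {
  fx <- lahj_fixture()
  st <- fx$stationary
  if (!is.null(p_hm)) st[["Healthy->ModeratelyWasted"]] <- p_hm
  if (!is.null(p_ms)) st[["ModeratelyWasted->SeverelyWasted"]] <- p_ms
  st
}

## constant admission series inside the observed Lahj ranges
constant_admissions <- function(n_months, tsfp = 0.10, otp = 0.30,
                                tfc = 0.10) {
  matrix(rep(c(tsfp, otp, tfc), each = n_months), ncol = 3,
         dimnames = list(NULL, c("tsfp", "otp", "tfc")))
}

## random feasible inputs (census + rates + admission series) for
## property-style tests; caller controls the RNG seed
random_inputs <- function(n_months = 14L) {
  fx <- lahj_fixture()
  st <- fx$stationary * runif(length(fx$stationary), 0.7, 1.3)
  st[["Healthy->ModeratelyWasted"]] <- runif(1, 0.01, 0.06)
  st[["ModeratelyWasted->SeverelyWasted"]] <- runif(1, 0.02, 0.1)
  ## keep each row feasible, leaving room for the admission probability
  ## of that row (at the top of its observed range) and for a calibration
  ## candidate of up to 0.3 in the incidence rows
  row_cap <- c(Healthy = 0.5, ModeratelyWasted = 0.45, SeverelyWasted = 0.3,
               SeverelyWastedComplicated = 0.7, TreatmentM = 0.95,
               TreatmentS = 0.95, TreatmentSC = 0.95, Deceased = 0)
  from <- sub("->.*$", "", names(st))
  for (s in unique(from)) {
    idx <- from == s
    tot <- sum(st[idx])
    if (tot > row_cap[[s]]) st[idx] <- st[idx] * row_cap[[s]] / tot
  }
  series <- vapply(fx$admission_ranges,
                   function(r) runif(n_months, r[1], r[2]),
                   numeric(n_months))
  series <- matrix(series, nrow = n_months,
                   dimnames = list(NULL, names(fx$admission_ranges)))
  counts <- fx$initial$census$counts * runif(8, 0.5, 1.5)
  list(initial = new_state_census(counts, 0L),
       stationary = st,
       admission_series = series)
}

## independent matrix-power oracle: P^h applied to the initial counts
matrix_power_counts <- function(initial_counts, P, horizon) {
  Ph <- diag(8)
  for (i in seq_len(horizon)) Ph <- Ph %*% unclass(P)
  drop(initial_counts %*% Ph)
}
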