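test_that("forward prevalence matches an independent matrix-power oracle", {
  set.seed(31)
  inp <- random_inputs(6L)
  inp$admission_series <- constant_admissions(6L)
  cand <- 0.08
  got <- forward_prevalence(cand, "severe", inp, 6L)
  ## oracle: insert the candidate, take the matrix power, add the final
  ## month's admission inflow by hand
  st <- inp$stationary
  st[["ModeratelyWasted->SeverelyWasted"]] <- cand
  P <- build_transition_matrix(st, inp$admission_series[1L, ])
  at5 <- matrix_power_counts(inp$initial$counts, P, 5L)
  at6 <- drop(at5 %*% unclass(P))
  names(at6) <- names(at5) <- wasting_states()
  inflow_ts <- at6[["TreatmentS"]] -
    at5[["TreatmentS"]] * P["TreatmentS", "TreatmentS"]
  expect_equal(got, at6[["SeverelyWasted"]] + inflow_ts, tolerance = 1e-12)
})

test_that("forward prevalence is strictly increasing in the candidate", {
  set.seed(13)
  for (i in 1:5) {
    inp <- random_inputs(10L)
    for (tier in c("severe", "moderate")) {
      grid <- seq(0, 0.25, length.out = 6)
      prev <- vapply(grid, forward_prevalence, numeric(1), tier = tier,
                     inputs = inp, target_month = 10L)
      expect_true(all(diff(prev) > 0))
    }
  }
})

test_that("calibration recovers a candidate from its own forward run", {
  set.seed(17)
  inp <- random_inputs(12L)
  target_val <- forward_prevalence(0.05, "severe", inp, 12L)
  res <- calibrate_incidence(calibration_target("severe", target_val, 12L),
                             inp, solver_tol = 1e-8)
  expect_equal(res$probability, 0.05, tolerance = 1e-6)
  expect_lte(abs(res$achieved_prevalence - target_val), 1e-8)
  expect_gt(res$iterations, 0)
  ## invariants of the result object
  expect_equal(res$k, res$annual_incident_cases / res$baseline_prevalence,
               tolerance = 1e-9)
  expect_equal(res$mean_episode_duration_months, 12 / res$k,
               tolerance = 1e-12)
})

test_that("an unattainable target reports the bracket endpoints", {
  set.seed(19)
  inp <- random_inputs(8L)
  f0 <- forward_prevalence(0, "severe", inp, 8L)
  expect_error(
    calibrate_incidence(calibration_target("severe", max(f0 - 10, 0), 8L),
                        inp),
    "outside the attainable bracket"
  )
})

test_that("k and duration arithmetic matches the standard relationship", {
  expect_equal(duration_from_k(1.6), 7.5)
  expect_equal(duration_from_k(12), 1)
  expect_equal(round(duration_from_k(3.11), 2), 3.86)
  expect_equal(round(duration_from_k(2.59), 2), 4.63)
  ## consistent with the severe caseload arithmetic: 17,256 - 4,199 annual
  ## incident cases over a baseline prevalence of 4,199
  expect_equal(round(k_from_incidence(13059, 4199), 2), 3.11)
  expect_equal(k_from_incidence(0, 10), 0)
  expect_equal(k_from_incidence(7, 7), 1)
  ## round trip: P * k incident cases over baseline P gives back 12 / k
  for (P in c(10, 4199)) {
    for (k in c(0.5, 1.6, 3.11)) {
      expect_equal(duration_from_k(k_from_incidence(P * k, P)), 12 / k)
    }
  }
  expect_error(k_from_incidence(10, 0), "baseline_prevalence")
  expect_error(duration_from_k(0), "k must be > 0")
  expect_error(duration_from_k(-2), "k must be > 0")
})

test_that("moderate calibration cannot run without a severe incidence", {
  inp <- random_inputs(6L)
  inp$stationary <- inp$stationary[
    names(inp$stationary) != "ModeratelyWasted->SeverelyWasted"]
  expect_error(forward_prevalence(0.02, "moderate", inp, 6L),
               "severe incidence")
  expect_error(
    calibrate_incidence(calibration_target("moderate", 100, 6L), inp),
    "severe incidence"
  )
})

test_that("sequential calibration rejects a pre-set severe incidence", {
  lc <- lahj_calibration_inputs(seed = 2)
  lc$inputs$stationary[["ModeratelyWasted->SeverelyWasted"]] <- 0.05
  expect_error(
    sequential_calibration(lc$inputs, lc$targets$severe,
                           lc$targets$moderate),
    "must not be present"
  )
  expect_error(
    sequential_calibration(lahj_calibration_inputs(seed = 2)$inputs,
                           lc$targets$moderate, lc$targets$severe),
    "in order"
  )
})

test_that("sequential calibration recovers known incidences end to end", {
  bundle <- generate_scenario(scenario_config(seed = 3))
  cal <- calibrate_scenario(bundle)
  expect_lt(abs(cal$severe$probability - bundle$truth$p_ms) /
              bundle$truth$p_ms, 0.05)
  expect_lt(abs(cal$moderate$probability - bundle$truth$p_hm) /
              bundle$truth$p_hm, 0.05)
  expect_lte(abs(cal$severe$achieved_prevalence -
                   cal$severe$target_prevalence), 1e-3)
  expect_lte(abs(cal$moderate$achieved_prevalence -
                   cal$moderate$target_prevalence), 1e-3)
})

test_that("a zero-severe scenario still calibrates the moderate tier", {
  ## targets generated with no progression at all: the severe target is
  ## whatever the model yields at progression 0
  lc <- lahj_calibration_inputs(seed = 4)
  inp <- lc$inputs
  inp$stationary[["Healthy->ModeratelyWasted"]] <- 0.03
  f0_sev <- forward_prevalence(0, "severe", inp, 14L)
  inp$stationary[["ModeratelyWasted->SeverelyWasted"]] <- 0
  f_mod <- forward_prevalence(0.03, "moderate", inp, 14L)
  base <- lc$inputs
  base$stationary <- base$stationary[
    !names(base$stationary) %in%
      c("Healthy->ModeratelyWasted", "ModeratelyWasted->SeverelyWasted")]
  res <- sequential_calibration(base,
                                calibration_target("severe", f0_sev, 14L),
                                calibration_target("moderate", f_mod, 14L))
  expect_equal(res$severe$probability, 0, tolerance = 1e-6)
  expect_equal(res$moderate$probability, 0.03, tolerance = 1e-4)
})
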