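test_that("identical seeds give identical bundles, different seeds differ", {
  a <- generate_scenario(scenario_config(seed = 12))
  b <- generate_scenario(scenario_config(seed = 12))
  expect_identical(a, b)
  c <- generate_scenario(scenario_config(seed = 13))
  expect_false(identical(a$truth$admission_series,
                         c$truth$admission_series))
  expect_false(identical(a$records, c$records))
})

test_that("generated admission probabilities stay inside the ranges", {
  fx <- lahj_fixture()
  for (seed in 1:5) {
    b <- generate_scenario(scenario_config(seed = seed))
    for (p in c("tsfp", "otp", "tfc")) {
      r <- fx$admission_ranges[[p]]
      expect_true(all(b$truth$admission_series[, p] >= r[1] - 1e-12))
      expect_true(all(b$truth$admission_series[, p] <= r[2] + 1e-12))
      ## records-derived probabilities only differ by integer rounding
      expect_true(all(abs(b$derived_admission_series[, p] -
                            b$truth$admission_series[, p]) < 0.01))
    }
  }
})

test_that("generated records are integer-valued and internally consistent", {
  b <- generate_scenario(scenario_config(seed = 21))
  rec <- validate_program_records(b$records)
  count_cols <- c("admissions", "enrolled", "cured", "defaulted",
                  "non_response", "referred_tsfp", "referred_otp",
                  "referred_tfc", "died")
  for (col in count_cols) {
    expect_true(all(rec[[col]] == round(rec[[col]])))
  }
  outcome_cols <- c("cured", "defaulted", "non_response", "referred_tsfp",
                    "referred_otp", "referred_tfc", "died")
  expect_true(all(rowSums(rec[outcome_cols]) <= rec$enrolled))
  expect_equal(nrow(rec), 3 * b$config$n_months)
})

test_that("the end survey matches the truth trajectory when noise-free", {
  b <- generate_scenario(scenario_config(seed = 8))
  n <- b$config$n_months
  expect_equal(b$surveys$end$severe_prevalence * b$config$population,
               observed_prevalence(b$truth$trajectory, n, "severe"))
  expect_equal(b$surveys$end$moderate_prevalence * b$config$population,
               observed_prevalence(b$truth$trajectory, n, "moderate"))
  ## with noise the prevalences move but stay non-negative
  noisy <- generate_scenario(scenario_config(seed = 8,
                                             survey_noise_sd = 0.005))
  expect_false(noisy$surveys$end$severe_prevalence ==
                 b$surveys$end$severe_prevalence)
  expect_gte(noisy$surveys$end$severe_prevalence, 0)
})

test_that("the packaged Lahj configuration matches its source values", {
  fx <- lahj_fixture()
  expect_equal(fx$population, 167907)
  expect_equal(sum(fx$initial$probabilities), 1, tolerance = 1e-6)
  printed <- c(Healthy = 0.7717, ModeratelyWasted = 0.1145,
               SeverelyWasted = 0.0250, SeverelyWastedComplicated = 0.001174,
               TreatmentM = 0.05948, TreatmentS = 0.02810,
               TreatmentSC = 0, Deceased = 0)
  expect_true(all(abs(fx$initial$probabilities[names(printed)] - printed)
                  <= 5e-5))
  expect_equal(fx$stationary[["SeverelyWasted->ModeratelyWasted"]], 0.0914)
  expect_equal(fx$stationary[["ModeratelyWasted->Healthy"]], 0.07814)
  expect_equal(fx$stationary[["Healthy->Deceased"]], 0.00075)
  expect_equal(fx$stationary[["TreatmentS->Healthy"]], 0.307)
  expect_equal(fx$admission_ranges$otp, c(0.200, 0.678))
  expect_equal(fx$admission_ranges$tsfp, c(0.0529, 0.176))
  expect_equal(fx$admission_ranges$tfc, c(0.0, 0.229))
  ## incidence edges are the calibrated unknowns, not packaged values
  expect_false("ModeratelyWasted->SeverelyWasted" %in%
                 names(fx$stationary))
  expect_false("Healthy->ModeratelyWasted" %in% names(fx$stationary))
})

test_that("scenario configs are validated", {
  expect_error(scenario_config(seed = 1, true_p_ms = 1.5))
  expect_error(scenario_config(seed = 1,
                               admission_ranges = list(tsfp = c(0.3, 0.1),
                                                       otp = c(0, 1),
                                                       tfc = c(0, 1))),
               "low, high")
  expect_error(generate_scenario(list()), "scenario_config")
})
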