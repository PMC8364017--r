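make_survey <- function(pop, mod, sev, region = "r", month = "2018-08") {
  survey_summary(region, pop, mod, sev, 0.00075, month)
}

test_that("combine_surveys takes population-weighted means", {
  a <- make_survey(60000, 0.10, 0.02, region = "lowlands")
  b <- make_survey(40000, 0.15, 0.03, region = "highlands")
  comb <- combine_surveys(list(a, b))
  expect_equal(comb$moderate_prevalence, 0.12)
  expect_equal(comb$severe_prevalence, 0.024)
  expect_equal(comb$under5_population, 100000)
  ## invariant to ordering
  comb2 <- combine_surveys(list(b, a))
  expect_equal(comb2$moderate_prevalence, comb$moderate_prevalence)
  expect_equal(comb2$region, comb$region)
  ## identical prevalences pass through; single survey unchanged
  same <- combine_surveys(list(make_survey(10, 0.1, 0.02),
                               make_survey(99, 0.1, 0.02)))
  expect_equal(same$moderate_prevalence, 0.1)
  single <- combine_surveys(list(a))
  expect_equal(single$moderate_prevalence, a$moderate_prevalence)
  expect_error(combine_surveys(list()), "at least one")
  expect_error(
    combine_surveys(list(a, make_survey(1, 0.1, 0.01, month = "2019-10"))),
    "inconsistent survey_month"
  )
})

test_that("the initial census reproduces the packaged Lahj distribution", {
  ## reconstruct the packaged census from survey-style inputs
  pop <- 167907
  comb <- make_survey(pop, 19224 / pop, (4199 + 197) / pop)
  spec <- build_initial_census(
    comb,
    treatment_enrolled = c(tsfp = 9987 + 1200, otp = 4719 + 800),
    last_month_admissions = c(tsfp = 1200, otp = 800),
    otp_admissions_total = 4199, tfc_admissions_total = 197
  )
  counts <- spec$census$counts
  expect_equal(counts[["ModeratelyWasted"]], 19224)
  expect_equal(counts[["SeverelyWasted"]], 4199)
  expect_equal(counts[["SeverelyWastedComplicated"]], 197)
  expect_equal(counts[["TreatmentM"]], 9987)
  expect_equal(counts[["TreatmentS"]], 4719)
  expect_equal(counts[["Healthy"]], 129581)
  expect_equal(counts[["TreatmentSC"]], 0)
  expect_equal(counts[["Deceased"]], 0)
  expect_equal(sum(spec$probabilities), 1, tolerance = 1e-6)
  expect_true(all(abs(unname(spec$probabilities[c("Healthy",
                                                  "ModeratelyWasted",
                                                  "SeverelyWasted")]) -
                        c(0.7717, 0.1145, 0.0250)) <= 5e-5))
})

test_that("degenerate and invalid census inputs are handled", {
  pop <- 1000
  all_healthy <- build_initial_census(
    make_survey(pop, 0, 0),
    treatment_enrolled = c(tsfp = 0, otp = 0),
    last_month_admissions = c(tsfp = 0, otp = 0),
    otp_admissions_total = 1, tfc_admissions_total = 0
  )
  expect_equal(all_healthy$probabilities[["Healthy"]], 1)
  expect_error(
    build_initial_census(make_survey(pop, 0.5, 0.4),
                         treatment_enrolled = c(tsfp = 200, otp = 100),
                         last_month_admissions = c(tsfp = 0, otp = 0),
                         otp_admissions_total = 1, tfc_admissions_total = 0),
    "negative"
  )
  expect_error(
    build_initial_census(make_survey(pop, 0.1, 0.1),
                         treatment_enrolled = c(tsfp = 5, otp = 5),
                         last_month_admissions = c(tsfp = 10, otp = 0),
                         otp_admissions_total = 1, tfc_admissions_total = 0),
    "exceed enrolment"
  )
})

test_that("complication split is proportional to the admissions ratio", {
  expect_equal(complication_split(1000, 955, 45),
               c(uncomplicated = 955, complicated = 45))
  expect_equal(complication_split(500, 10, 0),
               c(uncomplicated = 500, complicated = 0))
  expect_equal(complication_split(0, 3, 4),
               c(uncomplicated = 0, complicated = 0))
  split <- complication_split(123.4, 7, 3)
  expect_equal(sum(split), 123.4)
  expect_error(complication_split(10, 0, 0), "both admission counts")
})

test_that("outcome probabilities pool months and sum to one with remain", {
  rec <- data.frame(program = "otp", month = 0, admissions = 100,
                    enrolled = 1000, cured = 307, defaulted = 26,
                    non_response = 0, referred_tsfp = 5, referred_otp = 0,
                    referred_tfc = 4, died = 0)
  p <- outcome_probabilities(rec)
  expect_equal(p[["cured"]], 0.307)
  expect_equal(p[["defaulted"]], 0.026)
  expect_equal(p[["referred_tsfp"]], 0.005)
  expect_equal(p[["referred_tfc"]], 0.004)
  expect_equal(p[["died"]], 0)
  expect_equal(p[["remain"]], 0.658)
  expect_equal(sum(p), 1)
  ## pooling across months: two months identical to one doubled month
  two <- rbind(rec, rec)
  expect_equal(outcome_probabilities(two), p)
  ## everyone cured
  all_cured <- within(rec, {cured <- 1000; defaulted <- 0
                            referred_tsfp <- 0; referred_tfc <- 0})
  p2 <- outcome_probabilities(all_cured)
  expect_equal(p2[["cured"]], 1)
  expect_equal(p2[["remain"]], 0)
  bad <- within(rec, cured <- 2000)
  expect_error(outcome_probabilities(bad), "exceed enrolment")
  expect_error(outcome_probabilities(within(rec, enrolled <- 0)),
               "enrolment must be > 0")
})

test_that("admission probability divides by the eligible pool and clamps", {
  expect_equal(admission_probability(200, 1000), 0.2)
  expect_equal(admission_probability(0, 500), 0)
  expect_equal(admission_probability(c(10, 20), c(100, 100)), c(0.1, 0.2))
  expect_warning(p <- admission_probability(150, 100), "clamped")
  expect_equal(p, 1)
  expect_error(admission_probability(10, 0), "eligible_pool")
  expect_error(admission_probability(-1, 10), "admissions")
})
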