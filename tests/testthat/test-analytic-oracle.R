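test_that("enumeration matches independent closed forms for no titration", {
  e <- expected_patient_consumption(cohort_distributions(), titration_policy())
  # E[v0] * E[D] * 1440 with the literal default values
  ev0 <- (0.5 + 1.0 + 2.0) / 3
  ed <- sum(1:5 * c(0.32, 0.27, 0.18, 0.12, 0.11))
  expect_equal(e$expected_volume, ev0 * ed * 1440)
  expect_equal(e$expected_volume, 4082.4)
  # Var = 1440^2 (E[v0^2]E[D^2] - (E[v0]E[D])^2) by independence
  ev0_2 <- (0.25 + 1 + 4) / 3
  ed_2 <- sum((1:5)^2 * c(0.32, 0.27, 0.18, 0.12, 0.11))
  expect_equal(e$variance, 1440^2 * (ev0_2 * ed_2 - (ev0 * ed)^2))
  expect_equal(e$expected_savings, 0)
})

test_that("enumeration matches the independent grid oracle for every policy", {
  d <- cohort_distributions()
  cases <- list(
    list(pol = titration_policy(1440),
         fn = function(p, v, D) ref_zoh(p, v, D, d$k, 1440)),
    list(pol = titration_policy(3),
         fn = function(p, v, D) ref_zoh(p, v, D, d$k, 3)),
    list(pol = titration_policy(0),
         fn = function(p, v, D) ref_continuous(p, v, D, d$k))
  )
  ref_init <- ref_expectation(function(p, v, D) v * D * 1440)["mean"]
  for (cs in cases) {
    e <- expected_patient_consumption(d, cs$pol)
    want <- ref_expectation(cs$fn)
    expect_equal(e$expected_volume, unname(want["mean"]), tolerance = 1e-9)
    expect_equal(e$variance,
                 unname(want["second"] - want["mean"]^2), tolerance = 1e-6)
    expect_equal(e$expected_savings,
                 unname(1 - want["mean"] / ref_init), tolerance = 1e-9)
  }
})

test_that("expected savings reproduce the daily and continuous fractions", {
  d <- cohort_distributions()
  s24 <- expected_patient_consumption(d, titration_policy(1440))$expected_savings
  scont <- expected_patient_consumption(d, titration_policy(0))$expected_savings
  s3 <- expected_patient_consumption(d, titration_policy(3))$expected_savings
  expect_equal(s24, 0.0796, tolerance = 1e-3)
  expect_equal(scont, 0.1146, tolerance = 1e-3)
  # the 3-minute hold sits just below the continuous limit
  expect_lt(scont - s3, 1e-4)
  expect_gt(scont - s3, 0)
  # savings shrink as the titration interval grows
  sv <- vapply(c(3, 60, 360, 1440), function(dt) {
    expected_patient_consumption(d, titration_policy(dt))$expected_savings
  }, numeric(1))
  expect_true(all(diff(sv) < 0))
  expect_equal(
    expected_patient_consumption(d, titration_policy())$expected_savings, 0)
})

test_that("Monte Carlo means agree with the oracle within 4 CLT SDs", {
  d <- cohort_distributions()
  n <- 1e5
  coh <- sample_cohort(n, d, seed = 123)
  for (pol in list(titration_policy(), titration_policy(1440),
                   titration_policy(3))) {
    e <- expected_patient_consumption(d, pol)
    mc <- mean(consumed_volume(coh, pol, d$k))
    expect_lt(abs(mc - e$expected_volume), 4 * sqrt(e$variance / n))
  }
})

test_that("predicted replicate SEM follows sqrt(n Var / r)", {
  sem <- predicted_replicate_sem(n = 100, r = 3)
  expect_equal(sem / 1000, 19.4, tolerance = 0.01)
  e <- expected_patient_consumption(cohort_distributions(), titration_policy())
  expect_equal(sem, sqrt(100 * e$variance / 3))
  # SEM/mean vanishes as cohorts grow
  big <- predicted_replicate_sem(n = 1e8, r = 3) / (1e8 * e$expected_volume)
  expect_lt(big, 1e-3)
  # without weaning every policy has the same SEM
  d0 <- cohort_distributions(k = 0)
  expect_equal(predicted_replicate_sem(d0, titration_policy(3), 100, 3),
               predicted_replicate_sem(d0, titration_policy(), 100, 3))
})

test_that("only the decreasing-weaning profile reading matches the study bands", {
  # enumerated savings under the adopted profiles sit inside the reported
  # 8.1% +/- 5.1% and 11.7% +/- 5.1% bands ...
  d <- cohort_distributions()
  s24 <- expected_patient_consumption(d, titration_policy(1440))$expected_savings
  s3 <- expected_patient_consumption(d, titration_policy(3))$expected_savings
  expect_lt(abs(s24 - 0.081), 0.051)
  expect_lt(abs(s3 - 0.117), 0.051)
  # ... whereas profiles that *increase* at rate k would make titration cost
  # oxygen rather than save it (negative savings), contradicting the report
  rising_zoh <- function(p, v, D, dt) {
    ref_zoh(p, v, D, -d$k, dt)  # flipping the sign of k raises the flow
  }
  e_init <- ref_expectation(function(p, v, D) v * D * 1440)["mean"]
  e_rise <- ref_expectation(function(p, v, D) rising_zoh(p, v, D, 1440))["mean"]
  expect_gt(e_rise, e_init)
})
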