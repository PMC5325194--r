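test_that("a paired cohort evaluates every scenario on the same patients", {
  res <- run_cohort(200, seed = 11)
  expect_s3_class(res, "titration_cohort")
  expect_named(res$totals, c("I", "II", "III"))
  # totals are the sums of the per-patient records
  for (lab in names(res$totals)) {
    rec <- res$records[res$records$scenario == lab, ]
    expect_equal(rec$patient_id, res$patients$id)
    expect_equal(sum(rec$volume_liters), unname(res$totals[lab]),
                 tolerance = 1e-6)
    expect_equal(unname(res$cumulative[[lab]][res$n]),
                 unname(res$totals[lab]))
  }
  # monotone in titration interval: 3 min <= 24 h <= initial-only
  expect_lte(res$totals[["III"]], res$totals[["II"]])
  expect_lte(res$totals[["II"]], res$totals[["I"]])
  # bit-identical reruns under the same seed
  expect_identical(res, run_cohort(200, seed = 11))
  expect_error(run_cohort(10, scenarios = list()), "non-empty")
})

test_that("a degenerate cohort reproduces single-patient arithmetic", {
  d <- cohort_distributions(v0_support = 1, v0_probs = 1,
                            duration_support = 2, duration_probs = 1)
  res <- run_cohort(1, scenarios = list(titration_policy()), dists = d,
                    seed = 1)
  expect_equal(unname(res$totals), 2880)
})

test_that("savings fractions match the reported cohort arithmetic", {
  expect_equal(savings_fraction(374000, 344000), 1 - 344 / 374)
  expect_equal(round(savings_fraction(374000, 344000), 4), 0.0802)
  expect_equal(round(savings_fraction(374000, 330000), 4), 0.1176)
  expect_equal(savings_fraction(1000, 1000), 0)
  expect_error(savings_fraction(1000, 1001), "exceeds")
  expect_error(savings_fraction(0, 0), "positive")
})

test_that("volume-to-hours conversion is exact arithmetic", {
  expect_equal(liters_to_hours_at_flow(30000, 1), 500)
  expect_equal(liters_to_hours_at_flow(44000, 1), 44000 / 60)
  expect_equal(round(liters_to_hours_at_flow(44000, 1), 1), 733.3)
  expect_equal(liters_to_hours_at_flow(0, 1), 0)
  expect_equal(liters_to_hours_at_flow(600, 2), 5)
  expect_error(liters_to_hours_at_flow(100, 0), "positive")
})

test_that("replicate summaries use per-replicate savings and n-1 SEM", {
  study <- run_replicates(n = 100, r = 3, base_seed = 5)
  expect_s3_class(study, "titration_study")
  expect_equal(study$seeds, 5:7)
  expect_equal(dim(study$totals), c(3L, 3L))
  # each replicate row is an independent run_cohort under its own seed
  expect_equal(unname(study$totals[2, ]),
               unname(run_cohort(100, seed = 6)$totals))
  # summaries recompute from the stored matrices
  expect_equal(unname(study$mean_totals), unname(colMeans(study$totals)))
  expect_equal(unname(study$sem_totals),
               unname(apply(study$totals, 2, stats::sd) / sqrt(3)))
  expect_equal(unname(study$savings[, "II"]),
               unname(1 - study$totals[, "II"] / study$totals[, "I"]))
  # per-replicate savings land in the sanity band for the defaults
  expect_true(all(study$savings[, c("II", "III")] > 0 &
                    study$savings[, c("II", "III")] < 0.3))
  expect_error(run_replicates(n = 10, r = 1), ">= 2")

  df <- as.data.frame(study)
  expect_equal(df$scenario, c("I", "II", "III"))
  expect_equal(df$saved_liters_vs_reference,
               unname(study$mean_totals["I"] - study$mean_totals))
  expect_equal(df$equivalent_hours_at_1lpm,
               df$saved_liters_vs_reference / 60)
})

test_that("disabling weaning nullifies savings in every scenario", {
  d0 <- cohort_distributions(k = 0)
  study <- run_replicates(n = 50, dists = d0, r = 3, base_seed = 2)
  expect_equal(unname(study$mean_savings), c(0, 0, 0))
  expect_equal(unname(study$sem_savings), c(0, 0, 0))
  expect_equal(study$totals[, "I"], study$totals[, "III"])
})

test_that("large-cohort means and scaling follow the law of large numbers", {
  res <- run_cohort(1e5, scenarios = list(titration_policy()), seed = 3)
  expect_lt(abs(res$totals[[1]] / 1e5 - 4082.4), 30)

  # expected totals scale linearly in n: compare many replicate pairs
  m100 <- mean(vapply(1:40, function(s) {
    run_cohort(100, list(titration_policy()), seed = 1000 + s)$totals[[1]]
  }, numeric(1)))
  m200 <- mean(vapply(1:40, function(s) {
    run_cohort(200, list(titration_policy()), seed = 2000 + s)$totals[[1]]
  }, numeric(1)))
  # relative CLT error of the ratio (per-patient variance from the oracle)
  rel_se <- sqrt((100 * 11239482 / 40) / (100 * 4082.4)^2 +
                   (200 * 11239482 / 40) / (200 * 4082.4)^2)
  expect_lt(abs(m200 / m100 - 2), 2 * 4 * rel_se)
})
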