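test_that("simulated cohorts have the requested size and schema", {
  co <- simulate_cohort(fx_spec213())
  expect_equal(nrow(co), 213)
  expect_true(all(c("patient_id", "mca_length_cm", "mca_bl_cm", "mca_ti",
                    "mean_mca_diameter_mm", "diameter_at_occlusion_mm", "ica_ti",
                    "onset_to_puncture_min", "ivt", "age_years", "baseline_mrs",
                    "complete_recan", "fpe", "successful_recan",
                    "excellent_outcome", "sich", "sah", "ph2", "severe_ht")
                  %in% names(co)))
  eps <- c("complete_recan", "fpe", "successful_recan", "excellent_outcome",
           "sich", "sah", "ph2", "severe_ht")
  for (ep in eps) expect_true(all(co[[ep]] %in% 0:1))
  # composite endpoint is derived, not drawn
  expect_identical(co$severe_ht, as.integer(co$sah | co$ph2))
})

test_that("simulation is reproducible given a seed and varies across seeds", {
  spec <- fx_spec213()
  expect_identical(simulate_cohort(spec, seed = 42), simulate_cohort(spec, seed = 42))
  expect_false(identical(simulate_cohort(spec, seed = 42)$mca_ti,
                         simulate_cohort(spec, seed = 43)$mca_ti))
})

test_that("an intercept-only endpoint hits its target rate", {
  spec <- cohort_spec(n = 10000, outcome_models = list(
    complete_recan = list(rate = 0.5, coef = c())))
  co <- simulate_cohort(spec, seed = 9)
  # binomial SE at n = 10000 is 0.005; allow 3 SE
  expect_lt(abs(mean(co$complete_recan) - 0.5), 3 * 0.005)
})

test_that("feature marginals match their calibration targets", {
  spec <- cohort_spec(n = 10000, seed = 2)
  co <- simulate_cohort(spec)
  expect_lt(abs(median(co$mca_ti) - 0.26), 0.03)
  expect_lt(abs(median(co$mca_length_cm) - 3.82), 0.15)
  expect_lt(abs(median(co$mca_bl_cm) - 0.79), 0.05)
  expect_lt(abs(median(co$mean_mca_diameter_mm) - 2.99), 0.05)
  expect_lt(abs(median(co$diameter_at_occlusion_mm) - 2.61), 0.05)
  expect_lt(abs(median(co$ica_ti) - 0.34), 0.02)
  # IQRs too, for the skewed laws
  expect_lt(abs(quantile(co$mca_bl_cm, 0.75) - 1.31), 0.1)
  expect_lt(abs(quantile(co$mca_ti, 0.25) - 0.17), 0.03)
})

test_that("marginal law quantiles honor their defining summaries", {
  ln <- law_lnorm(0.79, 0.49, 1.31)
  expect_equal(ln$q(0.5), 0.79, tolerance = 1e-9)
  expect_equal(ln$q(0.75) / ln$q(0.25), 1.31 / 0.49, tolerance = 1e-9)
  bt <- law_beta(0.26, 0.17, 0.38, max = 1.5)
  # two shape parameters against three quantile targets: least-squares fit,
  # so ask for closeness, not equality
  expect_lt(abs(bt$q(0.5) - 0.26), 5e-3)
  expect_lt(abs(bt$q(0.25) - 0.17), 5e-3)
  expect_lt(abs(bt$q(0.75) - 0.38), 5e-3)
  tn <- law_tnorm(2.99, 2.80, 3.22)
  expect_equal(tn$q(0.5), 2.99, tolerance = 1e-3)
  expect_true(all(tn$q(c(1e-9, 0.5, 1 - 1e-9)) > 0))
})

test_that("outcome models referencing unknown columns are rejected", {
  expect_error(cohort_spec(outcome_models = list(
    complete_recan = list(rate = 0.5, coef = c(not_a_column = 1)))),
    "undeclared")
  expect_error(cohort_spec(n = 0), "n must be")
})

test_that("null feature effects leave endpoints independent of features", {
  # all feature coefficients zero: per-feature adjusted fits should reject at
  # the nominal 5% level; check the rejection rate over replicate cohorts
  spec <- cohort_spec(n = 400, outcome_models = list(
    complete_recan = list(rate = 0.5, coef = c(onset_to_puncture_min = -0.002,
                                               ivt = 0.25))))
  n_rep <- 400
  rej <- 0
  for (k in seq_len(n_rep)) {
    co <- simulate_cohort(spec, seed = 1000 + k)
    f <- fit_adjusted_logistic(co, "mca_bl_cm", "complete_recan")
    if (f$p_value < 0.05) rej <- rej + 1
  }
  # binomial(400, .05): mean 20, sd ~4.36; allow 4 SD
  expect_lt(abs(rej / n_rep - 0.05), 4 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("substreams give independent, reproducible seeds", {
  expect_identical(substream_seed(1, "cohort"), substream_seed(1, "cohort"))
  expect_false(substream_seed(1, "cohort") == substream_seed(1, "rasterize"))
  expect_false(substream_seed(1, "cohort") == substream_seed(2, "cohort"))
  expect_lt(substream_seed(.Machine$integer.max, "x"), 2^31)
})
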