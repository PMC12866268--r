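test_that("endpoint percentages use one-decimal half-away-from-zero rounding", {
  expect_equal(summarize_endpoint(93, 213)$percent, 43.7)
  expect_equal(summarize_endpoint(47, 213)$percent, 22.1)
  expect_equal(summarize_endpoint(0, 213)$percent, 0.0)
  expect_equal(summarize_endpoint(1, 800)$percent, 0.1) # 0.125 rounds up
  expect_error(summarize_endpoint(214, 213), "exceed")
  expect_error(summarize_endpoint(1, 0), "n must be")

  tab <- data.frame(fpe = c(1, 0, 1, NA))
  s <- summarize_endpoint(tab, endpoint = "fpe")
  expect_equal(s$n, 3)
  expect_equal(s$percent, 66.7)
})

test_that("the normality gate selects the t-test for Gaussian data and the
           Mann-Whitney U for skewed data", {
  picks_t <- picks_u <- 0
  for (k in 1:10) {
    set.seed(100 + k)
    g <- rep(0:1, each = 100)
    gauss <- rnorm(200)
    skew <- exp(rnorm(200, sd = 1.2))
    if (group_compare(gauss, g)$test_used == "student_t") picks_t <- picks_t + 1
    if (group_compare(skew, g)$test_used == "mann_whitney_u") picks_u <- picks_u + 1
  }
  expect_gte(picks_t, 8)
  expect_gte(picks_u, 9)
})

test_that("group comparison reports medians/IQRs and handles degenerate input", {
  set.seed(5)
  v <- c(rnorm(50, 10), rnorm(50, 12))
  g <- rep(c("a", "b"), each = 50)
  gt <- group_compare(v, g)
  expect_equal(gt$median1, median(v[1:50]))
  expect_equal(gt$q75_2, unname(quantile(v[51:100], 0.75)))
  expect_lt(gt$p_value, 0.05)

  const <- group_compare(rep(1, 20), rep(0:1, each = 10))
  expect_equal(const$p_value, 1)
  expect_match(const$flag, "zero variance")

  expect_error(group_compare(c(1, 2, NA), c(0, 1, 1)), "at least 3")
  expect_error(group_compare(rnorm(10), rep(1, 10)), "two groups")
})

test_that("adjusted logistic fits report Wald intervals on the aOR scale", {
  co <- simulate_cohort(cohort_spec(n = 4000, seed = 30), seed = 30)
  f <- fit_adjusted_logistic(co, "mca_bl_cm", "complete_recan")
  expect_true(f$converged)
  expect_true(f$ci_low <= f$aor && f$aor <= f$ci_high)
  expect_true(all(c(f$aor, f$ci_low, f$ci_high) > 0))
  expect_equal(f$adjusters, "onset_to_puncture_min+ivt")
  expect_equal(f$n_used, 4000)

  # excellent outcome adds age and baseline mRS to the adjuster set
  fe <- fit_adjusted_logistic(co, "mca_bl_cm", "excellent_outcome")
  expect_equal(fe$adjusters, "onset_to_puncture_min+ivt+age_years+baseline_mrs")
})

test_that("tortuosity features are scaled x10 and the scaling is idempotent", {
  co <- simulate_cohort(cohort_spec(n = 4000, seed = 31), seed = 31)
  f_auto <- fit_adjusted_logistic(co, "mca_ti", "complete_recan")
  expect_match(f_auto$scaling_note, "x10")
  # pre-scaling by hand (under a non-TI name) must give the same answer
  co$mca_ti_x10 <- 10 * co$mca_ti
  names(co)[names(co) == "mca_ti_x10"] <- "prescaled_feature"
  f_manual <- fit_adjusted_logistic(co, "prescaled_feature", "complete_recan")
  expect_equal(f_auto$aor, f_manual$aor, tolerance = 1e-9)
  expect_equal(f_auto$p_value, f_manual$p_value, tolerance = 1e-9)
})

test_that("logistic estimates are equivariant under feature rescaling", {
  co <- simulate_cohort(cohort_spec(n = 3000, seed = 32), seed = 32)
  f1 <- fit_adjusted_logistic(co, "mca_bl_cm", "complete_recan")
  co$mca_bl_scaled <- 4 * co$mca_bl_cm
  f4 <- fit_adjusted_logistic(co, "mca_bl_scaled", "complete_recan")
  expect_equal(log(f4$aor), log(f1$aor) / 4, tolerance = 1e-6)
  expect_equal(f4$p_value, f1$p_value, tolerance = 1e-6)
})

test_that("separation is flagged, not thrown", {
  set.seed(8)
  n <- 120
  tab <- data.frame(
    sep_feature = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
    onset_to_puncture_min = rlnorm(n, log(240), 0.4),
    ivt = rbinom(n, 1, 0.3),
    endpoint = rep(0:1, each = n / 2))
  f <- fit_adjusted_logistic(tab, "sep_feature", "endpoint")
  expect_false(f$converged)
  expect_true(is.na(f$ci_low))

  tab$endpoint <- 1L
  expect_error(fit_adjusted_logistic(tab, "sep_feature", "endpoint"), "single class")
})

test_that("correlation matrix is symmetric with unit diagonal and flags constants", {
  set.seed(12)
  tab <- data.frame(a = rnorm(500), b = rnorm(500), c = rep(1, 500))
  tab$d <- 0.8 * tab$a + 0.6 * rnorm(500)
  cm <- correlation_matrix(tab, features = c("a", "b", "c", "d"))
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$r, t(cm$r))
  expect_true(is.na(cm$r["a", "c"]))
  expect_match(paste(cm$flags, collapse = ";"), "constant")
  expect_lt(abs(cm$r["a", "b"]), 0.1)
  expect_gt(cm$r["a", "d"], 0.6)
})

test_that("the full analysis covers every feature-endpoint cell and survives failures", {
  co <- simulate_cohort(cohort_spec(n = 800, seed = 33), seed = 33)
  res <- run_full_analysis(co)
  expect_equal(nrow(res$adjusted) + sum(grepl("^aor:", names(res$failures))), 48)
  expect_equal(nrow(res$endpoint_summaries), 8)
  expect_equal(dim(res$correlations$r), c(6, 6))

  # wreck one endpoint: single class -> recorded failure, run continues
  co$sich <- 0L
  res2 <- run_full_analysis(co)
  expect_gte(length(res2$failures), 6)
  expect_true(any(grepl("single class", unlist(res2$failures))))

  dir <- tempfile()
  write_analysis(res, dir)
  expect_true(all(file.exists(file.path(dir,
    c("adjusted_results.csv", "group_tests.csv", "correlations.csv",
      "endpoint_summaries.csv", "results.json")))))
})
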