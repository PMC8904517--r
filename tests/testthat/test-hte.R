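test_that("the cut-off grid is deduplicated, ascending, zero-first", {
  expect_equal(roc_cutoffs(c(0.2, 0.2, 0.7)), c(0, 0.2, 0.7))
  expect_equal(roc_cutoffs(rep(0.4, 5)), c(0, 0.4))
  set.seed(30)
  s <- runif(43)
  expect_length(roc_cutoffs(s), 44)
  g <- roc_cutoffs(s, max_size = 10)
  expect_lte(length(g), 10)
  expect_equal(g[1], 0)
  expect_true(!is.unsorted(g, strictly = TRUE))
  expect_error(roc_cutoffs(numeric(0)), "no training scores")
})

test_that("subgroup selection is boundary-inclusive and arm-blind", {
  expect_equal(select_subgroup(c(0.1, 0.5, 0.9), 0.5), c(2L, 3L))
  expect_equal(select_subgroup(c(0.1, 0.5, 0.9), 0), 1:3)
  expect_length(select_subgroup(c(0.1, 0.5), 0.95), 0)
})

test_that("unadjusted effect equals the difference in arm means exactly", {
  tr <- simulate_trial(trial_config(n_patients = 300, seed = 33))
  eff <- estimate_effect(tr)
  d <- mean(tr$delta_hba1c[tr$arm == "treatment"]) -
    mean(tr$delta_hba1c[tr$arm == "control"])
  expect_equal(eff$effect, d, tolerance = 1e-12)
  expect_true(eff$ci_low <= eff$effect && eff$effect <= eff$ci_high)
})

test_that("effect CIs cover the simulated truth at the nominal rate", {
  covered <- 0
  for (s in 1:40) {
    tr <- simulate_trial(trial_config(n_patients = 2000, tau = -0.4, seed = 600 + s))
    eff <- estimate_effect(tr, adjustment = c("age", "hba1c_baseline"))
    if (eff$ci_low <= -0.4 && -0.4 <= eff$ci_high) covered <- covered + 1
  }
  expect_gte(covered, 34)  # binomial 99.9% lower bound at 95% coverage
})

test_that("degenerate and aliased subgroup models are handled", {
  df <- tibble::tibble(arm = rep(c("treatment", "control"), each = 10),
                       delta_hba1c = 0)
  eff <- estimate_effect(df)
  expect_equal(eff$effect, 0)
  expect_true(eff$estimable)

  tr <- simulate_trial(trial_config(n_patients = 100, seed = 34))
  tr$arm_copy <- as.numeric(tr$arm == "treatment")
  expect_warning(eff2 <- estimate_effect(tr, adjustment = c("age", "arm_copy")),
                 "aliased")
  expect_true(eff2$estimable)

  one_arm <- tr[tr$arm == "treatment", ]
  expect_false(estimate_effect(one_arm)$estimable)
  expect_false(estimate_effect(tr[1:6, ], adjustment = c("age", "bmi"))$estimable)
})

test_that("sweep output is nested, truncates gracefully, and finds the best cut-off", {
  tr <- simulate_trial(trial_config(n_patients = 500, tau = -0.4,
                                    gamma = c(hba1c_baseline = -0.4), seed = 35))
  scores <- plogis(as.numeric(scale(tr$hba1c_baseline)))
  sw <- suppressMessages(
    sweep_thresholds(tr, scores, roc_cutoffs(scores, max_size = 20),
                     adjustment = c("age", "male"))
  )
  expect_s3_class(sw, "threshold_sweep")
  expect_true(attr(sw, "nested"))
  expect_true(all(diff(sw$n) <= 0))  # nested: monotonically shrinking
  expect_lt(sw$n[nrow(sw)], sw$n[1])
  expect_equal(sw$cutoff[1], 0)
  expect_equal(sw$n[1], 500)
  b <- attr(sw, "best_cutoff")
  expect_equal(sw$effect[sw$cutoff == b], min(sw$effect))
  expect_true(all(sw$n_treatment + sw$n_control == sw$n))
  gl <- glance(sw)
  expect_equal(gl$full_sample_effect, sw$effect[1])
})

test_that("a single-point grid reproduces the full-sample estimate", {
  tr <- simulate_trial(trial_config(n_patients = 200, seed = 36))
  sw <- sweep_thresholds(tr, runif(200), grid = 0)
  expect_equal(nrow(sw), 1)
  expect_equal(sw$effect, estimate_effect(tr)$effect)
})

test_that("missing adjustment covariates are dropped with a warning", {
  tr <- simulate_trial(trial_config(n_patients = 200, seed = 37))
  expect_warning(
    sw <- sweep_thresholds(tr, runif(200), grid = 0,
                           adjustment = c("age", "carotid_imt_max")),
    "carotid_imt_max"
  )
  expect_equal(nrow(sw), 1)
})

test_that("contingency test reproduces published responder comparisons", {
  prologue <- contingency_test(c(57, 81), c(193, 192))
  expect_equal(round(prologue$p_value, 3), 0.010)
  sais1 <- contingency_test(c(34, 30), c(49, 43))
  expect_equal(round(sais1$p_value, 3), 0.969)
  ident <- contingency_test(c(10, 10), c(20, 20))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(contingency_test(c(0, 0), c(20, 20)), "zero margin")
})

test_that("contingency test matches a hypergeometric permutation null", {
  obs <- contingency_test(c(57, 81), c(193, 192))
  # independent conditional null: resample the first arm's responder count
  # with both margins fixed and compare chi-squared statistics
  stat <- function(a, n1 = 193, n2 = 192, m = 138) {
    tab <- rbind(c(a, m - a), c(n1 - a, n2 - (m - a)))
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    sum((tab - e)^2 / e)
  }
  set.seed(8)
  draws <- stats::rhyper(20000, 138, 385 - 138, 193)
  p_perm <- mean(vapply(draws, stat, numeric(1)) >= obs$statistic - 1e-9)
  expect_lt(abs(p_perm - obs$p_value), 0.01)
})

test_that("group summaries report type-7 quartiles and binary percentages", {
  tr <- tibble::tibble(
    arm = rep(c("treatment", "control"), each = 5),
    age = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
    male = c(1, 1, 1, 1, 1, 0, 1, 0, 1, 0),
    delta_hba1c = rep(0, 10)
  )
  schema <- covariate_schema(tibble::tibble(
    variable = c("age", "male"), kind = c("continuous", "binary"), unit = ""
  ))
  gs <- group_summary(tr, schema)
  expect_equal(gs$treatment[gs$variable == "age"], "2.00/3.00/4.00")
  expect_equal(gs$treatment[gs$variable == "male"], "100% (5)")
  # identical continuous distributions: rank-sum p in the null region
  expect_gt(gs$p_value[gs$variable == "age"], 0.99)
})

test_that("balance tables compute standardized mean differences", {
  tr <- simulate_trial(trial_config(n_patients = 4000, seed = 38))
  bt <- balance_table(tr, c("age", "male", "bmi"))
  expect_equal(nrow(bt), 3)
  expect_true(all(abs(bt$smd) < 0.2))  # randomized arms are balanced
})

test_that("sweep plots build without error", {
  tr <- simulate_trial(trial_config(n_patients = 300, seed = 39))
  scores <- runif(300)
  sw <- suppressMessages(sweep_thresholds(tr, scores,
                                          roc_cutoffs(scores, max_size = 8)))
  p1 <- autoplot(sw)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_subgroup_outcomes(tr, scores)
  expect_s3_class(p2, "ggplot")
})
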