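test_that("degenerate noise-free null config yields an all-zero outcome", {
  cfg <- trial_config(n_patients = 50, beta_main = numeric(), tau = 0,
                      sigma = 1e-12, mu = 0, seed = 1)
  tr <- simulate_trial(cfg)
  expect_equal(tr$delta_hba1c, rep(0, 50), tolerance = 1e-9)
  expect_setequal(unique(tr$arm), c("treatment", "control"))
})

test_that("arm-mean difference recovers tau under a homogeneous effect", {
  cfg <- trial_config(n_patients = 10000, tau = -0.4, seed = 21)
  tr <- simulate_trial(cfg)
  d <- mean(tr$delta_hba1c[tr$arm == "treatment"]) -
    mean(tr$delta_hba1c[tr$arm == "control"])
  se <- cfg$sigma * sqrt(1 / sum(tr$arm == "treatment") +
                           1 / sum(tr$arm == "control"))
  expect_lt(abs(d - (-0.4)), 4 * se)
})

test_that("effect calibration holds at large n with the stated tolerance", {
  cfg <- trial_config(n_patients = 50000, tau = -0.4, seed = 3)
  tr <- simulate_trial(cfg)
  d <- mean(tr$delta_hba1c[tr$arm == "treatment"]) -
    mean(tr$delta_hba1c[tr$arm == "control"])
  expect_lt(abs(d - (-0.4)), 3 * cfg$sigma / sqrt(cfg$n_patients))
})

test_that("missing_rate = 0 leaves every covariate cell observed", {
  tr <- simulate_trial(trial_config(n_patients = 200, seed = 4))
  expect_false(anyNA(tr[default_schema()$variable]))
  expect_false(anyNA(tr$delta_hba1c))
})

test_that("same config and seed reproduce the dataset through a CSV round-trip", {
  cfg <- trial_config(n_patients = 80, missing_rate = 0.15,
                      missing_mechanism = "MAR", outcome_missing_rate = 0.1,
                      seed = 9)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1, t2)
  p1 <- file.path(tempdir(), "t1.csv"); p2 <- file.path(tempdir(), "t2.csv")
  write_trial_csv(t1, p1); write_trial_csv(t2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_equal(as.data.frame(read_trial_csv(p1)), as.data.frame(t1))
})

test_that("arm allocation is balanced within binomial bounds, exactly when asked", {
  tr <- simulate_trial(trial_config(n_patients = 385, seed = 10))
  n_t <- sum(tr$arm == "treatment")
  bound <- stats::qbinom(c(0.0005, 0.9995), 385, 0.5)
  expect_gte(n_t, bound[1]); expect_lte(n_t, bound[2])
  trx <- simulate_trial(trial_config(n_patients = 385, exact_split = TRUE, seed = 10))
  expect_lte(abs(sum(trx$arm == "treatment") - sum(trx$arm == "control")), 1)
})

test_that("planted interaction makes the top effect quartile beat the bottom", {
  cfg <- trial_config(n_patients = 20000, tau = -0.4,
                      gamma = c(hba1c_baseline = -0.4), seed = 12)
  tr <- simulate_trial(cfg)
  # individual effect is tau + gamma * z(hba1c); top quartile of benefit =
  # highest baseline HbA1c (gamma negative)
  q <- stats::quantile(tr$hba1c_baseline, c(0.25, 0.75))
  armdiff <- function(d) mean(d$delta_hba1c[d$arm == "treatment"]) -
    mean(d$delta_hba1c[d$arm == "control"])
  top <- armdiff(tr[tr$hba1c_baseline >= q[2], ])
  bottom <- armdiff(tr[tr$hba1c_baseline <= q[1], ])
  expect_lt(top, bottom)  # more negative = larger benefit
})

test_that("trial pairs share the schema, differ row-wise, and are reproducible", {
  sc <- trial_config(n_patients = 48, outcome_missing_rate = 0.1, seed = 5)
  tc <- trial_config(n_patients = 385, seed = 5)
  pair <- simulate_trial_pair(sc, tc)
  expect_equal(nrow(pair$source), 48)
  expect_equal(nrow(pair$target), 385)
  expect_identical(names(pair$source), names(pair$target))
  pair2 <- simulate_trial_pair(sc, tc)
  expect_identical(pair, pair2)
  # identical configs: the derived sub-seed streams keep the trials distinct
  same <- simulate_trial_pair(tc, tc)
  expect_false(identical(same$source$delta_hba1c, same$target$delta_hba1c))
})

test_that("invalid config fields are rejected with the field named", {
  expect_error(trial_config(n_patients = 10, sigma = -1), "sigma")
  expect_error(trial_config(n_patients = 10, missing_rate = 1), "missing_rate")
  expect_error(trial_config(n_patients = 0), "n_patients")
  expect_error(trial_config(n_patients = 10, allocation_ratio = 1.5),
               "allocation_ratio")
  expect_error(simulate_trial(trial_config(n_patients = 10,
                                           beta_main = c(nope = 1))),
               "nope")
})

test_that("gaussian copula induces the requested correlation sign", {
  k <- nrow(default_covariate_params())
  R <- diag(k)
  R[1, 3] <- R[3, 1] <- 0.7   # age with bmi
  tr <- simulate_trial(trial_config(n_patients = 5000, copula = R, seed = 31))
  expect_gt(stats::cor(tr$age, tr$bmi), 0.5)
})
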