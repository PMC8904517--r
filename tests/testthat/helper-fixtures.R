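# Shared fixtures: small learner menus and planted-signal trials, all
# generated in code under fixed seeds.

# fast menu used where the test exercises the stacking machinery, not the
# individual learners
fast_menu <- function() {
  list(learner_spec("glm_logistic"),
       learner_spec("cart"),
       learner_spec("gbm", list(trees = 100)))
}

# the six-learner benchmark menu for oracle-property checks
bench_menu <- function() {
  list(learner_spec("glm_logistic"),
       learner_spec("glm_logistic_unadjusted"),
       learner_spec("glmnet_elastic"),
       learner_spec("cart"),
       learner_spec("random_forest", list(trees = 200)),
       learner_spec("gbm"))
}

# trial whose responder status carries a strong (logistic-like) covariate
# signal: baseline HbA1c and BMI drive the outcome through beta_main
signal_trial <- function(n, seed, tau = -0.4, gamma = numeric()) {
  simulate_trial(trial_config(
    n_patients = n,
    beta_main = c(hba1c_baseline = -0.5, bmi = 0.3),
    tau = tau, gamma = gamma, sigma = 0.4, seed = seed
  ))
}

# brute-force pairwise-concordance AUC: the independent oracle for auc()
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}
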