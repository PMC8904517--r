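# slhte

Detecting heterogeneous treatment effects across two randomized trials that
share a covariate schema, by transferring a Super Learner outcome model from
one trial to the other.

## The problem

Two randomized trials of the same add-on anti-diabetic therapy (a DPP-4
inhibitor) collect the same baseline measures — age, sex, BMI, blood
pressures, lipids, baseline HbA1c, fasting plasma glucose, adiponectin — and
the same continuous outcome, the change in glycated haemoglobin from
baseline (ΔHbA1c, in percentage points; negative = improvement). A small
*source* trial tells us which treated patients responded (ΔHbA1c ≤ −0.5%,
the clinically significant improvement). The question for the larger
*target* trial is whether the treatment effect is heterogeneous: do patients
who *look like* the source trial's responders benefit more than average?

`slhte` implements that transfer analysis end to end:

1. **Outcome model.** On the treated arm of the source trial (patients with
   a missing follow-up outcome excluded), the dichotomized response
   Y = 1{ΔHbA1c ≤ −0.5} is modelled by a **Super Learner**: a menu of base
   learners Ψ₁…Ψ_L (penalized and plain logistic regression, CART, bagged
   trees, random forest, gradient boosting with 500 trees / depth 5 /
   learning rate 0.1, RBF-kernel SVM, adaptive hinge-basis splines, a
   sum-of-trees surrogate slot), each optionally refitted on a
   random-forest-screened covariate subset. Stratified 5-fold
   cross-validation yields the out-of-fold prediction matrix Z; the ensemble
   weight vector solves

   min‖Y − Zw‖² s.t. w ≥ 0, then w ← w / Σw,

   so the stacked prediction is a convex combination of learner
   probabilities. Per-learner risk is reported both as cross-validated MSE
   and as 1 − AUC; the ensemble's cross-validated AUC is AUC(Zw, Y).
2. **Transfer.** Missing target-trial covariates are completed by chained
   equations with random-forest draws (monotone visit sequence, terminal-node
   donor sampling), then every target patient receives a responder
   probability from the refitted ensemble.
3. **Cut-off sweep.** The distinct out-of-fold training scores — the
   thresholds an ROC curve would step through — define nested subgroups
   {score ≥ c}. Within each subgroup (both arms retained, so randomization
   still protects the comparison) the treatment effect on the *continuous*
   ΔHbA1c is estimated by a covariate-adjusted linear model, with its 95%
   confidence interval. A rising benefit as the subgroup narrows to
   predicted responders is evidence of effect heterogeneity.

A synthetic twin-trial generator, calibrated to the published baseline
summaries of the two motivating trials, stands in for the deposited patient
data, so the whole pipeline is testable offline.

## Worked example

```r
library(slhte)

pair <- simulate_trial_pair(
  trial_config(n_patients = 150, beta_main = c(hba1c_baseline = -0.5, bmi = 0.3),
               tau = -0.4, gamma = c(hba1c_baseline = -0.5), sigma = 0.4, seed = 2),
  trial_config(n_patients = 400, beta_main = c(hba1c_baseline = -0.5, bmi = 0.3),
               tau = -0.4, gamma = c(hba1c_baseline = -0.5), sigma = 0.4, seed = 2)
)
src  <- pair$source |> filter_analysis_set(arm_filter = "treatment") |> add_responder()
vars <- default_schema()$variable

menu <- list(learner_spec("glm_logistic"),
             learner_spec("random_forest", list(trees = 200)),
             learner_spec("gbm", list(trees = 100)))
sl <- fit_super_learner(menu, src[vars], src$responder, seed = 2)
sl
#> Super Learner: 3 learners, n = 75
#>   cross-validated AUC: 0.8779
#> # A tibble: 3 × 4
#>   learner       cv_risk_mse cv_risk_one_minus_auc weight
#> 1 glm_logistic        0.178                 0.124 0.293
#> 2 random_forest       0.150                 0.124 0.686
#> 3 gbm                 0.174                 0.154 0.0206

scores <- predict(sl, pair$target[vars])
sw <- sweep_thresholds(pair$target, scores,
                       roc_cutoffs(sl$oof_ensemble, max_size = 10),
                       adjustment = c("age", "male", "sbp", "hba1c_baseline"))
glance(sw)
#> # A tibble: 1 × 5
#>   n_cutoffs best_cutoff best_effect best_n full_sample_effect
#> 1         9       0.865      -0.873     55             -0.465
autoplot(sw)
```

Reading the numbers: the ensemble separates source-trial responders from
non-responders well out of fold (CV AUC 0.88; per-learner 1 − AUC risks and
NNLS weights in the table). Swept over the target trial, the adjusted
treatment effect on ΔHbA1c grows from −0.47 percentage points in all 400
patients to −0.87 in the 55 patients scoring above 0.865 — the simulated
covariate-by-treatment interaction is recovered as a steadily increasing
benefit in the nested predicted-responder subgroups. Under a homogeneous
simulated effect the same trajectory stays flat.

`tidy()` on the sweep gives the per-cutoff table (cut-off, subgroup sizes
per arm, effect, CI, p); `group_summary()` and `balance_table()` emit
baseline-characteristics and standardized-mean-difference tables;
`run_pipeline()` drives the whole analysis from a config and writes
deterministic CSV artifacts plus a digest manifest.

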