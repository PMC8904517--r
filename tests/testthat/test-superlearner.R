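test_that("stratified folds respect per-class and overall balance", {
  # 43 rows, 5 folds: validation folds of 8 or 9 whatever the class split
  for (s in 1:10) {
    set.seed(s)
    n_pos <- sample(6:37, 1)
    y <- sample(rep(c(1, 0), c(n_pos, 43 - n_pos)))
    f <- make_folds(y, k = 5, seed = s)
    expect_equal(sort(as.integer(table(f))), c(8, 8, 9, 9, 9))
    per_class <- table(factor(f, levels = 1:5), y)
    expect_lte(max(apply(per_class, 2, function(x) diff(range(x)))), 1)
  }
  # perfect stratification when classes divide evenly
  y <- rep(0:1, 5)
  tab <- table(make_folds(y, k = 5, seed = 1), y)
  expect_true(all(tab == 1))
  expect_identical(make_folds(y, 5, seed = 4), make_folds(y, 5, seed = 4))
  expect_error(make_folds(rep(0:1, 2), k = 5), "exceed")
  expect_error(make_folds(rep(1, 10), k = 2), "both classes")
})

test_that("AUC agrees with the hand-enumerated example and brute force", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), rep(0:1, 3)), 0.5)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(101)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # coarse grid forces ties
    expect_equal(auc(s, y), auc_bruteforce(s, y))
  }
})

test_that("attainable AUC values sit on the 1/(2pq) concordance grid", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- runif(n)
    p <- sum(y == 1); q <- sum(y == 0)
    expect_equal(auc(s, y) * 2 * p * q, round(auc(s, y) * 2 * p * q),
                 tolerance = 1e-9)
  }
})

test_that("out-of-fold risks separate oracle, constant and noise learners", {
  tr <- signal_trial(200, seed = 24) |> add_responder()
  X <- tr[default_schema()$variable]
  y <- tr$responder
  folds <- make_folds(y, 5, seed = 1)
  cv <- cross_validate_learners(list(learner_spec("glm_logistic"),
                                     learner_spec("glm_logistic_unadjusted")),
                                X, y, folds, seed = 1)
  expect_equal(dim(cv$Z), c(200, 2))
  expect_true(all(cv$Z >= 0 & cv$Z <= 1))
  # the signal learner must carry strictly lower MSE risk than the constant
  expect_lt(cv$risks$cv_risk_mse[1], cv$risks$cv_risk_mse[2])
  expect_equal(cv$risks$cv_risk_one_minus_auc[2], 0.5, tolerance = 1e-9)
})

test_that("NNLS weights match a brute-force simplex search and handle degeneracy", {
  set.seed(6)
  y <- rbinom(200, 1, 0.5)
  Z <- cbind(sig = y, noise = runif(200))
  w <- nnls_weights(Z, y)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
  expect_gt(w["sig"], 0.9)
  # independent oracle: grid search over the 1-simplex for the same loss
  grid <- seq(0, 1, 1e-3)
  loss <- vapply(grid, function(a) sum((y - Z %*% c(a, 1 - a))^2), numeric(1))
  expect_equal(unname(w["sig"]), grid[which.min(loss)], tolerance = 2e-3)

  w1 <- nnls_weights(matrix(y, ncol = 1, dimnames = list(NULL, "only")), y)
  expect_equal(unname(w1), 1)
  # identical columns: any split is optimal; the contract is the simplex and
  # invariance of the combined prediction
  Z2 <- cbind(a = y, b = y)
  w2 <- nnls_weights(Z2, y)
  expect_equal(sum(w2), 1)
  expect_equal(drop(Z2 %*% w2), as.numeric(y))
})

test_that("the fitted ensemble reports simplex weights and a sane CV AUC", {
  tr <- signal_trial(150, seed = 25) |> add_responder()
  X <- tr[default_schema()$variable]
  sl <- fit_super_learner(fast_menu(), X, tr$responder, seed = 9)
  expect_true(all(sl$weights >= 0))
  expect_equal(sum(sl$weights), 1)
  expect_true(all(sl$Z >= 0 & sl$Z <= 1))
  expect_gt(sl$cv_auc, 0.5)
  expect_equal(sl$cv_risk_one_minus_auc, 1 - sl$cv_auc)
  td <- tidy(sl)
  expect_named(td, c("learner", "cv_risk_mse", "cv_risk_one_minus_auc", "weight"))
  expect_equal(nrow(td), 3)
  gl <- glance(sl)
  expect_equal(gl$n, 150)
  expect_equal(gl$cv_auc, sl$cv_auc)
})

test_that("ensemble predictions are the weighted learner combination", {
  # transparent stub learners (identity hinge bases) give an arithmetic oracle
  stub <- function(var, nm) {
    structure(list(
      spec = learner_spec("mars", name = nm), vars = var,
      model = list(terms = list(list(list(var = 1, sign = 1, knot = 0))),
                   coefficients = 1, vars = var),
      n_train = 3
    ), class = "fitted_learner")
  }
  sl <- structure(list(weights = c(a = 0.25, b = 0.75),
                       learners = list(a = stub("x1", "a"), b = stub("x2", "b"))),
                  class = "super_learner")
  nd <- tibble::tibble(x1 = c(0.2, 0.8, 0.6), x2 = c(0.4, 0.0, 1.0))
  expect_equal(predict(sl, nd), c(0.35, 0.2, 0.9))
})

test_that("ensemble predictions stay within the component envelope", {
  tr <- signal_trial(120, seed = 26) |> add_responder()
  X <- tr[default_schema()$variable]
  sl <- fit_super_learner(fast_menu(), X, tr$responder, seed = 11)
  P <- vapply(sl$learners, predict_proba, numeric(nrow(X)), new_data = X)
  p <- predict(sl, X)
  expect_true(all(p >= apply(P, 1, min) - 1e-12))
  expect_true(all(p <= apply(P, 1, max) + 1e-12))
})

test_that("a failing learner is dropped with a warning, not fatal", {
  tr <- signal_trial(80, seed = 27) |> add_responder()
  X <- tr[default_schema()$variable]
  # k larger than the training-fold column count makes screening fail
  bad <- learner_spec("cart", screen = TRUE, screen_k = 99, name = "broken")
  expect_warning(
    sl <- fit_super_learner(list(learner_spec("glm_logistic"), bad), X,
                            tr$responder, seed = 12),
    "dropped"
  )
  expect_equal(sl$dropped, "broken")
  expect_named(sl$weights, "glm_logistic")
})
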