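#' Base learner specification
#'
#' A base learner is a candidate probability-of-response algorithm in the
#' ensemble menu. Each spec names a model family, optional hyperparameter
#' overrides, and whether the learner is fitted on a random-forest-screened
#' covariate subset instead of the full set.
#'
#' Families: `"gbm"` (gradient boosting; defaults 500 trees, interaction
#' depth 5, learning rate 0.1), `"glm_logistic"`, `"glm_logistic_unadjusted"`
#' (intercept-only), `"glmnet_elastic"` (elastic-net logistic, alpha 0.5),
#' `"mars"` (adaptive hinge-basis regression, forward selection + GCV
#' pruning, interaction degree <= 2), `"random_forest"`, `"cart"`,
#' `"bagging"` (bootstrap-aggregated trees), `"svm_kernel"` (RBF SVM with
#' Platt-calibrated probabilities), and `"bart_like"` — a slot for a
#' sum-of-trees Bayesian model whose default implementation is a
#' gradient-boosted surrogate (many shallow trees, slow learning rate) and is
#' flagged as non-faithful in reports.
#'
#' @param family One of the families above.
#' @param hyperparameters Named list of overrides (e.g. `list(trees = 200)`).
#' @param screen If `TRUE`, fit on the top-`screen_k` covariates ranked by
#'   random-forest importance.
#' @param screen_k Number of covariates kept by screening (default 6).
#' @param name Unique identifier within a menu; defaults to the family name
#'   with a `_screen` suffix when screened.
#' @return List of class `learner_spec`.
#' @export
learner_spec <- function(family, hyperparameters = list(), screen = FALSE,
                         screen_k = 6, name = NULL) {
  families <- c("gbm", "glm_logistic", "glm_logistic_unadjusted",
                "glmnet_elastic", "mars", "random_forest", "cart", "bagging",
                "svm_kernel", "bart_like")
  if (!family %in% families) {
    stop("unknown learner family '", family, "'", call. = FALSE)
  }
  if (is.null(name)) name <- paste0(family, if (screen) "_screen" else "")
  structure(list(name = name, family = family,
                 hyperparameters = hyperparameters,
                 screen = isTRUE(screen), screen_k = screen_k),
            class = "learner_spec")
}

#' Default ensemble menu
#'
#' Seventeen learners mirroring the published ensemble: each tree/kernel
#' family with and without random-forest variable screening, plus the
#' screened elastic-net logistic model. The gradient-boosting family is
#' available for custom menus via [learner_spec()].
#'
#' @param screen_k Covariates kept by the screening wrapper.
#' @return List of [learner_spec()] objects.
#' @export
default_learner_menu <- function(screen_k = 6) {
  both <- function(family) {
    list(learner_spec(family, screen_k = screen_k),
         learner_spec(family, screen = TRUE, screen_k = screen_k))
  }
  c(both("bart_like"), both("random_forest"), both("cart"), both("bagging"),
    both("svm_kernel"),
    list(learner_spec("glmnet_elastic", screen = TRUE, screen_k = screen_k)),
    both("glm_logistic"), both("glm_logistic_unadjusted"), both("mars"))
}

#' Random-forest variable screening
#'
#' Ranks covariates by impurity-based importance from a regression forest on
#' the 0/1 outcome and returns the top `k` in rank order. Deterministic under
#' a fixed seed; with an uninformative (e.g. constant) outcome, importances
#' tie at zero and the ranking falls back to column order.
#'
#' @param X Covariate data frame (numeric columns, no missing cells).
#' @param y Binary 0/1 outcome vector.
#' @param k Number of variables to keep.
#' @param seed Integer seed for the forest.
#' @return Character vector of `k` variable names.
#' @export
rf_screen <- function(X, y, k, seed = 1L) {
  if (k < 1 || k > ncol(X)) {
    stop("k must be between 1 and ncol(X) = ", ncol(X), call. = FALSE)
  }
  df <- data.frame(.y = as.numeric(y), X, check.names = FALSE)
  fit <- ranger::ranger(.y ~ ., data = df, num.trees = 200,
                        importance = "impurity", seed = seed, num.threads = 1)
  imp <- fit$variable.importance[names(X)]
  imp[is.na(imp)] <- 0
  names(X)[order(-imp, seq_along(imp))][seq_len(k)]
}

# ---- family backends ---------------------------------------------------

#' @keywords internal
as_num_matrix <- function(X) {
  m <- as.matrix(as.data.frame(lapply(X, as.numeric)))
  colnames(m) <- names(X)
  m
}

#' @keywords internal
hp <- function(spec, key, default) {
  v <- spec$hyperparameters[[key]]
  if (is.null(v)) default else v
}

#' @keywords internal
fit_family <- function(spec, X, y) {
  switch(spec$family,
    gbm = {
      d <- xgboost::xgb.DMatrix(as_num_matrix(X), label = y)
      list(model = xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp(spec, "interaction_depth", 5),
                      eta = hp(spec, "learning_rate", 0.1), nthread = 1),
        data = d, nrounds = hp(spec, "trees", 500), verbose = 0))
    },
    bart_like = {
      d <- xgboost::xgb.DMatrix(as_num_matrix(X), label = y)
      list(model = xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp(spec, "interaction_depth", 2),
                      eta = hp(spec, "learning_rate", 0.05),
                      subsample = hp(spec, "subsample", 0.8), nthread = 1),
        data = d, nrounds = hp(spec, "trees", 200), verbose = 0),
        note = "surrogate: gradient-boosted stand-in for a sum-of-trees Bayesian model")
    },
    glm_logistic = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      list(model = suppressWarnings(
        stats::glm(.y ~ ., data = df, family = stats::binomial())))
    },
    glm_logistic_unadjusted = list(model = mean(y)),
    glmnet_elastic = {
      cv <- glmnet::cv.glmnet(as_num_matrix(X), y, family = "binomial",
                              alpha = hp(spec, "alpha", 0.5),
                              nfolds = hp(spec, "nfolds", 5))
      list(model = cv)
    },
    mars = list(model = fit_mars_hinge(as_num_matrix(X), y,
                                       max_terms = hp(spec, "max_terms", 12),
                                       degree = hp(spec, "degree", 2))),
    random_forest = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
      list(model = ranger::ranger(.y ~ ., data = df,
                                  num.trees = hp(spec, "trees", 500),
                                  probability = TRUE,
                                  seed = sample.int(.Machine$integer.max, 1),
                                  num.threads = 1))
    },
    cart = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
      list(model = rpart::rpart(.y ~ ., data = df, method = "class",
                                control = rpart::rpart.control(xval = 0)))
    },
    bagging = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
      B <- hp(spec, "bags", 50)
      list(model = lapply(seq_len(B), function(b) {
        idx <- sample.int(nrow(df), replace = TRUE)
        rpart::rpart(.y ~ ., data = df[idx, ], method = "class",
                     control = rpart::rpart.control(xval = 0))
      }))
    },
    svm_kernel = {
      list(model = e1071::svm(as_num_matrix(X), factor(y, levels = c(0, 1)),
                              kernel = hp(spec, "kernel", "radial"),
                              probability = TRUE))
    }
  )
}

#' @keywords internal
predict_family <- function(fitted, X) {
  spec <- fitted$spec
  switch(spec$family,
    gbm = ,
    bart_like = predict(fitted$model, xgboost::xgb.DMatrix(as_num_matrix(X))),
    glm_logistic = {
      df <- data.frame(X, check.names = FALSE)
      as.numeric(stats::predict(fitted$model, newdata = df, type = "response"))
    },
    glm_logistic_unadjusted = rep(fitted$model, nrow(X)),
    glmnet_elastic = as.numeric(stats::predict(fitted$model, as_num_matrix(X),
                                               s = "lambda.min",
                                               type = "response")),
    mars = predict_mars_hinge(fitted$model, as_num_matrix(X)),
    random_forest = predict(fitted$model, data.frame(X, check.names = FALSE),
                            num.threads = 1)$predictions[, "1"],
    cart = stats::predict(fitted$model, data.frame(X, check.names = FALSE),
                          type = "prob")[, "1"],
    bagging = {
      df <- data.frame(X, check.names = FALSE)
      rowMeans(vapply(fitted$model, function(tr) {
        stats::predict(tr, df, type = "prob")[, "1"]
      }, numeric(nrow(df))))
    },
    svm_kernel = {
      pr <- stats::predict(fitted$model, as_num_matrix(X), probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    }
  )
}

# ---- fit / predict contract --------------------------------------------

#' Fit a base learner
#'
#' Fits one learner spec on a complete covariate table and binary outcome.
#' When `spec$screen` is set, the covariate set is first reduced by
#' [rf_screen()] and the learner is fitted on that subset only.
#'
#' @param spec A [learner_spec()].
#' @param X Covariate data frame, no missing cells.
#' @param y Binary 0/1 outcome; both classes must be present.
#' @param seed Integer seed covering screening and any stochastic fit.
#' @return Object of class `fitted_learner` holding the spec, the variables
#'   used, and the fitted state.
#' @export
fit_learner <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("y must contain both classes", call. = FALSE)
  }
  if (anyNA(X)) stop("X contains missing cells; impute first", call. = FALSE)
  withr::with_seed(seed, {
    vars <- names(X)
    if (spec$screen) {
      vars <- rf_screen(X, y, k = spec$screen_k,
                        seed = sample.int(.Machine$integer.max, 1))
    }
    fitted <- fit_family(spec, X[vars], y)
    structure(list(spec = spec, vars = vars, model = fitted$model,
                   note = fitted$note, n_train = length(y)),
              class = "fitted_learner")
  })
}

#' Predict response probabilities from a fitted learner
#'
#' Columns of `new_data` are realigned to the training schema by name, so
#' column order does not matter; missing or mistyped columns raise an error
#' naming them.
#'
#' @param fitted A `fitted_learner`.
#' @param new_data Data frame with at least the training covariates.
#' @return Numeric vector of probabilities in `[0, 1]`, one per row.
#' @export
predict_proba <- function(fitted, new_data) {
  stopifnot(inherits(fitted, "fitted_learner"))
  missing_cols <- setdiff(fitted$vars, names(new_data))
  if (length(missing_cols)) {
    stop("new_data is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- new_data[fitted$vars]
  if (anyNA(X)) stop("new_data contains missing cells", call. = FALSE)
  p <- predict_family(fitted, X)
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat("<fitted_learner>", x$spec$name, "on", length(x$vars), "covariates,",
      x$n_train, "rows\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
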