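#' Stratified cross-validation folds
#'
#' Assigns rows to `k` folds so that each outcome class is spread as evenly
#' as possible (per-class fold counts differ by at most one) and overall fold
#' sizes are as balanced as the class split allows: members of each class are
#' shuffled under the seed and dealt one at a time to the currently smallest
#' fold (ties by fold index). With 43 rows and 5 folds every seed yields
#' validation folds of 8 or 9 patients.
#'
#' @param y Binary 0/1 outcome vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, one per row.
#' @export
#' @examples
#' table(make_folds(rep(0:1, c(13, 30)), k = 5, seed = 1))
make_folds <- function(y, k = 5, seed = 1L) {
  n <- length(y)
  if (k > n) stop("k must not exceed the number of rows", call. = FALSE)
  if (length(unique(y)) < 2) stop("y must contain both classes", call. = FALSE)
  withr::with_seed(seed, {
    fold <- integer(n)
    totals <- integer(k)
    classes <- names(sort(table(y), decreasing = TRUE))
    for (cl in classes) {
      idx <- sample(which(y == cl))
      for (i in idx) {
        f <- order(totals, seq_len(k))[1]
        fold[i] <- f
        totals[f] <- totals[f] + 1L
      }
    }
    fold
  })
}

#' Area under the ROC curve
#'
#' Probability of concordance: over all (positive, negative) label pairs, a
#' pair where the positive scores higher counts 1, a tie counts 1/2, and the
#' sum is divided by the number of pairs. Computed in rank (Mann-Whitney)
#' form, which is exact including ties.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("labels must contain both classes", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Out-of-fold predictions and per-learner cross-validated risks
#'
#' For every fold, each learner (with its screening step, when requested,
#' refitted inside the training fold) is trained on the other folds and
#' predicts the held-out rows, giving the out-of-fold matrix `Z` with
#' `Z[i, l]` the prediction for row `i` from the fit excluding row `i`'s
#' fold. Risks per learner: mean over folds of the out-of-fold squared error,
#' and one minus the AUC of the pooled out-of-fold predictions. A learner
#' that fails on any fold is dropped with a warning.
#'
#' @param specs List of [learner_spec()]; names must be unique.
#' @param X Complete covariate data frame.
#' @param y Binary 0/1 outcome.
#' @param folds Fold assignment from [make_folds()].
#' @param seed Integer seed for per-fold learner fits.
#' @return List: `Z` (n x L matrix, surviving learners), `risks` (tibble:
#'   learner, cv_risk_mse, cv_risk_one_minus_auc), `dropped` (names).
#' @export
cross_validate_learners <- function(specs, X, y, folds, seed = 1L) {
  nm <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("learner names must be unique", call. = FALSE)
  n <- length(y)
  k <- max(folds)
  L <- length(specs)
  Z <- matrix(NA_real_, n, L, dimnames = list(NULL, nm))
  fold_mse <- matrix(NA_real_, k, L)
  failed <- rep(FALSE, L)

  for (f in seq_len(k)) {
    tr <- folds != f
    for (l in seq_len(L)) {
      if (failed[l]) next
      res <- tryCatch(
        {
          fit <- fit_learner(specs[[l]], X[tr, , drop = FALSE], y[tr],
                             seed = derive_subseed(seed, f * 1000L + l))
          predict_proba(fit, X[!tr, , drop = FALSE])
        },
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failed[l] <- TRUE
        warning("learner '", nm[l], "' failed on fold ", f, " (",
                conditionMessage(res), "); dropped from the ensemble",
                call. = FALSE)
      } else {
        Z[!tr, l] <- res
        fold_mse[f, l] <- mean((y[!tr] - res)^2)
      }
    }
  }

  keep <- !failed
  if (!any(keep)) stop("all learners failed cross-validation", call. = FALSE)
  Z <- Z[, keep, drop = FALSE]
  risks <- tibble::tibble(
    learner = nm[keep],
    cv_risk_mse = unname(colMeans(fold_mse[, keep, drop = FALSE])),
    cv_risk_one_minus_auc = unname(apply(Z, 2, function(z) 1 - auc(z, y)))
  )
  list(Z = Z, risks = risks, dropped = nm[!keep])
}

#' Non-negative least squares stacking weights
#'
#' Solves `min ||y - Z w||^2` subject to `w >= 0` over the out-of-fold
#' prediction matrix, then normalizes the solution to sum to one so the
#' ensemble prediction is a convex combination of learner probabilities. If
#' every coefficient is zero (no learner better than nothing), uniform
#' weights are returned with a warning.
#'
#' @param Z Out-of-fold prediction matrix (n x L).
#' @param y Binary 0/1 outcome.
#' @return Named weight vector, nonnegative, summing to 1.
#' @export
nnls_weights <- function(Z, y) {
  if (is.null(dim(Z)) || ncol(Z) == 0) stop("Z has no learner columns", call. = FALSE)
  w <- pracma::lsqnonneg(unname(as.matrix(Z)), as.numeric(y))$x
  if (sum(w) <= 0) {
    warning("all NNLS coefficients are zero; falling back to uniform weights",
            call. = FALSE)
    w <- rep(1, ncol(Z))
  }
  stats::setNames(w / sum(w), colnames(Z))
}

#' Fit the Super Learner ensemble
#'
#' Composes the full stacking procedure: stratified folds, out-of-fold
#' cross-validation of every learner in the menu, non-negative least squares
#' meta-weights on the out-of-fold matrix, and a refit of each surviving
#' learner on all rows. The ensemble's cross-validated AUC is the AUC of the
#' convex combination of out-of-fold predictions, `Z w`, against the
#' observed outcome.
#'
#' @param specs Learner menu (list of [learner_spec()]); default
#'   [default_learner_menu()].
#' @param X Complete covariate data frame.
#' @param y Binary 0/1 outcome with both classes present.
#' @param k Folds (default 5).
#' @param seed Integer seed for folds and learner fits.
#' @return Object of class `super_learner`: `weights`, `risks`, `Z`,
#'   `cv_auc`, `cv_risk_one_minus_auc`, refitted `learners`, `folds`.
#' @export
#' @examples
#' \donttest{
#' tr <- simulate_trial(trial_config(n_patients = 120, seed = 3)) |>
#'   add_responder()
#' sl <- fit_super_learner(list(learner_spec("glm_logistic"),
#'                              learner_spec("cart")),
#'                         tr[default_schema()$variable], tr$responder,
#'                         seed = 3)
#' glance(sl)
#' }
fit_super_learner <- function(specs = default_learner_menu(), X, y, k = 5,
                              seed = 1L) {
  y <- as.integer(y)
  folds <- make_folds(y, k = k, seed = derive_subseed(seed, 11L))
  cv <- cross_validate_learners(specs, X, y, folds,
                                seed = derive_subseed(seed, 12L))
  w <- nnls_weights(cv$Z, y)
  surviving <- specs[vapply(specs, `[[`, character(1), "name") %in% colnames(cv$Z)]
  refits <- lapply(seq_along(surviving), function(l) {
    fit_learner(surviving[[l]], X, y, seed = derive_subseed(seed, 13L + l))
  })
  names(refits) <- colnames(cv$Z)
  ens_oof <- drop(cv$Z %*% w)
  structure(
    list(weights = w, risks = cv$risks, Z = cv$Z, folds = folds,
         cv_auc = auc(ens_oof, y), cv_risk_one_minus_auc = 1 - auc(ens_oof, y),
         oof_ensemble = ens_oof, learners = refits, dropped = cv$dropped,
         n = length(y), y = y),
    class = "super_learner"
  )
}

#' Predict responder probabilities from a fitted Super Learner
#'
#' The weighted combination of the refitted learners' probabilities; lies in
#' `[0, 1]` by convexity of the weights.
#'
#' @param object A `super_learner`.
#' @param new_data Complete data frame carrying the training covariates.
#' @param ... Unused.
#' @return Numeric probability vector.
#' @export
predict.super_learner <- function(object, new_data, ...) {
  P <- vapply(object$learners, predict_proba, numeric(nrow(new_data)),
              new_data = new_data)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1, dimnames = list(NULL, names(object$learners)))
  drop(P[, names(object$weights), drop = FALSE] %*% object$weights)
}

#' @export
print.super_learner <- function(x, ...) {
  cat("Super Learner:", length(x$learners), "learners, n =", x$n, "\n")
  cat("  cross-validated AUC:", round(x$cv_auc, 4), "\n")
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  print(tidy.super_learner(x), n = Inf)
  invisible(x)
}

#' Per-learner risk and weight table
#'
#' One row per surviving learner: cross-validated mean squared error risk,
#' 1 - AUC risk, and the NNLS stacking weight — the ensemble's training
#' performance report.
#'
#' @param x A `super_learner`.
#' @param ... Unused.
#' @return Tibble with columns `learner`, `cv_risk_mse`,
#'   `cv_risk_one_minus_auc`, `weight`.
#' @method tidy super_learner
#' @export
tidy.super_learner <- function(x, ...) {
  dplyr::mutate(x$risks, weight = unname(x$weights[.data$learner]))
}

#' One-row ensemble summary
#'
#' @param x A `super_learner`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_learners`, `n_dropped`, `cv_auc`,
#'   `cv_risk_one_minus_auc`.
#' @method glance super_learner
#' @export
glance.super_learner <- function(x, ...) {
  tibble::tibble(n = x$n, n_learners = length(x$learners),
                 n_dropped = length(x$dropped), cv_auc = x$cv_auc,
                 cv_risk_one_minus_auc = x$cv_risk_one_minus_auc)
}
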