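#' Probability cut-off grid from training scores
#'
#' The thresholds used to define nested responder subgroups are the distinct
#' out-of-fold ensemble scores from the source-trial model — the same values
#' an ROC curve would step through — deduplicated, sorted ascending, with 0
#' prepended so the first subgroup is the whole target trial. Optionally the
#' grid is thinned to `max_size` quantile-spaced values.
#'
#' @param training_scores Out-of-fold ensemble predictions in `[0, 1]`.
#' @param max_size Optional cap on grid length (0 included).
#' @return Numeric vector, strictly ascending, starting at 0.
#' @export
#' @examples
#' roc_cutoffs(c(0.2, 0.2, 0.7))
roc_cutoffs <- function(training_scores, max_size = NULL) {
  if (!length(training_scores)) stop("no training scores supplied", call. = FALSE)
  grid <- sort(unique(training_scores))
  if (!is.null(max_size) && length(grid) + 1 > max_size) {
    grid <- sort(unique(stats::quantile(grid, probs = seq(0, 1, length.out = max_size - 1),
                                        names = FALSE, type = 7)))
  }
  c(0, grid[grid > 0])
}

#' Select the subgroup at a probability cut-off
#'
#' Rows whose predicted responder probability is at least the cut-off;
#' selection ignores the arm, so both arms stay represented and the
#' randomized comparison within the subgroup remains valid.
#'
#' @param scores Predicted probabilities, one per target-trial row.
#' @param cutoff Probability threshold (boundary inclusive).
#' @return Integer row indices.
#' @export
select_subgroup <- function(scores, cutoff) {
  which(scores >= cutoff)
}

#' Covariate-adjusted treatment effect in one subgroup
#'
#' Fits the linear model `delta_hba1c ~ arm + adjustment covariates`
#' (Gaussian family, identity link) and reports the treatment-vs-control
#' coefficient with its t-based Wald 95% confidence interval and p-value.
#' With no adjusters this equals the difference in arm means. Aliased
#' adjusters are dropped with a warning; a subgroup with an empty arm or
#' fewer than `p + 5` rows per arm (p = number of adjusters) is flagged
#' non-estimable instead of fitted.
#'
#' @param data Subgroup rows: `arm`, `delta_hba1c`, adjustment columns.
#' @param adjustment Character vector of covariate names (may be empty).
#' @param min_per_arm Minimum rows per arm; default `length(adjustment) + 5`.
#' @return One-row tibble: `n_treatment`, `n_control`, `effect`, `ci_low`,
#'   `ci_high`, `p_value`, `estimable`.
#' @export
estimate_effect <- function(data, adjustment = character(),
                            min_per_arm = length(adjustment) + 5) {
  adjustment <- intersect(adjustment, names(data))
  n_t <- sum(data$arm == "treatment")
  n_c <- sum(data$arm == "control")
  not_est <- tibble::tibble(n_treatment = n_t, n_control = n_c,
                            effect = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            estimable = FALSE)
  if (n_t < max(1, min_per_arm) || n_c < max(1, min_per_arm)) return(not_est)
  df <- data.frame(
    delta_hba1c = data$delta_hba1c,
    arm = factor(data$arm, levels = c("control", "treatment")),
    data[adjustment], check.names = FALSE
  )
  fit <- stats::lm(delta_hba1c ~ ., data = df)
  cf <- stats::coef(fit)
  if (is.na(cf["armtreatment"])) return(not_est)
  if (anyNA(cf)) {
    warning("aliased adjustment column(s) dropped: ",
            paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  est <- sm["armtreatment", "Estimate"]
  se <- sm["armtreatment", "Std. Error"]
  tcrit <- stats::qt(0.975, df = fit$df.residual)
  p <- sm["armtreatment", "Pr(>|t|)"]
  if (is.nan(se) || se == 0) {  # degenerate: outcome constant within arms
    se <- 0; p <- NA_real_
  }
  tibble::tibble(n_treatment = n_t, n_control = n_c, effect = est,
                 ci_low = est - tcrit * se, ci_high = est + tcrit * se,
                 p_value = p, estimable = TRUE)
}

#' Sweep probability cut-offs over nested target-trial subgroups
#'
#' For each cut-off in ascending order, selects the subgroup of
#' target-trial patients scoring at least that probability and estimates the
#' adjusted treatment effect inside it. The subgroups are nested by
#' construction (a higher cut-off keeps a subset); this is asserted and
#' recorded. The sweep stops at the first non-estimable cut-off. The best
#' cut-off is the estimable one with the largest beneficial effect (most
#' negative adjusted difference in HbA1c change).
#'
#' @param target Target-trial tibble (`arm`, `delta_hba1c`, covariates).
#' @param scores Predicted responder probabilities, one per row of `target`.
#' @param grid Cut-off grid from [roc_cutoffs()].
#' @param adjustment Covariates to adjust for; names absent from `target`
#'   are dropped with a warning.
#' @return Object of class `threshold_sweep`: tibble of per-cutoff effects
#'   plus attributes `best_cutoff`, `nested`, `full_sample_effect`.
#' @export
sweep_thresholds <- function(target, scores, grid = NULL,
                             adjustment = character()) {
  if (length(scores) != nrow(target)) {
    stop("scores must have one value per target row", call. = FALSE)
  }
  if (is.null(grid)) grid <- roc_cutoffs(scores)
  if (is.unsorted(grid, strictly = TRUE) || grid[1] != 0) {
    stop("grid must be strictly ascending and start at 0", call. = FALSE)
  }
  absent <- setdiff(adjustment, names(target))
  if (length(absent)) {
    warning("adjustment covariate(s) not in target, dropped: ",
            paste(absent, collapse = ", "), call. = FALSE)
    adjustment <- setdiff(adjustment, absent)
  }

  rows <- list()
  prev_set <- NULL
  nested <- TRUE
  for (cut in grid) {
    idx <- select_subgroup(scores, cut)
    if (!is.null(prev_set)) nested <- nested && all(idx %in% prev_set)
    prev_set <- idx
    eff <- estimate_effect(target[idx, , drop = FALSE], adjustment)
    eff <- dplyr::mutate(eff, cutoff = cut, n = length(idx), .before = 1)
    if (!eff$estimable) {
      message("cut-off ", signif(cut, 4),
              " not estimable (subgroup too small); sweep truncated")
      break
    }
    rows[[length(rows) + 1]] <- eff
  }
  if (!length(rows)) stop("no estimable cut-off in the grid", call. = FALSE)
  res <- dplyr::bind_rows(rows)
  stopifnot(nested)  # by construction of score >= cutoff selection
  structure(res,
            best_cutoff = res$cutoff[which.min(res$effect)],
            nested = nested,
            full_sample_effect = res$effect[res$cutoff == 0],
            class = c("threshold_sweep", class(res)))
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Threshold sweep over", nrow(x), "cut-offs; best cut-off",
      signif(attr(x, "best_cutoff"), 4), "\n")
  NextMethod()
}

#' Tidy a threshold sweep
#'
#' @param x A `threshold_sweep`.
#' @param ... Unused.
#' @return Plain tibble: `cutoff`, `n`, `n_treatment`, `n_control`,
#'   `effect`, `ci_low`, `ci_high`, `p_value`.
#' @method tidy threshold_sweep
#' @export
tidy.threshold_sweep <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("cutoff", "n", "n_treatment", "n_control",
                                 "effect", "ci_low", "ci_high", "p_value")])
}

#' One-row sweep summary
#'
#' @param x A `threshold_sweep`.
#' @param ... Unused.
#' @return Tibble: `n_cutoffs`, `best_cutoff`, `best_effect`, `best_n`,
#'   `full_sample_effect`.
#' @method glance threshold_sweep
#' @export
glance.threshold_sweep <- function(x, ...) {
  b <- attr(x, "best_cutoff")
  tibble::tibble(
    n_cutoffs = nrow(x), best_cutoff = b,
    best_effect = x$effect[x$cutoff == b],
    best_n = x$n[x$cutoff == b],
    full_sample_effect = attr(x, "full_sample_effect")
  )
}

#' Pearson chi-squared test on a 2x2 responder table
#'
#' Compares responder counts between two arms, by default without continuity
#' correction (which reproduces the published contingency p-values); the
#' Yates-corrected variant is available by flag.
#'
#' @param responders Length-2 vector of responder counts per arm.
#' @param totals Length-2 vector of arm sizes.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' contingency_test(c(57, 81), c(193, 192))
contingency_test <- function(responders, totals, correct = FALSE) {
  stopifnot(length(responders) == 2, length(totals) == 2,
            all(responders >= 0), all(responders <= totals))
  tab <- rbind(responders, totals - responders)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin", call. = FALSE)
  }
  ht <- stats::chisq.test(tab, correct = correct)
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' Per-arm baseline summary table
#'
#' Continuous variables as 1st quartile/median/3rd quartile (type-7
#' quantiles) per arm with a two-sided Wilcoxon rank-sum comparison; binary
#' variables as count and percentage per arm with a chi-squared comparison.
#'
#' @param trial Trial tibble.
#' @param schema A [covariate_schema()].
#' @param include_outcome Also summarize `delta_hba1c` (default `TRUE`).
#' @return Tibble: `variable`, `kind`, `treatment`, `control`, `p_value`.
#' @export
group_summary <- function(trial, schema = default_schema(),
                          include_outcome = TRUE) {
  vars <- intersect(schema_vars(schema), names(trial))
  kinds <- stats::setNames(schema$kind[match(vars, schema$variable)], vars)
  if (include_outcome && "delta_hba1c" %in% names(trial)) {
    vars <- c(vars, "delta_hba1c")
    kinds <- c(kinds, delta_hba1c = "continuous")
  }
  fmt_cont <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    sprintf("%.2f/%.2f/%.2f", q[1], q[2], q[3])
  }
  fmt_bin <- function(x) {
    x <- x[!is.na(x)]
    sprintf("%.0f%% (%d)", 100 * mean(x), sum(x))
  }
  purrr::map_dfr(vars, function(v) {
    xt <- trial[[v]][trial$arm == "treatment"]
    xc <- trial[[v]][trial$arm == "control"]
    if (kinds[[v]] == "continuous") {
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(xt, xc, exact = FALSE)$p.value),
        error = function(e) NA_real_
      )
      tibble::tibble(variable = v, kind = "continuous",
                     treatment = fmt_cont(xt), control = fmt_cont(xc),
                     p_value = p)
    } else {
      p <- tryCatch(
        suppressWarnings(
          contingency_test(c(sum(xt, na.rm = TRUE), sum(xc, na.rm = TRUE)),
                           c(sum(!is.na(xt)), sum(!is.na(xc))))$p_value
        ),
        error = function(e) NA_real_
      )
      tibble::tibble(variable = v, kind = "binary",
                     treatment = fmt_bin(xt), control = fmt_bin(xc),
                     p_value = p)
    }
  })
}

#' Standardized mean differences between arms of a subgroup
#'
#' Balance diagnostic for a selected subgroup: per covariate, the difference
#' in arm means divided by the pooled standard deviation (binary variables
#' use the binomial variance). No pass/fail threshold is applied.
#'
#' @param data Subgroup rows with `arm` and covariates.
#' @param vars Covariate names to assess.
#' @return Tibble: `variable`, `smd`.
#' @export
balance_table <- function(data, vars) {
  vars <- intersect(vars, names(data))
  purrr::map_dfr(vars, function(v) {
    xt <- data[[v]][data$arm == "treatment"]
    xc <- data[[v]][data$arm == "control"]
    s <- sqrt((stats::var(xt, na.rm = TRUE) + stats::var(xc, na.rm = TRUE)) / 2)
    d <- (mean(xt, na.rm = TRUE) - mean(xc, na.rm = TRUE)) / max(s, .Machine$double.eps)
    tibble::tibble(variable = v, smd = d)
  })
}
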