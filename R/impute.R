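#' Monotone visit sequence
#'
#' Order in which the chained-equations sweep visits incomplete variables:
#' ascending by missing count (fully observed variables are skipped), ties
#' broken by the supplied schema order.
#'
#' @param missing_counts Named integer vector of per-variable missing counts.
#' @param schema_order Character vector giving the tie-break order; defaults
#'   to the order of `missing_counts`.
#' @return Character vector of variable names.
#' @export
#' @examples
#' monotone_visit_sequence(c(x1 = 0, x2 = 5, x3 = 2))
monotone_visit_sequence <- function(missing_counts,
                                    schema_order = names(missing_counts)) {
  stopifnot(!is.null(names(missing_counts)), all(missing_counts >= 0))
  vars <- names(missing_counts)[missing_counts > 0]
  vars[order(missing_counts[vars], match(vars, schema_order))]
}

# One RF imputation of `var` given current completed covariates: fit on rows
# where `var` is observed, then for each missing row draw a donor from the
# terminal-node co-occupants of a randomly chosen tree (continuous), or a
# Bernoulli draw from the forest class probability (binary).
#' @keywords internal
rf_impute_one <- function(completed, var, obs_rows, miss_rows, kind, rf_trees,
                          seed) {
  preds <- setdiff(names(completed), var)
  form <- stats::as.formula(paste0("`", var, "` ~ ."))
  train <- completed[obs_rows, c(var, preds)]
  if (kind == "binary") {
    train[[var]] <- factor(train[[var]], levels = c(0, 1))
    fit <- ranger::ranger(form, data = train, num.trees = rf_trees,
                          probability = TRUE, seed = seed, num.threads = 1)
    p1 <- predict(fit, completed[miss_rows, preds, drop = FALSE],
                  num.threads = 1)$predictions[, "1"]
    as.numeric(stats::runif(length(miss_rows)) < p1)
  } else {
    fit <- ranger::ranger(form, data = train, num.trees = rf_trees,
                          seed = seed, num.threads = 1)
    node_obs <- predict(fit, train, type = "terminalNodes",
                        num.threads = 1)$predictions
    node_mis <- predict(fit, completed[miss_rows, , drop = FALSE],
                        type = "terminalNodes", num.threads = 1)$predictions
    obs_vals <- completed[[var]][obs_rows]
    tree <- sample.int(rf_trees, length(miss_rows), replace = TRUE)
    vapply(seq_along(miss_rows), function(i) {
      donors <- obs_vals[node_obs[, tree[i]] == node_mis[i, tree[i]]]
      if (!length(donors)) donors <- obs_vals
      donors[sample.int(length(donors), 1)]
    }, numeric(1))
  }
}

#' Chained-equations imputation with random-forest draws
#'
#' Multivariate imputation by chained equations for the covariate columns of
#' a trial table, with a random forest as the elementary imputation method
#' and a monotone visit sequence (variables sorted by increasing
#' missingness). Each sweep revisits every incomplete variable: a forest of
#' that variable on all other covariates is fitted on its observed rows, and
#' missing entries are filled stochastically — a donor drawn from the target
#' row's terminal-node co-occupants for continuous variables, a Bernoulli
#' draw from the forest class probability for binary ones. Cells start from
#' a random draw of the observed marginal. The outcome and arm columns never
#' enter the imputation model: the fitted outcome model must score
#' covariates that were completed without looking at treatment or response.
#'
#' @param trial Trial tibble (or any data frame containing the schema's
#'   covariate columns).
#' @param schema A [covariate_schema()]; only its variables are imputed.
#' @param n_iterations Chained-equation sweeps (default 10).
#' @param m Number of completed datasets (default 1, the dataset the
#'   transferred model is scored on; for `m > 1` downstream effect estimates
#'   can be averaged).
#' @param rf_trees Trees per elementary forest (default 100).
#' @param seed Integer seed; fixed seed reproduces the imputations exactly.
#' @return List of class `mice_result`: `completed` (list of `m` tibbles with
#'   no missing covariate cells, observed cells untouched), `missing_counts`,
#'   `visit_sequence`, and `trace` (per sweep/variable mean of imputed
#'   values).
#' @export
mice_rf_impute <- function(trial, schema = default_schema(),
                           n_iterations = 10, m = 1, rf_trees = 100,
                           seed = 1L) {
  stopifnot(n_iterations >= 1, m >= 1, rf_trees >= 1)
  vars <- intersect(schema_vars(schema), names(trial))
  if (!length(vars)) stop("no schema covariates found in `trial`", call. = FALSE)
  kinds <- stats::setNames(schema$kind[match(vars, schema$variable)], vars)

  miss <- vapply(trial[vars], function(x) sum(is.na(x)), integer(1))
  if (any(miss == nrow(trial))) {
    stop("covariate(s) 100% missing: ",
         paste(names(miss)[miss == nrow(trial)], collapse = ", "), call. = FALSE)
  }
  if (!any(miss == 0)) {
    stop("at least one fully observed covariate is required", call. = FALSE)
  }
  visit <- monotone_visit_sequence(miss, vars)

  if (!length(visit)) {
    return(structure(list(completed = rep(list(tibble::as_tibble(trial)), m),
                          missing_counts = miss, visit_sequence = character(),
                          trace = tibble::tibble()),
                     class = "mice_result"))
  }

  run_chain <- function(chain_seed) {
    withr::with_seed(chain_seed, {
      completed <- tibble::as_tibble(trial)
      miss_idx <- lapply(trial[vars], function(x) which(is.na(x)))
      for (v in visit) {  # initial fill from the observed marginal
        obs <- completed[[v]][-miss_idx[[v]]]
        completed[[v]][miss_idx[[v]]] <-
          obs[sample.int(length(obs), length(miss_idx[[v]]), replace = TRUE)]
      }
      trace <- vector("list", n_iterations * length(visit)); ti <- 1
      for (it in seq_len(n_iterations)) {
        for (v in visit) {
          mi <- miss_idx[[v]]
          oi <- setdiff(seq_len(nrow(completed)), mi)
          completed[[v]][mi] <- rf_impute_one(
            completed[vars], v, oi, mi, kinds[[v]], rf_trees,
            seed = sample.int(.Machine$integer.max, 1)
          )
          trace[[ti]] <- tibble::tibble(sweep = it, variable = v,
                                        mean_imputed = mean(completed[[v]][mi]))
          ti <- ti + 1
        }
      }
      list(completed = completed, trace = dplyr::bind_rows(trace))
    })
  }

  chains <- lapply(seq_len(m), function(i) run_chain(derive_subseed(seed, i)))
  structure(
    list(completed = lapply(chains, `[[`, "completed"),
         missing_counts = miss, visit_sequence = visit,
         trace = dplyr::bind_rows(lapply(seq_along(chains), function(i) {
           dplyr::mutate(chains[[i]]$trace, imputation = i, .before = 1)
         }))),
    class = "mice_result"
  )
}

#' @export
print.mice_result <- function(x, ...) {
  cat("Chained-equations RF imputation\n")
  cat("  completed datasets:", length(x$completed), "\n")
  cat("  visit sequence:", if (length(x$visit_sequence))
    paste(x$visit_sequence, collapse = " -> ") else "(nothing to impute)", "\n")
  inc <- x$missing_counts[x$missing_counts > 0]
  if (length(inc)) {
    cat("  missing before:",
        paste(sprintf("%s=%d", names(inc), inc), collapse = ", "), "\n")
  }
  invisible(x)
}
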