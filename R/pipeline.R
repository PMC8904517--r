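#' Read a trial table from CSV
#'
#' Expects a header row, an `arm` column coded `"treatment"`/`"control"`
#' (or values mapped through `relabel`), numeric covariate and outcome
#' columns with dot decimals, and empty fields for missing cells.
#'
#' @param path CSV file path.
#' @param schema A [covariate_schema()] used to validate columns.
#' @param relabel Optional named character vector mapping foreign arm codes
#'   to `"treatment"`/`"control"`, e.g. `c(sitagliptin = "treatment")`.
#' @return Trial tibble.
#' @export
read_trial_csv <- function(path, schema = default_schema(), relabel = NULL) {
  spec <- readr::cols(.default = readr::col_double(),
                      patient_id = readr::col_character(),
                      arm = readr::col_character())
  trial <- readr::read_csv(path, col_types = spec, na = "")
  pr <- readr::problems(trial)
  if (nrow(pr)) {
    stop("unparseable cell(s) in ", path, ": row ", pr$row[1], ", column ",
         pr$col[1], " (", pr$expected[1], ")", call. = FALSE)
  }
  if (!is.null(relabel)) {
    hit <- trial$arm %in% names(relabel)
    trial$arm[hit] <- unname(relabel[trial$arm[hit]])
  }
  check_trial(trial, schema, what = path)
  trial
}

#' Write a trial table to CSV
#'
#' Missing cells are written as empty fields; the file round-trips through
#' [read_trial_csv()] losslessly.
#'
#' @param trial Trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  readr::write_csv(trial, path, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs: the two trials (as
#' [trial_config()] objects to simulate, or CSV paths to read), the
#' responder rule, the learner menu, cross-validation and imputation
#' settings, and the adjustment covariates for the subgroup effect models.
#' The default adjustment set mirrors the variables used to balance
#' allocation in the target trial; names absent from the shared schema are
#' simply dropped at sweep time with a warning.
#'
#' @param source,target [trial_config()] or CSV path.
#' @param schema Shared [covariate_schema()].
#' @param rule [responder_rule()].
#' @param menu Learner menu (list of [learner_spec()]).
#' @param k Cross-validation folds.
#' @param impute List: `n_iterations`, `m`, `rf_trees`.
#' @param adjustment Covariate names for the per-subgroup linear models.
#' @param max_grid Cap on the cut-off grid length.
#' @param seed Integer master seed for every stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(source, target,
                            schema = default_schema(),
                            rule = responder_rule(),
                            menu = default_learner_menu(),
                            k = 5,
                            impute = list(n_iterations = 10, m = 1, rf_trees = 100),
                            adjustment = c("age", "male", "sbp", "hba1c_baseline"),
                            max_grid = 50,
                            seed = 1L) {
  structure(list(source = source, target = target, schema = schema,
                 rule = rule, menu = menu, k = k, impute = impute,
                 adjustment = adjustment, max_grid = max_grid,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @keywords internal
resolve_trial <- function(x, schema, stream, seed) {
  if (inherits(x, "trial_config")) {
    x$seed <- derive_subseed(seed, stream)
    simulate_trial(x, schema)
  } else if (is.character(x)) {
    read_trial_csv(x, schema)
  } else {
    stop("trial input must be a trial_config or a CSV path", call. = FALSE)
  }
}

#' Run the full transfer analysis end to end
#'
#' Simulates (or reads) the source and target trials, restricts the source
#' to its treated arm with an observed outcome and dichotomizes the outcome,
#' imputes any missing target covariates by chained-equations random
#' forests, fits the Super Learner on the source arm, scores every target
#' patient's responder probability, and sweeps the training-score cut-offs
#' over nested target subgroups. All artifacts are written under `out_dir`
#' (`source.csv`, `target.csv`, `table1.csv`, `sweep.csv`, `summary.csv`)
#' together with `manifest.json` listing every output with an MD5 digest,
#' the seed, and headline numbers. Two runs from one config produce
#' byte-identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `source`, `target`, `sl`, `scores`,
#'   `sweep`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schema <- config$schema
  seed <- config$seed

  source_raw <- resolve_trial(config$source, schema, 101L, seed)
  target_raw <- resolve_trial(config$target, schema, 102L, seed)

  source_trt <- filter_analysis_set(source_raw, arm_filter = "treatment")
  target <- filter_analysis_set(target_raw)

  if (anyNA(source_trt[schema_vars(schema)])) {
    source_trt[schema_vars(schema)] <- mice_rf_impute(
      source_trt, schema, n_iterations = config$impute$n_iterations,
      m = 1, rf_trees = config$impute$rf_trees,
      seed = derive_subseed(seed, 103L)
    )$completed[[1]][schema_vars(schema)]
  }
  imp <- NULL
  if (anyNA(target[schema_vars(schema)])) {
    imp <- mice_rf_impute(target, schema,
                          n_iterations = config$impute$n_iterations,
                          m = config$impute$m,
                          rf_trees = config$impute$rf_trees,
                          seed = derive_subseed(seed, 104L))
    target <- imp$completed[[1]]
  }

  source_trt <- add_responder(source_trt, config$rule)
  sl <- fit_super_learner(config$menu, source_trt[schema_vars(schema)],
                          source_trt$responder, k = config$k,
                          seed = derive_subseed(seed, 105L))
  scores <- predict(sl, target[schema_vars(schema)])
  grid <- roc_cutoffs(sl$oof_ensemble, max_size = config$max_grid)
  swp <- sweep_thresholds(target, scores, grid, adjustment = config$adjustment)

  paths <- c(source = file.path(out_dir, "source.csv"),
             target = file.path(out_dir, "target.csv"),
             table1 = file.path(out_dir, "table1.csv"),
             sweep = file.path(out_dir, "sweep.csv"),
             summary = file.path(out_dir, "summary.csv"))
  write_trial_csv(source_trt, paths["source"])
  write_trial_csv(target, paths["target"])
  readr::write_csv(tidy.super_learner(sl), paths["table1"])
  readr::write_csv(tidy.threshold_sweep(swp), paths["sweep"])
  readr::write_csv(group_summary(target, schema), paths["summary"])

  manifest <- list(
    seed = seed,
    n_source_treated = nrow(source_trt),
    n_source_dropped_outcome = attr(source_trt, "n_dropped_outcome"),
    n_target = nrow(target),
    n_target_dropped_outcome = attr(target, "n_dropped_outcome"),
    n_imputed_cells = if (is.null(imp)) 0 else sum(imp$missing_counts),
    dropped_learners = sl$dropped,
    cv_auc = sl$cv_auc,
    best_cutoff = attr(swp, "best_cutoff"),
    best_effect = glance.threshold_sweep(swp)$best_effect,
    files = lapply(as.list(paths), function(p) {
      list(path = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(source = source_trt, target = target, sl = sl,
                 scores = scores, sweep = swp, manifest = manifest))
}
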