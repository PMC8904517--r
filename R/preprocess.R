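#' Responder rule
#'
#' A clinically significant improvement is a drop in HbA1c of at least half a
#' percentage point (0.5% is about 5.5 mmol/mol). The comparison is inclusive
#' by default (`delta_hba1c <= -0.5` counts as response); an exclusive
#' variant is available since published descriptions use both readings.
#'
#' @param threshold Change-in-HbA1c cut-point in % units (default -0.5).
#' @param comparison `"at_most"` (<=, default) or `"less_than"` (<).
#' @return List of class `responder_rule`.
#' @export
responder_rule <- function(threshold = -0.5,
                           comparison = c("at_most", "less_than")) {
  comparison <- match.arg(comparison)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  structure(list(threshold = threshold, comparison = comparison),
            class = "responder_rule")
}

#' Add derived clinical flags
#'
#' Row-local derived variables: hypertension (SBP >= 130 mmHg or
#' DBP >= 80 mmHg), total cholesterol (LDL + HDL + triglyceride/5, mg/dl) and
#' dyslipidemia (LDL >= 130 or HDL < 35 or triglyceride >= 150 or total
#' cholesterol >= 200). Rows with a missing input get `NA` flags: in the
#' pipeline the flags are computed after covariate imputation.
#'
#' @param data Data frame with `sbp`, `dbp`, `ldl`, `hdl`, `triglyceride`.
#' @return The input with `hypertension`, `total_cholesterol`,
#'   `dyslipidemia` columns appended (binary flags as 0/1).
#' @export
#' @examples
#' add_derived_flags(tibble::tibble(sbp = 130, dbp = 70, ldl = 100,
#'                                  hdl = 50, triglyceride = 150))
add_derived_flags <- function(data) {
  need <- c("sbp", "dbp", "ldl", "hdl", "triglyceride")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(
    data,
    hypertension = as.numeric(.data$sbp >= 130 | .data$dbp >= 80),
    total_cholesterol = .data$ldl + .data$hdl + .data$triglyceride / 5,
    dyslipidemia = as.numeric(.data$ldl >= 130 | .data$hdl < 35 |
                                .data$triglyceride >= 150 |
                                .data$total_cholesterol >= 200)
  )
}

#' Dichotomize the continuous outcome into responder status
#'
#' @param delta_hba1c Numeric vector of HbA1c changes (% units, no missing
#'   values; filter the analysis set first).
#' @param rule A [responder_rule()].
#' @return Integer vector, 1 = responder.
#' @export
dichotomize_outcome <- function(delta_hba1c, rule = responder_rule()) {
  if (anyNA(delta_hba1c)) {
    stop("delta_hba1c contains missing values; run filter_analysis_set() first",
         call. = FALSE)
  }
  if (rule$comparison == "at_most") {
    as.integer(delta_hba1c <= rule$threshold)
  } else {
    as.integer(delta_hba1c < rule$threshold)
  }
}

#' Add a responder column to a trial table
#'
#' @param data Data frame with a `delta_hba1c` column (no missing outcomes).
#' @param rule A [responder_rule()].
#' @return `data` with an integer `responder` column appended.
#' @export
add_responder <- function(data, rule = responder_rule()) {
  dplyr::mutate(data, responder = dichotomize_outcome(.data$delta_hba1c, rule))
}

#' Filter to the analyzable patient set
#'
#' Drops rows whose follow-up outcome was never measured (missing
#' `delta_hba1c`), optionally restricts to one arm, and records the
#' accounting in attributes. Retained rows are returned unaltered.
#'
#' @param trial Trial tibble with `arm` and `delta_hba1c`.
#' @param arm_filter Optional `"treatment"` or `"control"`.
#' @return Filtered tibble with attributes `n_input`, `n_dropped_outcome`,
#'   `n_dropped_arm`.
#' @export
#' @examples
#' tr <- simulate_trial(trial_config(n_patients = 48,
#'                                   outcome_missing_rate = 0.1, seed = 9))
#' nrow(filter_analysis_set(tr))
filter_analysis_set <- function(trial, arm_filter = NULL) {
  n_in <- nrow(trial)
  out <- trial
  n_arm <- 0L
  if (!is.null(arm_filter)) {
    arm_filter <- match.arg(arm_filter, c("treatment", "control"))
    out <- dplyr::filter(out, .data$arm == arm_filter)
    n_arm <- n_in - nrow(out)
  }
  n_before <- nrow(out)
  out <- dplyr::filter(out, !is.na(.data$delta_hba1c))
  n_out <- n_before - nrow(out)
  if (nrow(out) == 0) stop("no analyzable patients", call. = FALSE)
  attr(out, "n_input") <- n_in
  attr(out, "n_dropped_arm") <- n_arm
  attr(out, "n_dropped_outcome") <- n_out
  out
}
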