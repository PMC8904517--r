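#' Covariate schema for a trial table
#'
#' A schema is a tibble with one row per baseline variable, giving its name,
#' kind (`"continuous"` or `"binary"`) and measurement unit. Both trials in a
#' paired analysis must share one schema: the outcome model is trained on the
#' source trial and scores target-trial patients on the same columns.
#'
#' @param variables Tibble or data frame with columns `variable`, `kind`,
#'   `unit`. Defaults to [default_schema()].
#' @return A tibble of class `cov_schema`.
#' @export
#' @examples
#' covariate_schema()
covariate_schema <- function(variables = default_schema()) {
  sch <- tibble::as_tibble(variables)
  req <- c("variable", "kind", "unit")
  if (!all(req %in% names(sch))) {
    stop("schema must have columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sch$variable)) {
    stop("schema variable names must be unique", call. = FALSE)
  }
  if (!all(sch$kind %in% c("continuous", "binary"))) {
    stop("schema kind must be 'continuous' or 'binary'", call. = FALSE)
  }
  class(sch) <- c("cov_schema", class(sch))
  sch
}

#' Default shared covariate schema
#'
#' The eleven baseline measures collected by both trials: age, sex, BMI,
#' blood pressures, lipids, glycaemic markers and adiponectin.
#'
#' @return A tibble with columns `variable`, `kind`, `unit`.
#' @export
default_schema <- function() {
  tibble::tribble(
    ~variable,        ~kind,        ~unit,
    "age",            "continuous", "years",
    "male",           "binary",     "",
    "bmi",            "continuous", "kg/m2",
    "sbp",            "continuous", "mmHg",
    "dbp",            "continuous", "mmHg",
    "ldl",            "continuous", "mg/dl",
    "hdl",            "continuous", "mg/dl",
    "triglyceride",   "continuous", "mg/dl",
    "hba1c_baseline", "continuous", "%",
    "fpg",            "continuous", "mmol/l",
    "adiponectin",    "continuous", "mg/l"
  ) |> covariate_schema()
}

#' @keywords internal
schema_vars <- function(schema) schema$variable

# Check that a trial tibble carries exactly the schema's covariate columns
# (plus patient_id, arm, delta_hba1c); errors name what is missing/extra.
#' @keywords internal
check_trial <- function(trial, schema, what = "trial") {
  need <- c("patient_id", "arm", schema_vars(schema), "delta_hba1c")
  missing_cols <- setdiff(need, names(trial))
  if (length(missing_cols)) {
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(trial$arm))) stop("arm must be non-missing for every row", call. = FALSE)
  bad <- setdiff(unique(trial$arm), c("treatment", "control"))
  if (length(bad)) {
    stop("arm values outside {treatment, control}: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(trial)
}
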