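#' Default covariate generating parameters
#'
#' Location-scale generating laws for each schema variable, calibrated so that
#' simulated marginal quartiles approximate the published baseline summaries
#' of the two trials: normal draws for roughly symmetric measures, log-normal
#' for the right-skewed ones (triglyceride, fasting plasma glucose,
#' adiponectin), Bernoulli(0.68) for male sex. These are marginal-only
#' calibrations; the joint law is independent unless a copula correlation is
#' supplied in the config.
#'
#' @return Tibble with columns `variable`, `dist` (`"norm"`, `"lnorm"`,
#'   `"bernoulli"`), `p1`, `p2` (mean/sd, meanlog/sdlog, or probability/NA).
#' @export
default_covariate_params <- function() {
  tibble::tribble(
    ~variable,        ~dist,       ~p1,          ~p2,
    "age",            "norm",      70,           8.9,
    "male",           "bernoulli", 0.68,         NA,
    "bmi",            "norm",      24.7,         3.45,
    "sbp",            "norm",      129,          16.3,
    "dbp",            "norm",      72,           11.9,
    "ldl",            "norm",      92.4,         24.9,
    "hdl",            "norm",      55,           14,
    "triglyceride",   "lnorm",     log(120),     0.51,
    "hba1c_baseline", "norm",      6.85,         0.52,
    "fpg",            "lnorm",     log(6.94),    0.218,
    "adiponectin",    "lnorm",     log(3.53),    0.78
  )
}

#' Configuration for one simulated trial
#'
#' Encodes the data-generating assumptions the downstream analysis relies on:
#' randomized arm assignment, a linear baseline covariate effect on the
#' outcome, a treatment effect `tau` with optional covariate-by-treatment
#' interactions `gamma` (heterogeneity), Gaussian outcome noise, and
#' configurable covariate/outcome missingness. Covariates are standardized by
#' their generating location and scale before `beta_main` and `gamma` are
#' applied, so `tau` is exactly the average treatment effect on the change in
#' HbA1c (in percentage-point units, negative = improvement) whatever the
#' interaction structure.
#'
#' @param n_patients Number of patients (positive integer).
#' @param allocation_ratio Probability of assignment to the treatment arm.
#' @param covariate_params Generating parameters per variable; see
#'   [default_covariate_params()].
#' @param beta_main Named vector: effects of standardized covariates on the
#'   outcome, both arms.
#' @param tau Average treatment effect on delta HbA1c (% units).
#' @param gamma Named vector of covariate-by-treatment interaction
#'   coefficients on the standardized scale; all zero means a homogeneous
#'   effect.
#' @param sigma Outcome noise standard deviation (> 0).
#' @param mu Outcome intercept (control-arm mean at covariate means).
#' @param missing_rate Per-covariate probability of a missing cell, in
#'   `[0, 1)`.
#' @param missing_mechanism `"MCAR"` (uniform) or `"MAR"` (missingness
#'   probability a logistic function of standardized age and baseline HbA1c,
#'   which stay fully observed).
#' @param outcome_missing_rate Probability that the follow-up outcome is
#'   missing, in `[0, 1)`.
#' @param tau_multiplier Per-trial scalar on `tau`, e.g. to encode a
#'   different follow-up horizon; default 1.
#' @param exact_split If `TRUE`, arms are filled to exact target sizes
#'   (differing by at most one) instead of independent Bernoulli draws.
#' @param copula Optional correlation matrix (Gaussian copula) over the
#'   schema variables; `NULL` means independent covariates.
#' @param seed Integer seed; the same config and seed reproduce the dataset
#'   exactly.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(n_patients,
                         allocation_ratio = 0.5,
                         covariate_params = default_covariate_params(),
                         beta_main = c(hba1c_baseline = -0.25),
                         tau = -0.4,
                         gamma = numeric(),
                         sigma = 0.6,
                         mu = -0.3,
                         missing_rate = 0,
                         missing_mechanism = c("MCAR", "MAR"),
                         outcome_missing_rate = 0,
                         tau_multiplier = 1,
                         exact_split = FALSE,
                         copula = NULL,
                         seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  chk(is.numeric(n_patients) && length(n_patients) == 1 && n_patients >= 1 &&
        n_patients == floor(n_patients), "n_patients", "must be a positive integer")
  chk(is.numeric(allocation_ratio) && allocation_ratio > 0 && allocation_ratio < 1,
      "allocation_ratio", "must be in (0, 1)")
  chk(is.numeric(sigma) && length(sigma) == 1 && sigma > 0, "sigma", "must be > 0")
  chk(all(is.finite(tau)) && length(tau) == 1, "tau", "must be a finite number")
  chk(length(gamma) == 0 || (all(is.finite(gamma)) && !is.null(names(gamma))),
      "gamma", "must be a named finite vector (or empty)")
  chk(length(beta_main) == 0 || (all(is.finite(beta_main)) && !is.null(names(beta_main))),
      "beta_main", "must be a named finite vector (or empty)")
  chk(missing_rate >= 0 && missing_rate < 1, "missing_rate", "must be in [0, 1)")
  chk(outcome_missing_rate >= 0 && outcome_missing_rate < 1,
      "outcome_missing_rate", "must be in [0, 1)")
  cp <- tibble::as_tibble(covariate_params)
  chk(all(c("variable", "dist", "p1", "p2") %in% names(cp)),
      "covariate_params", "needs columns variable, dist, p1, p2")
  cont <- cp$dist %in% c("norm", "lnorm")
  chk(all(is.finite(cp$p1)), "covariate_params", "every p1 must be finite")
  chk(all(is.finite(cp$p2[cont]) & cp$p2[cont] > 0),
      "covariate_params", "continuous variables need a positive spread (p2)")
  if (!is.null(copula)) {
    chk(is.matrix(copula) && nrow(copula) == nrow(cp) && isSymmetric(copula),
        "copula", "must be a symmetric matrix matching covariate_params rows")
  }
  structure(
    list(n_patients = as.integer(n_patients), allocation_ratio = allocation_ratio,
         covariate_params = cp, beta_main = beta_main, tau = tau, gamma = gamma,
         sigma = sigma, mu = mu, missing_rate = missing_rate,
         missing_mechanism = missing_mechanism,
         outcome_missing_rate = outcome_missing_rate,
         tau_multiplier = tau_multiplier, exact_split = exact_split,
         copula = copula, seed = as.integer(seed)),
    class = "trial_config"
  )
}

# mean/sd of each generating law, used to standardize before beta/gamma
#' @keywords internal
param_moments <- function(cp) {
  m <- numeric(nrow(cp)); s <- numeric(nrow(cp))
  for (i in seq_len(nrow(cp))) {
    if (cp$dist[i] == "norm") {
      m[i] <- cp$p1[i]; s[i] <- cp$p2[i]
    } else if (cp$dist[i] == "lnorm") {
      m[i] <- exp(cp$p1[i] + cp$p2[i]^2 / 2)
      s[i] <- m[i] * sqrt(exp(cp$p2[i]^2) - 1)
    } else {
      m[i] <- cp$p1[i]; s[i] <- sqrt(cp$p1[i] * (1 - cp$p1[i]))
    }
  }
  list(mean = stats::setNames(m, cp$variable), sd = stats::setNames(s, cp$variable))
}

#' @keywords internal
draw_covariates <- function(cp, n, copula = NULL) {
  k <- nrow(cp)
  if (is.null(copula)) {
    u <- matrix(stats::runif(n * k), n, k)
  } else {
    z <- matrix(stats::rnorm(n * k), n, k) %*% chol(copula)
    u <- stats::pnorm(z)
  }
  out <- vector("list", k)
  for (i in seq_len(k)) {
    out[[i]] <- switch(cp$dist[i],
      norm      = stats::qnorm(u[, i], cp$p1[i], cp$p2[i]),
      lnorm     = stats::qlnorm(u[, i], cp$p1[i], cp$p2[i]),
      bernoulli = as.numeric(u[, i] < cp$p1[i]),
      stop("unknown dist '", cp$dist[i], "'", call. = FALSE)
    )
  }
  names(out) <- cp$variable
  tibble::as_tibble(out)
}

#' Simulate one randomized trial
#'
#' Draws baseline covariates from the configured generating laws, assigns
#' arms at random, generates the continuous outcome
#' `delta_hba1c = mu + beta'z + (tau + gamma'z) * treated + noise` on
#' standardized covariates `z`, then applies covariate and outcome
#' missingness. Missing cells are `NA`; the same config yields the identical
#' tibble on every call.
#'
#' @param config A [trial_config()].
#' @param schema A [covariate_schema()]; its variables must match
#'   `config$covariate_params`.
#' @return Tibble with `patient_id`, `arm` (`"treatment"`/`"control"`), one
#'   column per schema variable, and `delta_hba1c`.
#' @export
#' @examples
#' tr <- simulate_trial(trial_config(n_patients = 100, seed = 42))
#' dplyr::count(tr, arm)
simulate_trial <- function(config, schema = default_schema()) {
  stopifnot(inherits(config, "trial_config"))
  cp <- config$covariate_params
  if (!setequal(cp$variable, schema_vars(schema))) {
    stop("covariate_params variables do not match the schema", call. = FALSE)
  }
  cp <- cp[match(schema_vars(schema), cp$variable), ]
  bad <- setdiff(c(names(config$beta_main), names(config$gamma)), cp$variable)
  if (length(bad)) {
    stop("invalid `beta_main`/`gamma`: unknown variable(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  withr::with_seed(config$seed, {
    n <- config$n_patients
    if (config$exact_split) {
      n_trt <- round(n * config$allocation_ratio)
      arm <- rep("control", n)
      arm[sample.int(n, n_trt)] <- "treatment"
    } else {
      arm <- ifelse(stats::runif(n) < config$allocation_ratio, "treatment", "control")
    }
    X <- draw_covariates(cp, n, config$copula)

    mom <- param_moments(cp)
    Z <- sweep(sweep(as.matrix(X), 2, mom$mean[colnames(X)]), 2,
               pmax(mom$sd[colnames(X)], .Machine$double.eps), "/")
    lin <- rep(config$mu, n)
    if (length(config$beta_main)) {
      lin <- lin + drop(Z[, names(config$beta_main), drop = FALSE] %*% config$beta_main)
    }
    te <- rep(config$tau * config$tau_multiplier, n)
    if (length(config$gamma)) {
      te <- te + drop(Z[, names(config$gamma), drop = FALSE] %*% config$gamma)
    }
    delta <- lin + te * (arm == "treatment") + stats::rnorm(n, 0, config$sigma)

    # missingness is applied after outcome generation
    if (config$missing_rate > 0) {
      maskable <- cp$variable
      if (config$missing_mechanism == "MAR") {
        maskable <- setdiff(maskable, c("age", "hba1c_baseline"))
        p_miss <- stats::plogis(stats::qlogis(config$missing_rate) +
                                  0.7 * Z[, "age"] + 0.7 * Z[, "hba1c_baseline"])
      } else {
        p_miss <- rep(config$missing_rate, n)
      }
      for (v in maskable) {
        X[[v]][stats::runif(n) < p_miss] <- NA_real_
      }
    }
    if (config$outcome_missing_rate > 0) {
      delta[stats::runif(n) < config$outcome_missing_rate] <- NA_real_
    }

    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("P%05d", seq_len(n)), arm = arm),
      X,
      tibble::tibble(delta_hba1c = delta)
    )
  })
}

#' @keywords internal
derive_subseed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 104729) %% 2147483647)
}

#' Simulate a source/target trial pair
#'
#' Draws two independent trials on one shared covariate schema, the setting
#' the transfer analysis assumes: the outcome model is trained on the source
#' trial's treated arm and scores the target trial. Sub-seeds for the two
#' trials are derived deterministically from each config's seed (distinct
#' streams), so identical configs still produce distinct datasets while the
#' whole pair is reproducible.
#'
#' @param source_config,target_config [trial_config()] objects; their
#'   covariate parameters must name the same schema variables.
#' @param schema Shared [covariate_schema()].
#' @return Named list with tibbles `source` and `target`.
#' @export
simulate_trial_pair <- function(source_config, target_config,
                                schema = default_schema()) {
  if (!setequal(source_config$covariate_params$variable,
                target_config$covariate_params$variable)) {
    stop("source and target configs do not share a covariate schema", call. = FALSE)
  }
  src <- source_config; src$seed <- derive_subseed(source_config$seed, 1L)
  tgt <- target_config; tgt$seed <- derive_subseed(target_config$seed, 2L)
  list(source = simulate_trial(src, schema), target = simulate_trial(tgt, schema))
}
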