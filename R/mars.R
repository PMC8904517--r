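# Adaptive hinge-basis regression: forward selection of hinge-function
# products (interaction degree capped, a variable at most once per term)
# followed by greedy backward pruning under the GCV criterion. Serves as the
# multivariate-adaptive-regression-splines slot of the learner menu; fitted
# by least squares on the 0/1 response, predictions clamped downstream.

#' @keywords internal
mars_term_col <- function(term, X) {
  col <- rep(1, nrow(X))
  for (cmp in term) {
    col <- col * pmax(cmp$sign * (X[, cmp$var] - cmp$knot), 0)
  }
  col
}

#' @keywords internal
fit_mars_hinge <- function(X, y, max_terms = 12, degree = 2, gcv_penalty = 3) {
  n <- nrow(X)
  knots <- lapply(seq_len(ncol(X)), function(j) {
    unique(stats::quantile(X[, j], probs = seq(0.1, 0.9, by = 0.2),
                           names = FALSE, type = 7))
  })
  cands <- list()
  for (j in seq_len(ncol(X))) {
    for (t in knots[[j]]) for (s in c(1, -1)) {
      cands[[length(cands) + 1]] <- list(var = j, sign = s, knot = t)
    }
  }

  terms <- list(list())              # intercept term
  B <- matrix(1, n, 1)
  rss <- sum((y - mean(y))^2)
  repeat {
    if (length(terms) >= max_terms) break
    best <- NULL
    for (parent in terms) {
      if (length(parent) >= degree) next
      used <- vapply(parent, `[[`, integer(1), "var")
      pcol <- mars_term_col(parent, X)
      for (cand in cands) {
        if (cand$var %in% used) next
        newcol <- pcol * pmax(cand$sign * (X[, cand$var] - cand$knot), 0)
        if (all(newcol == 0)) next
        fit <- stats::lm.fit(cbind(B, newcol), y)
        r <- sum(fit$residuals^2)
        if (is.null(best) || r < best$rss) {
          best <- list(term = c(parent, list(cand)), col = newcol, rss = r)
        }
      }
    }
    if (is.null(best) || rss - best$rss < 1e-10) break
    terms[[length(terms) + 1]] <- best$term
    B <- cbind(B, best$col)
    rss <- best$rss
  }

  gcv <- function(rss_k, k) {
    eff <- k + gcv_penalty * (k - 1) / 2
    if (eff >= n) return(Inf)
    (rss_k / n) / (1 - eff / n)^2
  }
  # greedy backward pass; keep the subset with the smallest GCV on the path
  keep <- seq_along(terms)
  best_keep <- keep
  best_gcv <- gcv(sum(stats::lm.fit(B[, keep, drop = FALSE], y)$residuals^2),
                  length(keep))
  cur <- keep
  while (length(cur) > 1) {
    step <- NULL
    for (drop_i in cur[-1]) {        # never drop the intercept
      sub <- setdiff(cur, drop_i)
      r <- sum(stats::lm.fit(B[, sub, drop = FALSE], y)$residuals^2)
      if (is.null(step) || r < step$rss) step <- list(sub = sub, rss = r)
    }
    cur <- step$sub
    g <- gcv(step$rss, length(cur))
    if (g < best_gcv) {
      best_gcv <- g
      best_keep <- cur
    }
  }

  terms <- terms[best_keep]
  Bk <- B[, best_keep, drop = FALSE]
  coefs <- stats::lm.fit(Bk, y)$coefficients
  coefs[is.na(coefs)] <- 0
  list(terms = terms, coefficients = unname(coefs), vars = colnames(X))
}

#' @keywords internal
predict_mars_hinge <- function(model, X) {
  X <- X[, model$vars, drop = FALSE]
  B <- vapply(model$terms, function(tm) mars_term_col(tm, X), numeric(nrow(X)))
  if (is.null(dim(B))) B <- matrix(B, nrow = 1)
  drop(B %*% model$coefficients)
}
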