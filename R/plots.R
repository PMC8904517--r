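#' Plot the cut-off sweep
#'
#' The per-subgroup adjusted treatment effect with its 95% confidence
#' interval against the probability cut-off, annotated with the subgroup
#' size below each point. A dashed horizontal line marks no effect.
#'
#' @param object A `threshold_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  df <- tidy.threshold_sweep(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$effect)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0, colour = "grey55") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_text(ggplot2::aes(y = min(.data$ci_low), label = .data$n),
                       vjust = 1.8, size = 2.7, colour = "grey30") +
    ggplot2::labs(
      x = "responder probability cut-off",
      y = expression(paste("adjusted treatment effect on ", Delta, "HbA1c (%)")),
      title = "Treatment effect in nested responder subgroups"
    ) +
    ggplot2::theme_minimal()
}

#' Outcome distributions by arm across cut-offs
#'
#' Boxplots of the change in HbA1c by arm, one panel per probability
#' cut-off, showing how the treated-arm distribution shifts as the subgroup
#' narrows to predicted responders.
#'
#' @param target Target-trial tibble.
#' @param scores Predicted responder probabilities, one per row.
#' @param cutoffs Cut-offs to panel (default quartiles of the scores with 0).
#' @return A ggplot object.
#' @export
plot_subgroup_outcomes <- function(target, scores,
                                   cutoffs = c(0, stats::quantile(scores, c(0.25, 0.5, 0.75),
                                                                  names = FALSE))) {
  cutoffs <- sort(unique(cutoffs))
  df <- purrr::map_dfr(cutoffs, function(cut) {
    idx <- select_subgroup(scores, cut)
    dplyr::mutate(target[idx, c("arm", "delta_hba1c")],
                  cutoff = sprintf("cut-off %.3f (n=%d)", cut, length(idx)))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$delta_hba1c,
                                   fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~cutoff, nrow = 1) +
    ggplot2::labs(x = NULL,
                  y = expression(paste(Delta, "HbA1c (%)"))) +
    ggplot2::theme_minimal()
}
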