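#' Error-bar figure for a replication study
#'
#' One panel of points and one-SD bars per estimator across coefficients,
#' with triangles marking the true values — the standard way to compare the
#' spread of a robust and a classical estimator under contamination.
#'
#' @param object A [run_replications()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.replication_summary <- function(object, ...) {
  eb <- error_bar_summary(object)
  eb$term <- factor(eb$term, levels = unique(eb$term))
  ggplot2::ggplot(eb, ggplot2::aes(x = .data$term, colour = .data$estimator)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
      width = 0.3, position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$mean),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$true), colour = "black",
                        shape = 17, size = 2) +
    ggplot2::labs(x = "coefficient", y = "estimate (mean ± SD)",
                  colour = "estimator") +
    ggplot2::theme_minimal()
}

#' Residual/weight diagnostic for an ESL fit
#'
#' Observation weights `exp(-r^2/gamma)` against residuals, with
#' pseudo-outliers highlighted: shows directly which observations the fit
#' down-weighted.
#'
#' @param object An `esl_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.esl_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$.resid, y = .data$.weight,
                                    colour = .data$.pseudo_outlier)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residual", y = "weight exp(-r²/γ)",
                  colour = "pseudo-outlier") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
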