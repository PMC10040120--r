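# ggplot2 displays: Bland-Altman scatter, imputation trace plots, and the
# method-comparison bar chart.

#' Bland-Altman plot of self-reported versus measured values
#'
#' Scatter of pairwise differences (self minus measured) against pair means,
#' with a solid line at the mean difference and dashed lines at the limits
#' of agreement (mean difference plus and minus 1.96 SD).
#'
#' @inheritParams bland_altman
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(self_vals, meas_vals, weights = NULL,
                              title = NULL) {
  rep <- bland_altman(self_vals, meas_vals, weights)
  df <- tibble::tibble(avg = (self_vals + meas_vals) / 2,
                       diff = self_vals - meas_vals)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = rep$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(rep$loa_lower, rep$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of self-reported and measured",
                  y = "Self-reported minus measured", title = title) +
    ggplot2::theme_minimal()
}

#' Trace plot of a chained imputation run
#'
#' Mean (or SD) of the imputed values per iteration, one line per
#' imputation chain, faceted by variable — the standard convergence display
#' for chained-equations runs.
#'
#' @param object A `completed_set` from [run_chained()].
#' @param statistic `"mean"` or `"sd"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.completed_set <- function(object, statistic = c("mean", "sd"), ...) {
  statistic <- match.arg(statistic)
  tr <- object$trace
  tr$value <- tr[[statistic]]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   group = .data$imputation,
                                   colour = factor(.data$imputation))) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "Iteration", y = paste(statistic, "of imputed values"),
                  colour = "Chain") +
    ggplot2::theme_minimal()
}

#' Method-comparison bar chart of prevalence estimates
#'
#' Prevalence of each indicator by estimation method, with error bars of one
#' standard error.
#'
#' @param object A `mime_pipeline` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mime_pipeline <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$indicator, y = .data$estimate,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$se,
                   ymax = .data$estimate + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Weighted prevalence", fill = "Method") +
    ggplot2::theme_minimal()
}
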