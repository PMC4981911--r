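#' Plot a performance summary
#'
#' Coverage view: one point per method and estimand with the nominal 95%
#' level (dotted) and the 90-97% acceptability band (dashed) used to judge
#' simulation performance. Bias view: percent bias per method with a zero
#' line.
#'
#' @param object A `crt_performance` summary from [run_scenario()].
#' @param metric `"coverage"` or `"bias"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crt_performance <- function(object, metric = c("coverage", "bias"),
                                     ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  df$method <- factor(toupper(df$method),
                      levels = c("CCA", "SMI", "FMI", "MMI"))
  if (metric == "coverage") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                     y = .data$coverage_pct)) +
      ggplot2::geom_hline(yintercept = 95, linetype = "dotted") +
      ggplot2::geom_hline(yintercept = c(90, 97), linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$coverage_pct - 2 * .data$mc_se_coverage,
        ymax = .data$coverage_pct + 2 * .data$mc_se_coverage)) +
      ggplot2::facet_wrap(ggplot2::vars(.data$term)) +
      ggplot2::labs(x = NULL, y = "95% CI coverage (%)",
                    title = "Coverage by missing-data method",
                    subtitle = "bars: +/- 2 Monte Carlo SE; band: 90-97% acceptability") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                     y = .data$percent_bias)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::geom_col(width = 0.6) +
      ggplot2::facet_wrap(ggplot2::vars(.data$term)) +
      ggplot2::labs(x = NULL, y = "Percent bias of treatment effect",
                    title = "Bias by missing-data method") +
      ggplot2::theme_minimal()
  }
}

#' Plot an incremental net benefit curve
#'
#' @param object A `crt_inb` tibble from [inb()] evaluated at one or more
#'   willingness-to-pay values.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crt_inb <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$lambda, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (per outcome unit)",
                  y = "Incremental net benefit",
                  title = "Incremental net benefit") +
    ggplot2::theme_minimal()
}
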