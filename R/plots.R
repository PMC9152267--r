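#' Tornado diagram of the one-way sensitivity analysis
#'
#' Horizontal bars spanning the ICER obtained at each parameter's low and
#' high bound, widest at the top, with the base-case ICER and the WTP
#' threshold as reference lines. Zero-width bars (fixed or irrelevant
#' parameters) are dropped by default.
#'
#' @param dsa Tibble from [one_way_dsa()].
#' @param base_icer Optional base-case ICER (vertical reference line).
#' @param wtp Optional WTP threshold (dashed reference line).
#' @param drop_zero_width Drop bars with zero width (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_tornado <- function(dsa, base_icer = NULL, wtp = NULL,
                         drop_zero_width = TRUE) {
  d <- dsa
  if (drop_zero_width) d <- d[d$width > 0, ]
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  p <- ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                   yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
  if (!is.null(base_icer)) {
    p <- p + ggplot2::geom_vline(xintercept = base_icer, colour = "grey30")
  }
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Incremental cost-effectiveness plane scatter of the PSA
#'
#' One point per Monte Carlo iteration on the (incremental QALY,
#' incremental cost) plane, with the WTP threshold as a line through the
#' origin.
#'
#' @param psa A `cea_psa`.
#' @param wtp WTP threshold drawn as a line (default the stored one).
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa, wtp = psa$wtp) {
  ggplot2::ggplot(psa$iterations,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.3, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed",
                         colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Probabilistic sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_tbl A CEAC tibble from [ceac()].
#' @param wtp Optional WTP threshold (vertical dashed line).
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl, wtp = NULL) {
  p <- ggplot2::ggplot(ceac_tbl,
                       ggplot2::aes(x = .data$wtp,
                                    y = .data$probability_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' @rdname plot_psa_scatter
#' @param object A `cea_psa`.
#' @param ... Unused.
#' @export
autoplot.cea_psa <- function(object, ...) {
  plot_psa_scatter(object)
}
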