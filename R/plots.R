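# Publication-shaped figures for the sensitivity and decision-uncertainty
# outputs.

#' Tornado diagram of one-way sensitivity results
#'
#' @param tornado An [owsa()] result.
#' @param top Number of parameters to show (by NMB swing).
#' @return A ggplot.
#' @export
plot_tornado <- function(tornado, top = 15) {
  df <- utils::head(tornado, top)
  # labels repeat across parameter groups (e.g. AE incidence vs disutility)
  lab <- make.unique(as.character(df$label), sep = " #")
  df$label <- factor(lab, levels = rev(lab))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$inmb_low, xend = .data$inmb_high,
                                       y = .data$label, yend = .data$label),
                          linewidth = 4, colour = "#9ecae1") +
    ggplot2::labs(x = "Incremental net monetary benefit (USD)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param acc A [ceac()] result.
#' @return A ggplot.
#' @export
plot_ceac <- function(acc) {
  ggplot2::ggplot(acc, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective", colour = "Strategy") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' EVPI curve
#'
#' @param ev An [evpi()] result.
#' @return A ggplot.
#' @export
plot_evpi <- function(ev) {
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$wtp, y = .data$evpi)) +
    ggplot2::geom_line(colour = "#31a354") +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "EVPI (USD per patient)") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter with a WTP ray
#'
#' @param cloud A `psa_cloud` with two strategies (intervention first in
#'   factor order of appearance).
#' @param wtp Willingness-to-pay threshold drawn as a ray.
#' @return A ggplot of incremental (QALY, cost) pairs.
#' @export
plot_psa_scatter <- function(cloud, wtp = 150000) {
  arms <- unique(cloud$strategy)
  wide_c <- tidyr::pivot_wider(cloud, id_cols = "draw", names_from = "strategy",
                               values_from = "cost")
  wide_q <- tidyr::pivot_wider(cloud, id_cols = "draw", names_from = "strategy",
                               values_from = "qaly")
  inc <- tibble::tibble(
    dq = wide_q[[arms[1]]] - wide_q[[arms[2]]],
    dc = wide_c[[arms[1]]] - wide_c[[arms[2]]]
  )
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$dq, y = .data$dc)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7, colour = "#3182bd") +
    ggplot2::geom_abline(intercept = 0, slope = wtp, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)") +
    ggplot2::theme_minimal()
}
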