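#' Plot a simulated evolutionary trajectory
#'
#' Frequency-weighted trait means against growth cycle, one panel per trait,
#' with the active environment shown as a colour strip along the x axis.
#'
#' @param object A `fusion_sim`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fusion_sim <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::filter(.data$statistic == "mean")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_rug(ggplot2::aes(colour = .data$env), sides = "b",
                      length = ggplot2::unit(0.02, "npc"),
                      data = long[long$trait == long$trait[1], ]) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "growth cycle", y = "population mean",
                  colour = "environment") +
    ggplot2::theme_minimal()
}

#' Plot an adaptive-dynamics flow trajectory
#'
#' @param object An `ad_flow`.
#' @param ... Unused.
#' @return A ggplot of the trajectory in the (m, alpha) plane.
#' @export
autoplot.ad_flow <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$alpha)) +
    ggplot2::geom_path(arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                       colour = "steelblue4") +
    ggplot2::labs(x = "daughter-cell mass m", y = "fusion rate alpha",
                  subtitle = paste("outcome:", attr(object, "outcome"))) +
    ggplot2::theme_minimal()
}

#' Plot the selection-gradient field
#'
#' Normalised arrows of the evolutionary flow over a trait grid, with the
#' fixed points overlaid.
#'
#' @param params An [ad_params()].
#' @param n Grid points per axis.
#' @param m_max,alpha_max Grid extent.
#' @return A ggplot.
#' @export
plot_flow_field <- function(params, n = 21, m_max = 2.5 * params$beta,
                            alpha_max = 10 / params$ET) {
  gf <- gradient_field(params,
                       m = seq(m_max / n, m_max, length.out = n),
                       alpha = seq(0, alpha_max, length.out = n))
  nrm <- sqrt(gf$Hm^2 + gf$Halpha^2)
  sc_m <- 0.4 * m_max / n
  sc_a <- 0.4 * alpha_max / n
  gf$dm <- sc_m * gf$Hm / pmax(nrm, 1e-300)
  gf$da <- sc_a * gf$Halpha / pmax(nrm, 1e-300)
  fp <- fixed_points(params)
  fp <- fp[is.finite(fp$alpha) & !is.na(fp$m) & fp$stability != "nonphysical", ]
  ggplot2::ggplot(gf, ggplot2::aes(x = .data$m, y = .data$alpha)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$m + .data$dm, yend = .data$alpha + .data$da),
      arrow = ggplot2::arrow(length = ggplot2::unit(1, "mm")),
      colour = "grey40") +
    ggplot2::geom_point(data = fp,
                        ggplot2::aes(shape = .data$stability),
                        colour = "red3", size = 3) +
    ggplot2::labs(x = "daughter-cell mass m", y = "fusion rate alpha") +
    ggplot2::theme_minimal()
}

#' Plot a facultative-fusion regime map
#'
#' @param map A tibble from [regime_map()].
#' @return A ggplot tile map over cost and harshness ratio.
#' @export
plot_regime_map <- function(map) {
  ggplot2::ggplot(map, ggplot2::aes(x = .data$C, y = .data$beta2_over_beta1,
                                    fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      both = "#4477aa", neither = "#cc6677",
      facultative_env2 = "#882e72", facultative_env1 = "#f4a6c8")) +
    ggplot2::labs(x = "fusion cost C",
                  y = expression(beta[2] / beta[1]),
                  fill = "fusion evolves in") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
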