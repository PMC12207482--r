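# ggplot2 views of the result types. Plots are conveniences; the tibbles
# are the contract.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an association trajectory
#'
#' Partner-type probabilities per iteration, with the cooperator mass
#' `gamma` overlaid.
#'
#' @param object A `partner_trajectory` from [trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot partner_trajectory
#' @export
autoplot.partner_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("iteration", dist_names)],
    -"iteration", names_to = "type", values_to = "probability")
  long$type <- factor(long$type, levels = dist_names,
                      labels = c("purple cooperator", "purple defector",
                                 "teal cooperator", "teal defector"))
  ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$probability,
                                     colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_manual(values = c(
      "purple cooperator" = "#7b3294", "purple defector" = "#c2a5cf",
      "teal cooperator" = "#008837", "teal defector" = "#a6dba0")) +
    ggplot2::labs(x = "iteration (race)", y = "association probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a discrimination trace
#'
#' Per-race discrimination index with its bootstrap confidence ribbon.
#'
#' @param object A `discrimination_trace` from [discrimination_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot discrimination_trace
#' @export
autoplot.discrimination_trace <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$race, .data$d)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, fill = "#2c7fb8") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::labs(x = "race", y = "discrimination index D") +
    ggplot2::theme_minimal()
}

#' Plot a stickiness-awareness sweep as a filled contour
#'
#' The discrimination index averaged over the color-bias grid, as a function
#' of stickiness (x) and awareness (y).
#'
#' @param object A `sweep_result` from [contour_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  surf <- sweep_surface(object)
  ggplot2::ggplot(surf, ggplot2::aes(.data$s, .data$omega,
                                     z = .data$d_mean)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$d_mean)) +
    ggplot2::geom_contour(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "#f7f7f7",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "stickiness s", y = "awareness ω",
                  fill = "mean D") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @export
plot.sweep_result <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.discrimination_trace <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.partner_trajectory <- function(x, ...) print(autoplot(x, ...))
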