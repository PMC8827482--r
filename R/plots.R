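#' Plot state fractions before and after stimulation
#'
#' Bar chart of the four behavioral-state fractions at the two time points
#' with their bootstrap confidence intervals.
#'
#' @param fractions output of [state_fractions()].
#' @return A ggplot object.
#' @export
plot_state_fractions <- function(fractions) {
  fractions$when <- factor(fractions$when, levels = c("before", "after"))
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$state, y = .data$fraction,
                               fill = .data$when)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = "fraction of events", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a transition-probability surface as a tile map
#'
#' @param surface output of [transition_surface()].
#' @param behavior one state to show, or `NULL` for a facet per state.
#' @return A ggplot object.
#' @export
plot_transition_surface <- function(surface, behavior = NULL) {
  if (!is.null(behavior)) {
    surface <- surface[surface$state == behavior, , drop = FALSE]
  }
  p <- ggplot2::ggplot(surface,
                       ggplot2::aes(x = .data$I_head, y = .data$I_tail,
                                    fill = .data$p)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey80") +
    ggplot2::labs(x = expression(I[head] ~ (mu * W / mm^2)),
                  y = expression(I[tail] ~ (mu * W / mm^2)),
                  fill = "P") +
    ggplot2::theme_minimal()
  if (is.null(behavior)) p <- p + ggplot2::facet_wrap(~state)
  p
}

#' Gradient-vector plot of a fitted response plane
#'
#' @param object a [fit_plane()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.plane_fit <- function(object, ...) {
  df <- tibble::tibble(x0 = 0, y0 = 0, x1 = object$d_head,
                       y1 = object$d_tail)
  lim <- max(abs(c(df$x1, df$y1))) * 1.2 + 1e-6
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.1, "in"))) +
    ggplot2::coord_equal(xlim = c(-lim, lim), ylim = c(-lim, lim)) +
    ggplot2::labs(x = expression(partialdiff * P / partialdiff * I[head]),
                  y = expression(partialdiff * P / partialdiff * I[tail]),
                  title = object$behavior) +
    ggplot2::theme_minimal()
}

#' Plot a habituation curve
#'
#' @param curve output of [habituation_curve()].
#' @return A ggplot object.
#' @export
plot_habituation <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$t_mid_s / 60, y = .data$p)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "fraction reversing") +
    ggplot2::theme_minimal()
}
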