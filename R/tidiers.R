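#' Tidy a plane fit
#'
#' @param x a [fit_plane()] result.
#' @param ... unused.
#' @return A tibble with one row per term (`intercept`, `d_head`, `d_tail`):
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.plane_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "d_head", "d_tail"),
    estimate = c(x$intercept, x$d_head, x$d_tail),
    conf.low = x$ci[1, ],
    conf.high = x$ci[2, ])
}

#' @rdname tidy.plane_fit
#' @export
glance.plane_fit <- function(x, ...) {
  grad_mag <- sqrt(x$d_head^2 + x$d_tail^2)
  tibble::tibble(behavior = x$behavior, n_events = x$n_events,
                 gradient_magnitude = grad_mag,
                 gradient_angle_rad = atan2(x$d_tail, x$d_head))
}

#' @export
tidy.state_cutoffs <- function(x, ...) {
  tibble::tibble(term = c("c1", "c2"), estimate = c(x$c1, x$c2))
}

#' @export
glance.calibration_map <- function(x, ...) {
  tibble::tibble(residual_rms_um = x$residual_rms_um, n_points = x$n_points)
}
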