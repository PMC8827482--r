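#' Turn-trigger configuration
#'
#' Thresholds for ellipse-ratio turn-onset detection. The real-time trigger
#' fires when the blob ellipse ratio crosses below `ellipse_threshold`; post
#' hoc validation uses the slightly looser `posthoc_ellipse_threshold`,
#' requires the velocity to stay above `pre_velocity_floor_mm_s` throughout
#' the `pre_window_s` before the crossing (guarding against tail bends during
#' reversals being mistaken for turns), and requires the stimulus to land
#' within `onset_window_s` after the crossing.
#'
#' @param ellipse_threshold real-time trigger threshold (default 3.5).
#' @param posthoc_ellipse_threshold post hoc threshold (default 3.6).
#' @param refractory_s per-worm refractory period (s).
#' @param pre_velocity_floor_mm_s minimum pre-crossing velocity (mm/s).
#' @param pre_window_s length of the pre-crossing velocity window (s).
#' @param onset_window_s window after the crossing within which the stimulus
#'   must land to count as a turn-onset stimulation (s).
#' @return A list of class `"turn_trigger_config"`.
#' @export
turn_trigger_config <- function(ellipse_threshold = 3.5,
                                posthoc_ellipse_threshold = 3.6,
                                refractory_s = 30,
                                pre_velocity_floor_mm_s = -0.05,
                                pre_window_s = 0.15,
                                onset_window_s = 0.33) {
  stopifnot(ellipse_threshold > 1, posthoc_ellipse_threshold > 1,
            refractory_s >= 0)
  structure(list(ellipse_threshold = ellipse_threshold,
                 posthoc_ellipse_threshold = posthoc_ellipse_threshold,
                 refractory_s = refractory_s,
                 pre_velocity_floor_mm_s = pre_velocity_floor_mm_s,
                 pre_window_s = pre_window_s,
                 onset_window_s = onset_window_s),
            class = "turn_trigger_config")
}

# Centered boxcar mean of (approximately) 1 s; edge frames use the partial
# window. NA samples are dropped from the window mean.
boxcar_smooth <- function(v, fps, window_s = 1) {
  half <- floor(window_s * fps / 2)
  n <- length(v)
  vapply(seq_len(n), function(i) {
    w <- v[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Signed, smoothed velocity of a tracked worm
#'
#' Raw velocity is the frame-to-frame displacement of the body midpoint
#' (centerline point 10 of 0-19) times the frame rate, projected onto the
#' midpoint-to-head body axis so that head-first motion is positive. The raw
#' trace is then smoothed with a centered 1-second boxcar window (partial
#' windows at the track edges).
#'
#' @param centerlines list of oriented centerline matrices (head at row 1;
#'   `NULL` where orientation is unknown, yielding masked velocity).
#' @param time_s frame times (s).
#' @param fps frame rate.
#' @return A tibble with `time_s`, `v_raw_mm_s` and smoothed `v_mm_s`
#'   (`NA` where undefined).
#' @export
compute_velocity <- function(centerlines, time_s, fps) {
  nf <- length(centerlines)
  v <- rep(NA_real_, nf)
  for (i in seq_len(nf)[-1]) {
    cl <- centerlines[[i]]; cp <- centerlines[[i - 1]]
    if (is.null(cl) || is.null(cp)) next
    k <- min(11, nrow(cl))  # point index 10, 0-based
    mid <- cl[k, ]; midp <- cp[k, ]
    disp <- mid - midp
    axis <- cl[1, ] - mid
    na <- sqrt(sum(axis^2))
    if (na == 0) next
    v[i] <- sum(disp * axis / na) * fps
  }
  tibble::tibble(time_s = time_s, v_raw_mm_s = v,
                 v_mm_s = boxcar_smooth(v, fps))
}

#' Equal-area cutoffs for the positive-velocity states
#'
#' The three states with positive velocity (pause/slow, forward, sprint) are
#' divided so that they are equally likely in the fitting sample: the
#' cutoffs are the empirical 1/3 and 2/3 quantiles of the strictly positive
#' velocities, taken midway between the bracketing order statistics so the
#' three bins differ by at most one count.
#'
#' @param v numeric vector of velocities (mm/s); the pooled sample of an
#'   experiment, typically including control runs.
#' @param min_positive minimum number of strictly positive samples required.
#' @return A list of class `"state_cutoffs"` with `c1`, `c2` and `n_pos`.
#' @export
fit_state_cutoffs <- function(v, min_positive = 100) {
  pos <- sort(v[!is.na(v) & v > 0])
  n <- length(pos)
  if (n < min_positive) {
    abort(sprintf("need >= %d positive velocities, got %d", min_positive, n))
  }
  k1 <- floor(n / 3); k2 <- floor(2 * n / 3)
  c1 <- (pos[k1] + pos[k1 + 1]) / 2
  c2 <- (pos[k2] + pos[k2 + 1]) / 2
  if (!(0 < c1 && c1 < c2)) {
    abort("degenerate-cutoffs", class = "wormloop_degenerate_cutoffs")
  }
  structure(list(c1 = c1, c2 = c2, n_pos = n), class = "state_cutoffs")
}

#' @export
print.state_cutoffs <- function(x, ...) {
  cat(sprintf("<state_cutoffs> c1 = %.4f, c2 = %.4f mm/s (n = %d)\n",
              x$c1, x$c2, x$n_pos))
  invisible(x)
}

BEHAVIOR_STATES <- c("reverse", "pause/slow", "forward", "sprint")

#' Classify velocity into the four behavioral states
#'
#' `v < 0` is reverse; positive velocities are split at the equal-area
#' cutoffs into pause/slow, forward and sprint. Boundaries are assigned
#' upward (`v = 0` is pause/slow, `v = c1` is forward), so the four states
#' are exhaustive and exclusive.
#'
#' @param v velocities (mm/s), `NA` allowed.
#' @param cutoffs a [fit_state_cutoffs()] result.
#' @return A factor with levels reverse, pause/slow, forward, sprint.
#' @export
classify_state <- function(v, cutoffs) {
  out <- ifelse(v < 0, "reverse",
         ifelse(v < cutoffs$c1, "pause/slow",
         ifelse(v < cutoffs$c2, "forward", "sprint")))
  factor(out, levels = BEHAVIOR_STATES)
}

#' Detect turn onsets from the ellipse-ratio series
#'
#' In `"realtime"` mode, triggers at each downward crossing of the ellipse
#' ratio below the threshold, suppressing crossings within the per-worm
#' refractory period. In `"posthoc"` mode, additionally requires the
#' velocity to stay above the pre-window floor before the crossing and, when
#' stimulus onsets are supplied, that a stimulus landed within the onset
#' window after the crossing.
#'
#' @param time_s,ellipse_ratio,v_mm_s aligned series for one worm
#'   (`v_mm_s` may be `NULL` in realtime mode).
#' @param cfg a [turn_trigger_config()].
#' @param mode `"realtime"` or `"posthoc"`.
#' @param stim_onsets_s optional stimulus onset times for posthoc
#'   validation.
#' @return A tibble with `t_cross`, `accepted` and `reject_reason`
#'   (`NA` when accepted), plus `t_stim` in posthoc mode.
#' @export
detect_turn_onset <- function(time_s, ellipse_ratio, v_mm_s = NULL,
                              cfg = turn_trigger_config(),
                              mode = c("realtime", "posthoc"),
                              stim_onsets_s = NULL) {
  mode <- match.arg(mode)
  thr <- if (mode == "realtime") cfg$ellipse_threshold else
    cfg$posthoc_ellipse_threshold
  n <- length(ellipse_ratio)
  cross <- which(ellipse_ratio[-1] < thr & ellipse_ratio[-n] >= thr) + 1L
  out <- list()
  last_trig <- -Inf
  for (i in cross) {
    t <- time_s[i]
    if (mode == "realtime") {
      if (t - last_trig < cfg$refractory_s) next
      last_trig <- t
      out[[length(out) + 1]] <- tibble::tibble(
        t_cross = t, accepted = TRUE, reject_reason = NA_character_)
    } else {
      reason <- NA_character_
      pre <- which(time_s >= t - cfg$pre_window_s & time_s < t)
      vpre <- v_mm_s[pre]
      if (length(vpre) == 0 || anyNA(vpre) ||
          any(vpre <= cfg$pre_velocity_floor_mm_s)) {
        reason <- "pre-velocity"
      }
      t_stim <- NA_real_
      if (is.na(reason) && !is.null(stim_onsets_s)) {
        hit <- stim_onsets_s[stim_onsets_s >= t &
                             stim_onsets_s <= t + cfg$onset_window_s]
        if (length(hit) == 0) reason <- "no-stimulus-in-window" else
          t_stim <- hit[1]
      }
      out[[length(out) + 1]] <- tibble::tibble(
        t_cross = t, t_stim = t_stim, accepted = is.na(reason),
        reject_reason = reason)
    }
  }
  if (length(out) == 0) {
    base <- tibble::tibble(t_cross = numeric(), accepted = logical(),
                           reject_reason = character())
    if (mode == "posthoc") base <- dplyr::mutate(base, t_stim = numeric(),
                                                 .after = "t_cross")
    return(base)
  }
  dplyr::bind_rows(out)
}

#' Did a stimulus evoke a reversal?
#'
#' A reversal response requires the smoothed velocity to dip strictly below
#' -0.1 mm/s at least once during the stimulus window
#' `[onset, onset + duration)`.
#'
#' @param v_mm_s,time_s aligned velocity trace for one worm.
#' @param onset_s stimulus onset time.
#' @param duration_s stimulus duration (default 3 s).
#' @param threshold_mm_s reversal threshold (default -0.1).
#' @return `TRUE`/`FALSE`, or `NA` if the velocity is undefined anywhere in
#'   the window (the event is then excluded, not counted as a non-response).
#' @export
is_reversal_response <- function(v_mm_s, time_s, onset_s, duration_s = 3,
                                 threshold_mm_s = -0.1) {
  win <- which(time_s >= onset_s & time_s < onset_s + duration_s)
  if (length(win) == 0) return(NA)
  vw <- v_mm_s[win]
  if (anyNA(vw)) return(NA)
  min(vw) < threshold_mm_s
}
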