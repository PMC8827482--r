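#' Build the inclusion-filtered stimulus-event table
#'
#' Joins a stimulus log onto finalized per-frame tracks and applies the
#' postprocessing inclusion criteria: the worm must be valid (length within
#' bounds, sane shape, not stationary), tracked continuously for the
#' required window before and after stimulus onset, and must not have
#' collided with another worm around the stimulation. Each commanded
#' stimulus yields exactly one record with its exclusion reasons.
#'
#' @param tracks per-frame track tibble with columns `worm_id`, `frame`,
#'   `time_s`, `x_mm`, `y_mm`, and (where available) `length_um`,
#'   `ellipse_ratio`, `solidity`, `v_mm_s`, `state` (a [classify_state()]
#'   factor) and `merged`.
#' @param stim_log stimulus tibble with `command_id`, `worm_id`, `t_on`,
#'   `duration_s`, `I_head`, `I_tail` (worm ids must refer to `tracks`).
#' @param crit a [validity_criteria()]; use [turning_criteria()] for
#'   turn-triggered runs.
#' @param experiment_type `"headtail"` or `"turning"` (sets the context
#'   labeling convention only; windows and length bounds come from `crit`).
#' @param fps frame rate.
#' @param trigger_cfg a [turn_trigger_config()] used for the turn-context
#'   label.
#' @param collision_margin_s window around stimulation within which a merge
#'   counts as a collision ("before, during, or immediately after").
#' @return A tibble, one row per stimulus: identity, intensities, `context`
#'   (`forward`, `turn` or `other` at onset), `pre_state` (2 s before
#'   onset), `post_state` (at stimulus end), `reversal_response`,
#'   `included`, and `reasons` (comma-separated exclusion codes).
#' @export
build_event_table <- function(tracks, stim_log, crit = validity_criteria(),
                              experiment_type = c("headtail", "turning"),
                              fps = 30,
                              trigger_cfg = turn_trigger_config(),
                              collision_margin_s = 1) {
  experiment_type <- match.arg(experiment_type)
  by_worm <- split(tracks, tracks$worm_id)
  rows <- vector("list", nrow(stim_log))
  for (k in seq_len(nrow(stim_log))) {
    s <- stim_log[k, ]
    tw <- by_worm[[as.character(s$worm_id)]]
    reasons <- character(0)
    context <- NA_character_
    pre_state <- NA_character_; post_state <- NA_character_
    reversal <- NA
    if (is.null(tw)) {
      reasons <- "orphan"
    } else {
      t_on <- s$t_on; t_end <- s$t_on + s$duration_s
      tol <- 1.5 / fps
      cover <- function(a, b) {
        ok <- tt_ok(tw) & tw$time_s >= a - tol & tw$time_s <= b + tol
        tt <- sort(tw$time_s[ok])
        if (length(tt) == 0) return(FALSE)
        if (min(tt) > a + tol || max(tt) < b - tol) return(FALSE)
        length(tt) < 2 || max(diff(tt)) <= 2 * tol
      }
      if (!cover(t_on - crit$min_track_pre_s, t_on)) {
        reasons <- c(reasons, "short-pre-track")
      }
      post_need <- max(crit$min_track_post_s, s$duration_s)
      if (!cover(t_on, t_on + post_need)) {
        reasons <- c(reasons, "short-post-track")
      }
      i_on <- which.min(abs(tw$time_s - t_on))
      if ("merged" %in% names(tw)) {
        near <- tw$time_s >= t_on - collision_margin_s &
          tw$time_s <= t_end + collision_margin_s
        if (any(tw$merged[near])) reasons <- c(reasons, "collision")
      }
      if ("length_um" %in% names(tw)) {
        len <- tw$length_um[i_on]
        blob <- list(area_px = tw$area_px[i_on] %||% NA,
                     solidity = tw$solidity[i_on] %||% 1)
        disp <- NA
        pre10 <- tw$time_s >= t_on - 10 & tw$time_s <= t_on
        if (sum(pre10) > 2) {
          disp <- 1000 * sqrt((tw$x_mm[i_on] - tw$x_mm[which(pre10)[1]])^2 +
                              (tw$y_mm[i_on] - tw$y_mm[which(pre10)[1]])^2)
        }
        v <- validate_worm(blob, len, crit,
                           um_per_px = attr(tracks, "um_per_px") %||% 44,
                           trailing_disp_um = disp)
        reasons <- c(reasons, v$reasons)
      }
      # behavioral context at onset
      if ("ellipse_ratio" %in% names(tw)) {
        pre_win <- tw$time_s >= t_on - trigger_cfg$onset_window_s &
          tw$time_s <= t_on
        in_turn <- any(tw$ellipse_ratio[pre_win] <
                         trigger_cfg$posthoc_ellipse_threshold, na.rm = TRUE)
        if (in_turn) context <- "turn"
      }
      if (is.na(context) && "state" %in% names(tw)) {
        st_on <- as.character(tw$state[i_on])
        context <- if (identical(st_on, "forward")) "forward" else "other"
      }
      if ("state" %in% names(tw)) {
        i_pre <- which.min(abs(tw$time_s - (t_on - 2)))
        i_post <- which.min(abs(tw$time_s - t_end))
        if (abs(tw$time_s[i_pre] - (t_on - 2)) <= tol) {
          pre_state <- as.character(tw$state[i_pre])
        }
        if (abs(tw$time_s[i_post] - t_end) <= tol) {
          post_state <- as.character(tw$state[i_post])
        }
        if (is.na(pre_state) || is.na(post_state)) {
          reasons <- c(reasons, "state-undefined")
        }
      }
      if ("v_mm_s" %in% names(tw)) {
        reversal <- is_reversal_response(tw$v_mm_s, tw$time_s, t_on,
                                         s$duration_s)
        if (is.na(reversal)) reasons <- c(reasons, "velocity-masked")
      }
    }
    rows[[k]] <- tibble::tibble(
      event_id = s$command_id %||% k, worm_id = s$worm_id,
      t_on = s$t_on, duration_s = s$duration_s,
      I_head = s$I_head, I_tail = s$I_tail,
      context = context %||% NA_character_,
      pre_state = pre_state, post_state = post_state,
      reversal_response = reversal,
      included = length(reasons) == 0,
      reasons = paste(unique(reasons), collapse = ","))
  }
  dplyr::bind_rows(rows)
}

# coverage helper: rows of tw are usable (non-merged) observations
tt_ok <- function(tw) {
  if ("merged" %in% names(tw)) !tw$merged else rep(TRUE, nrow(tw))
}
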