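#' Open-loop stimulus schedule
#'
#' Every `isi_s` seconds, each currently tracked valid worm receives one
#' stimulus. In head/tail mode, head and tail intensities are drawn
#' independently and uniformly from `cfg$intensity_set`; in whole-body mode
#' one intensity is drawn uniformly from `cfg$wholebody_intensity_set`.
#'
#' @param presence a tibble with `worm_id` and `time_s` (one row per tracked
#'   worm-frame), used to decide which worms are present at each epoch; a
#'   worm is present if it has an observation within half a frame of the
#'   epoch time (set `tol_s`).
#' @param duration_total_s length of the recording (s).
#' @param cfg a [schedule_config()] with an open-loop mode.
#' @param tol_s presence tolerance around each epoch (s).
#' @return A tibble of commands: `command_id`, `worm_id`, `t_on`,
#'   `duration_s`, `target`, `I_head`, `I_tail`.
#' @export
open_loop_scheduler <- function(presence, duration_total_s, cfg, tol_s = 0.1) {
  stopifnot(cfg$mode %in% c("open_loop_headtail", "open_loop_wholebody"))
  n_epochs <- floor((duration_total_s - 1e-9) / cfg$isi_s) + 1
  epochs <- (seq_len(n_epochs) - 1) * cfg$isi_s
  rows <- list()
  for (t in epochs) {
    ids <- unique(presence$worm_id[abs(presence$time_s - t) <= tol_s])
    if (length(ids) == 0) next
    if (cfg$mode == "open_loop_headtail") {
      Ih <- sample(cfg$intensity_set, length(ids), replace = TRUE)
      It <- sample(cfg$intensity_set, length(ids), replace = TRUE)
      tgt <- "both"
    } else {
      Ih <- sample(cfg$wholebody_intensity_set, length(ids), replace = TRUE)
      It <- Ih
      tgt <- "whole_body"
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      worm_id = ids, t_on = t, duration_s = cfg$duration_s, target = tgt,
      I_head = Ih, I_tail = It)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(command_id = integer(), worm_id = integer(),
                          t_on = numeric(), duration_s = numeric(),
                          target = character(), I_head = numeric(),
                          I_tail = numeric()))
  }
  dplyr::mutate(out, command_id = dplyr::row_number(), .before = 1)
}

#' Closed-loop (turn-triggered) stimulus schedule
#'
#' One whole-body command per accepted trigger, enforcing the per-worm
#' refractory period; the intensity is drawn uniformly from the whole-body
#' experiment/control pair.
#'
#' @param triggers a tibble with `worm_id` and `t_cross` (trigger times,
#'   e.g. from [detect_turn_onset()]).
#' @param cfg a [schedule_config()] with `mode = "closed_loop_turn"`.
#' @return A command tibble as in [open_loop_scheduler()].
#' @export
closed_loop_scheduler <- function(triggers, cfg) {
  stopifnot(cfg$mode == "closed_loop_turn")
  trg <- dplyr::arrange(triggers, .data$t_cross)
  last <- new.env(parent = emptyenv())
  keep <- logical(nrow(trg))
  for (i in seq_len(nrow(trg))) {
    key <- as.character(trg$worm_id[i])
    t0 <- get0(key, envir = last, ifnotfound = -Inf)
    if (trg$t_cross[i] - t0 >= cfg$refractory_s) {
      keep[i] <- TRUE
      assign(key, trg$t_cross[i], envir = last)
    }
  }
  trg <- trg[keep, , drop = FALSE]
  n <- nrow(trg)
  I <- if (n > 0) sample(cfg$wholebody_intensity_set, n, replace = TRUE)
       else numeric(0)
  tibble::tibble(command_id = seq_len(n), worm_id = trg$worm_id,
                 t_on = trg$t_cross, duration_s = cfg$duration_s,
                 target = "whole_body", I_head = I, I_tail = I)
}
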