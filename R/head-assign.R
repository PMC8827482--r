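#' Assign head/tail orientation along a track
#'
#' Uses the rule that a worm cannot crawl backward for long: the centerline
#' end that leads the direction of motion for more than 10 seconds is the
#' head. In `"realtime"` mode a provisional orientation is kept per frame and
#' flipped only after it has been contradicted continuously for more than
#' `flip_after_s`; in `"posthoc"` mode a single orientation is chosen for the
#' whole track so that total time moving head-first is maximal.
#'
#' @param centerlines list (one per frame, in time order) of `n x 2`
#'   matrices of mm coordinates as extracted (ends in arbitrary order);
#'   `NULL` entries are tolerated and inherit the surrounding orientation.
#' @param time_s numeric vector of frame times.
#' @param mode `"posthoc"` or `"realtime"`.
#' @param flip_after_s continuous contradiction needed to flip (realtime).
#' @param window_s trailing window for the provisional direction estimate.
#' @param stationary_floor_mm displacement (mm) over the trailing window
#'   below which orientation is `"unknown"` (`NA`).
#' @return A list with `head_at_index0` (logical per frame, `NA` where
#'   unknown) and `aligned` (centerlines flipped frame-to-frame into a
#'   consistent order before orientation was decided).
#' @export
assign_head <- function(centerlines, time_s,
                        mode = c("posthoc", "realtime"),
                        flip_after_s = 10, window_s = 2,
                        stationary_floor_mm = 0.05) {
  mode <- match.arg(mode)
  nf <- length(centerlines)
  stopifnot(length(time_s) == nf)
  # 1. align successive frames into one consistent (still arbitrary) order
  aligned <- centerlines
  last <- NULL
  for (i in seq_len(nf)) {
    cl <- aligned[[i]]
    if (is.null(cl)) next
    if (!is.null(last)) {
      n <- nrow(cl)
      d_same <- sum((cl[1, ] - last[1, ])^2) + sum((cl[n, ] - last[n, ])^2)
      d_flip <- sum((cl[1, ] - last[n, ])^2) + sum((cl[n, ] - last[1, ])^2)
      if (d_flip < d_same) {
        cl <- cl[rev(seq_len(n)), , drop = FALSE]
        aligned[[i]] <- cl
      }
    }
    last <- cl
  }
  # 2. per-frame motion projected on the end0-ward body axis
  score <- rep(NA_real_, nf)
  prev_mid <- NULL; prev_i <- NA_integer_
  for (i in seq_len(nf)) {
    cl <- aligned[[i]]
    if (is.null(cl)) { prev_mid <- NULL; next }
    mid <- cl[ceiling(nrow(cl) / 2), ]
    if (!is.null(prev_mid)) {
      disp <- mid - prev_mid
      axis <- cl[1, ] - mid
      na <- sqrt(sum(axis^2))
      if (na > 0) score[i] <- sum(disp * axis) / na
    }
    prev_mid <- mid
  }
  head0 <- rep(NA, nf)
  if (mode == "posthoc") {
    dt <- c(0, diff(time_s))
    t_toward0 <- sum(dt[which(score > 0)])
    t_toward1 <- sum(dt[which(score < 0)])
    if (t_toward0 + t_toward1 > 0) {
      head0[] <- t_toward0 >= t_toward1
    }
  } else {
    assigned <- NA
    contra_since <- NA_real_
    for (i in seq_len(nf)) {
      if (is.null(aligned[[i]])) next
      win <- which(time_s > time_s[i] - window_s & time_s <= time_s[i])
      net <- sum(score[win], na.rm = TRUE) / max(1, length(win)) *
        length(win)  # net trailing displacement along axis
      if (is.na(net) || abs(net) < stationary_floor_mm) {
        head0[i] <- assigned
        next
      }
      provisional <- net > 0
      if (is.na(assigned)) {
        assigned <- provisional
        contra_since <- NA_real_
      } else if (provisional != assigned) {
        if (is.na(contra_since)) contra_since <- time_s[i]
        if (time_s[i] - contra_since > flip_after_s) {
          assigned <- provisional
          contra_since <- NA_real_
        }
      } else {
        contra_since <- NA_real_
      }
      head0[i] <- assigned
    }
  }
  list(head_at_index0 = head0, aligned = aligned)
}

#' Orient centerlines head-first
#'
#' Applies an [assign_head()] result: flips each aligned centerline so that
#' row 1 is the head; frames with unknown orientation become `NULL`.
#'
#' @param assignment result of [assign_head()].
#' @return List of oriented centerline matrices (head at row 1).
#' @export
orient_centerlines <- function(assignment) {
  purrr::map2(assignment$aligned, assignment$head_at_index0, function(cl, h0) {
    if (is.null(cl) || is.na(h0)) return(NULL)
    if (h0) cl else cl[rev(seq_len(nrow(cl))), , drop = FALSE]
  })
}
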