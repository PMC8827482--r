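#' Run a (closed-loop capable) simulated recording
#'
#' Steps the arena for `duration_s` seconds. At every frame the controller
#' observes the rendered image (and, for oracle controllers, the ground
#' truth) and may return stimulus commands; each command's illumination
#' pattern is applied after `cfg$latency_frames` frames of closed-loop
#' latency and held for its duration. At each stimulus onset the delivered
#' intensity is sampled at every worm's true head and tail tip and an evoked
#' response is drawn through [step_world()]. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param controller `NULL` (never stimulate) or
#'   `function(img, world, frame, time_s)` returning `NULL` or a list of
#'   commands; see [make_oracle_turn_controller()],
#'   [make_open_loop_controller()], [make_pipeline_controller()]. A command
#'   is a list with `pattern` (a [make_targeted_pattern()] result),
#'   `worm_id` (the controller's notion of the target, may be `NA`),
#'   `duration_s`, and optional `probe = TRUE` for zero-intensity targeting
#'   probes that never count as stimulus onsets.
#' @param duration_s recording length (s).
#' @param render render frames and pass them to the controller (needed for
#'   imaging-based controllers; oracle controllers can run without).
#' @param record_movie keep the rendered frames in the result.
#' @param record_truth keep the per-frame per-worm ground-truth log.
#' @return A list of class `"sim_experiment"`: `truth` (frame, worm_id,
#'   head/centroid mm coordinates, state), `events` (behavior events
#'   including stimulus outcomes), `stim_log` (one row per command:
#'   issue/onset times, intensities commanded and measured at the target's
#'   true tips), `targeting` (probe head-disk centers vs time), `movie`,
#'   and `controller_error` (condition or `NULL`) — a controller exception
#'   aborts the run with partial logs flushed.
#' @export
run_experiment <- function(cfg, controller = NULL, duration_s = 60,
                           render = TRUE, record_movie = FALSE,
                           record_truth = TRUE) {
  set.seed(cfg$seed)
  world <- init_world(cfg)
  n_frames <- as.integer(round(duration_s * cfg$fps))
  pending <- list()     # commands waiting for / under application
  next_cmd_id <- 1L
  stim_rows <- list(); ev_rows <- list()
  targ_rows <- list()
  nw <- cfg$n_worms
  truth <- NULL
  if (record_truth) {
    nn <- n_frames * nw
    truth <- list(frame = integer(nn), time_s = numeric(nn),
                  worm_id = integer(nn), head_x_mm = numeric(nn),
                  head_y_mm = numeric(nn), x_mm = numeric(nn),
                  y_mm = numeric(nn), state = character(nn))
  }
  movie <- if (record_movie) vector("list", n_frames) else NULL
  controller_error <- NULL

  for (f in seq_len(n_frames) - 1L) {      # world$frame == f here
    t <- world$time_s
    cls <- true_centerlines(world, cfg, n = 41)
    img <- NULL
    if (render) {
      W <- as.integer(round(cfg$arena_size_mm[1] * 1000 / cfg$um_per_px))
      H <- as.integer(round(cfg$arena_size_mm[2] * 1000 / cfg$um_per_px))
      img <- matrix(as.integer(cfg$bg_level), nrow = H, ncol = W)
      for (cl in cls) img <- paint_worm(img, cl, cfg)
      if (record_movie) movie[[f + 1L]] <- img
    }
    if (!is.null(controller) && is.null(controller_error)) {
      cmds <- tryCatch(controller(img, world, f, t),
                       error = function(e) e)
      if (inherits(cmds, "error")) {
        controller_error <- cmds
        cmds <- NULL
      }
      for (cmd in cmds %||% list()) {
        cmd$command_id <- next_cmd_id
        next_cmd_id <- next_cmd_id + 1L
        cmd$on_frame <- f + cfg$latency_frames
        cmd$off_frame <- cmd$on_frame +
          max(1L, as.integer(round(cmd$duration_s * cfg$fps)))
        cmd$t_issue <- t
        pending[[length(pending) + 1]] <- cmd
      }
    }
    keep <- vapply(pending, function(cm) cm$off_frame > f, logical(1))
    pending <- pending[keep]
    active <- pending[vapply(pending, function(cm) cm$on_frame <= f,
                             logical(1))]
    new_on <- active[vapply(active, function(cm) cm$on_frame == f,
                            logical(1))]

    w <- world$worms
    head_x <- w$x; head_y <- w$y
    tail_x <- vapply(cls, function(m) m[nrow(m), 1], numeric(1))
    tail_y <- vapply(cls, function(m) m[nrow(m), 2], numeric(1))
    stim <- NULL
    real_active <- Filter(function(cm) !isTRUE(cm$probe), active)
    real_new <- Filter(function(cm) !isTRUE(cm$probe), new_on)
    if (length(real_active) > 0) {
      pats <- lapply(real_active, `[[`, "pattern")
      Ih <- sample_intensity(pats, head_x, head_y, cfg$um_per_px)
      It <- sample_intensity(pats, tail_x, tail_y, cfg$um_per_px)
      onset_ids <- integer(0)
      if (length(real_new) > 0) {
        new_pats <- lapply(real_new, `[[`, "pattern")
        Ih_new <- sample_intensity(new_pats, head_x, head_y, cfg$um_per_px)
        It_new <- sample_intensity(new_pats, tail_x, tail_y, cfg$um_per_px)
        covered <- which(Ih_new > 0 | It_new > 0)
        onset_ids <- w$id[covered]
        for (cm in real_new) {
          # nearest true worm to the pattern centroid = the actual target
          cx <- mean(cm$pattern$disks$x_mm); cy <- mean(cm$pattern$disks$y_mm)
          d2 <- (w$x - cx)^2 + (w$y - cy)^2
          tgt <- which.min(d2)
          stim_rows[[length(stim_rows) + 1]] <- tibble::tibble(
            command_id = cm$command_id, worm_id = w$id[tgt],
            tracker_id = cm$worm_id %||% NA_integer_,
            t_issue = cm$t_issue, t_on = t, duration_s = cm$duration_s,
            target = cm$pattern$target,
            I_cmd = cm$pattern$disks$intensity[1],
            I_head = Ih[tgt], I_tail = It[tgt],
            delivered_area_frac = cm$pattern$delivered_area_frac %||% 1)
        }
      }
      if (length(onset_ids) > 0 || any(Ih > 0 | It > 0)) {
        ids <- union(onset_ids, w$id[Ih > 0 | It > 0])
        idx <- match(ids, w$id)
        stim <- tibble::tibble(worm_id = ids, I_head = Ih[idx],
                               I_tail = It[idx],
                               onset = ids %in% onset_ids)
      }
    }
    probes_on <- Filter(function(cm) isTRUE(cm$probe), active)
    if (length(probes_on) > 0) {
      for (cm in probes_on) {
        dh <- cm$pattern$disks[cm$pattern$disks$part == "head", ,
                               drop = FALSE]
        if (nrow(dh) > 0) {
          targ_rows[[length(targ_rows) + 1]] <- tibble::tibble(
            frame = f, time_s = t, tracker_id = cm$worm_id %||% NA_integer_,
            cx_mm = dh$x_mm[1], cy_mm = dh$y_mm[1])
        }
      }
    }
    if (record_truth) {
      cent <- vapply(cls, colMeans, numeric(2))
      ii <- (f * nw + 1):((f + 1) * nw)
      truth$frame[ii] <- f; truth$time_s[ii] <- t
      truth$worm_id[ii] <- w$id
      truth$head_x_mm[ii] <- head_x; truth$head_y_mm[ii] <- head_y
      truth$x_mm[ii] <- cent[1, ]; truth$y_mm[ii] <- cent[2, ]
      truth$state[ii] <- w$state
    }
    world <- step_world(world, cfg, stim)
    e <- attr(world, "events")
    if (nrow(e) > 0) ev_rows[[length(ev_rows) + 1]] <- e
  }

  structure(list(
    truth = if (record_truth)
      tibble::new_tibble(truth, nrow = n_frames * nw) else NULL,
    events = dplyr::bind_rows(ev_rows),
    stim_log = dplyr::bind_rows(stim_rows),
    targeting = dplyr::bind_rows(targ_rows),
    movie = if (record_movie) movie else NULL,
    cfg = cfg, duration_s = duration_s,
    controller_error = controller_error), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> %.0f s, %d worms, %d stimuli, %d events\n",
              x$duration_s, x$cfg$n_worms, nrow(x$stim_log), nrow(x$events)))
  invisible(x)
}

#' Oracle closed-loop controller (ground-truth turn trigger)
#'
#' Triggers on the true turn-initiation frame of each worm, enforcing the
#' refractory period, and emits a whole-body spot at the worm's true
#' position with an intensity drawn from the whole-body pair. Used to test
#' the closed-loop machinery independently of the imaging pipeline.
#'
#' @param sched_cfg a [schedule_config()] with `mode = "closed_loop_turn"`.
#' @return A controller function for [run_experiment()].
#' @export
make_oracle_turn_controller <- function(sched_cfg = schedule_config(
                                          mode = "closed_loop_turn",
                                          duration_s = 3)) {
  last_trig <- new.env(parent = emptyenv())
  function(img, world, frame, time_s) {
    w <- world$worms
    dt_tol <- 1.5 / 30
    just_turned <- w$state == "turn" & (time_s - w$turn_t0) < dt_tol &
      w$turn_t0 <= time_s
    cmds <- list()
    for (i in which(just_turned)) {
      key <- as.character(w$id[i])
      t0 <- get0(key, envir = last_trig, ifnotfound = -Inf)
      if (time_s - t0 < sched_cfg$refractory_s) next
      assign(key, time_s, envir = last_trig)
      I <- sample(sched_cfg$wholebody_intensity_set, 1)
      cl <- tibble::tibble(x_mm = w$x[i], y_mm = w$y[i])
      pat <- make_targeted_pattern(cl, "whole_body", intensity_head = I,
                                   cfg = sched_cfg)
      cmds[[length(cmds) + 1]] <- list(worm_id = w$id[i], pattern = pat,
                                       duration_s = sched_cfg$duration_s)
    }
    if (length(cmds) == 0) NULL else cmds
  }
}

#' Open-loop controller over the imaging pipeline
#'
#' Segments and tracks each frame; every `isi_s` seconds emits one
#' whole-body stimulus per tracked worm, with intensity drawn from the
#' whole-body pair (or head/tail draws in head/tail mode, centered on the
#' blob until a centerline orientation is available).
#'
#' @param sched_cfg a [schedule_config()] with an open-loop mode.
#' @param threshold,max_disp_px imaging parameters (see [segment_frame()],
#'   [tracker_init()]).
#' @param um_per_px image scale used to place patterns in mm.
#' @return A controller function for [run_experiment()].
#' @export
make_open_loop_controller <- function(sched_cfg = schedule_config(
                                        mode = "open_loop_wholebody",
                                        duration_s = 3),
                                      threshold = 105, max_disp_px = 20,
                                      um_per_px = 44) {
  env <- new.env(parent = emptyenv())
  env$tracker <- tracker_init(max_disp_px)
  env$next_epoch <- 0
  function(img, world, frame, time_s) {
    blobs <- segment_frame(img, threshold, frame_idx = frame,
                           keep_masks = FALSE)
    env$tracker <- link_tracks(env$tracker, blobs, frame)
    if (time_s + 1e-9 < env$next_epoch) return(NULL)
    env$next_epoch <- env$next_epoch + sched_cfg$isi_s
    act <- env$tracker$active
    act <- act[!act$merged & act$last_frame == frame, , drop = FALSE]
    cmds <- list()
    for (i in seq_len(nrow(act))) {
      I <- sample(sched_cfg$wholebody_intensity_set, 1)
      cl <- tibble::tibble(x_mm = px_to_mm(act$x[i], um_per_px),
                           y_mm = px_to_mm(act$y[i], um_per_px))
      pat <- make_targeted_pattern(cl, "whole_body", intensity_head = I,
                                   cfg = sched_cfg)
      cmds[[length(cmds) + 1]] <- list(worm_id = act$worm_id[i],
                                       pattern = pat,
                                       duration_s = sched_cfg$duration_s)
    }
    if (length(cmds) == 0) NULL else cmds
  }
}
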