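#' Real-time software pipeline as a closed-loop controller
#'
#' Re-creates the instrument's per-frame loop over the imaging, centerline
#' and behavior modules: segment the frame, stitch blobs into tracks, and
#' either (a) trigger a whole-body stimulus when a track's ellipse ratio
#' crosses below the turn threshold (`mode = "closed_loop_turn"`, with the
#' per-track refractory period), or (b) extract each track's centerline,
#' maintain the provisional head/tail orientation from the direction of
#' motion, and emit a zero-intensity head-targeted probe every frame
#' (`mode = "head_probe"`), which [run_experiment()] logs for targeting
#' accuracy without perturbing behavior.
#'
#' @param cfg the [sim_config()] (for the image scale and frame rate).
#' @param sched_cfg a [schedule_config()].
#' @param trigger_cfg a [turn_trigger_config()].
#' @param threshold,max_disp_px imaging parameters.
#' @param mode `"closed_loop_turn"` or `"head_probe"`.
#' @return A controller function for [run_experiment()].
#' @export
make_pipeline_controller <- function(cfg,
                                     sched_cfg = schedule_config(
                                       mode = "closed_loop_turn",
                                       duration_s = 3),
                                     trigger_cfg = turn_trigger_config(),
                                     threshold = 105, max_disp_px = 20,
                                     mode = c("closed_loop_turn",
                                              "head_probe")) {
  mode <- match.arg(mode)
  env <- new.env(parent = emptyenv())
  env$tracker <- tracker_init(max_disp_px)
  env$worms <- new.env(parent = emptyenv())  # per-track state
  dt <- 1 / cfg$fps
  window_s <- 2; floor_mm <- 0.02

  function(img, world, frame, time_s) {
    blobs <- segment_frame(img, threshold, frame_idx = frame,
                           keep_masks = (mode == "head_probe"))
    env$tracker <- link_tracks(env$tracker, blobs, frame)
    chunk <- if (length(env$tracker$obs) > 0)
      env$tracker$obs[[length(env$tracker$obs)]] else NULL
    if (is.null(chunk) || nrow(chunk) == 0 ||
        chunk$frame[1] != frame) return(NULL)
    cmds <- list()
    for (i in seq_len(nrow(chunk))) {
      ob <- chunk[i, ]
      if (ob$merged) next
      key <- as.character(ob$worm_id)
      st <- get0(key, envir = env$worms)
      if (is.null(st)) {
        st <- list(prev_ellipse = NA_real_, last_trig = -Inf,
                   prev_cl = NULL, orient = NA, contra_since = NA_real_,
                   scores = numeric(0), times = numeric(0))
      }
      if (mode == "closed_loop_turn") {
        if (!is.na(st$prev_ellipse) &&
            st$prev_ellipse >= trigger_cfg$ellipse_threshold &&
            ob$ellipse_ratio < trigger_cfg$ellipse_threshold &&
            time_s - st$last_trig >= trigger_cfg$refractory_s) {
          st$last_trig <- time_s
          I <- sample(sched_cfg$wholebody_intensity_set, 1)
          ctr <- tibble::tibble(x_mm = px_to_mm(ob$x_px, cfg$um_per_px),
                                y_mm = px_to_mm(ob$y_px, cfg$um_per_px))
          pat <- make_targeted_pattern(ctr, "whole_body",
                                       intensity_head = I, cfg = sched_cfg)
          cmds[[length(cmds) + 1]] <- list(worm_id = ob$worm_id,
                                           pattern = pat,
                                           duration_s = sched_cfg$duration_s)
        }
        st$prev_ellipse <- ob$ellipse_ratio
      } else {
        cl_t <- extract_centerline(ob$mask[[1]]$m, cfg$um_per_px,
                                   x0 = ob$mask[[1]]$x0,
                                   y0 = ob$mask[[1]]$y0)
        if (!is.null(cl_t)) {
          cl <- cbind(cl_t$x_mm, cl_t$y_mm)
          if (!is.null(st$prev_cl)) {
            n <- nrow(cl)
            d_same <- sum((cl[1, ] - st$prev_cl[1, ])^2) +
              sum((cl[n, ] - st$prev_cl[n, ])^2)
            d_flip <- sum((cl[1, ] - st$prev_cl[n, ])^2) +
              sum((cl[n, ] - st$prev_cl[1, ])^2)
            if (d_flip < d_same) cl <- cl[rev(seq_len(n)), , drop = FALSE]
            mid <- cl[ceiling(n / 2), ]
            midp <- st$prev_cl[ceiling(n / 2), ]
            axis <- cl[1, ] - mid
            na <- sqrt(sum(axis^2))
            if (na > 0) {
              st$scores <- c(st$scores, sum((mid - midp) * axis) / na)
              st$times <- c(st$times, time_s)
              keep <- st$times > time_s - window_s
              st$scores <- st$scores[keep]; st$times <- st$times[keep]
              net <- sum(st$scores)
              if (abs(net) >= floor_mm) {
                provisional <- net > 0
                if (is.na(st$orient)) {
                  st$orient <- provisional
                } else if (provisional != st$orient) {
                  if (is.na(st$contra_since)) st$contra_since <- time_s
                  if (time_s - st$contra_since > 10) {
                    st$orient <- provisional
                    st$contra_since <- NA_real_
                  }
                } else st$contra_since <- NA_real_
              }
            }
          }
          st$prev_cl <- cl
          if (!is.na(st$orient)) {
            ocl <- if (st$orient) cl else cl[rev(seq_len(nrow(cl))), ,
                                             drop = FALSE]
            pat <- make_targeted_pattern(
              tibble::tibble(x_mm = ocl[, 1], y_mm = ocl[, 2]),
              "head", intensity_head = 0, cfg = sched_cfg)
            cmds[[length(cmds) + 1]] <- list(worm_id = ob$worm_id,
                                             pattern = pat,
                                             duration_s = dt, probe = TRUE)
          }
        }
      }
      assign(key, st, envir = env$worms)
    }
    if (length(cmds) == 0) NULL else cmds
  }
}
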