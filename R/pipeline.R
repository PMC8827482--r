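#' Full postprocessing pipeline: movie to annotated tracks
#'
#' Segments and stitches tracks, extracts the two-pass centerline for every
#' observation, assigns head/tail orientation per track (post hoc by
#' default), and computes signed, boxcar-smoothed velocities. The result
#' feeds [fit_state_cutoffs()], [build_event_table()] and the statistics
#' layer.
#'
#' @param frames list of images ([render_frame()] output or [read_movie()]).
#' @param um_per_px image scale.
#' @param fps frame rate.
#' @param threshold,min_area_px,max_disp_px,max_gap imaging parameters.
#' @param orientation_mode `"posthoc"` or `"realtime"` head assignment.
#' @return A per-frame tibble with blob statistics, `length_um`,
#'   `centerline` (list of oriented 20 x 2 mm matrices, head first, `NULL`
#'   where extraction failed or orientation is unknown), `v_mm_s`, and
#'   `merged`; attribute `"um_per_px"` records the scale.
#' @export
process_movie <- function(frames, um_per_px, fps = 30, threshold = 105,
                          min_area_px = 5, max_disp_px = 20, max_gap = 3,
                          orientation_mode = "posthoc") {
  obs <- track_movie(frames, threshold, min_area_px, max_disp_px, max_gap,
                     fps)
  if (nrow(obs) == 0) return(obs)
  cl_raw <- purrr::map(obs$mask, function(mk) {
    if (is.null(mk$m)) return(NULL)
    extract_centerline(mk$m, um_per_px, x0 = mk$x0, y0 = mk$y0)
  })
  obs$length_um <- vapply(cl_raw, function(cl) {
    if (is.null(cl)) NA_real_ else attr(cl, "length_um")
  }, numeric(1))
  obs$x_mm <- px_to_mm(obs$x_px, um_per_px)
  obs$y_mm <- px_to_mm(obs$y_px, um_per_px)
  cl_mat <- purrr::map(cl_raw, function(cl) {
    if (is.null(cl)) NULL else cbind(cl$x_mm, cl$y_mm)
  })
  obs$centerline <- vector("list", nrow(obs))
  obs$v_mm_s <- NA_real_
  for (id in unique(obs$worm_id)) {
    rows <- which(obs$worm_id == id)
    asg <- assign_head(cl_mat[rows], obs$time_s[rows],
                       mode = orientation_mode)
    oriented <- orient_centerlines(asg)
    obs$centerline[rows] <- oriented
    vel <- compute_velocity(oriented, obs$time_s[rows], fps)
    obs$v_mm_s[rows] <- vel$v_mm_s
  }
  attr(obs, "um_per_px") <- um_per_px
  obs
}

#' Add behavior-state labels to processed tracks
#'
#' Fits (or reuses) the equal-area velocity cutoffs and adds a `state`
#' factor column.
#'
#' @param tracks output of [process_movie()].
#' @param cutoffs a [fit_state_cutoffs()] result, or `NULL` to fit on this
#'   table's pooled velocities.
#' @return `tracks` with a `state` column; attribute `"cutoffs"` holds the
#'   cutoffs used.
#' @export
add_behavior_states <- function(tracks, cutoffs = NULL) {
  if (is.null(cutoffs)) cutoffs <- fit_state_cutoffs(tracks$v_mm_s)
  tracks$state <- classify_state(tracks$v_mm_s, cutoffs)
  attr(tracks, "cutoffs") <- cutoffs
  tracks
}
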