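#' Write tracks, centerlines, logs and event tables as CSV
#'
#' Plain-CSV serializers for the pipeline's tabular outputs. List columns
#' (masks) are dropped; centerlines are written in long format with one row
#' per (frame, worm, point).
#'
#' @param tracks,centerlines,stim_log,events,truth tibbles produced by the
#'   pipeline.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  keep <- !vapply(tracks, is.list, logical(1))
  utils::write.csv(tracks[keep], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
write_centerlines_csv <- function(centerlines, path) {
  utils::write.csv(centerlines, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
write_stim_log_csv <- function(stim_log, path) {
  utils::write.csv(stim_log, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' Centerline list-column to long tibble
#'
#' @param tracks tibble with `worm_id`, `frame` and a `centerline` list
#'   column of `n x 2` mm matrices (head first).
#' @return Long tibble: `worm_id`, `frame`, `point_idx` (0-based), `x_mm`,
#'   `y_mm`, `head_flag` (TRUE at point 0).
#' @export
centerlines_long <- function(tracks) {
  purrr::pmap_dfr(
    list(tracks$worm_id, tracks$frame, tracks$centerline),
    function(id, fr, cl) {
      if (is.null(cl)) return(NULL)
      tibble::tibble(worm_id = id, frame = fr,
                     point_idx = seq_len(nrow(cl)) - 1L,
                     x_mm = cl[, 1], y_mm = cl[, 2],
                     head_flag = seq_len(nrow(cl)) == 1)
    })
}
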