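#' Validity criteria for worm blobs and tracks
#'
#' Inclusion thresholds used when deciding whether a blob is a single, sanely
#' shaped, moving worm. Defaults follow the head/tail stimulation analysis
#' (length at most 700 um); turning experiments additionally impose a 550-um
#' minimum length and longer pre-stimulus tracking.
#'
#' @param max_length_um maximum centerline length (um).
#' @param min_length_um minimum centerline length (um); `NA` to skip.
#' @param min_track_pre_s,min_track_post_s required continuous tracking
#'   before/after a stimulus onset (used by [build_event_table()]).
#' @param max_mean_width_um maximum mean body width, estimated as blob area
#'   divided by centerline length ("exceedingly fat" guard).
#' @param min_solidity minimum blob solidity ("oddly shaped" guard).
#' @param min_displacement_um minimum centroid displacement over the trailing
#'   10 s ("stationary" guard).
#' @return A list of class `"validity_criteria"`.
#' @export
validity_criteria <- function(max_length_um = 700,
                              min_length_um = NA,
                              min_track_pre_s = 8,
                              min_track_post_s = 8,
                              max_mean_width_um = 120,
                              min_solidity = 0.35,
                              min_displacement_um = 100) {
  if (!is.na(min_length_um) && min_length_um >= max_length_um) {
    abort("min_length_um must be < max_length_um")
  }
  structure(list(max_length_um = max_length_um,
                 min_length_um = min_length_um,
                 min_track_pre_s = min_track_pre_s,
                 min_track_post_s = min_track_post_s,
                 max_mean_width_um = max_mean_width_um,
                 min_solidity = min_solidity,
                 min_displacement_um = min_displacement_um),
            class = "validity_criteria")
}

#' Criteria preset for turn-triggered experiments
#' @param ... overrides passed to [validity_criteria()].
#' @export
#' @rdname validity_criteria
turning_criteria <- function(...) {
  args <- utils::modifyList(
    list(min_length_um = 550, min_track_pre_s = 17, min_track_post_s = 0),
    list(...))
  do.call(validity_criteria, args)
}

#' Validate one worm observation
#'
#' Applies the per-blob validity rules: centerline present, length within
#' bounds, mean width not excessive, solidity (shape), and non-stationarity.
#'
#' @param blob one row of a [segment_frame()] tibble (or a list with
#'   `area_px` and `solidity`).
#' @param length_um centerline arc length in um, or `NA` if extraction failed.
#' @param crit a [validity_criteria()].
#' @param um_per_px image scale, needed to convert blob area to um^2.
#' @param trailing_disp_um centroid displacement over the trailing 10 s, or
#'   `NULL` to skip the stationarity check.
#' @return `list(valid = logical, reasons = character vector)` with reason
#'   codes among `"no-centerline"`, `"too-long"`, `"too-short"`, `"too-fat"`,
#'   `"shape"`, `"stationary"`.
#' @export
validate_worm <- function(blob, length_um, crit, um_per_px,
                          trailing_disp_um = NULL) {
  reasons <- character(0)
  if (is.na(length_um) || length_um <= 0) {
    reasons <- c(reasons, "no-centerline")
  } else {
    if (length_um > crit$max_length_um) reasons <- c(reasons, "too-long")
    if (!is.na(crit$min_length_um) && length_um < crit$min_length_um) {
      reasons <- c(reasons, "too-short")
    }
    mean_width_um <- blob$area_px * um_per_px^2 / length_um
    if (mean_width_um > crit$max_mean_width_um) {
      reasons <- c(reasons, "too-fat")
    }
  }
  if (blob$solidity < crit$min_solidity) reasons <- c(reasons, "shape")
  if (!is.null(trailing_disp_um) && !is.na(trailing_disp_um) &&
      trailing_disp_um < crit$min_displacement_um) {
    reasons <- c(reasons, "stationary")
  }
  list(valid = length(reasons) == 0, reasons = reasons)
}

#' Start a tracker
#'
#' Greedy nearest-centroid track stitching in the Parallel Worm Tracker
#' lineage: each active track claims its nearest blob within `max_disp_px`;
#' unmatched blobs open new tracks; tracks unmatched for more than `max_gap`
#' frames are closed. When two tracks claim the same blob, both are closed
#' and the merged blob is followed as a new, merge-flagged (invalid) entity;
#' the merged entity is closed again once it splits back into several blobs.
#'
#' @param max_disp_px maximum per-frame centroid displacement.
#' @param max_gap frames a track may go unobserved before closing.
#' @return A tracker state list for [link_tracks()].
#' @export
tracker_init <- function(max_disp_px = 20, max_gap = 3) {
  list(max_disp_px = max_disp_px, max_gap = max_gap, next_id = 1L,
       active = tibble::tibble(worm_id = integer(), x = numeric(),
                               y = numeric(), last_frame = integer(),
                               merged = logical(), gap = integer()),
       obs = list())
}

#' Link one frame of blobs into the running tracks
#'
#' @param tracker state from [tracker_init()] (or a previous call).
#' @param blobs a [segment_frame()] tibble for this frame.
#' @param frame_idx integer frame index (strictly increasing across calls).
#' @return The updated tracker state.
#' @export
link_tracks <- function(tracker, blobs, frame_idx) {
  act <- as.list(tracker$active)
  na <- length(act$worm_id)
  nb <- nrow(blobs)
  assigned_track <- rep(NA_integer_, nb)   # index into act per blob
  closed <- logical(na)
  if (na > 0 && nb > 0) {
    d <- sqrt(outer(act$x, blobs$x_px, `-`)^2 +
              outer(act$y, blobs$y_px, `-`)^2)
    dm <- matrix(d, nrow = na)
    claim <- max.col(-dm, ties.method = "first")
    claim_d <- dm[cbind(seq_len(na), claim)]
    claim[claim_d > tracker$max_disp_px] <- NA_integer_
    # merge: several tracks claim one blob -> close them all
    tab <- tabulate(claim[!is.na(claim)], nb)
    merged_blobs <- which(tab >= 2)
    closed <- !is.na(claim) & claim %in% merged_blobs
    ok <- which(!is.na(claim) & !closed)
    if (length(ok) > 0) {
      for (i in ok[order(claim_d[ok])]) {
        j <- claim[i]
        if (is.na(assigned_track[j])) assigned_track[j] <- i
      }
    }
    # a merge-flagged track seeing >= 2 nearby blobs has split: close it
    for (i in which(act$merged)) {
      if (sum(dm[i, ] <= tracker$max_disp_px) >= 2) {
        closed[i] <- TRUE
        assigned_track[!is.na(assigned_track) & assigned_track == i] <-
          NA_integer_
      }
    }
  }

  ids <- integer(nb); mflags <- logical(nb)
  new_id <- integer(0); new_x <- new_y <- numeric(0); new_m <- logical(0)
  for (j in seq_len(nb)) {
    i <- assigned_track[j]
    if (!is.na(i) && !closed[i]) {
      ids[j] <- act$worm_id[i]; mflags[j] <- act$merged[i]
      act$x[i] <- blobs$x_px[j]; act$y[i] <- blobs$y_px[j]
      act$last_frame[i] <- frame_idx; act$gap[i] <- 0L
    } else {
      ids[j] <- tracker$next_id
      tracker$next_id <- tracker$next_id + 1L
      # an entity born where >= 2 tracks converged is a merge product
      mflags[j] <- na > 0 &&
        sum(sqrt((tracker$active$x - blobs$x_px[j])^2 +
                 (tracker$active$y - blobs$y_px[j])^2) <=
            tracker$max_disp_px) >= 2
      new_id <- c(new_id, ids[j]); new_x <- c(new_x, blobs$x_px[j])
      new_y <- c(new_y, blobs$y_px[j]); new_m <- c(new_m, mflags[j])
    }
  }
  keep <- !closed
  act <- lapply(act, function(col) col[keep])
  if (length(new_id) > 0) {
    act$worm_id <- c(act$worm_id, new_id)
    act$x <- c(act$x, new_x); act$y <- c(act$y, new_y)
    act$last_frame <- c(act$last_frame, rep(frame_idx, length(new_id)))
    act$merged <- c(act$merged, new_m)
    act$gap <- c(act$gap, integer(length(new_id)))
  }
  # age out unmatched tracks
  unmatched <- act$last_frame < frame_idx
  act$gap[unmatched] <- act$gap[unmatched] + 1L
  stay <- act$gap <= tracker$max_gap
  act <- lapply(act, function(col) col[stay])
  tracker$active <- tibble::new_tibble(act, nrow = length(act$worm_id))
  if (nb > 0) {
    chunk <- blobs
    chunk$worm_id <- ids
    chunk$merged <- mflags
    tracker$obs[[length(tracker$obs) + 1]] <- chunk
  }
  tracker
}

#' Collect all observations from a tracker
#'
#' @param tracker tracker state after the last [link_tracks()] call.
#' @param fps frames per second; adds a `time_s` column when given.
#' @return A tibble of observations sorted by `worm_id`, `frame`, with a
#'   `merged` flag marking collision entities.
#' @export
finalize_tracks <- function(tracker, fps = NULL) {
  if (length(tracker$obs) == 0) {
    return(tibble::tibble(worm_id = integer(), frame = integer()))
  }
  out <- dplyr::arrange(dplyr::bind_rows(tracker$obs),
                        .data$worm_id, .data$frame)
  if (!is.null(fps)) out$time_s <- out$frame / fps
  out
}

#' Segment and track a whole movie
#'
#' @param frames list of images (e.g. from [render_frame()] or
#'   [read_movie()]).
#' @param threshold,min_area_px passed to [segment_frame()].
#' @param max_disp_px,max_gap passed to [tracker_init()].
#' @param fps frame rate for the `time_s` column.
#' @return The observation tibble from [finalize_tracks()].
#' @export
track_movie <- function(frames, threshold = 105, min_area_px = 5,
                        max_disp_px = 20, max_gap = 3, fps = 30) {
  trk <- tracker_init(max_disp_px, max_gap)
  for (f in seq_along(frames)) {
    blobs <- segment_frame(frames[[f]], threshold, min_area_px,
                           frame_idx = f)
    trk <- link_tracks(trk, blobs, f)
  }
  finalize_tracks(trk, fps)
}

#' Cumulative recording duration in worm-hours
#'
#' Sums, over frames, the number of concurrently tracked valid worms and
#' converts to hours. Merge-flagged observations are excluded; pass a `valid`
#' logical column to restrict further.
#'
#' @param tracks observation tibble (needs `frame`, `worm_id`, optionally
#'   `merged` and `valid`).
#' @param fps frames per second.
#' @return Worm-hours (scalar).
#' @export
worm_hours <- function(tracks, fps) {
  if (nrow(tracks) == 0) return(0)
  keep <- rep(TRUE, nrow(tracks))
  if ("merged" %in% names(tracks)) keep <- keep & !tracks$merged
  if ("valid" %in% names(tracks)) keep <- keep & tracks$valid
  sum(keep) / fps / 3600
}
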