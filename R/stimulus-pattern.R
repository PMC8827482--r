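#' Schedule configuration for stimulus delivery
#'
#' @param isi_s interstimulus interval of the open-loop scheduler (s).
#' @param intensity_set intensities (uW/mm^2) drawn independently for head
#'   and tail in head/tail mode.
#' @param wholebody_intensity_set the two whole-body intensities (experiment
#'   and control) drawn in whole-body and closed-loop modes.
#' @param duration_s stimulus duration (s).
#' @param mode `"open_loop_headtail"`, `"open_loop_wholebody"` or
#'   `"closed_loop_turn"`.
#' @param refractory_s per-worm refractory period for closed-loop commands.
#' @param head_tail_diameter_mm,whole_body_diameter_mm spot diameters.
#' @return A list of class `"schedule_config"`.
#' @export
schedule_config <- function(isi_s = 30,
                            intensity_set = c(0, 20, 40, 60, 80),
                            wholebody_intensity_set = c(80, 0.5),
                            duration_s = 1,
                            mode = c("open_loop_headtail",
                                     "open_loop_wholebody",
                                     "closed_loop_turn"),
                            refractory_s = 30,
                            head_tail_diameter_mm = 0.5,
                            whole_body_diameter_mm = 1.5) {
  mode <- match.arg(mode)
  if (isi_s < duration_s) abort("isi_s must be >= duration_s")
  if (any(intensity_set < 0)) abort("intensities must be >= 0")
  structure(list(isi_s = isi_s, intensity_set = intensity_set,
                 wholebody_intensity_set = wholebody_intensity_set,
                 duration_s = duration_s, mode = mode,
                 refractory_s = refractory_s,
                 head_tail_diameter_mm = head_tail_diameter_mm,
                 whole_body_diameter_mm = whole_body_diameter_mm),
            class = "schedule_config")
}

#' Build a targeted illumination pattern from a centerline
#'
#' Head disks are centered on centerline point 0 (the head tip), tail disks
#' on point 19 (the tail tip), and whole-body disks on the centroid of the
#' 20 points.
#'
#' @param centerline a centerline tibble (from [extract_centerline()] or
#'   ground truth), oriented head-first unless `target = "whole_body"`.
#' @param target `"head"`, `"tail"`, `"both"` or `"whole_body"`.
#' @param intensity_head,intensity_tail intensities (uW/mm^2); for
#'   `whole_body`, `intensity_head` is used.
#' @param cfg a [schedule_config()] providing the spot diameters.
#' @param oriented is the centerline head-first? Targeting head or tail
#'   without orientation is an error.
#' @return A list of class `"stimulus_pattern"` with `disks` (tibble
#'   `x_mm`, `y_mm`, `diameter_mm`, `intensity`, `part`), `target`, and a
#'   `cropped` slot (`NULL` until [crop_against_others()]).
#' @export
make_targeted_pattern <- function(centerline, target = c("head", "tail",
                                                         "both", "whole_body"),
                                  intensity_head = 80, intensity_tail = 80,
                                  cfg = schedule_config(), oriented = TRUE) {
  target <- match.arg(target)
  if (!oriented && target != "whole_body") {
    abort("head/tail targeting requires an oriented centerline")
  }
  xs <- centerline$x_mm; ys <- centerline$y_mm
  n <- length(xs)
  d_ht <- cfg$head_tail_diameter_mm
  disks <- switch(target,
    head = tibble::tibble(x_mm = xs[1], y_mm = ys[1], diameter_mm = d_ht,
                          intensity = intensity_head, part = "head"),
    tail = tibble::tibble(x_mm = xs[n], y_mm = ys[n], diameter_mm = d_ht,
                          intensity = intensity_tail, part = "tail"),
    both = tibble::tibble(x_mm = c(xs[1], xs[n]), y_mm = c(ys[1], ys[n]),
                          diameter_mm = d_ht,
                          intensity = c(intensity_head, intensity_tail),
                          part = c("head", "tail")),
    whole_body = tibble::tibble(x_mm = mean(xs), y_mm = mean(ys),
                                diameter_mm = cfg$whole_body_diameter_mm,
                                intensity = intensity_head,
                                part = "whole_body"))
  structure(list(disks = disks, target = target, cropped = NULL),
            class = "stimulus_pattern")
}

#' Crop a stimulus pattern away from encroaching worms
#'
#' Removes from the pattern every pixel within `margin_um` of another worm's
#' body, so neighbors encroaching on a spot are never illuminated. The
#' target worm's own body is passed via `own_mask` and is never cropped.
#'
#' @param pattern a [make_targeted_pattern()] result.
#' @param other_masks list of neighbor masks, each `list(m, x0, y0)` as in
#'   [segment_frame()] output.
#' @param own_mask the target worm's mask (same format), or `NULL`.
#' @param margin_um crop margin around neighbors (um).
#' @param um_per_px image scale.
#' @return The pattern with a `cropped` raster (`list(m, x0, y0)`), plus
#'   `delivered_area_frac` (cropped / full pixel area) and logical
#'   `fully_cropped` per disk.
#' @export
crop_against_others <- function(pattern, other_masks, own_mask = NULL,
                                margin_um = 100, um_per_px = 44) {
  r_px <- pattern$disks$diameter_mm * 1000 / um_per_px / 2
  cx <- mm_to_px(pattern$disks$x_mm, um_per_px)
  cy <- mm_to_px(pattern$disks$y_mm, um_per_px)
  x0 <- floor(min(cx - r_px)); x1 <- ceiling(max(cx + r_px))
  y0 <- floor(min(cy - r_px)); y1 <- ceiling(max(cy + r_px))
  xs <- x0:x1; ys <- y0:y1
  full <- matrix(FALSE, length(ys), length(xs))
  for (k in seq_along(r_px)) {
    full <- full | outer((ys - cy[k])^2, (xs - cx[k])^2, `+`) <= r_px[k]^2
  }
  keep <- full
  margin_px <- margin_um / um_per_px
  own_idx <- NULL
  if (!is.null(own_mask)) {
    ow <- which(own_mask$m, arr.ind = TRUE)
    own_idx <- cbind(x = ow[, 2] - 1 + own_mask$x0,
                     y = ow[, 1] - 1 + own_mask$y0)
  }
  for (nm in other_masks) {
    nw <- which(nm$m, arr.ind = TRUE)
    if (nrow(nw) == 0) next
    nx <- nw[, 2] - 1 + nm$x0; ny <- nw[, 1] - 1 + nm$y0
    inwin <- nx >= x0 - margin_px & nx <= x1 + margin_px &
      ny >= y0 - margin_px & ny <= y1 + margin_px
    if (!any(inwin)) next
    nx <- nx[inwin]; ny <- ny[inwin]
    pidx <- which(keep)
    if (length(pidx) == 0) break
    pr <- ((pidx - 1) %% length(ys)) + 1
    pc <- ((pidx - 1) %/% length(ys)) + 1
    px <- xs[pc]; py <- ys[pr]
    d2 <- outer(px, nx, function(a, b) (a - b)^2) +
      outer(py, ny, function(a, b) (a - b)^2)
    hit <- apply(d2, 1, min) <= margin_px^2
    keep[pidx[hit]] <- FALSE
  }
  # never crop the target worm's own body
  if (!is.null(own_idx) && nrow(own_idx) > 0) {
    inwin <- own_idx[, 1] >= x0 & own_idx[, 1] <= x1 &
      own_idx[, 2] >= y0 & own_idx[, 2] <= y1
    oi <- own_idx[inwin, , drop = FALSE]
    if (nrow(oi) > 0) {
      sel <- cbind(oi[, 2] - y0 + 1, oi[, 1] - x0 + 1)
      keep[sel] <- keep[sel] | full[sel]
    }
  }
  pattern$cropped <- list(m = keep, x0 = x0, y0 = y0)
  pattern$delivered_area_frac <- sum(keep) / max(1, sum(full))
  # per-disk full cropping
  pattern$fully_cropped <- vapply(seq_along(r_px), function(k) {
    disk <- outer((ys - cy[k])^2, (xs - cx[k])^2, `+`) <= r_px[k]^2
    sum(keep & disk) == 0
  }, logical(1))
  pattern
}

#' Sample the delivered intensity at points
#'
#' Returns, for each query point, the summed intensity of all pattern disks
#' covering it, honoring any cropped raster.
#'
#' @param patterns list of `stimulus_pattern`s currently applied.
#' @param x_mm,y_mm query coordinates (e.g. true head/tail tips).
#' @param um_per_px image scale (needed when patterns are cropped).
#' @return Numeric vector of intensities (uW/mm^2).
#' @export
sample_intensity <- function(patterns, x_mm, y_mm, um_per_px = 44) {
  out <- numeric(length(x_mm))
  for (p in patterns) {
    for (k in seq_len(nrow(p$disks))) {
      d <- p$disks[k, ]
      inside <- (x_mm - d$x_mm)^2 + (y_mm - d$y_mm)^2 <= (d$diameter_mm / 2)^2
      if (!is.null(p$cropped)) {
        px <- round(mm_to_px(x_mm, um_per_px)) - p$cropped$x0 + 1
        py <- round(mm_to_px(y_mm, um_per_px)) - p$cropped$y0 + 1
        okwin <- px >= 1 & px <= ncol(p$cropped$m) &
          py >= 1 & py <= nrow(p$cropped$m)
        crop_ok <- rep(FALSE, length(x_mm))
        crop_ok[okwin] <- p$cropped$m[cbind(py[okwin], px[okwin])]
        inside <- inside & crop_ok
      }
      out <- out + inside * d$intensity
    }
  }
  out
}
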