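#' Fit a camera-to-projector projective calibration
#'
#' Least-squares 8-parameter projective (homography) fit to dot-grid
#' correspondences, as produced by projecting a calibration pattern and
#' locating the dots in the camera image.
#'
#' @param cam_px `n x 2` matrix of camera pixel coordinates of the dots.
#' @param proj_px `n x 2` matrix of the corresponding projector pixels.
#' @param um_per_px physical scale of projector pixels, for the residual.
#' @return A list of class `"calibration_map"` with the 3x3 matrix `H`
#'   (camera -> projector, `H[3,3] = 1`), `residual_rms_um` and `n_points`.
#' @export
fit_calibration <- function(cam_px, proj_px, um_per_px = 44) {
  cam_px <- as.matrix(cam_px); proj_px <- as.matrix(proj_px)
  n <- nrow(cam_px)
  if (n < 4) abort("need at least 4 correspondences")
  x <- cam_px[, 1]; y <- cam_px[, 2]
  u <- proj_px[, 1]; v <- proj_px[, 2]
  A <- rbind(
    cbind(x, y, 1, 0, 0, 0, -u * x, -u * y),
    cbind(0, 0, 0, x, y, 1, -v * x, -v * y))
  b <- c(u, v)
  qrA <- qr(A)
  if (qrA$rank < 8) abort("degenerate (collinear) calibration points")
  h <- qr.coef(qrA, b)
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  mapped <- apply_calibration_H(H, cam_px)
  res <- sqrt(mean(rowSums((mapped - proj_px)^2)))
  structure(list(H = H, residual_rms_um = res * um_per_px,
                 um_per_px = um_per_px, n_points = n),
            class = "calibration_map")
}

apply_calibration_H <- function(H, xy) {
  p <- cbind(xy, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3]
}

#' Map points through (or back through) a calibration
#'
#' @param map a `"calibration_map"`.
#' @param xy `n x 2` matrix of points.
#' @param inverse map projector -> camera instead.
#' @return `n x 2` matrix of mapped points.
#' @export
apply_calibration <- function(map, xy, inverse = FALSE) {
  H <- if (inverse) solve(map$H) else map$H
  apply_calibration_H(H, as.matrix(xy))
}

#' Quantify calibration drift over a recording
#'
#' Maps the end-of-run dot positions through the start-of-run transform and
#' reports the mean displacement from the reference projector positions.
#'
#' @param map the start-of-run [fit_calibration()] result.
#' @param cam_px_end `n x 2` camera positions of the dots at the end of the
#'   recording.
#' @param proj_px the reference projector positions (same order).
#' @return Drift in um (mean displacement).
#' @export
measure_drift <- function(map, cam_px_end, proj_px) {
  mapped <- apply_calibration(map, cam_px_end)
  mean(sqrt(rowSums((mapped - as.matrix(proj_px))^2))) * map$um_per_px
}

#' Write a calibration report as JSON
#'
#' @param map a `"calibration_map"`.
#' @param path output path.
#' @param drift_um optional drift from [measure_drift()].
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(map, path, drift_um = NULL) {
  jsonlite::write_json(
    list(H = map$H, residual_rms_um = map$residual_rms_um,
         um_per_px = map$um_per_px, n_points = map$n_points,
         drift_um = drift_um),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Binary visual frame stamp
#'
#' Encodes a frame index as dots equally spaced on a circle, one dot per
#' binary digit (dot present = bit 1, least significant bit at angle 0,
#' proceeding counterclockwise). `decode_timestamp()` inverts the encoding
#' exactly; worms inside the circle should be excluded from analysis using
#' [timestamp_exclusion_mask()].
#'
#' @param frame_idx integer in `[0, 2^n_bits)`.
#' @param n_bits number of dots/bits.
#' @param size `c(H, W)` image size in px.
#' @param center `c(x, y)` circle center (0-based px); default image center.
#' @param radius circle radius (px).
#' @param dot_radius dot radius (px).
#' @param fg dot intensity.
#' @return `encode_timestamp()`: an integer image matrix;
#'   `decode_timestamp()`: the decoded frame index.
#' @export
encode_timestamp <- function(frame_idx, n_bits = 16, size = c(128, 128),
                             center = NULL, radius = NULL, dot_radius = 3,
                             fg = 255) {
  if (frame_idx < 0 || frame_idx >= 2^n_bits) {
    abort("frame_idx out of range for n_bits")
  }
  H <- size[1]; W <- size[2]
  center <- center %||% c((W - 1) / 2, (H - 1) / 2)
  radius <- radius %||% (min(H, W) / 2 - dot_radius - 2)
  img <- matrix(0L, H, W)
  bits <- as.integer(intToBits(frame_idx))[seq_len(n_bits)]
  ang <- 2 * pi * (seq_len(n_bits) - 1) / n_bits
  for (k in which(bits == 1L)) {
    cx <- center[1] + radius * cos(ang[k])
    cy <- center[2] + radius * sin(ang[k])
    xs <- max(0, floor(cx - dot_radius)):min(W - 1, ceiling(cx + dot_radius))
    ys <- max(0, floor(cy - dot_radius)):min(H - 1, ceiling(cy + dot_radius))
    hit <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= dot_radius^2
    sub <- img[ys + 1, xs + 1, drop = FALSE]
    sub[hit] <- as.integer(fg)
    img[ys + 1, xs + 1] <- sub
  }
  img
}

#' @rdname encode_timestamp
#' @param img image matrix containing the stamp.
#' @param threshold intensity above which a dot position reads as 1.
#' @export
decode_timestamp <- function(img, n_bits = 16, center = NULL, radius = NULL,
                             dot_radius = 3, threshold = 127) {
  H <- nrow(img); W <- ncol(img)
  center <- center %||% c((W - 1) / 2, (H - 1) / 2)
  radius <- radius %||% (min(H, W) / 2 - dot_radius - 2)
  ang <- 2 * pi * (seq_len(n_bits) - 1) / n_bits
  val <- 0
  for (k in seq_len(n_bits)) {
    cx <- center[1] + radius * cos(ang[k])
    cy <- center[2] + radius * sin(ang[k])
    if (cx - dot_radius < 0 || cx + dot_radius > W - 1 ||
        cy - dot_radius < 0 || cy + dot_radius > H - 1) {
      abort("timestamp circle extends outside the image",
            class = "wormloop_timestamp_unreadable")
    }
    xs <- floor(cx - dot_radius):ceiling(cx + dot_radius)
    ys <- floor(cy - dot_radius):ceiling(cy + dot_radius)
    hit <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= (dot_radius / 2)^2
    m <- mean(img[ys + 1, xs + 1][hit])
    if (m > threshold) val <- val + 2^(k - 1)
  }
  as.integer(val)
}

#' @rdname encode_timestamp
#' @export
timestamp_exclusion_mask <- function(n_bits = 16, size = c(128, 128),
                                     center = NULL, radius = NULL,
                                     dot_radius = 3) {
  H <- size[1]; W <- size[2]
  center <- center %||% c((W - 1) / 2, (H - 1) / 2)
  radius <- radius %||% (min(H, W) / 2 - dot_radius - 2)
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  outer((ys - center[2])^2, (xs - center[1])^2, `+`) <=
    (radius + dot_radius)^2
}
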