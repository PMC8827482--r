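#' Render a dark-field frame of the arena
#'
#' Paints each worm as the union of filled disks along its ground-truth
#' centerline with an elliptical width profile (maximum `worm_width_um`,
#' tapering to about one pixel at both tips). Overlapping worms merge into a
#' single bright region, as in real dark-field imaging.
#'
#' @param world a `world_state`.
#' @param cfg the [sim_config()]; `um_per_px` sets the image scale and
#'   `bg_level`/`fg_level` the 8-bit intensities.
#' @return An integer matrix (rows = y, columns = x) of 8-bit values; pixel
#'   `(row r, col c)` has 0-based pixel coordinates `x = c - 1`, `y = r - 1`.
#' @export
render_frame <- function(world, cfg) {
  W <- as.integer(round(cfg$arena_size_mm[1] * 1000 / cfg$um_per_px))
  H <- as.integer(round(cfg$arena_size_mm[2] * 1000 / cfg$um_per_px))
  img <- matrix(as.integer(cfg$bg_level), nrow = H, ncol = W)
  cls <- true_centerlines(world, cfg, n = 41)
  for (cl in cls) {
    img <- paint_worm(img, cl, cfg)
  }
  img
}

# Paint one worm into img: disks of tapered radius along a dense centerline.
paint_worm <- function(img, cl, cfg) {
  H <- nrow(img); W <- ncol(img)
  nd <- nrow(cl)
  s_frac <- seq(0, 1, length.out = nd)
  # elliptical half-width profile in px, floor of ~half a pixel at the tips
  r_px <- pmax(0.5,
               (cfg$worm_width_um / 2 / cfg$um_per_px) *
                 sqrt(pmax(0, 1 - (2 * s_frac - 1)^2)))
  cx <- mm_to_px(cl[, 1], cfg$um_per_px)
  cy <- mm_to_px(cl[, 2], cfg$um_per_px)
  fg <- as.integer(cfg$fg_level)
  for (k in seq_len(nd)) {
    rk <- r_px[k]
    xk <- max(0, floor(cx[k] - rk)):min(W - 1, ceiling(cx[k] + rk))
    yk <- max(0, floor(cy[k] - rk)):min(H - 1, ceiling(cy[k] + rk))
    if (length(xk) == 0 || length(yk) == 0) next
    dy2 <- (yk - cy[k])^2
    for (xv in xk) {
      sel <- yk[dy2 + (xv - cx[k])^2 <= rk^2]
      if (length(sel) > 0) img[sel + 1, xv + 1] <- fg
    }
  }
  img
}

#' Write a movie as a multi-page 8-bit grayscale TIFF
#'
#' @param frames list of integer matrices from [render_frame()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(frames, path) {
  pages <- lapply(frames, function(f) f / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a multi-page TIFF (or a directory of single-frame images) as a movie
#'
#' @param path a `.tif`/`.tiff` file or a directory of per-frame TIFFs
#'   (sorted by file name).
#' @return A list of integer matrices scaled to 0-255.
#' @export
read_movie <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) == 0) abort("no TIFF frames found in directory")
    pages <- lapply(files, function(f) tiff::readTIFF(f, all = FALSE))
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.integer(round(p * 255)), nrow = nrow(p))
  })
}
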