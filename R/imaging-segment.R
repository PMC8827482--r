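#' Label connected components of a binary mask (8-connectivity)
#'
#' @param mask logical matrix.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered from 1 in first-pixel (column-major) order.
#' @export
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, H, W)
  if (length(idx) == 0) return(lab)
  rank <- integer(H * W)
  rank[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  edges <- NULL
  nbr <- function(ok, off) {
    from <- idx[ok]; to <- from + off
    keep <- mask[to]
    cbind(rank[from[keep]], rank[to[keep]])
  }
  e <- rbind(
    nbr(cc < W, H),                 # right
    nbr(r < H, 1L),                 # down
    nbr(r < H & cc < W, H + 1L),    # down-right
    nbr(r > 1L & cc < W, H - 1L))   # up-right
  g <- igraph::make_graph(t(e), n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  # renumber in first-pixel order
  first <- !duplicated(lab[idx])
  remap <- integer(max(memb))
  remap[lab[idx][first]] <- seq_len(sum(first))
  lab[idx] <- remap[lab[idx]]
  lab
}

# Second-central-moment ellipse ratio of a set of 0-based pixel coords:
# sqrt of the eigenvalue ratio of the coordinate covariance.
mask_ellipse_ratio <- function(x, y) {
  if (length(x) < 2) return(1)
  cxx <- mean(x^2) - mean(x)^2 + 1 / 12  # + pixel extent
  cyy <- mean(y^2) - mean(y)^2 + 1 / 12
  cxy <- mean(x * y) - mean(x) * mean(y)
  tr <- cxx + cyy
  det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 0) return(Inf)
  sqrt(l1 / l2)
}

# Solidity: pixel area / area of the convex hull of the pixel squares.
mask_solidity <- function(x, y) {
  if (length(x) < 3) return(1)
  # corners of each pixel square so the hull bounds the full pixel footprint
  px <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  py <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- grDevices::chull(px, py)
  hx <- px[h]; hy <- py[h]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (hull_area <= 0) return(1)
  min(1, length(x) / hull_area)
}

#' Segment one frame into candidate worm blobs
#'
#' Thresholds the frame at a global intensity, labels 8-connected foreground
#' components, and reports per-blob statistics including the ellipse
#' (major/minor axis) ratio computed from second central moments of the
#' binarized blob.
#'
#' @param img integer matrix (8-bit grayscale; rows = y, cols = x).
#' @param threshold global intensity threshold; foreground is `img > threshold`.
#' @param min_area_px,max_area_px area gates; components outside are dropped.
#' @param frame_idx optional frame index recorded in the output.
#' @param keep_masks keep each blob's cropped binary mask as a list column
#'   (needed downstream for centerlines and solidity).
#' @return A tibble, one row per blob: `frame`, `blob_id`, `area_px`,
#'   centroid `x_px`, `y_px` (0-based), bounding box `x0, y0, x1, y1`
#'   (inclusive), `ellipse_ratio`, `solidity`, and `mask` (list of
#'   `list(m, x0, y0)` with `m` a logical matrix whose top-left pixel has
#'   0-based coordinates `(x0, y0)`).
#' @export
segment_frame <- function(img, threshold = 105, min_area_px = 5,
                          max_area_px = Inf, frame_idx = NA_integer_,
                          keep_masks = TRUE) {
  lab <- label_components(img > threshold)
  n <- max(lab)
  empty <- tibble::tibble(
    frame = integer(), blob_id = integer(), area_px = integer(),
    x_px = numeric(), y_px = numeric(), x0 = integer(), y0 = integer(),
    x1 = integer(), y1 = integer(), ellipse_ratio = numeric(),
    solidity = numeric(), mask = list())
  if (n == 0) return(empty)
  idx <- which(lab > 0)
  H <- nrow(lab)
  r <- ((idx - 1L) %% H)        # 0-based y
  cc <- ((idx - 1L) %/% H)      # 0-based x
  lb <- lab[idx]
  ord <- order(lb)
  r <- r[ord]; cc <- cc[ord]; lb <- lb[ord]
  bounds <- c(0L, cumsum(tabulate(lb, n)))
  keep <- integer(0)
  area <- x_px <- y_px <- er <- sol <- numeric(0)
  bx0 <- by0 <- bx1 <- by1 <- integer(0)
  masks <- list()
  for (k in seq_len(n)) {
    sel <- (bounds[k] + 1L):bounds[k + 1L]
    a <- length(sel)
    if (a < min_area_px || a > max_area_px) next
    x <- cc[sel]; y <- r[sel]
    x0 <- min(x); x1 <- max(x); y0 <- min(y); y1 <- max(y)
    m <- NULL
    if (keep_masks) {
      m <- matrix(FALSE, nrow = y1 - y0 + 1, ncol = x1 - x0 + 1)
      m[cbind(y - y0 + 1L, x - x0 + 1L)] <- TRUE
    }
    keep <- c(keep, k); area <- c(area, a)
    x_px <- c(x_px, mean(x)); y_px <- c(y_px, mean(y))
    bx0 <- c(bx0, x0); by0 <- c(by0, y0); bx1 <- c(bx1, x1); by1 <- c(by1, y1)
    er <- c(er, mask_ellipse_ratio(x, y))
    sol <- c(sol, mask_solidity(x, y))
    masks[[length(masks) + 1]] <- list(m = m, x0 = x0, y0 = y0)
  }
  if (length(keep) == 0) return(empty)
  tibble::new_tibble(list(
    frame = rep(frame_idx, length(keep)), blob_id = keep,
    area_px = as.integer(area), x_px = x_px, y_px = y_px,
    x0 = bx0, y0 = by0, x1 = bx1, y1 = by1,
    ellipse_ratio = er, solidity = sol, mask = masks),
    nrow = length(keep))
}
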