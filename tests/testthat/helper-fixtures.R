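# Fixture builders and independent oracles used across the suite.

# logical matrix with a filled axis-aligned rectangle
rect_mask <- function(H, W, r0, c0, h, w) {
  m <- matrix(FALSE, H, W)
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
  m
}

disk_mask <- function(R, pad = 2) {
  n <- 2 * (R + pad) + 1
  ctr <- R + pad + 1
  xs <- seq_len(n)
  outer((xs - ctr)^2, (xs - ctr)^2, `+`) <= R^2
}

# draw a thick line into a mask (used to build L/T/X/H shapes)
draw_bar <- function(m, r0, c0, r1, c1, half = 1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) * 2 + 1
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  for (i in seq_len(n)) {
    m[max(1, rr[i] - half):min(nrow(m), rr[i] + half),
      max(1, cc[i] - half):min(ncol(m), cc[i] + half)] <- TRUE
  }
  m
}

# single-pixel polyline skeleton from integer waypoints (8-connected)
draw_thin_path <- function(m, pts) {
  for (k in seq_len(nrow(pts) - 1)) {
    r0 <- pts[k, 1]; c0 <- pts[k, 2]; r1 <- pts[k + 1, 1]; c1 <- pts[k + 1, 2]
    n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
    rr <- round(seq(r0, r1, length.out = n))
    cc <- round(seq(c0, c1, length.out = n))
    m[cbind(rr, cc)] <- TRUE
  }
  m
}

# Exhaustive longest endpoint-to-endpoint path oracle on the pixel graph
# (igraph all_simple_paths over every endpoint pair), independent of the
# two-pass implementation.
oracle_longest_path_length <- function(skel) {
  idx <- which(skel)
  H <- nrow(skel)
  n <- length(idx)
  if (n == 1) return(0)
  rank <- integer(length(skel)); rank[idx] <- seq_len(n)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  at <- function(rr, ncc) {
    ok <- rr >= 1 & rr <= H & ncc >= 1 & ncc <= ncol(skel)
    out <- logical(length(rr))
    out[ok] <- skel[(ncc[ok] - 1L) * H + rr[ok]]
    out
  }
  edges <- NULL
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nr <- r + dr; nc <- cc + dc
    ok <- at(nr, nc)
    if (dr != 0 && dc != 0) {
      # same graph rule as the implementation's skeleton: drop diagonals
      # that shortcut a shared foreground 4-neighbor
      ok <- ok & !(at(r, nc) | at(nr, cc))
    }
    tgt <- (nc - 1L) * H + nr
    from <- rank[idx[ok]]; to <- rank[tgt[ok]]
    keep <- from < to
    edges <- rbind(edges, cbind(from[keep], to[keep]))
  }
  edges <- unique(edges)
  w <- ifelse(abs(r[edges[, 1]] - r[edges[, 2]]) +
                abs(cc[edges[, 1]] - cc[edges[, 2]]) == 2, sqrt(2), 1)
  g <- igraph::make_graph(t(edges), n = n, directed = FALSE)
  deg <- igraph::degree(g)
  eps <- which(deg == 1)
  best <- -Inf
  for (i in seq_along(eps)) for (j in seq_along(eps)) {
    if (j <= i) next
    ps <- igraph::all_simple_paths(g, eps[i], eps[j])
    for (p in ps) {
      v <- as.integer(p)
      len <- sum(w[match(paste(pmin(v[-length(v)], v[-1]),
                               pmax(v[-length(v)], v[-1])),
                         paste(edges[, 1], edges[, 2]))])
      if (len > best) best <- len
    }
  }
  best
}

# random small blob mask whose skeleton has few segments
random_blob_mask <- function(seed, size = 28, n_strokes = 3) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  for (k in seq_len(n_strokes)) {
    r0 <- sample(4:(size - 4), 1); c0 <- sample(4:(size - 4), 1)
    r1 <- sample(4:(size - 4), 1); c1 <- sample(4:(size - 4), 1)
    m <- draw_bar(m, r0, c0, r1, c1, half = 1)
  }
  # keep the largest connected component only
  lab <- label_components(m)
  if (max(lab) > 1) {
    biggest <- which.max(tabulate(lab[lab > 0]))
    m <- lab == biggest
  }
  m
}

# oriented centerline sequence for a rigidly translating straight worm;
# point 0 is the leading end when v > 0
translating_centerlines <- function(n_frames, v_mm_s, fps,
                                    length_mm = 1, head_first = TRUE,
                                    x_start = 0) {
  lapply(seq_len(n_frames), function(f) {
    x0 <- x_start + (f - 1) * v_mm_s / fps
    xs <- seq(x0, x0 - length_mm, length.out = 20)
    cl <- cbind(xs, rep(0, 20))
    if (!head_first) cl <- cl[20:1, , drop = FALSE]
    cl
  })
}

# minimal single-worm world at a given pose (bypasses init_world RNG)
manual_world <- function(cfg, x, y, heading = 0, phase = 0,
                         state = "forward", length_mm = 1, time_s = 0) {
  n <- length(x)
  structure(list(time_s = time_s, frame = 0L, worms = list(
    id = seq_len(n), x = x, y = y,
    heading = rep(heading, n), phase = rep(phase, n),
    state = rep(state, n), state_until = rep(Inf, n),
    bend_dir = rep(1, n), turn_t0 = rep(-Inf, n),
    length_mm = rep(length_mm, n), speed_mult = rep(1, n))),
    class = "world_state")
}
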