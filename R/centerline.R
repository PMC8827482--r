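#' Morphological thinning of a binary mask
#'
#' Zhang-Suen thinning iterated to a fixed point: returns a 1-px-wide
#' 8-connected skeleton contained in the mask. Idempotent by construction
#' (a fixed point thins to itself).
#'
#' @param mask logical matrix (nonempty).
#' @return Logical matrix of the same shape.
#' @export
thin_mask <- function(mask) {
  if (!any(mask)) abort("empty", class = "wormloop_empty_mask")
  m <- mask
  H <- nrow(m); W <- ncol(m)
  # pad so neighbor shifts are trivial
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  sh <- function(mm, dr, dc) {
    mm[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      P2 <- sh(p, -1, 0); P3 <- sh(p, -1, 1); P4 <- sh(p, 0, 1)
      P5 <- sh(p, 1, 1);  P6 <- sh(p, 1, 0);  P7 <- sh(p, 1, -1)
      P8 <- sh(p, 0, -1); P9 <- sh(p, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
        (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      core <- p[2:(H + 1), 2:(W + 1)] & B >= 2 & B <= 6 & A == 1
      del <- if (pass == 1) {
        core & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        core & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(del)) {
        changed <- TRUE
        sub <- p[2:(H + 1), 2:(W + 1)]
        sub[del] <- FALSE
        p[2:(H + 1), 2:(W + 1)] <- sub
      }
    }
    if (!changed) break
  }
  thin_cleanup(p[2:(H + 1), 2:(W + 1)])
}

# Sequential removal of remaining 8-simple non-endpoint pixels (staircase
# artifacts of parallel thinning), leaving a strictly 1-px-wide skeleton.
thin_cleanup <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(FALSE, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  ring <- function(r, c) {
    # x1..x8 = E NE N NW W SW S SE (counterclockwise from east)
    c(p[r, c + 1], p[r - 1, c + 1], p[r - 1, c], p[r - 1, c - 1],
      p[r, c - 1], p[r + 1, c - 1], p[r + 1, c], p[r + 1, c + 1])
  }
  repeat {
    changed <- FALSE
    idx <- which(p)
    for (i in idx) {
      r <- ((i - 1) %% (H + 2)) + 1
      c <- ((i - 1) %/% (H + 2)) + 1
      if (r == 1 || r == H + 2 || c == 1 || c == W + 2) next
      x <- ring(r, c)
      B <- sum(x)
      if (B < 2 || B > 7) next
      # Yokoi connectivity number for 8-connected foreground
      xb <- !x
      C8 <- sum(vapply(c(1, 3, 5, 7), function(k) {
        k1 <- (k %% 8) + 1; k2 <- ((k + 1) %% 8) + 1
        xb[k] - xb[k] * xb[k1] * xb[k2]
      }, numeric(1)))
      if (C8 == 1) {
        p[r, c] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(H + 1), 2:(W + 1)]
}

# Build the pixel graph of a skeleton: coords, adjacency, degrees.
# Adjacency is 8-connectivity minus redundant diagonals: a diagonal edge is
# dropped when the two pixels already share a foreground 4-neighbor, so
# ideal junctions decompose into clean branches instead of triangles.
skeleton_graph <- function(skel) {
  idx <- which(skel)
  H <- nrow(skel); W <- ncol(skel)
  n <- length(idx)
  rank <- integer(length(skel)); rank[idx] <- seq_len(n)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  at <- function(rr, ccc) {
    ok <- rr >= 1L & rr <= H & ccc >= 1L & ccc <= W
    out <- logical(length(rr))
    out[ok] <- skel[(ccc[ok] - 1L) * H + rr[ok]]
    out
  }
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nbrs <- integer(0)
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      rr <- r[i] + dr; ccc <- cc[i] + dc
      if (!at(rr, ccc)) next
      if (dr != 0L && dc != 0L &&
          (at(r[i], ccc) || at(rr, cc[i]))) next  # redundant diagonal
      nbrs <- c(nbrs, rank[(ccc - 1L) * H + rr])
    }
    adj[[i]] <- sort(nbrs)
  }
  list(r = r, c = cc, adj = adj, deg = lengths(adj))
}

#' Decompose a skeleton into branch segments (pass 1)
#'
#' Traverses the skeleton depth-first from the deterministic starting
#' endpoint (lowest `(y, x)`), cutting it into maximal runs of degree-2
#' pixels between nodes (endpoints or branch points). Every skeleton edge
#' belongs to exactly one segment. Step weights are 1 for axial and
#' `sqrt(2)` for diagonal moves.
#'
#' @param skel logical skeleton matrix from [thin_mask()].
#' @return A list of class `"skeleton_segments"`: each element has `pixels`
#'   (an ordered `m x 2` matrix of 0-based `(x, y)` pixel coordinates),
#'   `from`, `to` (node pixel keys) and `length` (weighted steps). A
#'   skeleton with no endpoint raises a `"cyclic-skeleton"` error, matching
#'   the real-time failure mode when an animal touches itself.
#' @export
segment_skeleton <- function(skel) {
  g <- skeleton_graph(skel)
  n <- length(g$deg)
  if (n == 0) abort("empty", class = "wormloop_empty_mask")
  endpoints <- which(g$deg == 1)
  if (n == 1) {
    seg <- list(list(pixels = cbind(x = g$c - 1L, y = g$r - 1L),
                     from = 1L, to = 1L, length = 0))
    return(structure(seg, class = "skeleton_segments", graph = g))
  }
  if (length(endpoints) == 0) {
    abort("cyclic-skeleton", class = "wormloop_cyclic_skeleton")
  }
  is_node <- g$deg != 2
  ord <- order(g$r, g$c)
  start <- ord[ord %in% endpoints][1]
  step_w <- function(a, b) {
    if (abs(g$r[a] - g$r[b]) + abs(g$c[a] - g$c[b]) == 2) sqrt(2) else 1
  }
  edge_key <- function(a, b) {
    if (a < b) paste0(a, "-", b) else paste0(b, "-", a)
  }
  seen <- new.env(parent = emptyenv())
  segs <- list()
  stack <- start
  queued <- logical(n); queued[start] <- TRUE
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (u in g$adj[[v]]) {
      if (!is.null(seen[[edge_key(v, u)]])) next
      # walk from node v through u until the next node
      run <- c(v, u)
      w <- step_w(v, u)
      assign(edge_key(v, u), TRUE, envir = seen)
      prev <- v; cur <- u
      while (!is_node[cur]) {
        nxt <- setdiff(g$adj[[cur]], prev)
        if (length(nxt) == 0) break   # safety; deg-2 should have a next
        nxt <- nxt[1]
        if (!is.null(seen[[edge_key(cur, nxt)]])) break
        assign(edge_key(cur, nxt), TRUE, envir = seen)
        w <- w + step_w(cur, nxt)
        run <- c(run, nxt)
        prev <- cur; cur <- nxt
      }
      segs[[length(segs) + 1]] <- list(
        pixels = cbind(x = g$c[run] - 1L, y = g$r[run] - 1L),
        from = run[1], to = run[length(run)], length = w)
      endnode <- run[length(run)]
      if (!queued[endnode] && is_node[endnode]) {
        queued[endnode] <- TRUE
        stack <- c(stack, endnode)
      }
    }
  }
  structure(segs, class = "skeleton_segments", graph = g)
}

#' Longest endpoint-to-endpoint path through the segments (pass 2)
#'
#' Recursively explores all simple paths through the segment graph that run
#' from one skeleton endpoint to another and returns one of maximal weighted
#' length (diagonal steps weigh `sqrt(2)`). Ties are broken by the
#' lexicographically smallest `(y, x)` endpoint pair.
#'
#' @param segs a `"skeleton_segments"` object from [segment_skeleton()].
#' @return An ordered `m x 2` matrix of 0-based `(x, y)` pixel coordinates
#'   with attribute `"length"` (weighted steps).
#' @export
longest_skeleton_path <- function(segs) {
  g <- attr(segs, "graph")
  if (length(segs) == 1 && segs[[1]]$from == segs[[1]]$to &&
      nrow(segs[[1]]$pixels) == 1) {
    return(structure(segs[[1]]$pixels, length = 0))
  }
  endpoints <- which(g$deg == 1)
  if (length(endpoints) < 2) {
    # a path running into a cycle has a single endpoint: a self-touching
    # posture the real-time algorithm gives up on
    abort("cyclic-skeleton", class = "wormloop_cyclic_skeleton")
  }
  # incident segment ids per node
  inc <- vector("list", length(g$deg))
  for (si in seq_along(segs)) {
    s <- segs[[si]]
    inc[[s$from]] <- c(inc[[s$from]], si)
    if (s$to != s$from) inc[[s$to]] <- c(inc[[s$to]], si)
  }
  best <- new.env(parent = emptyenv())
  best$len <- -Inf; best$segs <- NULL; best$key <- NULL
  pair_key <- function(a, b) {
    ka <- c(g$r[a], g$c[a]); kb <- c(g$r[b], g$c[b])
    if (ka[1] < kb[1] || (ka[1] == kb[1] && ka[2] <= kb[2])) {
      c(ka, kb)
    } else c(kb, ka)
  }
  key_less <- function(k1, k2) {
    for (i in seq_along(k1)) {
      if (k1[i] != k2[i]) return(k1[i] < k2[i])
    }
    FALSE
  }
  visited <- logical(length(g$deg))
  used <- logical(length(segs))
  path <- integer(0)
  start0 <- 0L
  dfs <- function(v, len) {
    if (g$deg[v] == 1 && v != start0) {
      better <- len > best$len + 1e-9
      tie <- abs(len - best$len) <= 1e-9
      k <- pair_key(start0, v)
      if (better || (tie && (is.null(best$key) || key_less(k, best$key)))) {
        best$len <- len; best$segs <- path; best$key <- k
      }
      return(invisible())
    }
    for (si in inc[[v]]) {
      if (used[si]) next
      s <- segs[[si]]
      other <- if (s$from == v) s$to else s$from
      if (other == v) next          # self-loop cannot be on a simple path
      if (visited[other]) next
      used[si] <<- TRUE; visited[other] <<- TRUE
      path[[length(path) + 1]] <<- si
      dfs(other, len + s$length)
      path <<- path[-length(path)]
      used[si] <<- FALSE; visited[other] <<- FALSE
    }
    invisible()
  }
  for (e in endpoints) {
    start0 <- e
    visited[] <- FALSE; visited[e] <- TRUE
    used[] <- FALSE; path <- integer(0)
    dfs(e, 0)
  }
  if (is.null(best$segs)) abort("no endpoint-to-endpoint path")
  # stitch the winning segments into one ordered pixel run
  cur <- best$key            # (r1,c1,r2,c2) of the smaller endpoint
  # rebuild starting node id from the stored key
  node_id <- function(rc) which(g$r == rc[1] & g$c == rc[2])[1]
  v <- node_id(cur[1:2])
  pix <- NULL
  for (si in best$segs) {
    s <- segs[[si]]
    p <- s$pixels
    if (s$from != v) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
    v <- if (s$from == v) s$to else s$from
    pix <- if (is.null(pix)) p else rbind(pix, p[-1, , drop = FALSE])
  }
  structure(pix, length = best$len)
}

#' Resample a pixel path to a fixed-point centerline
#'
#' Linearly resamples an ordered pixel path to `n` points uniformly spaced
#' in arc length; the two endpoints are preserved exactly.
#'
#' @param path `m x 2` matrix of `(x, y)` pixel coordinates (`m >= 2`).
#' @param n number of output points (default 20).
#' @param um_per_px image scale.
#' @return A tibble with `point_idx` (0-based), `x_px`, `y_px`, `x_mm`,
#'   `y_mm`, and attribute `"length_um"` (total arc length).
#' @export
resample_centerline <- function(path, n = 20, um_per_px = 1) {
  if (is.null(nrow(path)) || nrow(path) < 2) {
    abort("path must contain at least 2 pixels")
  }
  d <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  s <- c(0, cumsum(d))
  total <- s[length(s)]
  if (total <= 0) abort("degenerate path of zero length")
  tgt <- seq(0, total, length.out = n)
  x <- approx(s, path[, 1], xout = tgt, ties = "ordered")$y
  y <- approx(s, path[, 2], xout = tgt, ties = "ordered")$y
  out <- tibble::tibble(
    point_idx = seq_len(n) - 1L,
    x_px = x, y_px = y,
    x_mm = px_to_mm(x, um_per_px), y_mm = px_to_mm(y, um_per_px))
  # arc length of the reported centerline (the resampled polyline)
  attr(out, "length_um") <- sum(sqrt(diff(x)^2 + diff(y)^2)) * um_per_px
  out
}

# Moving average of path coordinates (endpoints fixed, shrinking window
# near the ends): damps the one-pixel jitter of discrete skeletons before
# resampling.
smooth_path <- function(path, half = 2) {
  m <- nrow(path)
  if (m < 3) return(path)
  sm <- path
  for (i in 2:(m - 1)) {
    h <- min(half, i - 1, m - i)
    sm[i, ] <- colMeans(path[(i - h):(i + h), , drop = FALSE])
  }
  sm
}

#' Extract a worm centerline from a binary mask
#'
#' The full two-pass pipeline: thinning, branch segmentation, longest
#' endpoint-to-endpoint path, and 20-point arc-length resampling. Because
#' thinning erodes the blob tips, extracted centerlines are slightly shorter
#' than the full body length.
#'
#' @param mask logical matrix (a blob's cropped mask).
#' @param um_per_px image scale.
#' @param n number of centerline points.
#' @param x0,y0 0-based pixel offset of the mask's top-left corner within
#'   the full frame (added to the output coordinates).
#' @return As [resample_centerline()]; `NULL` if the skeleton is cyclic or
#'   degenerate (self-touching or blob-like mask).
#' @export
extract_centerline <- function(mask, um_per_px, n = 20, x0 = 0, y0 = 0) {
  res <- tryCatch({
    skel <- thin_mask(mask)
    segs <- segment_skeleton(skel)
    path <- longest_skeleton_path(segs)
    if (nrow(path) < 2) return(NULL)
    resample_centerline(smooth_path(path), n, um_per_px)
  }, wormloop_cyclic_skeleton = function(e) NULL,
     wormloop_empty_mask = function(e) NULL)
  if (is.null(res)) return(NULL)
  res$x_px <- res$x_px + x0
  res$y_px <- res$y_px + y0
  res$x_mm <- px_to_mm(res$x_px, um_per_px)
  res$y_mm <- px_to_mm(res$y_px, um_per_px)
  res
}
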