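test_that("thinning a straight bar gives a single-pixel line, idempotently", {
  m <- rect_mask(20, 60, 9, 5, 3, 50)
  sk <- thin_mask(m)
  expect_true(all(sk <= m))                     # contained in the mask
  expect_lte(max(rowSums(sk)[rowSums(sk) > 0] / 50), 1)  # 1 px wide
  segs <- segment_skeleton(sk)
  expect_equal(length(segs), 1L)
  expect_identical(thin_mask(sk), sk)           # idempotent
})

test_that("thinning an empty mask is an error; a disk collapses to a blip", {
  expect_error(thin_mask(matrix(FALSE, 5, 5)), "empty")
  sk <- thin_mask(disk_mask(10, 3))
  expect_lt(sum(sk), 8)   # near-point skeleton, downstream length ~ 0
})

test_that("an L-shaped bar thins to two joined segments with 2 endpoints", {
  m <- matrix(FALSE, 50, 50)
  m <- draw_bar(m, 45, 5, 45, 45)
  m <- draw_bar(m, 45, 45, 10, 45)
  sk <- thin_mask(m)
  g <- wormloop:::skeleton_graph(sk)
  expect_lte(sum(g$deg == 1), 3)   # no spurious endpoints beyond the corner
  expect_gte(sum(g$deg == 1), 2)
})

test_that("a T-shaped skeleton splits into 3 segments with the drawn arm
           lengths and the longest path takes the two longest arms", {
  m <- matrix(FALSE, 100, 100)
  ctr <- c(60, 50)
  pts_left <- rbind(c(60, 20), ctr)      # arm 30
  pts_right <- rbind(ctr, c(60, 90))     # arm 40
  pts_up <- rbind(ctr, c(10, 50))        # arm 50
  sk <- matrix(FALSE, 100, 100)
  sk <- draw_thin_path(sk, pts_left)
  sk <- draw_thin_path(sk, pts_right)
  sk <- draw_thin_path(sk, pts_up)
  segs <- segment_skeleton(sk)
  expect_equal(length(segs), 3L)
  lens <- sort(vapply(segs, `[[`, numeric(1), "length"))
  expect_equal(lens, c(30, 40, 50), tolerance = 0.1)
  p <- longest_skeleton_path(segs)
  expect_equal(attr(p, "length"), 90, tolerance = 0.1)
  # path runs from the right arm tip to the top arm tip
  ends <- p[c(1, nrow(p)), ]
  expect_true(all(apply(ends, 1, function(e)
    any(abs(e[1] - c(90 - 1, 50 - 1)) < 1e-9))))
})

test_that("an X-shaped skeleton yields 4 segments sharing one node", {
  sk <- matrix(FALSE, 60, 60)
  sk <- draw_thin_path(sk, rbind(c(10, 10), c(30, 30)))
  sk <- draw_thin_path(sk, rbind(c(30, 30), c(50, 50)))
  sk <- draw_thin_path(sk, rbind(c(50, 10), c(30, 30)))
  sk <- draw_thin_path(sk, rbind(c(30, 30), c(10, 50)))
  segs <- segment_skeleton(sk)
  expect_equal(length(segs), 4L)
  nodes <- table(unlist(lapply(segs, function(s) c(s$from, s$to))))
  expect_equal(sum(nodes == 4), 1L)   # one shared branch node
})

test_that("a simple path skeleton is returned unchanged as its own longest
           path", {
  sk <- matrix(FALSE, 40, 40)
  sk <- draw_thin_path(sk, rbind(c(5, 5), c(20, 20), c(35, 20)))
  segs <- segment_skeleton(sk)
  expect_equal(length(segs), 1L)
  p <- longest_skeleton_path(segs)
  expect_equal(nrow(p), sum(sk))
})

test_that("an H-shaped skeleton matches the exhaustive-search oracle", {
  sk <- matrix(FALSE, 60, 60)
  sk <- draw_thin_path(sk, rbind(c(5, 10), c(50, 10)))
  sk <- draw_thin_path(sk, rbind(c(5, 40), c(50, 40)))
  sk <- draw_thin_path(sk, rbind(c(25, 10), c(25, 40)))
  segs <- segment_skeleton(sk)
  p <- longest_skeleton_path(segs)
  expect_equal(attr(p, "length"), oracle_longest_path_length(sk),
               tolerance = 1e-9)
})

test_that("a closed loop (self-touching worm) is rejected as cyclic", {
  sk <- matrix(FALSE, 30, 30)
  sk <- draw_thin_path(sk, rbind(c(5, 5), c(5, 25), c(25, 25), c(25, 5),
                                 c(5, 5)))
  expect_error(segment_skeleton(sk), class = "wormloop_cyclic_skeleton")
})

test_that("longest path equals the brute-force oracle on random small
           skeletons", {
  for (seed in 1:60) {
    m <- random_blob_mask(seed)
    sk <- thin_mask(m)
    segs <- tryCatch(segment_skeleton(sk), error = function(e) NULL)
    if (is.null(segs) || length(segs) > 12) next
    p <- longest_skeleton_path(segs)
    expect_equal(attr(p, "length"), oracle_longest_path_length(sk),
                 tolerance = 1e-9, label = paste("seed", seed))
    # on acyclic skeletons the path dominates every individual segment
    g <- wormloop:::skeleton_graph(sk)
    if (sum(g$deg) / 2 == length(g$deg) - 1) {
      expect_gte(attr(p, "length") + 1e-9,
                 max(vapply(segs, `[[`, numeric(1), "length")))
    }
  }
})

test_that("resampling a straight 191-px path reports ~1615 um and 20
           uniformly spaced collinear points", {
  path <- cbind(x = 0:190, y = rep(7, 191))
  cl <- resample_centerline(path, n = 20, um_per_px = 8.5)
  expect_equal(attr(cl, "length_um"), 190 * 8.5, tolerance = 1e-9)
  expect_equal(nrow(cl), 20L)
  expect_true(all(abs(cl$y_px - 7) < 1e-9))
  gaps <- diff(cl$x_px)
  expect_lt(max(gaps) - min(gaps), 0.01 * mean(gaps))
  expect_equal(cl$x_px[c(1, 20)], c(0, 190))   # endpoints preserved
})

test_that("resampling a semicircle preserves the endpoints and reports the
           analytic arc length within 1%", {
  R <- 40
  th <- seq(0, pi, length.out = 400)
  path <- cbind(R * cos(th) + 50, R * sin(th) + 10)
  cl <- resample_centerline(path, n = 20, um_per_px = 10)
  expect_equal(attr(cl, "length_um") / 10, pi * R, tolerance = 0.01)
  expect_equal(cl$x_px[1], 90)
  expect_equal(cl$x_px[20], 10, tolerance = 1e-6)
})

test_that("resampling to n = 2 returns just the two endpoints; degenerate
           paths error", {
  path <- cbind(c(0, 3, 10), c(0, 4, 10))
  cl <- resample_centerline(path, n = 2, um_per_px = 1)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$x_px, c(0, 10))
  expect_error(resample_centerline(cbind(1, 1), n = 20, um_per_px = 1),
               "2 pixels")
})

test_that("centerline length on rendered worms is within the
           skeleton-shortening band of truth and tracks the true curve", {
  cfg <- sim_config(arena_size_mm = c(6, 6), um_per_px = 20, n_worms = 1,
                    seed = 3)
  set.seed(3)
  w <- init_world(cfg)
  for (ph in seq(0, 2 * pi, length.out = 9)) {
    w$worms$phase <- ph
    b <- segment_frame(render_frame(w, cfg))
    mk <- b$mask[[1]]
    cl <- extract_centerline(mk$m, cfg$um_per_px, x0 = mk$x0, y0 = mk$y0)
    ratio <- attr(cl, "length_um") / (w$worms$length_mm * 1000)
    expect_gte(ratio, 0.85)
    expect_lte(ratio, 1.0)
    # mean point-to-curve distance to ground truth < 2 px
    truth <- true_centerlines(w, cfg, n = 200)[[1]]
    d <- vapply(seq_len(nrow(cl)), function(i) {
      min(sqrt((truth[, 1] - cl$x_mm[i])^2 + (truth[, 2] - cl$y_mm[i])^2))
    }, numeric(1))
    expect_lt(mean(d) * 1000 / cfg$um_per_px, 2)
  }
})

test_that("self-overlapping (coiled) rendered worms are rejected rather
           than given a bogus centerline", {
  # a full ring mask mimics a worm touching itself
  ring <- disk_mask(15, 3) & !disk_mask(10, 8)
  expect_null(extract_centerline(ring, 20))
})
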