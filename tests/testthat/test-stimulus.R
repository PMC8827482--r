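straight_centerline <- function(x0 = 1, y0 = 1, len_mm = 1) {
  tibble::tibble(x_mm = seq(x0, x0 + len_mm, length.out = 20),
                 y_mm = y0)
}

test_that("targeted patterns place 0.5-mm disks on the head and tail tips
           and a 1.5-mm disk on the body centroid", {
  cl <- straight_centerline()
  cfg <- schedule_config()
  ph <- make_targeted_pattern(cl, "head", 80, cfg = cfg)
  expect_equal(nrow(ph$disks), 1L)
  expect_equal(ph$disks$x_mm, 1)
  expect_equal(ph$disks$diameter_mm, 0.5)
  pb <- make_targeted_pattern(cl, "both", 60, 20, cfg = cfg)
  expect_equal(nrow(pb$disks), 2L)
  d <- sqrt(diff(pb$disks$x_mm)^2 + diff(pb$disks$y_mm)^2)
  expect_equal(d, 1)   # 20-point arc length apart
  expect_equal(pb$disks$intensity, c(60, 20))
  pw <- make_targeted_pattern(cl, "whole_body", 80, cfg = cfg)
  expect_equal(pw$disks$diameter_mm, 1.5)
  expect_equal(pw$disks$x_mm, mean(cl$x_mm))
  expect_error(make_targeted_pattern(cl, "head", oriented = FALSE),
               "oriented")
})

test_that("delivered intensity sampling respects disk geometry", {
  cl <- straight_centerline()
  p <- make_targeted_pattern(cl, "head", 80)
  # head tip inside, tail tip outside the 0.5-mm head disk
  I <- sample_intensity(list(p), c(1, 2), c(1, 1), um_per_px = 20)
  expect_equal(I, c(80, 0))
})

test_that("cropping removes neighbor-adjacent pattern area and never
           increases it; a swallowed disk is flagged fully cropped", {
  um <- 20
  cl <- straight_centerline(x0 = 1, y0 = 1)
  p <- make_targeted_pattern(cl, "tail", intensity_tail = 80)
  # no neighbors: identity
  p0 <- crop_against_others(p, list(), margin_um = 100, um_per_px = um)
  expect_equal(p0$delivered_area_frac, 1)
  # a neighbor overlapping half of the tail disk
  nb <- matrix(TRUE, 30, 10)
  nbm <- list(m = nb, x0 = round(2 * 1000 / um), y0 = round(0.8 * 1000 / um))
  p1 <- crop_against_others(p, list(nbm), margin_um = 100, um_per_px = um)
  expect_lt(p1$delivered_area_frac, 1)
  expect_gt(p1$delivered_area_frac, 0)
  # pixel-count oracle: no delivered pixel within the margin of the neighbor
  keep <- which(p1$cropped$m, arr.ind = TRUE)
  kx <- keep[, 2] - 1 + p1$cropped$x0; ky <- keep[, 1] - 1 + p1$cropped$y0
  nbpx <- which(nb, arr.ind = TRUE)
  nx <- nbpx[, 2] - 1 + nbm$x0; ny <- nbpx[, 1] - 1 + nbm$y0
  dmin <- min(outer(kx, nx, `-`)^2 + outer(ky, ny, `-`)^2)
  expect_gt(sqrt(dmin), 100 / um)
  # a neighbor covering the whole disk empties it
  big <- list(m = matrix(TRUE, 60, 60), x0 = round(1.7 * 1000 / um),
              y0 = round(0.7 * 1000 / um))
  p2 <- crop_against_others(p, list(big), margin_um = 100, um_per_px = um)
  expect_true(p2$fully_cropped[1])
  expect_equal(sum(p2$cropped$m), 0)
})

test_that("the target worm's own body is never cropped away", {
  um <- 20
  cl <- straight_centerline(x0 = 1, y0 = 1)
  p <- make_targeted_pattern(cl, "head", 80)
  own <- list(m = matrix(TRUE, 5, 20), x0 = round(1000 / um) - 10,
              y0 = round(1000 / um) - 2)
  nb <- list(m = matrix(TRUE, 40, 40), x0 = round(1000 / um) - 20,
             y0 = round(1000 / um) - 20)
  pc <- crop_against_others(p, list(nb), own_mask = own, margin_um = 100,
                            um_per_px = um)
  # own-body pixels inside the disk survive even under a blanketing neighbor
  expect_gt(sum(pc$cropped$m), 0)
})

test_that("open-loop scheduling delivers one stimulus per tracked worm per
           ISI epoch and skips absent worms", {
  fps <- 30
  presence <- tidyr::expand_grid(worm_id = 1:2,
                                 time_s = seq(0, 120, by = 1 / fps))
  cfg <- schedule_config(mode = "open_loop_headtail", duration_s = 1)
  set.seed(1)
  cmds <- open_loop_scheduler(presence, 120, cfg)
  expect_equal(nrow(cmds), 2 * 4)   # epochs at 0, 30, 60, 90
  expect_equal(sort(unique(cmds$t_on)), c(0, 30, 60, 90))
  # worm 2 lost after t = 50: no commands for it at later epochs
  p2 <- presence[!(presence$worm_id == 2 & presence$time_s > 50), ]
  cmds2 <- open_loop_scheduler(p2, 120, cfg)
  expect_equal(sum(cmds2$worm_id == 2), 2L)
})

test_that("head and tail intensities are drawn independently and uniformly
           from the 5-level set", {
  set.seed(42)
  cfg <- schedule_config(mode = "open_loop_headtail")
  presence <- tibble::tibble(worm_id = 1:400, time_s = 0)
  draws <- dplyr::bind_rows(lapply(1:25, function(i) {
    open_loop_scheduler(presence, 1, cfg)
  }))
  expect_equal(nrow(draws), 10000L)
  tab <- table(draws$I_head, draws$I_tail)
  chisq <- sum((tab - 400)^2 / 400)
  # chi-square with 24 df: 99.9th percentile ~ 51.2
  expect_lt(chisq, 51.2)
  expect_equal(sort(unique(draws$I_head)), c(0, 20, 40, 60, 80))
})

test_that("closed-loop scheduling enforces the per-worm 30-s refractory
           period and draws the whole-body intensity pair ~50/50", {
  cfg <- schedule_config(mode = "closed_loop_turn", duration_s = 3)
  trg <- tibble::tibble(worm_id = 1L, t_cross = seq(0, 100, by = 5))
  set.seed(7)
  cmds <- closed_loop_scheduler(trg, cfg)
  expect_equal(cmds$t_on, c(0, 30, 60, 90))
  # no triggers -> no commands
  none <- closed_loop_scheduler(trg[0, ], cfg)
  expect_equal(nrow(none), 0L)
  # intensity fractions over many events
  trg2 <- tibble::tibble(worm_id = 1:4000, t_cross = runif(4000, 0, 1800))
  cmds2 <- closed_loop_scheduler(trg2, cfg)
  f80 <- mean(cmds2$I_head == 80)
  expect_lt(abs(f80 - 0.5), 4 * sqrt(0.25 / nrow(cmds2)))
  # refractory property across a mixed log
  gaps <- cmds2 |>
    dplyr::arrange(.data$worm_id, .data$t_on) |>
    dplyr::group_by(.data$worm_id) |>
    dplyr::summarise(g = min(c(Inf, diff(t_on))), .groups = "drop")
  expect_true(all(gaps$g >= cfg$refractory_s))
})

test_that("calibration recovers exact transforms, reports residual and
           drift, and rejects degenerate dot grids", {
  grid <- as.matrix(expand.grid(x = seq(0, 400, by = 100),
                                y = seq(0, 400, by = 100)))
  idm <- fit_calibration(grid, grid, um_per_px = 44)
  expect_lt(idm$residual_rms_um, 1e-6)
  expect_equal(idm$H, diag(3), tolerance = 1e-8)
  # known affine: scale 2, shift 10 px
  aff <- grid * 2 + 10
  m <- fit_calibration(grid, aff, um_per_px = 44)
  expect_lt(m$residual_rms_um, 1e-6)
  expect_equal(apply_calibration(m, rbind(c(50, 70))), rbind(c(110, 150)),
               tolerance = 1e-6)
  # round trip: map and map back within 1 px
  pts <- cbind(runif(20, 0, 400), runif(20, 0, 400))
  back <- apply_calibration(m, apply_calibration(m, pts), inverse = TRUE)
  expect_lt(max(abs(back - pts)), 1)
  # drift: end grid uniformly shifted 2 px at 44 um/px -> ~88 um
  shifted <- grid; shifted[, 1] <- shifted[, 1] + 2
  expect_equal(measure_drift(idm, shifted, grid), 88, tolerance = 0.01)
  # collinear points are rejected
  line <- cbind(1:10, 2 * (1:10))
  expect_error(fit_calibration(line, line), "collinear")
  expect_error(fit_calibration(grid[1:3, ], grid[1:3, ]), "at least 4")
})

test_that("the binary visual timestamp round-trips exactly", {
  img0 <- encode_timestamp(0, n_bits = 16)
  expect_equal(sum(img0 > 0), 0L)
  expect_equal(decode_timestamp(img0, n_bits = 16), 0L)
  img <- encode_timestamp(1234, n_bits = 16)
  expect_equal(decode_timestamp(img, n_bits = 16), 1234L)
  # exhaustive roundtrip at 10 bits
  ok <- vapply(0:1023, function(k) {
    decode_timestamp(encode_timestamp(k, n_bits = 10), n_bits = 10) == k
  }, logical(1))
  expect_true(all(ok))
  # a cropped image makes the stamp unreadable (the circle leaves the frame)
  expect_error(decode_timestamp(img[1:40, ], n_bits = 16,
                                center = c(63.5, 63.5), radius = 55),
               class = "wormloop_timestamp_unreadable")
  expect_error(encode_timestamp(2^16, n_bits = 16), "out of range")
  # exclusion mask covers the dot circle
  msk <- timestamp_exclusion_mask(n_bits = 16)
  expect_true(all(msk[img > 0]))
})
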