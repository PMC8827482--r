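# synthetic per-frame track table for one worm
make_track <- function(worm_id, t0, t1, fps = 10, stationary = FALSE,
                       length_um = 650, merged_at = NULL, v = 0.2) {
  tt <- seq(t0, t1, by = 1 / fps)
  x <- if (stationary) rep(1, length(tt)) else 1 + v * (tt - t0)
  tibble::tibble(
    worm_id = worm_id, frame = round(tt * fps), time_s = tt,
    x_mm = x, y_mm = 1, area_px = 390L, length_um = length_um,
    ellipse_ratio = 5, solidity = 0.7,
    v_mm_s = if (stationary) 0 else v,
    state = factor("forward", levels = wormloop:::BEHAVIOR_STATES),
    merged = if (is.null(merged_at)) FALSE else
      tt >= merged_at[1] & tt <= merged_at[2])
}

test_that("event-table inclusion applies the constructed violations
           exactly: 60 of 100 events survive", {
  fps <- 10
  tracks <- dplyr::bind_rows(lapply(1:100, function(i) {
    if (i <= 10) {
      make_track(i, 25, 60, fps)                       # short pre-track
    } else if (i <= 20) {
      make_track(i, 0, 60, fps, length_um = 750)       # too long
    } else if (i <= 30) {
      make_track(i, 0, 60, fps, merged_at = c(29, 31)) # collision
    } else if (i <= 40) {
      make_track(i, 0, 60, fps, stationary = TRUE)     # stationary
    } else {
      make_track(i, 0, 60, fps)
    }
  }))
  attr(tracks, "um_per_px") <- 10
  stim <- tibble::tibble(command_id = 1:100, worm_id = 1:100, t_on = 30,
                         duration_s = 1, I_head = 80, I_tail = 0)
  ev <- build_event_table(tracks, stim, validity_criteria(), "headtail",
                          fps = fps)
  expect_equal(nrow(ev), 100L)
  expect_equal(sum(ev$included), 60L)
  expect_true(all(grepl("short-pre-track", ev$reasons[1:10])))
  expect_true(all(grepl("too-long", ev$reasons[11:20])))
  expect_true(all(grepl("collision", ev$reasons[21:30])))
  expect_true(all(grepl("stationary", ev$reasons[31:40])))
})

test_that("a stimulus to an unknown worm becomes an excluded orphan record
           and inclusion is order-independent", {
  tracks <- make_track(1, 0, 60)
  attr(tracks, "um_per_px") <- 10
  stim <- tibble::tibble(command_id = 1:2, worm_id = c(99L, 1L),
                         t_on = 30, duration_s = 1, I_head = 0, I_tail = 0)
  ev <- build_event_table(tracks, stim, validity_criteria(), fps = 10)
  expect_false(ev$included[1])
  expect_equal(ev$reasons[1], "orphan")
  expect_true(ev$included[2])
  ev_rev <- build_event_table(tracks, stim[2:1, ], validity_criteria(),
                              fps = 10)
  expect_equal(ev$included, rev(ev_rev$included))
})

test_that("state fractions are a degenerate point mass when every event is
           forward, and always sum to one per time point", {
  ev <- tibble::tibble(pre_state = rep("forward", 40),
                       post_state = rep("forward", 40))
  set.seed(1)
  sf <- state_fractions(ev, n_boot = 200)
  fwd <- sf[sf$state == "forward", ]
  expect_equal(fwd$fraction, c(1, 1))
  expect_equal(fwd$ci_lo, c(1, 1))
  expect_equal(fwd$ci_hi, c(1, 1))
  sums <- tapply(sf$fraction, sf$when, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})

test_that("a constructed 30% forward-to-reverse flip is recovered with a
           covering bootstrap interval in most replicates", {
  set.seed(11)
  hits <- vapply(1:20, function(r) {
    n <- 400
    flipped <- rbinom(n, 1, 0.3) == 1
    ev <- tibble::tibble(pre_state = "forward",
                         post_state = ifelse(flipped, "reverse", "forward"))
    sf <- state_fractions(ev, n_boot = 300)
    rev_after <- sf[sf$state == "reverse" & sf$when == "after", ]
    rev_after$ci_lo <= 0.3 && rev_after$ci_hi >= 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("transition surfaces sum to one cell-wise and flag empty cells", {
  set.seed(2)
  grid <- c(0, 20, 40, 60, 80)
  ev <- tibble::tibble(
    I_head = sample(grid[1:4], 500, replace = TRUE),   # leave 80 empty
    I_tail = sample(grid, 500, replace = TRUE),
    post_state = sample(wormloop:::BEHAVIOR_STATES, 500, replace = TRUE))
  surf <- transition_surface(ev, grid)
  sums <- surf |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::summarise(s = sum(.data$p),
                     .by = c("I_head", "I_tail"))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_true(all(is.na(surf$p[surf$I_head == 80])))
  expect_true(all(surf$n_events[surf$I_head == 80] == 0))
})

test_that("a noiseless planar surface is recovered to machine precision and
           single-cell input is refused as rank-deficient", {
  grid <- c(0, 20, 40, 60, 80)
  cells <- expand.grid(I_head = grid, I_tail = grid)
  ev <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    p <- 0.1 + 0.004 * cells$I_head[i] - 0.001 * cells$I_tail[i]
    k <- round(p * 50)
    tibble::tibble(I_head = cells$I_head[i], I_tail = cells$I_tail[i],
                   post_state = c(rep("reverse", k), rep("forward", 50 - k)))
  }))
  pf <- fit_plane(ev, "reverse", n_boot = 50)
  expect_equal(pf$intercept, 0.1, tolerance = 1e-10)
  expect_equal(pf$d_head, 0.004, tolerance = 1e-12)
  expect_equal(pf$d_tail, -0.001, tolerance = 1e-12)
  single <- ev[ev$I_head == 0 & ev$I_tail == 0, ]
  expect_error(fit_plane(single, "reverse", n_boot = 10), "rank-deficient")
})

test_that("bootstrap plane CIs cover a zero slope in most replicates", {
  set.seed(5)
  grid <- c(0, 20, 40, 60, 80)
  cells <- expand.grid(I_head = grid, I_tail = grid)
  hits <- vapply(1:15, function(r) {
    ev <- dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
      # depends on head only; tail slope is truly zero
      p <- 0.1 + 0.004 * cells$I_head[i]
      tibble::tibble(I_head = cells$I_head[i], I_tail = cells$I_tail[i],
                     post_state = ifelse(rbinom(60, 1, p) == 1,
                                         "reverse", "forward"))
    }))
    pf <- fit_plane(ev, "reverse", n_boot = 200)
    pf$ci[1, "d_tail"] <= 0 && pf$ci[2, "d_tail"] >= 0
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the two-proportion Z statistic matches the chi-square identity
           of prop.test without continuity correction", {
  z <- two_proportion_z_test(300, 1000, 150, 1000)
  pt <- prop.test(c(300, 150), c(1000, 1000), correct = FALSE)
  expect_equal(z$z^2, unname(pt$statistic), tolerance = 1e-9)
  expect_equal(z$p_value, pt$p.value, tolerance = 1e-9)
})

test_that("reversal probabilities: degenerate all-responders give CI [1,1];
           gated turn-context probability is recovered and significant", {
  ev1 <- tibble::tibble(context = "forward", I_head = 80,
                        reversal_response = TRUE)[rep(1, 50), ]
  set.seed(3)
  rp1 <- reversal_probability(ev1, by = "context", n_boot = 500)
  expect_equal(rp1$estimates$p, 1)
  expect_equal(rp1$estimates$ci_lo, 1)
  expect_equal(rp1$estimates$ci_hi, 1)

  cfg <- sim_config(turn_gating_factor = 0.5,
                    response_plane_reverse = c(0.1, 0.009, 0.0005))
  n <- 2000
  fwd <- simulate_response_events(cfg, n, 80, 80, "forward")
  trn <- simulate_response_events(cfg, n, 80, 80, "turn")
  ev <- dplyr::bind_rows(fwd, trn) |>
    dplyr::mutate(reversal_response = .data$reversal)
  rp <- reversal_probability(ev, by = "context", n_boot = 2000)
  p_f <- rp$estimates$p[rp$estimates$context == "forward"]
  p_t <- rp$estimates$p[rp$estimates$context == "turn"]
  expect_equal(p_t / p_f, 0.5, tolerance = 0.15)
  expect_lt(rp$tests$p_value, 0.001)
})

test_that("habituation curves bin events half-open, stay flat for
           homogeneous responses and recover a constructed decay", {
  set.seed(4)
  ev_flat <- tibble::tibble(t_on = runif(2000, 0, 1800),
                            reversal_response = rbinom(2000, 1, 0.4) == 1)
  hc <- habituation_curve(ev_flat, n_boot = 500)
  expect_true(all(hc$ci_lo <= 0.4 + 0.08 & hc$ci_hi >= 0.4 - 0.08))
  # edge convention: an event exactly at 120 s goes to bin 2
  ev_edge <- tibble::tibble(t_on = c(0, 119.99, 120, 360),
                            reversal_response = TRUE)
  hc_edge <- habituation_curve(ev_edge, n_boot = 10)
  expect_equal(hc_edge$n[hc_edge$bin == 1], 2L)
  expect_equal(hc_edge$n[hc_edge$bin == 2], 1L)
  # exponential decay in response probability shows up monotonically
  t_on <- runif(4000, 0, 1800)
  p <- 0.6 * exp(-t_on / 900)
  ev_dec <- tibble::tibble(t_on = t_on,
                           reversal_response = rbinom(4000, 1, p) == 1)
  hd <- habituation_curve(ev_dec, n_boot = 500)
  expect_gt(hd$p[1], hd$p[nrow(hd)])
  expected <- 0.6 * exp(-hd$t_mid_s / 900)
  expect_gte(mean(hd$ci_lo <= expected & expected <= hd$ci_hi), 0.8)
})

test_that("throughput and yield reproduce the closed- and open-loop
           accounting and reject zero denominators", {
  cl <- throughput_yield(22608, 9776, 1060)
  expect_equal(cl$yield_pct, 43.2)
  expect_equal(cl$throughput_per_worm_hour, 9.2)
  ol <- throughput_yield(41623, 308, 633)
  expect_equal(ol$yield_pct, 0.7)
  expect_equal(ol$throughput_per_worm_hour, 0.5)
  zero <- throughput_yield(100, 0, 10)
  expect_equal(zero$yield_pct, 0)
  expect_equal(zero$throughput_per_worm_hour, 0)
  expect_error(throughput_yield(0, 0, 10), "n_stim_valid")
  expect_error(throughput_yield(10, 1, 0), "worm_hours")
})

test_that("tidy and glance expose plane-fit terms and gradient summaries", {
  grid <- c(0, 40, 80)
  ev <- tidyr::expand_grid(I_head = grid, I_tail = grid,
                           rep = 1:30) |>
    dplyr::mutate(post_state = ifelse(
      rbinom(dplyr::n(), 1, 0.2 + 0.005 * .data$I_head) == 1,
      "reverse", "forward"))
  pf <- fit_plane(ev, "reverse", grid = grid, n_boot = 50)
  td <- tidy(pf)
  expect_equal(td$term, c("intercept", "d_head", "d_tail"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(pf)
  expect_equal(gl$behavior, "reverse")
  expect_gt(gl$gradient_magnitude, 0)
})
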