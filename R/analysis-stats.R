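#' Behavioral-state fractions before and after stimulation
#'
#' Tabulates the fraction of events in each of the four velocity-defined
#' states 2 s before stimulus onset (`pre_state`) and precisely at the end
#' of the stimulus (`post_state`), with percentile bootstrap confidence
#' intervals over events and a Wilcoxon rank-sum p-value comparing the
#' before/after occupancy indicators per state.
#'
#' @param events an included-event tibble (see [build_event_table()]) with
#'   `pre_state` and `post_state`.
#' @param n_boot bootstrap resamples (default 1,000).
#' @param conf confidence level.
#' @return A tibble with one row per state and time point: `state`, `when`
#'   (`before`/`after`), `fraction`, `ci_lo`, `ci_hi`, `p_value` (same for
#'   both time points of a state), `n_events`.
#' @export
state_fractions <- function(events, n_boot = 1000, conf = 0.95) {
  ev <- events[!is.na(events$pre_state) & !is.na(events$post_state), ,
               drop = FALSE]
  n <- nrow(ev)
  if (n == 0) abort("no events with defined pre/post states")
  states <- BEHAVIOR_STATES
  pre <- factor(ev$pre_state, levels = states)
  post <- factor(ev$post_state, levels = states)
  frac <- function(f) as.numeric(table(f)) / length(f)
  boot_pre <- matrix(0, n_boot, 4)
  boot_post <- matrix(0, n_boot, 4)
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    boot_pre[b, ] <- frac(pre[i])
    boot_post[b, ] <- frac(post[i])
  }
  a <- (1 - conf) / 2
  out <- list()
  for (k in seq_along(states)) {
    ind_pre <- as.numeric(pre == states[k])
    ind_post <- as.numeric(post == states[k])
    p <- if (sd(c(ind_pre, ind_post)) == 0) 1 else
      suppressWarnings(wilcox.test(ind_pre, ind_post)$p.value)
    out[[length(out) + 1]] <- tibble::tibble(
      state = states[k], when = c("before", "after"),
      fraction = c(mean(ind_pre), mean(ind_post)),
      ci_lo = unname(c(quantile(boot_pre[, k], a),
                       quantile(boot_post[, k], a))),
      ci_hi = unname(c(quantile(boot_pre[, k], 1 - a),
                       quantile(boot_post[, k], 1 - a))),
      p_value = p, n_events = n)
  }
  dplyr::bind_rows(out)
}

#' Post-stimulus transition-probability surfaces over the intensity grid
#'
#' For each `(I_head, I_tail)` cell, the fraction of events whose
#' `post_state` is each of the four states. The four surfaces sum to one
#' cell-wise; cells with no events are marked missing.
#'
#' @param events included events with `I_head`, `I_tail`, `post_state`.
#' @param grid intensity levels defining the (square) grid.
#' @return A tibble with `I_head`, `I_tail`, `state`, `p`, `n_events`
#'   (`p = NA` for empty cells).
#' @export
transition_surface <- function(events, grid = c(0, 20, 40, 60, 80)) {
  ev <- events[!is.na(events$post_state), , drop = FALSE]
  cells <- tidyr::expand_grid(I_head = grid, I_tail = grid,
                              state = BEHAVIOR_STATES)
  counts <- ev |>
    dplyr::count(.data$I_head, .data$I_tail, .data$post_state) |>
    dplyr::rename(state = "post_state", k = "n")
  totals <- ev |>
    dplyr::count(.data$I_head, .data$I_tail, name = "n_events")
  cells |>
    dplyr::left_join(counts, by = c("I_head", "I_tail", "state")) |>
    dplyr::left_join(totals, by = c("I_head", "I_tail")) |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L),
                  n_events = dplyr::coalesce(.data$n_events, 0L),
                  p = ifelse(.data$n_events > 0,
                             .data$k / .data$n_events, NA_real_)) |>
    dplyr::select("I_head", "I_tail", "state", "p", "n_events")
}

#' Least-squares plane fit to a probability surface
#'
#' Ordinary least squares of the per-cell transition probability on
#' `(I_head, I_tail, 1)`, each populated cell weighted equally (a
#' count-weighted fit is available via `weight_by_n`). The gradient
#' `(dP/dI_head, dP/dI_tail)` summarizes how the behavior's probability
#' depends on head versus tail drive. 95% CIs per component come from
#' bootstrap resampling of the underlying events (resample, re-tabulate the
#' surface, refit).
#'
#' @param events included events (`I_head`, `I_tail`, `post_state`).
#' @param behavior which state's surface to fit.
#' @param grid intensity grid.
#' @param n_boot bootstrap resamples (default 1,000).
#' @param weight_by_n weight cells by event count instead of equally.
#' @param conf confidence level.
#' @return An object of class `"plane_fit"`: coefficients `intercept`,
#'   `d_head`, `d_tail`, per-component `ci` (matrix), `behavior`,
#'   `n_events`, cell table, and the bootstrap draws.
#' @export
fit_plane <- function(events, behavior = "reverse",
                      grid = c(0, 20, 40, 60, 80), n_boot = 1000,
                      weight_by_n = FALSE, conf = 0.95) {
  behavior <- match.arg(behavior, BEHAVIOR_STATES)
  ev <- events[!is.na(events$post_state), , drop = FALSE]
  # per-event cell index and behavior indicator; per-cell LS on fractions
  gi <- match(ev$I_head, grid); gj <- match(ev$I_tail, grid)
  if (anyNA(gi) || anyNA(gj)) abort("event intensities off the grid")
  ng <- length(grid)
  cell <- (gj - 1L) * ng + gi
  y <- ev$post_state == behavior
  cellX <- cbind(1, rep(grid, times = ng), rep(grid, each = ng))
  fit_once <- function(idx) {
    n_c <- tabulate(cell[idx], ng * ng)
    k_c <- tabulate(cell[idx][y[idx]], ng * ng)
    pop <- n_c > 0
    if (sum(pop) < 3) return(NULL)
    X <- cellX[pop, , drop = FALSE]
    if (qr(X)$rank < 3) return(NULL)
    w <- if (weight_by_n) n_c[pop] else rep(1, sum(pop))
    coef(lm.wfit(X, k_c[pop] / n_c[pop], w))
  }
  n <- nrow(ev)
  cf <- fit_once(seq_len(n))
  if (is.null(cf)) {
    abort("rank-deficient design: need >= 3 non-collinear populated cells")
  }
  boot <- matrix(NA_real_, n_boot, 3)
  for (b in seq_len(n_boot)) {
    cb <- fit_once(sample.int(n, n, replace = TRUE))
    if (!is.null(cb)) boot[b, ] <- cb
  }
  a <- (1 - conf) / 2
  ci <- apply(boot, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  colnames(ci) <- c("intercept", "d_head", "d_tail")
  structure(list(behavior = behavior,
                 intercept = unname(cf[1]), d_head = unname(cf[2]),
                 d_tail = unname(cf[3]), ci = ci, conf = conf,
                 n_events = n, grid = grid,
                 surface = transition_surface(ev, grid),
                 boot = boot),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf("<plane_fit> %s: P = %.4f + %.5f * I_head + %.5f * I_tail\n",
              x$behavior, x$intercept, x$d_head, x$d_tail))
  cat(sprintf("  %d%% CI d_head [%.5f, %.5f], d_tail [%.5f, %.5f], n = %d\n",
              round(100 * x$conf), x$ci[1, "d_head"], x$ci[2, "d_head"],
              x$ci[1, "d_tail"], x$ci[2, "d_tail"], x$n_events))
  invisible(x)
}

#' Two-proportion Z-test (pooled)
#'
#' @param x1,n1,x2,n2 successes and totals of the two samples.
#' @return A tibble with `z`, `p_value`, `p1`, `p2`.
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}

#' Reversal probability by condition, with bootstrap CIs and Z-tests
#'
#' Mean of the reversal-response indicator per condition with percentile
#' bootstrap CIs (default 10,000 resamples) and pairwise two-proportion
#' Z-tests between conditions.
#'
#' @param events included events with `reversal_response` and the grouping
#'   columns.
#' @param by character vector of grouping columns (default `context` and
#'   `I_head`).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @return A list with `estimates` (tibble per condition: `p`, `ci_lo`,
#'   `ci_hi`, `n`) and `tests` (pairwise Z-tests).
#' @export
reversal_probability <- function(events, by = c("context", "I_head"),
                                 n_boot = 10000, conf = 0.95) {
  ev <- events[!is.na(events$reversal_response), , drop = FALSE]
  if (nrow(ev) == 0) abort("no events with defined reversal response")
  grp <- dplyr::group_by(ev, dplyr::across(dplyr::all_of(by)))
  a <- (1 - conf) / 2
  est <- dplyr::summarise(grp,
    n = dplyr::n(),
    x = sum(.data$reversal_response),
    p = mean(.data$reversal_response),
    .groups = "drop")
  ci <- purrr::map2(est$x, est$n, function(x, n) {
    draws <- rbinom(n_boot, n, x / n) / n
    unname(quantile(draws, c(a, 1 - a)))
  })
  est$ci_lo <- vapply(ci, `[`, numeric(1), 1)
  est$ci_hi <- vapply(ci, `[`, numeric(1), 2)
  tests <- NULL
  if (nrow(est) > 1) {
    idx <- utils::combn(nrow(est), 2)
    tests <- purrr::map_dfr(seq_len(ncol(idx)), function(k) {
      i <- idx[1, k]; j <- idx[2, k]
      lab <- function(r) paste(unlist(est[r, by]), collapse = "/")
      dplyr::bind_cols(
        tibble::tibble(cond1 = lab(i), cond2 = lab(j)),
        two_proportion_z_test(est$x[i], est$n[i], est$x[j], est$n[j]))
    })
  }
  list(estimates = est, tests = tests)
}

#' Habituation curve: reversal fraction in consecutive time bins
#'
#' Events are partitioned into half-open bins `[0, bin_s), [bin_s, 2 bin_s),
#' ...` of recording time; per-bin reversal fractions get percentile
#' bootstrap CIs.
#'
#' @param events included events with `t_on` and `reversal_response`.
#' @param bin_s bin width in seconds (default 120).
#' @param n_boot bootstrap resamples (default 10,000).
#' @param conf confidence level.
#' @return A tibble per bin: `bin`, `t_mid_s`, `p`, `ci_lo`, `ci_hi`, `n`.
#' @export
habituation_curve <- function(events, bin_s = 120, n_boot = 10000,
                              conf = 0.95) {
  ev <- events[!is.na(events$reversal_response), , drop = FALSE]
  bin <- floor(ev$t_on / bin_s) + 1L
  a <- (1 - conf) / 2
  purrr::map_dfr(sort(unique(bin)), function(b) {
    r <- ev$reversal_response[bin == b]
    n <- length(r); x <- sum(r)
    draws <- rbinom(n_boot, n, x / n) / n
    tibble::tibble(bin = b, t_mid_s = (b - 0.5) * bin_s, p = x / n,
                   ci_lo = unname(quantile(draws, a)),
                   ci_hi = unname(quantile(draws, 1 - a)), n = n)
  })
}

#' Throughput and yield of a stimulation experiment
#'
#' @param n_stim_valid all stimulus events delivered to valid worms.
#' @param n_turn_associated stimulus events associated with turn onset.
#' @param worm_hours cumulative recording duration in worm-hours.
#' @return A tibble with `n_stim_valid`, `n_turn_associated`, `worm_hours`,
#'   `yield_pct` (percent, one decimal) and `throughput_per_worm_hour`
#'   (one decimal).
#' @export
#' @examples
#' throughput_yield(22608, 9776, 1060)
throughput_yield <- function(n_stim_valid, n_turn_associated, worm_hours) {
  if (n_stim_valid <= 0) abort("n_stim_valid must be > 0")
  if (worm_hours <= 0) abort("worm_hours must be > 0")
  if (n_turn_associated < 0) abort("counts must be >= 0")
  tibble::tibble(
    n_stim_valid = n_stim_valid,
    n_turn_associated = n_turn_associated,
    worm_hours = worm_hours,
    yield_pct = round(100 * n_turn_associated / n_stim_valid, 1),
    throughput_per_worm_hour = round(n_turn_associated / worm_hours, 1))
}

#' Closed-loop spatial-targeting bound
#'
#' The spatial error bound that closed-loop latency imposes on targeting a
#' moving animal: distance traveled during the latency.
#'
#' @param speed_um_s animal speed (um/s).
#' @param latency_s closed-loop latency (s).
#' @return Bound in um.
#' @export
#' @examples
#' targeting_bound_um(200, 0.2)  # 40 um
targeting_bound_um <- function(speed_um_s, latency_s) {
  speed_um_s * latency_s
}
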