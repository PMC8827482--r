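STATE_LEVELS <- c("forward", "reverse", "turn", "pause", "sprint")

#' Create an initial arena state
#'
#' Seeds `cfg$n_worms` worms at uniform random positions and headings inside
#' the arena (with a half-body-length margin). Worm lengths are drawn from a
#' normal distribution truncated at 50% of the mean. Uses the current RNG
#' stream; seed it (or use [simulate_world()] / [run_experiment()], which
#' seed from `cfg$seed`).
#'
#' @param cfg a [sim_config()].
#' @return A list of class `"world_state"` with elements `time_s`, `frame`
#'   and `worms` (a list of parallel vectors: position of the head tip in mm,
#'   heading of travel in radians, undulation phase, behavior state, timers).
#' @export
init_world <- function(cfg) {
  n <- cfg$n_worms
  margin <- cfg$worm_length_um / 1000
  len <- rnorm(n, cfg$worm_length_um, cfg$worm_length_sd_um)
  len <- pmax(len, 0.5 * cfg$worm_length_um)
  worms <- list(
    id = seq_len(n),
    x = runif(n, margin, cfg$arena_size_mm[1] - margin),
    y = runif(n, margin, cfg$arena_size_mm[2] - margin),
    heading = runif(n, -pi, pi),
    phase = runif(n, 0, 2 * pi),
    state = rep("forward", n),
    state_until = rep(Inf, n),
    bend_dir = rep(1, n),
    turn_t0 = rep(-Inf, n),
    length_mm = len / 1000,
    speed_mult = 1 + rnorm(n, 0, cfg$speed_cv)
  )
  structure(list(time_s = 0, frame = 0L, worms = worms),
            class = "world_state")
}

#' @export
print.world_state <- function(x, ...) {
  cat(sprintf("<world_state> t = %.2f s, frame %d, %d worms (%s)\n",
              x$time_s, x$frame, length(x$worms$id),
              paste(sprintf("%s:%d", STATE_LEVELS,
                            tabulate(match(x$worms$state, STATE_LEVELS),
                                     length(STATE_LEVELS))), collapse = " ")))
  invisible(x)
}

# One evoked-response draw per stimulated worm at stimulus onset.
# Returns "reverse", "sprint" or "none".
draw_response <- function(cfg, state, I_head, I_tail) {
  if (any(!is.finite(I_head)) || any(!is.finite(I_tail))) {
    abort("stimulus intensities must be finite")
  }
  pr <- clip01(cfg$response_plane_reverse[1] +
               cfg$response_plane_reverse[2] * I_head +
               cfg$response_plane_reverse[3] * I_tail)
  ps <- clip01(cfg$response_plane_sprint[1] +
               cfg$response_plane_sprint[2] * I_head +
               cfg$response_plane_sprint[3] * I_tail)
  gate <- ifelse(state == "turn", cfg$turn_gating_factor, 1)
  pr <- pr * gate
  ps <- pmin(ps * gate, 1 - pr)  # outcomes are exclusive
  u <- runif(length(pr))
  ifelse(u < pr, "reverse", ifelse(u < pr + ps, "sprint", "none"))
}

rgamma_mean <- function(n, mean, shape = 4) {
  if (mean <= 0) return(rep(0, n))
  rgamma(n, shape = shape, scale = mean / shape)
}

#' Advance the arena by one frame
#'
#' Applies timed state exits, spontaneous Poisson behavior transitions
#' (per-frame Bernoulli with probability rate/fps), evoked responses at
#' stimulus onsets drawn from the planar response model, and kinematics
#' (translation along the heading, sign-flipped when reversing; heading
#' diffusion; boundary reflection; undulation phase advance).
#'
#' @param world a `world_state` from [init_world()].
#' @param cfg the [sim_config()].
#' @param stim `NULL`, or a data frame with columns `worm_id`, `I_head`,
#'   `I_tail` (uW/mm^2 sampled at the true head/tail tips) and `onset`
#'   (logical; `TRUE` on the first frame a stimulus is applied to that worm).
#'   A response is drawn once per onset row.
#' @return The advanced `world_state`; attribute `"events"` holds a tibble of
#'   this frame's events (`type` is `"turn_init"`, `"reversal_init"`,
#'   `"sprint_init"` or `"stim_response"`, with the drawn `outcome`).
#' @export
step_world <- function(world, cfg, stim = NULL) {
  dt <- 1 / cfg$fps
  w <- world$worms
  n <- length(w$id)
  t_new <- world$time_s + dt
  ev_id <- integer(0); ev_type <- character(0); ev_out <- character(0)

  # timed exits back to forward crawling
  done <- w$state != "forward" & t_new >= w$state_until
  if (any(done)) {
    w$state[done] <- "forward"
    w$state_until[done] <- Inf
  }

  # spontaneous transitions
  non_turn <- w$state != "turn"
  if (cfg$turn_rate_hz > 0 && any(non_turn)) {
    init <- non_turn & runif(n) < cfg$turn_rate_hz * dt
    if (any(init)) {
      w$state[init] <- "turn"
      w$turn_t0[init] <- t_new
      w$bend_dir[init] <- sample(c(-1, 1), sum(init), replace = TRUE)
      w$state_until[init] <- t_new + rgamma_mean(sum(init), cfg$turn_duration_s)
      ev_id <- c(ev_id, w$id[init])
      ev_type <- c(ev_type, rep("turn_init", sum(init)))
      ev_out <- c(ev_out, rep(NA_character_, sum(init)))
    }
  }
  fwd <- w$state == "forward"
  if (cfg$spont_reversal_rate_hz > 0 && any(fwd)) {
    rev <- fwd & runif(n) < cfg$spont_reversal_rate_hz * dt
    if (any(rev)) {
      w$state[rev] <- "reverse"
      w$state_until[rev] <- t_new + rgamma_mean(sum(rev), cfg$reversal_duration_s)
      ev_id <- c(ev_id, w$id[rev])
      ev_type <- c(ev_type, rep("reversal_init", sum(rev)))
      ev_out <- c(ev_out, rep(NA_character_, sum(rev)))
    }
  }
  fwd <- w$state == "forward"
  if (cfg$spont_sprint_rate_hz > 0 && any(fwd)) {
    spr <- fwd & runif(n) < cfg$spont_sprint_rate_hz * dt
    if (any(spr)) {
      w$state[spr] <- "sprint"
      w$state_until[spr] <- t_new + rgamma_mean(sum(spr), cfg$sprint_duration_s)
      ev_id <- c(ev_id, w$id[spr])
      ev_type <- c(ev_type, rep("sprint_init", sum(spr)))
      ev_out <- c(ev_out, rep(NA_character_, sum(spr)))
    }
  }

  # evoked responses, one draw per stimulus onset
  if (!is.null(stim) && nrow(stim) > 0) {
    on <- stim[stim$onset, , drop = FALSE]
    if (nrow(on) > 0) {
      idx <- match(on$worm_id, w$id)
      if (anyNA(idx)) abort("stimulus references unknown worm id")
      out <- draw_response(cfg, w$state[idx], on$I_head, on$I_tail)
      take_r <- out == "reverse"
      take_s <- out == "sprint"
      if (any(take_r)) {
        i <- idx[take_r]
        w$state[i] <- "reverse"
        w$state_until[i] <- t_new +
          rgamma_mean(length(i), cfg$reversal_duration_s)
      }
      if (any(take_s)) {
        i <- idx[take_s]
        w$state[i] <- "sprint"
        w$state_until[i] <- t_new + rgamma_mean(length(i), cfg$sprint_duration_s)
      }
      ev_id <- c(ev_id, on$worm_id)
      ev_type <- c(ev_type, rep("stim_response", nrow(on)))
      ev_out <- c(ev_out, out)
    }
  }

  # slowly varying speed multiplier (AR(1), 2-s correlation time)
  rho <- exp(-dt / 2)
  w$speed_mult <- 1 + rho * (w$speed_mult - 1) +
    rnorm(n, 0, cfg$speed_cv * sqrt(1 - rho^2))

  spd <- cfg$speed_mm_s * pmax(w$speed_mult, 0)
  v <- numeric(n)
  st <- w$state
  v[st == "forward"] <- spd[st == "forward"]
  v[st == "sprint"] <- cfg$sprint_speed_mult * spd[st == "sprint"]
  v[st == "reverse"] <- -spd[st == "reverse"]
  v[st == "turn"] <- 0.25 * spd[st == "turn"]
  # pause: 0

  moving_fwd <- st %in% c("forward", "sprint")
  w$heading[moving_fwd] <- w$heading[moving_fwd] +
    rnorm(sum(moving_fwd), 0, 0.3 * sqrt(dt))
  turning <- st == "turn"
  w$heading[turning] <- w$heading[turning] + w$bend_dir[turning] * 2.0 * dt

  w$x <- w$x + v * dt * cos(w$heading)
  w$y <- w$y + v * dt * sin(w$heading)
  w$phase <- (w$phase + 2 * pi * 0.6 * dt) %% (2 * pi)

  # walls: a continuous version of specular reflection. Inside the margin
  # the heading is steered rapidly toward the mirror direction, so the body
  # (which hangs off the head anchor) never jumps between frames.
  m <- w$length_mm
  steer <- 4 * dt                      # rad per frame of wall steering
  phi <- ifelse(v >= 0, w$heading, w$heading + pi)   # direction of motion
  wrap <- function(a) ((a + pi) %% (2 * pi)) - pi
  need_x <- (w$x < m & cos(phi) < 0) |
    (w$x > cfg$arena_size_mm[1] - m & cos(phi) > 0)
  if (any(need_x)) {
    delta <- wrap(pi - 2 * phi[need_x])
    w$heading[need_x] <- w$heading[need_x] +
      sign(delta) * pmin(abs(delta), steer)
  }
  phi <- ifelse(v >= 0, w$heading, w$heading + pi)
  need_y <- (w$y < m & sin(phi) < 0) |
    (w$y > cfg$arena_size_mm[2] - m & sin(phi) > 0)
  if (any(need_y)) {
    delta <- wrap(-2 * phi[need_y])
    w$heading[need_y] <- w$heading[need_y] +
      sign(delta) * pmin(abs(delta), steer)
  }
  # hard floor so nothing ever leaves the plate
  eps <- 0.02
  w$x <- pmin(pmax(w$x, eps), cfg$arena_size_mm[1] - eps)
  w$y <- pmin(pmax(w$y, eps), cfg$arena_size_mm[2] - eps)

  out <- structure(list(time_s = t_new, frame = world$frame + 1L, worms = w),
                   class = "world_state")
  ne <- length(ev_id)
  attr(out, "events") <- tibble::new_tibble(list(
    frame = rep(out$frame, ne), time_s = rep(t_new, ne), worm_id = ev_id,
    type = ev_type, outcome = ev_out), nrow = ne)
  out
}

#' Ground-truth centerline of each simulated worm
#'
#' Builds the body curve from the parametric shape model: a traveling
#' sinusoidal undulation (tangent-angle amplitude chosen so the lateral
#' excursion is ~10% of body length, one wavelength per body) plus, during a
#' turn, a uniformly distributed extra bend that ramps in and out and drives
#' the omega-like posture.
#'
#' @param world a `world_state`.
#' @param cfg the [sim_config()].
#' @param n number of points per centerline (head first).
#' @return A list (one element per worm) of `n x 2` matrices of mm
#'   coordinates, head at row 1; each has attribute `"length_mm"`.
#' @export
true_centerlines <- function(world, cfg, n = 20) {
  w <- world$worms
  lapply(seq_along(w$id), function(i) {
    bend <- 0
    if (w$state[i] == "turn") {
      ramp <- min(1,
                  (world$time_s - w$turn_t0[i]) / cfg$turn_ramp_s,
                  max(0, (w$state_until[i] - world$time_s) / cfg$turn_ramp_s))
      bend <- cfg$turn_bend_rad * max(ramp, 0) * w$bend_dir[i]
    }
    worm_curve(w$x[i], w$y[i], w$heading[i], w$phase[i], w$length_mm[i],
               bend, n)
  })
}

# Integrate the tangent-angle model head -> tail.
worm_curve <- function(x0, y0, heading, phase, length_mm, bend_rad, n) {
  nd <- max(n, 41)
  s <- seq(0, length_mm, length.out = nd)
  ds <- s[2] - s[1]
  s_mid <- (s[-1] + s[-nd]) / 2
  psi <- (heading + pi) + 0.45 * sin(2 * pi * s_mid / length_mm - phase) +
    bend_rad * s_mid / length_mm
  x <- x0 + c(0, cumsum(ds * cos(psi)))
  y <- y0 + c(0, cumsum(ds * sin(psi)))
  if (n < nd) {
    keep <- round(seq(1, nd, length.out = n))
    x <- x[keep]; y <- y[keep]
  }
  structure(cbind(x = x, y = y), length_mm = length_mm)
}

#' Run the simulator without imaging
#'
#' Fast path used for rate calibration and event-level experiments: steps the
#' world for `duration_s` seconds with no rendering, accumulating the event
#' log and per-state occupancy (worm-seconds). Optionally applies a
#' pre-computed stimulus schedule and/or records a per-frame ground-truth
#' log.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds the RNG.
#' @param duration_s simulated duration in seconds.
#' @param stim_schedule `NULL`, or a data frame with columns `frame`,
#'   `worm_id`, `I_head`, `I_tail`, `duration_s`; each row is one stimulus
#'   whose onset is at `frame`.
#' @param record one of `"none"` or `"centroid"`: whether to keep a per-frame
#'   per-worm ground-truth log (head-tip position and state).
#' @return A list with `events` (tibble), `occupancy_s` (named worm-seconds
#'   per behavior state), `exposure_nonturn_s`, `truth` (tibble or `NULL`)
#'   and the final `world`.
#' @export
#' @examples
#' sim <- simulate_world(sim_config(n_worms = 5, seed = 7), duration_s = 60)
#' table(sim$events$type)
simulate_world <- function(cfg, duration_s,
                           stim_schedule = NULL,
                           record = c("none", "centroid")) {
  record <- match.arg(record)
  set.seed(cfg$seed)
  world <- init_world(cfg)
  n_frames <- as.integer(round(duration_s * cfg$fps))
  dt <- 1 / cfg$fps
  occ <- setNames(numeric(length(STATE_LEVELS)), STATE_LEVELS)
  exposure <- 0
  ev <- vector("list", 64); n_ev <- 0
  truth <- NULL
  if (record == "centroid") {
    nw <- cfg$n_worms
    truth <- list(frame = integer(n_frames * nw), time_s = numeric(n_frames * nw),
                  worm_id = integer(n_frames * nw), x_mm = numeric(n_frames * nw),
                  y_mm = numeric(n_frames * nw),
                  state = character(n_frames * nw))
  }
  sched <- NULL
  if (!is.null(stim_schedule)) {
    stopifnot(all(c("frame", "worm_id", "I_head", "I_tail", "duration_s")
                  %in% names(stim_schedule)))
    sched <- split(stim_schedule, stim_schedule$frame)
  }
  for (f in seq_len(n_frames)) {
    st <- world$worms$state
    cnt <- tabulate(match(st, STATE_LEVELS), length(STATE_LEVELS))
    occ <- occ + cnt * dt
    exposure <- exposure + sum(st != "turn") * dt
    stim <- NULL
    if (!is.null(sched)) {
      s <- sched[[as.character(f)]]
      if (!is.null(s)) {
        stim <- tibble::tibble(worm_id = s$worm_id, I_head = s$I_head,
                               I_tail = s$I_tail, onset = TRUE)
      }
    }
    world <- step_world(world, cfg, stim)
    e <- attr(world, "events")
    if (nrow(e) > 0) {
      n_ev <- n_ev + 1
      if (n_ev > length(ev)) ev <- c(ev, vector("list", length(ev)))
      ev[[n_ev]] <- e
    }
    if (record == "centroid") {
      nw <- length(world$worms$id)
      i <- ((f - 1) * nw + 1):(f * nw)
      truth$frame[i] <- world$frame
      truth$time_s[i] <- world$time_s
      truth$worm_id[i] <- world$worms$id
      truth$x_mm[i] <- world$worms$x
      truth$y_mm[i] <- world$worms$y
      truth$state[i] <- world$worms$state
    }
  }
  events <- if (n_ev > 0) dplyr::bind_rows(ev[seq_len(n_ev)]) else
    tibble::tibble(frame = integer(), time_s = numeric(),
                   worm_id = integer(), type = character(),
                   outcome = character())
  list(events = events, occupancy_s = occ, exposure_nonturn_s = exposure,
       truth = if (is.null(truth)) NULL else tibble::as_tibble(truth),
       world = world)
}

#' Empirical spontaneous turn-initiation rate of the simulator
#'
#' Runs [simulate_world()] with no stimulation and estimates the
#' turn-initiation rate as initiations per second of non-turning worm time,
#' with its Poisson standard error.
#'
#' @param cfg a [sim_config()].
#' @param worm_hours total simulated worm-hours (split across `cfg$n_worms`).
#' @return A tibble with `n_turns`, `exposure_s` (non-turning worm-seconds),
#'   `rate_hz` and `se_hz`.
#' @export
measure_turn_rate <- function(cfg, worm_hours = 50) {
  duration_s <- worm_hours * 3600 / cfg$n_worms
  sim <- simulate_world(cfg, duration_s)
  n_turns <- sum(sim$events$type == "turn_init")
  tibble::tibble(
    n_turns = n_turns,
    exposure_s = sim$exposure_nonturn_s,
    rate_hz = n_turns / sim$exposure_nonturn_s,
    se_hz = sqrt(n_turns) / sim$exposure_nonturn_s)
}

#' Draw evoked-response outcomes at the event level
#'
#' Samples `n` stimulus onsets through the simulator's planar response model
#' (the same code path used by [step_world()]) for a fixed behavioral context
#' and intensity pair. Used for event-level statistics where the imaging path
#' is not under study.
#'
#' @param cfg a [sim_config()].
#' @param n number of stimulus events.
#' @param I_head,I_tail intensities (uW/mm^2), scalars or length-`n` vectors.
#' @param context `"forward"` or `"turn"` — the behavior state at onset.
#' @return A tibble with `event_id`, `I_head`, `I_tail`, `context`,
#'   `outcome` and logical `reversal`.
#' @export
simulate_response_events <- function(cfg, n, I_head, I_tail,
                                     context = "forward") {
  stopifnot(context %in% STATE_LEVELS)
  I_head <- rep_len(I_head, n); I_tail <- rep_len(I_tail, n)
  out <- draw_response(cfg, rep(context, n), I_head, I_tail)
  tibble::tibble(event_id = seq_len(n), I_head = I_head, I_tail = I_tail,
                 context = context, outcome = out,
                 reversal = out == "reverse")
}
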