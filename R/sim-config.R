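#' Configuration for the synthetic multi-worm arena
#'
#' Builds the configuration object consumed by [init_world()], [step_world()],
#' [render_frame()] and [run_experiment()]. The defaults describe the study
#' conditions the package emulates: adult *C. elegans* (~1 mm long, ~80 um
#' wide) crawling at ~0.2 mm/s on a 9-cm plate imaged in dark field at 30 Hz
#' and ~44 um/px, with spontaneous omega-turn initiation at ~0.03 Hz.
#'
#' The optogenetic stimulus-response model is planar: at each stimulus onset
#' the probability of an evoked reversal (or sprint) is a clipped planar
#' function of the light intensity delivered at the head tip and at the tail
#' tip, `clip01(b0 + bh * I_head + bt * I_tail)` with intensities in uW/mm^2.
#' During a turn both probabilities are multiplied by `turn_gating_factor`,
#' reproducing turn-gating of mechanosensory reversals by construction.
#'
#' @param arena_size_mm numeric length 2, arena width and height in mm.
#' @param um_per_px image scale, microns per pixel (> 0).
#' @param fps frame rate, frames per second.
#' @param n_worms number of worms seeded into the arena.
#' @param worm_length_um,worm_length_sd_um mean and SD of worm length (um).
#' @param worm_width_um maximum body width (um); the rendered width profile
#'   tapers to about one pixel at the head and tail tips.
#' @param speed_mm_s mean forward crawling speed (mm/s).
#' @param speed_cv coefficient of variation of the slowly varying speed
#'   multiplier (AR(1) noise), giving a realistic spread of positive
#'   velocities for the equal-area state cutoffs.
#' @param turn_rate_hz spontaneous turn-initiation rate (Hz) applied in every
#'   non-turning state.
#' @param spont_reversal_rate_hz spontaneous reversal-initiation rate (Hz)
#'   applied during forward locomotion.
#' @param spont_sprint_rate_hz spontaneous sprint-initiation rate (Hz);
#'   defaults to 0 (sprints then occur only as evoked responses or as the
#'   fast tail of the speed distribution).
#' @param turn_duration_s mean turn duration (s); durations are drawn from a
#'   Gamma(shape = 4) with this mean so that near-zero turns are rare.
#' @param reversal_duration_s mean duration of a (spontaneous or evoked)
#'   reversal bout (s), Gamma(shape = 4).
#' @param sprint_duration_s mean duration of an evoked sprint bout (s).
#' @param sprint_speed_mult speed multiplier during a sprint.
#' @param turn_bend_rad total body bend during a fully developed turn
#'   (radians); ~4.7 rad gives an omega-like posture whose rendered ellipse
#'   ratio falls below 3.5.
#' @param turn_ramp_s time to ramp the turn bend in and out (s).
#' @param response_plane_reverse,response_plane_sprint numeric length 3
#'   `(b0, bh, bt)`: intercept and head/tail intensity slopes (per uW/mm^2)
#'   of the planar response-probability model.
#' @param turn_gating_factor multiplier in `[0, 1]` applied to both evoked
#'   response probabilities when the stimulus arrives during a turn.
#' @param latency_frames closed-loop latency: frames between an observation
#'   reaching the controller and its stimulus mask being applied
#'   (6 frames = 200 ms at 30 Hz).
#' @param bg_level,fg_level 8-bit background and worm intensity of rendered
#'   frames.
#' @param seed integer RNG seed used by [run_experiment()] and
#'   [simulate_world()].
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_worms = 2, arena_size_mm = c(6, 6), um_per_px = 20)
#' cfg$turn_rate_hz
sim_config <- function(arena_size_mm = c(90.1, 66.2),
                       um_per_px = 44,
                       fps = 30,
                       n_worms = 40,
                       worm_length_um = 1000,
                       worm_length_sd_um = 100,
                       worm_width_um = 80,
                       speed_mm_s = 0.2,
                       speed_cv = 0.25,
                       turn_rate_hz = 0.03,
                       spont_reversal_rate_hz = 0.02,
                       spont_sprint_rate_hz = 0,
                       turn_duration_s = 2,
                       reversal_duration_s = 1.5,
                       sprint_duration_s = 2,
                       sprint_speed_mult = 2,
                       turn_bend_rad = 4.7,
                       turn_ramp_s = 0.25,
                       response_plane_reverse = c(0.10, 0.009, 0.0005),
                       response_plane_sprint = c(0.20, -0.002, 0.0005),
                       turn_gating_factor = 0.5,
                       latency_frames = 6,
                       bg_level = 10,
                       fg_level = 200,
                       seed = 1L) {
  stopifnot(length(arena_size_mm) == 2, all(arena_size_mm > 0))
  if (um_per_px <= 0) abort("um_per_px must be > 0")
  rates <- c(turn_rate_hz, spont_reversal_rate_hz, spont_sprint_rate_hz)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    abort("rates must be finite and >= 0")
  }
  if (turn_gating_factor < 0 || turn_gating_factor > 1) {
    abort("turn_gating_factor must be in [0, 1]")
  }
  stopifnot(length(response_plane_reverse) == 3,
            length(response_plane_sprint) == 3,
            fps > 0, n_worms >= 0)
  structure(list(
    arena_size_mm = as.numeric(arena_size_mm),
    um_per_px = um_per_px, fps = fps, n_worms = as.integer(n_worms),
    worm_length_um = worm_length_um, worm_length_sd_um = worm_length_sd_um,
    worm_width_um = worm_width_um,
    speed_mm_s = speed_mm_s, speed_cv = speed_cv,
    turn_rate_hz = turn_rate_hz,
    spont_reversal_rate_hz = spont_reversal_rate_hz,
    spont_sprint_rate_hz = spont_sprint_rate_hz,
    turn_duration_s = turn_duration_s,
    reversal_duration_s = reversal_duration_s,
    sprint_duration_s = sprint_duration_s,
    sprint_speed_mult = sprint_speed_mult,
    turn_bend_rad = turn_bend_rad, turn_ramp_s = turn_ramp_s,
    response_plane_reverse = as.numeric(response_plane_reverse),
    response_plane_sprint = as.numeric(response_plane_sprint),
    turn_gating_factor = turn_gating_factor,
    latency_frames = as.integer(latency_frames),
    bg_level = bg_level, fg_level = fg_level,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  arena %.1f x %.1f mm at %.1f um/px, %g fps\n",
              x$arena_size_mm[1], x$arena_size_mm[2], x$um_per_px, x$fps))
  cat(sprintf("  %d worms, length %g +/- %g um, speed %g mm/s\n",
              x$n_worms, x$worm_length_um, x$worm_length_sd_um, x$speed_mm_s))
  cat(sprintf("  turn rate %g Hz, reversal rate %g Hz, gating %g\n",
              x$turn_rate_hz, x$spont_reversal_rate_hz, x$turn_gating_factor))
  cat(sprintf("  reverse plane (%g, %g, %g); sprint plane (%g, %g, %g)\n",
              x$response_plane_reverse[1], x$response_plane_reverse[2],
              x$response_plane_reverse[3], x$response_plane_sprint[1],
              x$response_plane_sprint[2], x$response_plane_sprint[3]))
  invisible(x)
}

#' Read or write a flat key-value simulator configuration file
#'
#' One `key = value` pair per line; vector values are comma-separated.
#'
#' @param cfg a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lines <- vapply(names(cfg), function(nm) {
    paste0(nm, " = ", paste(format(cfg[[nm]], digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- lapply(kv, function(p) as.numeric(strsplit(trimws(p[2]), ",")[[1]]))
  names(args) <- vapply(kv, function(p) trimws(p[1]), character(1))
  do.call(sim_config, args)
}
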