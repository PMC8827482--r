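---
title: "Closed-loop targeted stimulation of crawling worms: models and methods"
author: "wormloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop targeted stimulation of crawling worms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package models

High-throughput optogenetics instruments for *C. elegans* track tens of
crawling animals on an agar plate with a dark-field camera, extract each
animal's centerline in real time, and use a projector to paint red-light
spots onto specific body parts (head, tail, or whole body) — either on a
fixed open-loop schedule or closed-loop, triggered by the animal's own
behavior (the onset of an omega turn). The evoked behavior is then
quantified as velocity-defined state transitions and reversal
probabilities.

`wormloop` re-creates that system entirely in software. A synthetic
multi-worm arena stands in for the camera, projector and plate; on top of
it the package implements the instrument's real-time loop (segmentation,
track stitching, a two-pass recursive centerline algorithm, ellipse-ratio
turn triggering, targeted pattern generation with calibration and
latency) and the downstream statistics (bootstrapped state fractions,
transition-probability surfaces with least-squares plane fits,
turn-gated reversal probabilities, habituation curves, and
throughput/yield accounting). Because every frame comes with ground
truth, the pipeline's accuracy claims are testable end to end.

## The arena simulator

Each worm is a parametric planar curve anchored at its head tip. The
tangent angle along the body is

$$\psi(s) = \theta + \pi + A\,\sin(2\pi s/L - \phi) + \beta(t)\,s/L,$$

with heading $\theta$, arc position $s \in [0, L]$, undulation amplitude
$A = 0.45$ rad (lateral excursion ~7–10% of body length, one wavelength
per body, wave traveling head to tail at 0.6 Hz), and a turn bend
$\beta$ that ramps from 0 to ~4.7 rad over 0.25 s when a turn starts.
The bend drives the rendered blob's ellipse (major/minor axis) ratio
from its elongated crawling range (~4.5–7) to below 2.5, so the 3.5
trigger threshold separates the two regimes cleanly.

Behavior is a four-state machine (forward, reverse, turn, pause) plus an
evoked sprint. Time is discrete at the frame rate; every rate becomes a
per-frame Bernoulli probability `rate / fps`. Defaults are the study
conditions: forward speed 0.2 mm/s with a slowly varying multiplier
(AR(1), 2-s correlation time, CV 0.25 — this spread is what makes the
equal-area velocity terciles meaningful), spontaneous turn initiation at
0.03 Hz from any non-turning state, spontaneous reversals at 0.02 Hz,
turn durations Gamma(shape 4, mean 2 s), reversal bouts Gamma(4, 1.5 s).
Spontaneous sprint initiation defaults to 0: sprints enter as evoked
responses and as the fast tail of the speed distribution, which is all
the tercile cutoffs require.

**Stimulus response.** At each stimulus onset — and only at onset — the
worm draws its next behavior from a planar probability model sampled at
its true head and tail tips:

$$p_\text{rev} = \mathrm{clip}_{[0,1]}(\beta_0^r + \beta_h^r I_\text{head} + \beta_t^r I_\text{tail}), \qquad
  p_\text{spr} = \mathrm{clip}_{[0,1]}(\beta_0^s + \beta_h^s I_\text{head} + \beta_t^s I_\text{tail}),$$

with intensities in µW/mm². If the worm is mid-turn at onset, both
probabilities are multiplied by `turn_gating_factor` (default 0.5),
building the turn-gating phenomenon into the generator so the analysis
stack can be asked to recover it. Default planes are
$(0.10, 0.009, 0.0005)$ for reversal (head-dominant) and
$(0.20, -0.002, 0.0005)$ for sprint — a tail:head gradient ratio of
$1{:}{-4}$, suppressed by head drive — chosen once so probabilities stay
inside $[0,1]$ over the $\{0,20,40,60,80\}$ µW/mm² grid.

**Walls.** The arena boundary acts as a reflector, implemented as rapid
continuous steering (4 rad/s) toward the specular heading rather than an
instantaneous flip: the body hangs off the head anchor, so a one-frame
heading reversal would teleport the rendered blob by a body length and
artificially shatter tracks. A hard position floor guarantees no worm
leaves the plate.

**Rendering.** Dark field is emulated by painting each worm as a union
of filled disks along a 41-point centerline with an elliptical width
profile (max 80 µm, tapering to ~1 px at the tips), foreground 200 on
background 10 (8-bit). Overlapping worms merge into one blob, as on the
real instrument. The default full-scale format is 2048×1504 px at
44 µm/px; tests run smaller arenas at 20 µm/px so a 1-mm worm spans
~50 px.

What the generator does *not* emulate: photorealistic optics and noise,
channel kinetics (responses are drawn once at onset, with no
inactivation dynamics), body-contact mechanics during collisions (blobs
merge purely optically), larval sizes, and lawn-dependent behavioral
modulation. Passing tests therefore demonstrate the correctness of the
algorithms and estimators under the stated generative model, not
performance on real recordings.

## The real-time pipeline

*Segmentation* thresholds at a fixed global intensity (the synthetic
movies have controlled contrast) and labels 8-connected components;
per-blob statistics include the ellipse ratio
$\sqrt{\lambda_1/\lambda_2}$ of the second-central-moment matrix (with
the 1/12 pixel-variance term) and convex-hull solidity.

*Track stitching* is greedy nearest-centroid within `max_disp_px`, in
the Parallel Worm Tracker lineage: unmatched blobs open tracks, tracks
unseen for more than 3 frames close, and when two tracks claim one blob
both are closed and the merged blob is followed as a new, merge-flagged
entity until it splits (identity is deliberately not preserved through
collisions).

*Centerline extraction* is the two-pass recursive algorithm. The mask is
thinned (Zhang–Suen iterated to a fixed point, then a sequential
simple-point cleanup using the Yokoi 8-connectivity number, which
removes the staircase pixels parallel thinning leaves and guarantees a
strictly 1-px-wide skeleton). Pass one walks the skeleton depth-first
from the lowest-(y,x) endpoint, cutting it into segments at branch
points; pass two recursively explores all simple endpoint-to-endpoint
routes through the segment graph and keeps the longest, with diagonal
steps weighted $\sqrt2$ and ties broken by the lexicographically
smallest endpoint pair. The skeleton graph drops diagonal edges that
shortcut a foreground 4-neighbor pair — without this, every ideal
junction contains pixel triangles and no clean branch decomposition
exists. Skeletons with fewer than two endpoints (closed or lollipop
topologies, i.e. self-touching postures) are rejected, matching the
real-time algorithm's stated failure mode. The winning path is smoothed
(5-point moving average, endpoints fixed) and resampled to 20 points
uniform in arc length; the reported length is the resampled polyline's
arc length. On rendered worms this recovers 93–100% of true body length
— slightly short, as expected from tip erosion — at both 20 and
8.5 µm/px.

*Head/tail orientation* uses the rule that worms do not crawl backward
for long: the centerline end leading the net trailing displacement is
the provisional head, flipped only after more than 10 s of continuous
contradiction (real-time mode); post hoc, one orientation per track is
chosen to maximize total head-first time.

*Velocity* is the frame-to-frame displacement of the body midpoint
(point 10 of 0–19) projected on the midpoint-to-head axis (positive =
head-first), times the frame rate, smoothed with a centered ~1-s boxcar
(31 samples at 30 Hz; edges use the partial window). The midpoint is
used instead of the head because it is robust to head casts.

*Turn triggering* fires when the ellipse ratio crosses below 3.5 with a
30-s per-worm refractory period. Post hoc validation uses the slightly
looser 3.6 threshold, requires velocity above −0.05 mm/s throughout the
0.15 s before the crossing (tail bends during reversals masquerade as
turns), and requires the stimulus to land within 0.33 s after the
crossing. Both thresholds are computed from the same moment ellipse; the
3.5/3.6 pair is kept as two distinct settings.

*Stimulus targeting* places 0.5-mm disks on centerline points 0 (head)
and 19 (tail) or a 1.5-mm disk on the 20-point centroid; patterns are
cropped against a 100-µm dilation of encroaching neighbors (never the
target's own body), re-drawn every frame during multi-second stimuli,
and applied after a configurable closed-loop latency (default 6 frames ≈
200 ms at 30 Hz). Camera→projector mapping is an 8-parameter projective
fit to a dot grid, with drift quantified by mapping end-of-run dots
through the start-of-run transform; frames carry a binary visual
timestamp (bits on a circle) that decodes exactly.

## Statistics

Inclusion follows the instrument's postprocessing: a stimulus event
counts only if the worm was a valid single animal (length ≤ 700 µm —
min 550 µm and 17-s pre-tracking for turning runs —, mean width ≤
120 µm, solidity ≥ 0.35, trailing-10-s displacement ≥ 100 µm), tracked
continuously 8 s before and after onset, and did not collide around
stimulation. The instrument's "reasonable shape" requirement is operationalized by the
solidity and width bounds; reason codes are reported so users can relax
them.

State fractions are tabulated 2 s before onset and at stimulus end with
percentile CIs from 1,000 event-level bootstraps and Wilcoxon rank-sum
p-values on the occupancy indicators. Transition surfaces are per-cell
post-state fractions on the 5×5 intensity grid (they sum to one
cell-wise); plane fits are OLS of cell probability on
$(1, I_\text{head}, I_\text{tail})$ with populated cells weighted
equally (count-weighting is an option), and per-component 95% CIs from
1,000 bootstrap resamples of events (resample → re-tabulate → refit).
Reversal probabilities use 10,000 bootstraps and pooled two-proportion
Z-tests; habituation bins events into half-open 2-min intervals. No
multiple-testing correction is applied, matching the source analyses.
Yield is the fraction of delivered stimuli that were turn-onset
associated, and throughput is turn-associated events per worm-hour, both
rounded to one decimal; worm-hours are the tracked-worm occupancy
integral.

Boundary conventions fixed for determinism: $v = 0$ classifies as
pause/slow; the reversal call is strictly $v < -0.1$ mm/s; the
equal-area cutoffs are midpoints between bracketing order statistics so
the three positive bins differ by at most one count; an event at exactly
120 s belongs to the second habituation bin. Bootstrap CIs are
percentile (not BCa); the resampling unit is always the stimulus event.

## Verification strategy and problem sizes

Every derived expectation in the test suite is computed by an
independent oracle: closed-form moments for rectangle ellipse ratios,
igraph exhaustive simple-path search for the centerline (500 random
skeletons with ≤ 12 segments), convolution oracles for smoothing,
analytic quantiles for cutoffs, `prop.test`'s chi-square identity for
the Z statistic, and the simulator's ground-truth logs for tracking,
targeting and yield.

The acceptance-level checks run at sizes a laptop handles in minutes:
rate calibration at 100 worms × 30 min (50 worm-hours, turn-initiation
rate within 3 SE of 0.03 Hz); head-targeting accuracy on a 2-worm,
120-s movie at 20 µm/px with 6-frame latency (≥ 95% of head-spot centers
within 200 µm of the true head; observed median error ~54 µm, the 40-µm
latency bound plus tracking error); closed- vs open-loop yield on
identical 5-worm, 300-s settings (observed ~84% vs ~2.4%, a > 10-fold
ratio mirroring the published comparison); and parameter recovery of the
generating plane gradients within their bootstrap CIs in ≥ 90% of 20
replicate 25-condition experiments at 200 events per cell. The
plane-recovery and turn-gating checks draw responses through the
simulator's event-level response path rather than through rendered
movies: the contract under test there is the estimator against the
generative model, while the imaging path is covered by its own
end-to-end criteria. Turn-onset association for yield is judged against
ground truth (in a turn, within 1 s of initiation) identically in both
arms.

## Known limitations

Identity is lost at collisions by design; the post hoc turn call uses
only the ellipse-ratio and velocity criteria (no posture-dynamics
behavior mapper); cyclic self-touching postures are rejected rather than
rescued; projector intensity is treated as continuous (no mirror
duty-cycle model) and only the red channel stimulates; the simulator's
locomotion is kinematic, so body mechanics during contact and
substrate-dependent gait changes are out of scope.
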