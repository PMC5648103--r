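---
title: "Methods: tracking, behavior classification and closed-loop simulation in ethotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking, behavior classification and closed-loop simulation in ethotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethotrack)
```

ethotrack is a desk-scale re-implementation of the software core of a
video-tracking platform for fly ethomics: machines that watch one fly per
glass tube, classify its behavior in real time, and can feed stimuli back to
individual animals when a behavioral condition is met. The package covers
the full chain — arena registration, tracking, behavior classification,
closed-loop triggering, and sleep analysis — and ships a synthetic arena
generator that renders ground-truthed recordings, so every stage is testable
end to end without recorded video or hardware.

This vignette explains the models and the numerical choices. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The synthetic arena

The generator emulates the standard sleep arena: 20 horizontal tubes
(60 mm × 5 mm interior), stacked with 2 mm gaps, imaged from above at
0.1 mm/px on an infrared backlight. The imaging model is deliberately
minimal: arena background at intensity 200/255, tube interior at 215, fly
and fiducial ink at 40, additive Gaussian pixel noise (SD 5 by default)
clipped to [0, 255]. The fly is an anti-aliased filled ellipse of
2.5 mm × 1 mm — one body length by the conventional figure for an adult fly.
Three filled fiducial discs (radius 1.5 mm) sit outside the tube block in a
*scalene* triangle; scaleneness is what makes the three-point correspondence
unambiguous without an orientation mark.

Frame timing follows the real-time regime of an embedded tracker: nominal
rates of 1–5 frames per second with inter-frame intervals drawn as
`(1/fps) · (1 + jitter · U(−1, 1))`, so timestamps are strictly increasing
but non-uniform.

For speed, frame noise is drawn from a 65,536-entry integer pool encoding
the distribution of `round(N(0, sd))`; this is distributionally equivalent
to adding Gaussian noise to the real-valued image and rounding, but runs in
integer arithmetic.

### Virtual fly kinematics

A behavior program is a list of (duration, state) segments over the three
states used throughout: **immobile**, **micromovement** (grooming, eating,
egg laying — in-place activity), and **walking**. Motion is simulated along
the tube axis in the same dimensionless velocity unit the classifier uses
(body lengths per second; see below), so a segment's realized per-window
maximal velocity is consistent with its state *by construction*:

| state | per-step velocity | burst probability per step |
|---|---|---|
| immobile | \|N(0.2, 0.1)\| | — |
| micromovement | N(1.75, 0.2) bursts over \|N(0.15, 0.1)\| | U(0.4, 0.7) per bout |
| walking | N(4.5, 0.5) strides over pauses | U(0.4, 0.8) per bout |

All burst distributions sit at least 3 SD inside the classification bands
delimited by the movement (1.0) and walking (2.5) thresholds. Two features
of the kinematics are deliberate and worth stating plainly:

* **Intermittency.** Grooming and walking are stop-and-go; a single stride
  is enough to make a 10-s window "walking" by maximal velocity while its
  cumulative path stays modest. This is precisely why maximal velocity, not
  cumulative distance, is the faithful per-window predictor of state — the
  relationship the feature-screening test verifies.
* **Per-bout vigor.** The burst probability is redrawn per bout from the
  ranges above. Without it, cumulative distance would be an almost perfect
  (and unrealistically clean) correlate of the state.

Immobile and micromoving flies oscillate around an anchor (mean-reverting),
walking flies keep a persistent direction that reflects at the tube ends,
and a small mean-reverting transverse jitter keeps the trajectory
two-dimensional. What the generator does **not** emulate: appearance
variation between flies, occlusions, shadows, reflections, condensation,
multi-animal scenes, or lens distortion. Passing tests therefore demonstrate
the correctness of the algorithms under the stated imaging model, not
field performance on arbitrary recordings.

## Registration

Arenas carry three printed reference marks. `detect_fiducials()` thresholds
dark ink halfway between the darkest pixel and the median background — a
plain Otsu split fails here because the arena/tube background is itself
bimodal — labels connected components (EBImage), and keeps candidates whose
equivalent radius is within ±50% of the expected fiducial radius and whose
moment-axis ratio is below 1.4 (a fly body, at ratio ≈ 2.5, is rejected).
Centroids are refined by intensity weighting, which locates a disc to a
small fraction of a pixel. With more than three candidates, the triplet
whose normalized triangle side lengths best match the template is chosen;
if none matches within tolerance the detection is ambiguous and errors.

`fit_arena_transform()` orders each triangle's vertices by the length of
the opposite side and solves the exact three-point affine map (an affine is
the most general transform determined by three points; it subsumes the
similarity case). `build_rois()` maps template corners through it and
recomputes the mm-per-px calibration from the transform's scale.
Registration runs once on the first frame and is held fixed — the arena is
mechanically locked for the duration of an experiment. Within a tube,
position is reported in mm from the food end along the tube axis, the
coordinate all zone predicates use.

## Tracking

The default tracker is adaptive background subtraction, one fly per ROI.
The concrete pipeline is a reconstruction — the platform it models does not
publish its internals — assembled from standard, individually testable
parts:

1. **Init**: per-pixel median of the first `n_init = 5` ROI crops. A median
   cannot see a fly parked at one spot through all init frames, so the
   model is additionally *bootstrapped*: a fly-sized dark blob segmented
   from the first frame by absolute darkness is patched out with the local
   background estimate. An immobile fly is thus segmentable from frame one.
2. **Segmentation**: threshold the positive difference `model − frame`
   (polarity is fixed: the fly is darker than the backlight), restricted to
   the tube mask; connected components of at least `min_area_px = 40` are
   blobs. The threshold is estimated once by Otsu on the pooled first 50
   difference images, floored at 12 intensity units so a fly-less start
   cannot produce a degenerate threshold.
3. **Update**: exponential running average with `alpha = 0.05`, applied
   only to pixels outside the detected blob (dilated by 3 px). The
   *selective* update is what keeps a fly that parks for hours from being
   absorbed into the background; the spot it later vacates heals at rate
   `alpha`, and because segmentation is dark-only the healing ghost can
   never be detected as a fly.
4. **Track point**: the blob nearest the previous position (largest, when
   there is none) yields the centroid and, from intensity-weighted second
   moments, the ellipse axes (`w = 4·sqrt(λ₁)`, `h = 4·sqrt(λ₂)`) and the
   orientation `phi`, reported modulo 180° since moments cannot resolve
   head from tail. Frames with no blob carry the previous position forward,
   flagged `is_inferred` — never silently mixed with real detections.

## Behavior classification

The corrected velocity of a step between consecutive *real* (non-inferred)
track points is

v_corr = (displacement in mm / body length) × (dt_nominal / Δt),

with body length 2.5 mm and `dt_nominal = 1` s: body lengths per second,
corrected for the actual frame interval, so that the classification
thresholds are frame-rate independent and a displacement of one body length
over one nominal interval is exactly 1. Inferred points contribute zero
displacement — velocity across a detection gap is computed between the
surrounding real points, avoiding phantom speed.

Features are computed on contiguous, non-overlapping 10-s windows aligned
to the trajectory start: the **maximal corrected velocity** and the
**cumulative walked distance**. A step ending exactly on a window boundary
belongs to the later window (the boundary sample opens the new window,
matching the generator's convention that a step's state is the state at its
end sample). The label rule is a pair of thresholds on the window maximum:

* `< 1.0` → immobile
* `[1.0, 2.5)` → micromovement
* `≥ 2.5` → walking,

with boundary values assigned upward. The walking threshold default is 2.5
relative units; both thresholds are plain arguments and raising either can
only move windows toward quieter classes (a monotonicity the tests assert).
Windows with no steps inherit the previous window's label.

`rank_features()` screens candidate features with random-forest variable
importance. The ranking statistic is *permutation* importance (mean
decrease in out-of-bag accuracy; small negative values, which are noise
around zero, are truncated to 0), with Gini importance reported alongside.
Gini importance was rejected as the ranking statistic because of its
split-accumulation artifact: a slightly weaker but correlated feature
collects more (deeper) splits and can accumulate a larger total impurity
decrease, making the ranking of two strong features essentially a coin
flip. Human annotation workflows are supported by `consensus_labels()`
(strict majority of at least three annotators; ambiguous windows are
excluded) and `score_classifier()` (per-class detection accuracy, i.e.
class recall, over non-excluded windows).

## The trigger engine

A trigger is a predicate tree over position, time and behavior with leaves
`behavior_is(state, d)`, `position_within(zone)`,
`position_crossed(boundary)`, `time_in(schedule)` and boolean combinators.
Semantics are sample-based and exact:

* `behavior_is(s, d)` holds when every visible sample back to at least `d`
  seconds ago is in state `s` — the run must have *started* at least `d`
  seconds before now.
* `position_crossed` compares the current side of the boundary with the
  last *non-zero* side: landing exactly on the boundary and retreating to
  the same side is not a crossing; passing through the exact boundary over
  two steps is.
* An empty history is `FALSE` for every predicate, never an error.

Two implementations exist on purpose. `evaluate_trigger()` re-scans the
recorded history from scratch — the reference. `trigger_stepper()` keeps
incremental per-leaf state (run start time, last side) for the real-time
loop. The acceptance suite proves them equal on every predicate tree up to
depth 3 over a fixed leaf set, evaluated along a 200-step stream.

`run_closed_loop()` replays a stream through a trigger: when it fires
inside the armed schedule an event is emitted and the following `mask_s = 5`
seconds are masked — samples in `(t, t + 5]` produce no track points and no
trigger evaluation (the stimulus itself moves the tube; masking avoids
motion artefacts), and continuity clocks restart after the mask. Evaluation
is sliding, once per processed frame, at the 1–5 Hz cadence of the frame
stream. One consequence worth spelling out: with 1 Hz samples, a
permanently immobile fly and a 20-s trigger yield a 26-s event period (20 s
of run, 5 s of mask, plus one sample to restart the clock), i.e. 138 events
per hour started at t = 0 — the package asserts this against an independent
discrete-event oracle rather than against a back-of-envelope `3600/25`.

Canned triggers mirror the two arms of the classic closed-loop
sleep-deprivation design: `sleep_deprivation_trigger()` (20 s of
immobility) and `yoked_trigger()` (midline crossing — the control fly is
stimulated only while demonstrably walking, equalizing stimulus exposure
without depriving sleep). Stimulus parameters (e.g. a 60° rotation in
0.12 s) are metadata on the event log; no hardware is driven.

## Sleep analysis and the virtual experiment

Sleep is scored with the field's five-minute rule: maximal runs of immobile
windows of at least `min_sleep_s = 300` become bouts (`annotate_sleep()`);
`sleep_profile()` bins bout coverage (30-min bins by default) and conserves
total bout time exactly. Uncertainty bands use a percentile bootstrap over
individuals (5,000 replicates, 95% by default); group comparisons use
pairwise two-sided Wilcoxon rank-sum tests (exact for small samples without
ties), with dead individuals excluded before testing and a zero-variance
comparison reported as p = 1. Boxplot whiskers follow Tukey's rule — the
most extreme values within 1.5 IQR of the hinges. Mean ± SD summaries use
the sample SD.

`simulate_sleep_experiment()` runs the three-arm design end to end on a
minimal homeostatic virtual fly: sleep pressure rises while awake
(1.5 h⁻¹), discharges during sleep (4 h⁻¹), and shifts the per-tick
logistic probabilities of falling asleep and waking together with a
12 h:12 h light-dark cycle. The one mechanistic commitment that matters is
that **only consolidated sleep discharges pressure** (bouts ≥ 300 s):
fragmented micro-sleeps are not restorative. That assumption is what makes
trigger-based fragmentation a deprivation at all — the deprived arm's
immobility trigger caps every sleep attempt at ~30 s, pressure saturates,
and the arm sleeps through the post-stimulation morning while the yoked arm
(stimulated only when walking) and the mock arm do not. The simulation is a
qualitative testbed for the design logic; its parameter values are chosen
for plausible fly-like profiles (roughly half the night asleep in
unstimulated arms, hundreds of stimuli per stimulated fly per night), not
fitted to any dataset, and no quantitative agreement with any real
experiment is claimed.

The experiment simulator evaluates its two triggers inline with the same
sample semantics as the engine (immobility run clock, last-non-zero-side
crossing, post-stimulus reset); at its 10-s tick the 5-s mask never covers
a full tick. The engine itself is validated separately by the
oracle-equivalence and closed-loop tests.

## Problem sizes and numerical conventions

The acceptance checks run at the study's conditions: 100 random placements
(rotation ≤ 10°, translation ≤ 30 px) of the 20-tube arena for
registration; twenty 300-s single-fly videos spanning 1–5 FPS at noise SD 5
for tracking (single-tube arenas, so each video is one fly's ROI); ≥ 1,000
ground-truth windows for classifier recovery; ten forest seeds for feature
screening; all ~1,200 depth-≤3 predicate trees for oracle equivalence;
n = 20 flies per arm × 10 seeds for the design property; 500 repetitions ×
5,000 bootstrap replicates for CI coverage. These sizes are the package's
choices for a thorough desk-scale run.

Conventions collected in one place: image origin top-left, x rightward, y
downward, 0-based pixel indices with integer pixel centres; angles in
degrees modulo 180; tube position in mm from the food end; windows
left-closed (`[start, end)`) with boundary samples opening the new window;
classification boundaries assigned upward; masking intervals left-open
(`(t, t + mask]`); strict majority for consensus; sample SD throughout.

## Known limitations

* One fly per ROI; no identity maintenance across flies, no multi-animal
  mode.
* The tracker is a faithful-by-properties reconstruction, not a port; its
  internals (update schedule, thresholding) are defaults overridable via
  `track_params()`.
* Recordings are PNG image-sequence directories with timestamp sidecars;
  video containers would need an external decoder that the package does not
  ship. Result stores are CSV (6-decimal round-trip) plus JSON metadata
  with a config hash.
* The virtual fly is a two-process caricature: no circadian oscillator
  proper, no siesta structure, no inter-individual variability beyond
  sampling noise.
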