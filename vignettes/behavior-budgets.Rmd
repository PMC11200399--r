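---
title: "Time budgets, plateau filtering and posture calls from detector output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time budgets, plateau filtering and posture calls from detector output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethotrack)
```

`ethotrack` analyzes the output of a box-detection model pointed at
enclosure CCTV: per-frame records of a behavior label, a confidence score
and a bounding box for a single focal subject. This vignette explains the
models and conventions behind each stage, the parameters that matter, what
the synthetic generator does and does not emulate, and the design choices
that were genuinely open.

## Data model and conventions

A **detection track** is a tibble with one row per detected frame
(`frame`, `time_s`, `behavior`, `confidence`, `x`, `y`, `width`,
`height`) plus two session attributes: `total_frames` — all frames of the
session, detected or not — and `fps`. The session context has to travel
with the data because undetected frames are invisible in the rows
themselves, and every budget is computed over `total_frames`. On disk the
context is a `#total_frames=N` comment line above the CSV header.

Conventions, fixed once and used everywhere:

* **Coordinates**: origin at the image top-left, x rightward, y downward,
  pixel units; boxes stored as `(x, y, width, height)`. PASCAL-VOC corner
  pairs `(xmin, ymin, xmax, ymax)` are converted on read. The box *bottom
  corner*, the point tracked by the false-positive filter, is
  `(x, y + height)`.
* **Frame indexing**: 0-based internally; VOC filename stems that carry
  1-based numbers are normalized on read (`index_base = "one"`).
* **Ethogram**: six categories — Locomotion, Inactive, Covered Inactive,
  Foraging/Feeding, Out of View/Not Labeled, Other. Detector output may
  carry only the first four; manual codings all six. The correction stage
  introduces a seventh, derived category, *False Positive (Locomotion)*.
* **Percent formatting**: one decimal, round half up, applied only at the
  reporting boundary (`print()`, `tidy()`); all arithmetic and all
  invariants are on unrounded values.
* **Single focal subject**: one detection per frame. Several objects in
  one frame or VOC file are an error by default; a
  `keep_highest_confidence` flag relaxes the CSV reader when a deployment
  really produces duplicates.

The CSV dialect itself is a defined convention of this package, not a
reconstruction of any particular labeling tool's export format. Numeric
fields are written in the shortest decimal form that parses back to the
same double, which makes write–read–write cycles byte-identical — the
property the reproducibility tests lean on.

## Time budgets

`budget_from_detections()` tallies frames per label; every frame without a
surviving detection is *Out of View/Not Labeled*. This merging is
deliberate: detector output cannot distinguish a subject that is truly out
of view from one the model was not confident about, so the model-side
budget has a single such category. `apply_confidence_threshold()` is
boundary-inclusive (a detection at exactly `tau` survives), reading a
detector "set to 80% confidence" as a minimum-acceptance rule; the
threshold is a parameter, not a constant.

At ~1 frame/s a frame count divided by `total_frames` and a duration
divided by session length agree only approximately; the package
standardizes on frames as the denominator everywhere, so counts and
percentages are always mutually consistent.

`compare_budgets()` reports model-minus-manual differences per category.
The summary `total_disagreement` sums absolute differences over the four
detector-visible behaviors only: *Other* is structurally absent from
detector output and *Out of View/Not Labeled* means different things on
the two sides, so including either would measure vocabulary mismatch, not
model quality.

## The plateau filter

The bottom-corner coordinates of *Locomotion*-labeled boxes, plotted by
frame, separate genuine movement (sustained change on both axes) from the
detector's characteristic failure: a stationary animal mislabeled as
moving, which produces a flat stretch — a plateau. The filter makes that
visual judgment algorithmic.

A plateau is a maximal run of Locomotion detections satisfying three
conditions, all exposed in `plateau_config()`:

* the coordinate **range** (max − min) over the run stays within
  `epsilon_x` / `epsilon_y` pixels (default 5 px each). A range criterion
  rather than frame-to-frame deltas tolerates sub-pixel jitter that
  accumulates slowly, matching what a flat stretch in the plot looks like;
* the run has at least `min_run` detections (default 3) — two coincident
  boxes are not evidence of stillness at 1 frame/s;
* consecutive members are separated by at most `max_gap` frames without a
  Locomotion detection (default 2), so a single missed detection does not
  split one plateau into two.

Whether "no movement" requires stillness on *both* axes or on either one
is genuinely ambiguous; both modes are implemented
(`require_both_axes_still`, default `TRUE`). The stricter both-axes
reading is the default because genuine locomotion at realistic speed must
move at least one axis fast, so requiring both axes still is the mode with
the lower false-alarm rate on true locomotion.

The scanner grows each candidate run greedily from the earliest unused
entry and emits disjoint, ordered runs; the test suite checks it against
an exhaustive all-windows oracle on series up to length 200. Both the
epsilon tolerances and `min_run` act monotonically (tightening them never
flags more frames), and the filter is translation-invariant.

Flagged frames move to their own category rather than to Inactive: the
plateau diagnoses that the frame is *not* locomotion, but not what the
animal was actually doing. Conservation then holds exactly:
`fp_percent + corrected_locomotion_percent = raw_locomotion_percent` on
unrounded values, and on the underlying integer counts.

The default tolerances are engineering choices — the visual plateau
removal they formalize was originally a manual step with no published
settings — and should be reviewed against the camera geometry of any new
deployment (5 px means something different at 640×480 than at 4K).

## Posture from the box aspect ratio

`classify_posture()` is a pure threshold rule on $r = h/w$:
$r \ge$ `upper_limit` → *Arms up*, $r \le$ `lower_limit` → *Lying down*,
else *Neutral*, with boundaries inclusive toward the extreme call. The
defaults (2.0 and 0.6) are placeholders around a roughly 2:3 sitting box;
real deployments must calibrate both limits on footage of the actual
subject, which is why `ratio_config()` is a required, visible part of the
call. Posture is reported alongside the behavior label, never merged into
it — it is a post-hoc channel derived from geometry, not an ethogram
category.

## The synthetic generator

`synthetic_scenario()` + `simulate_study()` stand in for the camera, the
animal and the trained detector, so every downstream stage is testable
without video. Three stages, each drawing from its own RNG stream derived
from the master seed (so a stage can be re-run in isolation), and fully
deterministic given `(scenario, seed)`:

1. **Behavior sequence** — alternating bouts; geometric durations
   (memoryless, chosen for minimal assumptions since no bout statistics
   are available to fit) with per-behavior means; bout categories drawn
   with probability proportional to `behavior_mix / bout_mean`, which
   makes the long-run *frame* fraction of each category equal
   `behavior_mix` whatever the bout means are. The default mix is the
   manual time budget of a 12-h captive-orangutan session — 3.6%
   Locomotion, 13.9% Inactive, 15.6% Covered Inactive, 18.1%
   Foraging/Feeding, 7.5% Other, 41.3% out of view. Default bout means
   (20/90/120/45/20/120 s) are plausible zoo-primate values chosen once;
   nothing downstream is sensitive to them except the variance of
   realized mixes in short sessions.
2. **Trajectory** — the subject's position persists across bouts. During
   Locomotion the box moves at `locomotion_speed` px/frame (default 15)
   in a per-bout random direction and *bounces* off the arena bounds —
   position and velocity both reflect, since a folded position with
   unchanged velocity would oscillate against the wall within a pixel and
   fake a plateau. Stationary behaviors hold a fixed anchor with
   per-frame Gaussian jitter (`stationary_jitter_sd`, default 1 px).
   Inactive bouts may be planted with an arms-up or lying-down posture,
   reshaping the box to `armsup_ratio` (2.5) or `lying_ratio` (0.4).
3. **Detector** — each in-view frame is detected with
   `detect_prob[true behavior]`; the emitted label comes from a
   row-stochastic confusion matrix whose default sends stationary
   behaviors to Locomotion 10% of the time; confidences are truncated
   normals per correct/incorrect stratum (0.93 ± 0.04 / 0.89 ± 0.05).

Label confusion is drawn **once per bout** by default
(`mislabel_mode = "bout"`): the failure being modeled is background-driven
— the detector keys on scene content that persists for as long as the
animal stays put — so a mislabeled stationary bout yields a whole plateau,
which is exactly the artifact the filter removes. Per-frame marginal
mislabel probabilities equal the matrix entries in both modes;
`mislabel_mode = "frame"` gives independent draws (and binomial planted-FP
counts) for tests that need them. Frames whose true behavior is stationary
but whose emitted label is Locomotion are recorded as the planted
false-positive set, the ground truth for filter evaluation.

What the generator does **not** emulate: appearance (no images are
rendered, so nothing about a real detector's feature space carries over),
observer error in manual coding (the manual coding is the ground truth
itself, because manual coding is treated as the reference method),
multi-animal scenes, camera motion, and diurnal structure in the bout
process. Passing the recovery tests therefore shows the *pipeline logic*
is sound — plateaus are found, splits conserved, postures recovered — not
that any particular detector reaches a given accuracy on real footage.

## Problem sizes and numerical choices

The test suite and the acceptance script use sessions of 4,348 frames (a
one-tenth-scale stand-in for a 12-h, ~1 frame/s session) for end-to-end
filter evaluation, pooled over 10 seeded replicates; mix-calibration
checks run the bout process alone at the full 43,483 frames with short
(8 s) bouts so the realized mix estimates the target within ±2 percentage
points; the plateau scanner is verified against the exhaustive oracle on
series of up to 200 entries. Filter sensitivity and specificity are pooled
over replicates (total recovered / total planted) rather than averaged,
since a short session can legitimately contain no planted false positive.
Degenerate inputs are first-class: empty tracks flow through every stage
(100% unlabeled budget, empty plateau report, empty posture series), and a
session with zero Locomotion yields an empty coordinate series rather than
an error.

## Known limitations

* The plateau filter assumes the false-positive mechanism is *temporal
  persistence of a stationary box*. Isolated single-frame mislabelings do
  not form plateaus and are invisible to it — by design, since at 1
  frame/s an isolated stationary-looking Locomotion frame is not
  distinguishable from a brief genuine movement.
* With `require_both_axes_still = TRUE`, locomotion directly toward or
  away from the camera (changing box size but not bottom-corner position)
  could in principle be flagged; the box-area signal is not currently
  used.
* The ratio posture rule is a coarse proxy: it cannot separate postures
  with similar box shapes, and its limits are camera- and
  subject-specific.
* Budgets treat frames as exchangeable; no inferential statistics are
  attached to budget differences, because frame-level autocorrelation
  (bouts) would invalidate naive tests. The comparison reports
  differences, not p-values.
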