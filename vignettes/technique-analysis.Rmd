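---
title: "Detecting climbing-technique errors from 3-D skeleton streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting climbing-technique errors from 3-D skeleton streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climbtech)
```

## The problem

Bouldering technique is taught by watching: an experienced partner points
out that the climber bent the holding arm while setting the feet, let a
foot dangle during a stand-up, or kept the hips too far from the wall.
`climbtech` automates this feedback from video-derived skeleton keypoints.
Its input is a fixed-rate stream of 13 body joints in 3-D (millimetres):
wrists `J7`/`J4`, elbows `J6`/`J3`, shoulders `J5`/`J2`, hip centre `J8`,
hips `J12`/`J9`, knees `J13`/`J10`, and ankles `J14`/`J11` (left/right).
The package takes no position on how the keypoints were produced; any
human-pose-estimation stack that yields these joints at a stable frame
rate (60 fps by default) will do.

The analysis rests on the observation that a boulder is climbed in a
repeating cycle of three phases:

* **preparation** — hands fixed, the feet are placed on the lower holds;
* **reaching** — feet fixed, the climber stands up and one hand reaches
  the next hold while the hips rise;
* **stabilization** — everything still, the body settles and the new
  holding arm stretches.

A joint arrangement that is an error in one phase is perfectly fine in
another, so every rule below is *gated* to its phase.

## Wall-anchored coordinates

All geometry is computed in a coordinate system fixed to the climbing
wall, which makes recordings from different camera positions comparable.
The wall is modelled as a rectangle with an optional tilt. From a point
cloud of the empty scene:

1. `fit_wall_plane()` finds the dominant plane by seeded RANSAC
   (500 hypotheses, 20 mm inlier tolerance by default) with a final total
   least-squares refinement; the normal is oriented toward the camera.
2. `extract_wall_rectangle()` projects the inliers into the plane and
   takes the minimum-area enclosing rectangle of their convex hull
   (rotating calipers).
3. `build_wall_model()` assembles the rigid transform: origin at the
   upper-left rectangle corner, x along the top edge, y pointing *up* the
   wall, z along the normal toward the climber. Wall-interior points thus
   have y in `[-height, 0]`, and "lowest point" is literally the minimum
   of y.

The rotation that aligns the camera z-axis with a plane normal is also
exported on its own (`rotation_from_normal()`, the symmetric-bisector
form of Rodrigues' formula); it is singular for a normal antiparallel to
z, so the model construction instead derives its axes from the rectangle
itself, which is equivalent up to the in-plane rotation that the
rectangle fixes anyway. For tilted walls the "upper-left" corner is
disambiguated in a gravity-aligned in-plane frame (camera y is taken as
up); the convention only has to be applied consistently for recordings to
be comparable.

## Motion segmentation

Phase transitions are driven by which joints move. Per joint,
`joint_speed()` projects the trajectory into the wall x-y plane (a
climber jittering in depth should not look like they are moving),
differentiates with a centered difference, and smooths with a 9-frame
moving average. `segment_motion()` then builds the envelope

$$ g(f) = \mathrm{rollmean}(v, w) + n\,\mathrm{rollsd}(v, w), $$

a rolling-window version of the standard score `zscore_series()`
computes globally, and marks as *moving* all frames where `g` reaches
half of its global maximum. Maximal runs shorter than `k_mu = 30` frames
are discarded as jitter.

Two numerical choices matter here:

* **Rolling window `window = 15` frames (0.25 s).** The window sets how
  far the envelope of a speed pulse spreads beyond the pulse: the
  half-maximum crossing sits roughly `0.37 * window` outside each true
  edge. It also sets the footprint of a short spike: an `s`-frame spike
  produces an above-threshold run of about `window + s` frames. For the
  30-frame minimum-movement rule to actually absorb the 5-frame spikes
  that keypoint jitter produces, the window must stay below roughly 25
  frames; 15 keeps spike runs near 16 frames (comfortably discarded)
  while real movements, lasting 35+ frames, survive. Larger windows give
  smoother envelopes but silently disable spike suppression.
* **Population standard deviation** everywhere, so results are exactly
  reproducible; at these series lengths the sample/population difference
  is far below any threshold.

The global-maximum threshold means one very fast movement can mask a much
slower one; `segment_motion()` warns when detected segments' peak speeds
differ by more than 4x, and `rho` is configurable.

`delimit_route()` trims the recording to the actual climb: the route
starts at the first frame of the first half where the hip centre is
lowest and ends at the last frame of the second half where either wrist
attains its maximum height, so the jump-off or down-climb is excluded.

## The phase state machine

`segment_phases()` classifies each route frame with transition priority:
a moving foot always means preparation; otherwise hip-vertical or hand
motion with both feet static means reaching; otherwise static hands mean
stabilization. The machine starts in stabilization (a climber hangs
static at the start hold — the start state is not observable, so the
resting state is the only defensible default), and runs shorter than
`min_phase_frames = 5` are absorbed into their predecessor to remove
boundary flicker. Because the three per-phase frame-set definitions can
overlap (feet and hands moving at once), the priority order is what makes
the classification a function; foot motion wins because foot placement is
what initiates a new cycle.

## Hand roles and the six error rules

The *holding* hand is the higher wrist (it bears the weight); the other
is the *supporting* hand (`assign_hands()`, ties sticky to the previous
assignment). The detectors, with defaults from the published validation
thresholds:

| rule | phase | condition flagged | default |
|---|---|---|---|
| decoupling | preparation | holding-arm elbow angle < `k_phi` or shoulder angle < `k_theta` | 130 / 120 deg |
| reaching hand supports | reaching | supporting hand in motion longer than `k_t` | 1 s |
| weight shift | reaching | knee never `k_dknee` past the supporting-side foot (middle half of the phase) | 200 mm |
| both feet set | reaching | a foot in motion or further than `eps_contact` from the wall | 150 mm |
| hip close to wall | reaching | hip z exceeds the DTW-coupled reference climb's hip z by `k_dhip` | 50 mm |
| shoulder relaxing | stabilization | same angle rule as decoupling, on the new holding arm | 130 / 120 deg |

Notes on the judgment calls:

* The elbow angle is the interior angle wrist-elbow-shoulder; the
  shoulder angle is elbow-shoulder-hip, both on the holding arm.
  Angle-based events shorter than `min_event_frames = 5` are treated as
  jitter and dropped.
* The feet never touch the wall *plane* — they stand on protruding holds
  — so "on the wall" is operationalised as z within `eps_contact`
  (150 mm, roughly hold depth plus shoe).
* The knee-pass distance is computed knee-minus-ankle on the
  supporting-side leg, signed toward the direction the hip travels within
  the phase, so "passing in front" is positive for either leg and either
  travel direction. The supporting hand flips mid-reach when the reaching
  hand overtakes the other wrist, so the leg is chosen by the majority
  assignment over the phase.
* The hip rule needs a reference climb of the same route. The two climbs
  are aligned by dynamic time warping (`dtw_align()`, absolute difference
  on the scalar hip-to-origin distance in the wall plane, no warping
  band) and the comparison is one-sided: being closer to the wall than
  the reference is never an error. Where the warp couples several
  reference frames to one query frame, the smallest reference distance is
  used — the most pessimistic comparison. Without a reference the rule is
  reported "not evaluated". A warning is raised when the two climbers'
  torso lengths differ by more than 10%, since a fixed 50 mm margin does
  not transfer across body sizes.

Counting is per phase instance: three decoupling events inside one
preparation still count as one error for that phase.

## Evaluation harness

Detections are scored against labelled error intervals with the 1-D
intersection-over-union of frame sets. `match_detections()` matches
greedily one-to-one by descending IoU; a matched pair above the threshold
is a true positive, a matched pair below it leaves the label as a false
negative *without* counting the detection as a false positive (false
positives are reserved for detections overlapping nothing — this differs
from object-detection practice and is deliberate). `pr_curve()` sweeps 20
thresholds over (0, 1] and marks the max-F1 point as the optimal
operating point, ties toward the stricter threshold; the full curve is
returned so any other operating-point rule can be recomputed. TP+FN
always equals the label count.

## The synthetic rig

No recordings ship with the package; `generate_climb()` scripts them.
A script defines wall geometry (default 3 x 4 m, 8 deg tilt, camera
2.8 m away), a lead-in hang, and per cycle: a 40-frame foot placement
(both feet, 300 mm up and 250 mm across), a 55-frame hip rise (300 mm)
whose first 36 frames carry a 600 mm hand reach, and a 120-frame
stabilization — at 60 fps, peak hand speed about 1.5 m/s, matching
the speed scale of real recordings. Hands alternate; the reaching hand
starts 300 mm below the other and ends 300 mm above it, so the
supporting role changes owner mid-reach exactly as in a real climb.

Clean scripts satisfy every rule with margin (holding arm 172 deg, feet
within 95 mm of the wall, knee passed 300 mm, supporting-hand motion
about 0.4 s, hip at constant wall distance). Each injection violates
exactly one rule inside a recorded window: a 110-deg holding arm during
one preparation or stabilization, a 70-frame near-constant-speed circling
of the supporting hand on its hold, a knee stalled at 100 mm, a foot
raised to 300 mm, the hip pushed 100 mm out. Noise is additive Gaussian
jitter on every coordinate (5 mm in the noisy suite) plus occasional
isolated 5-frame, 60 mm spike artifacts mimicking keypoint-tracker
glitches. Geometry is identical across seeds; only noise changes.
`generate_wall_cloud()` samples the wall on a regular lattice (as a
sensor depth grid does), with normal-direction noise and clutter points
floating in front of the wall.

What the rig does *not* emulate: occlusions (the dominant error source
for real keypoint trackers, and systematically worse for feet and the
stabilization-phase arm), depth-dependent noise, limb-length consistency
(joints are scripted directly), camera motion, and idiosyncratic
movement styles. Passing the synthetic suite therefore demonstrates that
the rules, gates, alignment and scoring are implemented correctly and are
robust to frame-level jitter — not that the system reaches any particular
accuracy on real recordings.

Joint positions are scripted directly rather than driven by an
articulated model; bone lengths are only approximately constant. The
detectors never measure bone lengths, so this does not affect what the
tests exercise, and it keeps every injected violation exactly
parameterisable.

## Problem sizes and determinism

The test-suite and acceptance runs use three-cycle routes of roughly
700-800 frames (12-13 s of video), 20 calibration clouds of ~2000 points,
200 short series for the exhaustive DTW cross-check, and a noisy suite of
14 climbs; these sizes make every property measurable while keeping a
full run in well under a minute. All randomness (RANSAC, jitter, spikes)
flows from explicit integer seeds, and a pipeline rerun with the same
config writes byte-identical JSON reports.

## Known limitations

* The global envelope maximum makes motion detection scale-dependent
  within one recording (fast move masks slow move); a per-segment or
  rolling maximum would be the natural extension.
* The fixed hip-distance margin does not transfer across body sizes; the
  package warns but does not normalise.
* Route delimitation assumes one ascent per recording.
* Frames where the two wrists are at exactly equal height make the
  holding-hand role briefly ambiguous; the sticky tie-break keeps the
  assignment stable but one-frame role flips near crossings are inherent
  to the height rule.
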