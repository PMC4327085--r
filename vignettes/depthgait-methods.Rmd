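---
title: "Anthropometric side-view joint tracking from depth frames: models, parameters and design choices"
author: "depthgait maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anthropometric side-view joint tracking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depthgait)
```

## The problem

Clinical gait screening with the Get Up and Go Test (rise from an armless
chair, walk a few metres) is scored by eye, so the score depends on the
rater.  A depth camera watching the subject **from the side** can in
principle make the score objective, but the skeleton trackers bundled with
consumer depth sensors are trained for frontal poses and become unreliable
in side view.  `depthgait` tracks six side-view joints (head, shoulder,
elbow, hip, knee, ankle) using nothing but background subtraction,
silhouette geometry and fixed anthropometric ratios, so it runs in real
time on modest hardware and needs no training data.

Everything operates in the **depth-frame pixel domain**: a frame is a
240 × 320 integer matrix of distances in mm (0 = no reading, row 1 = top of
image).  Joint positions are (row, column) pixel pairs; accuracy is
quantified in pixels against a reference track.

## Pipeline and model

### Background and silhouette

The empty scene (wall at ~3.3 m, sensor 0.92 m above the floor, the chair
the only object) is averaged over ~100 frames into a background frame *BF*;
0-readings are excluded per pixel, and the mean is rounded to integer mm
(whether the original system rounded or truncated is unstated; rounding is
the package's choice).  A pixel of a live frame *DF* is foreground when

$$|DF(x,y) - BF(x,y)| \ge Th, \qquad Th = 150\ \textrm{mm},$$

with the strict complement (`< Th`) mapped to background, so a difference of
exactly 150 mm is foreground.  The threshold is deliberately low: feet sit
only slightly in front of the floor behind them.  Pixels with no reading in
*DF* are never foreground — otherwise sensor dropout would masquerade as
subject.  The subject is the largest connected component of the mask.
**8-connectivity** is used (a design choice: diagonal chains of limb pixels
must not sever the silhouette); size ties go to the component whose first
pixel comes earliest in row-major order, which the C++ labelling kernel
guarantees by construction.  Residual chair noise after an accidental chair
shift is handled only by largest-component selection, mirroring the original
procedure.

### Metric-to-pixel conversion

All body-scale constants are stated in mm and converted through the pinhole
relation `px = round(L · f / Z)` with half-up rounding.  The depth `Z` used
is the **median depth of the silhouette pixels of the current frame** — a
single subject-plane depth rather than per-pixel depths, because these
shifts are body-scale quantities and a plane depth is stable under noise
(the conversion's required depth is otherwise unspecified).  Default
intrinsics are the canonical structured-light values scaled to 320 × 240
(f = 285.6 px, centre (159.5, 119.75), 0-based); a real deployment should
override them from device calibration, which the original authors cite but
do not print.

### Front-pose calibration

One frame of the subject facing the sensor at ≈3 m, arms outstretched
downward-outward, yields the per-subject body model:

* **Shoulder-top row**: starting 100 mm below the silhouette top, rows are
  sampled every 40 mm (a step sized to catch the neck-to-shoulder
  widening), counting silhouette columns per sampled row, until the scanned
  span reaches one third of the silhouette height (measured from the scan
  start — the stop rule's two textual statements conflict; the explicit
  formula was followed).  The sampled row with the maximal width increase
  over its predecessor is the shoulder top; ties, including the all-flat
  case, go to the topmost sampled row.
* **Head**: one third of the way from the silhouette top to the shoulder-top
  row (integer division, as stated); column = midpoint of the first/last
  silhouette columns on that row.
* **Head height** = (shoulder-top row − top row) − 100 mm of neck.  The
  100-mm subtraction direction is ambiguous in image coordinates; it is
  implemented as scanning *down* from the head top, since the scan must
  cross the neck to see the widening.
* **Hip row** = head top + `round(c × head height)`, where `c` comes from a
  six-branch piecewise-constant lookup on `R = stature / head height`,
  calibrated on printed anthropometric survey rows (`table1_ratio()`,
  `table1_coefficient()`, `anthropometric_table()`).  Branch edges are
  left-closed above (R = 6.4 → 3.4, R = 8.8 → 4.2), the reading implied by
  the printed inequalities.  At run time `R` is computed **in pixels**
  (silhouette height / head height); the survey version works in cm — both
  exist and are tested separately.
* **Ankle/knee**: ankle 40 mm above the silhouette bottom; ankle–knee
  distance = `round(0.2 × silhouette height)`; columns are silhouette
  column means.
* **Arm chain**: on the hip row a column gap separates the outstretched arm
  from the torso ("left" side = frame-left by default; `arm_side` flips it
  for mirrored rooms).  The lowest row of the beyond-gap sub-region is the
  end of the hand; the wrist sits half a head height above it; the elbow is
  the shoulder–wrist midpoint.  The hip *column* (needed to measure the
  knee–hip distance) is the centre of the largest contiguous column run on
  the hip row, which excludes both arms — a detail the source leaves open.

The five calibrated distances HS, SE, EW, KH are stored at full (sub-pixel)
precision — rounding them to integers measurably degrades segment recovery —
while AK is an integer because it is used directly as a row shift.

An important and non-obvious property: the `c`-lookup *compensates*
head-height estimation error.  The 40-mm scan grid can overshoot the true
shoulder row by up to one step, inflating the head height by up to ~20%;
but the inflated head height deflates `R`, which selects a smaller `c`, and
the product `c × head height` (the hip offset) stays nearly constant.  The
compensation fails only when `R` leaves the table's calibrated range
(< 6.4 or ≥ 8.8), where the lookup saturates — which is why head-height
*underestimates* (rowMaxDim above the true shoulder) are the dangerous
direction.  Realistic silhouettes, whose width jumps sharply at the
shoulder line, bias the scan the safe way.

### Side-view tracking

Each frame is processed independently — no temporal smoothing, explicitly
out of scope for the core tracker (`interpolate_trajectory()` exists for
plotting only).

* **Head**: the calibrated head shift below the first silhouette row;
  column = mean of silhouette columns there.
* **Near-side region**: half an ankle–knee distance above the lowest
  silhouette row, the column of minimal depth seeds a square window of side
  AK.  Window pixels deviating more than 80 mm from the central pixel are
  discarded; the survivors' mean depth is the reference, and the region is
  every silhouette pixel within 80 mm of it.  This selects the limbs
  nearest the sensor and drops the far leg/arm.  Robustness addition: when
  the central pixel itself is an outlier (fewer than 25% of the window's
  silhouette pixels survive), the reference is re-centred on the window
  median — without this a single noise spike at the seed hijacks the
  region.
* **Shoulder / knee re-projection**: a provisional estimate (HS rows below
  the head / AK rows above the ankle, column from the silhouette or region)
  fixes only the *direction*; the final joint is placed exactly HS (resp.
  AK) pixels from its anchor along that direction.  This keeps the segment
  lengths rigid while the trunk leans during stand-up, and makes the
  tracked head–shoulder and ankle–knee distances equal the calibrated ones
  to ±1 px (rounding) in every frame — a property the test suite asserts.
* **Rotating vectors (elbow, hip)**: a segment of calibrated length (SE
  from the shoulder; KH from the knee) is rasterized at each candidate
  angle and the angle with maximal overlap with the limb mask wins; ties go
  to the smallest angle.  The angle conventions are only drawn, not
  defined, in the source, so the package fixes them: **θ (elbow)** is
  measured from the image-horizontal axis and sweeps the lower half-plane,
  θ ∈ {2°, 4°, …, 178°}, so θ = 90° is straight down; **γ (hip)** likewise
  from the horizontal but over the upper half-plane, γ ∈ {4°, 6°, …, 176°}
  (the stated 4° start and 2° step), so γ = 90° is straight up.  This
  covers seated (near-horizontal thigh) and upright (vertical thigh)
  configurations regardless of walking direction.  The elbow's arm
  sub-region is extracted with the same windowed 80-mm rule, in a window of
  side SE centred SE/2 rows below the shoulder at the shoulder column; if
  fewer than 10 pixels survive the joint is reported missing rather than
  fitted (degenerate-occlusion guard; the source is silent).
* **Rasterization**: a rounded-DDA integer line — endpoints rounded to the
  pixel grid, one step per major-axis pixel — which is 8-connected,
  endpoint-inclusive and deterministic.  Rounding endpoints *before*
  stepping matters: it makes all sweep angles rasterize the same pixel
  count, so overlap ties are genuine ties.

Any locator failure (empty row, degenerate region) marks that joint missing
for that frame; a frame with no silhouette is missing entirely.  Missing
frames propagate to the validation stage, which excludes them from μ/σ —
internally an explicit `NA`, not the 0-distance sentinel some logs use
(0 is a legal distance); trajectory CSVs write `row = col = 0` plus a
`missing` flag column for fidelity with that convention.

### Validation

`D_i,k` is the Euclidean pixel distance between estimated and reference
positions of joint *i* in frame *k*.  Before summarizing, the constant 2-D
offset per joint minimizing the sum of squared differences over jointly
observed frames — i.e. the mean coordinate difference — is subtracted
(`compensate_offset()`), matching the original evaluation protocol; the
per-joint mean μ and standard deviation σ are computed over non-missing
frames only.  σ is the **sample** (n−1) standard deviation; the source does
not say which it used, and at n = 120 the difference is negligible.
`detect_markers()` is a deliberately simple stand-in for the infrared
marker-based reference tracker (threshold, label, centroid, assign by
vertical order): it exists so marker-style validation can be exercised on
synthetic imagery, not as a reconstruction of the original reference
system.

## The synthetic world

The generator emulates the reference recording room: wall 3300 mm from the
sensor, sensor 920 mm above the floor, armless chair 300 mm in front of the
wall, 320 × 240 frames at 30 fps.  The subject is a **2.5-D capsule
figure**: each body segment a constant-depth capsule projected through the
pinhole model, with near-side limbs 85 mm nearer the sensor than the trunk
surface and far-side limbs 35 mm deeper (120 mm near-to-far, within the
80–150 mm range a side-on human presents).  Flat per-segment depth is a
stated simplification — the tracker consumes only silhouettes and coarse
80-mm depth gaps, so a lateral depth gradient would change nothing it
measures while making the ground truth fuzzier.

Figure proportions follow the same survey the hip lookup was calibrated on
(default: the "ITALIAN MILITARY-1961" row): head = stature/7.64, hip
861 mm up for a 1700-mm figure, shank = 0.2 × stature, standard arm
ratios, glenohumeral centre 60 mm below the acromion apex.  The hand is a
100-mm capsule — a relaxed half-open hand without finger geometry; this
matters because the wrist heuristic measures half a head height up from the
arm's end, so a fully splayed 18-cm hand would bias the wrist (and with it
EW) on any tracker of this family.  The default noise model is additive
Gaussian σ = 10 mm plus 0.5% dropout to 0; real structured-light noise is
depth-dependent and quantized, so the flat σ is a stated approximation.

The simulated test: 25% of frames seated (arms hanging at the side — the
natural ready posture given the figure's arm lengths), 20% rising (trunk
lean peaking ~28°, pelvis translating up and forward over the feet), then
walking across the frame at 0.7 m/s with 0.9 Hz sinusoidal thigh swing,
knee flexion and anti-phase arm swing, all **at the chair line ≈3 m from
the sensor**.  The walking depth matters: the calibrated pixel distances
are fixed at front-pose depth, so a subject walking substantially nearer or
farther breaks the fixed-length vectors by the depth ratio — a real
limitation of the method, visible in the package if you move
`side_pose(body_depth = …)` away from 3 m.  Sitting on the chair *at the
chair's depth* also reproduces the documented chair-mismatch artefact:
pixels where the subject overlaps the chair within 150 mm silently vanish
from the silhouette, and the tracker must tolerate the resulting bites.

What a green test does — and does not — establish: the synthetic world has
exact ground truth, no clothing, no self-occlusion beyond capsule
ordering, no depth-dependent noise, and one figure shape per run.  Passing
means the chain of geometric rules is implemented consistently and is
robust to the stated noise; it does not certify accuracy on real sensor
recordings, which are not available.

## Numerical choices and degenerate inputs

* All mm→px conversions round half-up; `shift_row` uses integer division
  ("divided by three", as printed); survey ratios are reported to 2
  decimals half-up.
* Ties: topmost sampled row (width scan), smallest angle (rotating fits),
  first-in-row-major component (labelling).
* Degenerate rows (empty head/shoulder/ankle rows, no arm gap, all-discard
  windows) raise typed errors during calibration and become missing
  markers during tracking.
* The whole pipeline is deterministic given the seed; the only randomness
  is the noise model.

## Known limitations

* Single subject, side view, fixed room geometry; no multi-person scenes.
* The hip is the least accurate joint — the `c`-lookup is coarse (six
  levels) and the knee–hip vector quantizes to 2° — consistent with the
  published behaviour of this tracker family.
* No temporal model: a frame's failure is not bridged by its neighbours.
* Calibrated pixel distances assume tracking near the calibration depth.
* `pgm16-stack` and headered `raw` are the only frame dialects; 16-bit PNG
  was dropped because no capable reader/writer is available in the
  supported dependency set.
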