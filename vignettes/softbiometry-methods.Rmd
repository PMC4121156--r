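---
title: "Estimating height and weight of walking subjects: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating height and weight of walking subjects: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(softbiometry)
```

## The problem

In indoor surveillance footage a face is often too small or too oblique to
support recognition, but the whole body remains visible. Two coarse
("soft") biometric traits can then be measured from single-view video:
upright **height**, via projective geometry anchored on one known reference
length, and **body weight**, regressed from silhouette measurements. Neither
trait identifies a person uniquely; together they can pre-filter a gallery
or re-identify subjects across sessions. This package implements that
pipeline for low-frame-rate footage (frames retained at about 1 fps, so the
stride changes drastically between consecutive frames), together with a
ground-truthed synthetic scene generator used for all evaluation.

## Silhouette extraction

For each frame the object is separated from a per-sequence empty background
frame in four steps.

1. **Squared RGB differencing.** `D = sum over bands (bg - frame)^2`,
   a nonnegative, symmetric per-pixel difference.
2. **Suppressed Otsu thresholding.** `D` is linearly rescaled onto
   `[0, 255]` (anchored at zero, so `D > 0` maps to `q > 0`) and Otsu's
   between-class-variance criterion picks `T_thres`. The raw mask is
   `q > T_thres / c` with a suppression factor `c > 1` (default 2). Plain
   Otsu is too strict on dim regions — typically the legs — so dividing the
   threshold deliberately loosens the cut; the price is that cast shadows
   enter the mask, which the next step removes. Increasing `c` can only add
   pixels (monotonicity), and ties in the Otsu maximizer resolve to the
   smallest level so the stage is deterministic.
3. **Shadow removal.** For every masked pixel a combined brightness and
   chromaticity difference is computed,
   `B_D = |log(I_b / I_f)| + D_FB`, where `I` is the mean of R, G, B
   (plus one intensity level, so black pixels never produce infinities) and
   `D_FB` is the Euclidean distance between normalized-GB chromaticity
   coordinates of the frame and background. A cast shadow scales all three
   channels by an attenuation `a`, leaving chromaticity intact:
   its `B_D` is about `-log(a)`. True body pixels differ in chromaticity
   (and usually in brightness), so their `B_D` is larger. Masked pixels with
   `B_D < T` are treated as lighting changes and removed; the operation is
   purely subtractive.
4. **Cleanup.** Morphological opening (disc radius 1) and removal of
   connected components below 0.01% of the image area.

### Choosing `T`

`T` must satisfy `-log(a) < T < min(B_D of body pixels)`. The generator's
default shadow attenuation is 0.6 (`-log(0.6) = 0.51`) and its body surfaces
are strongly chromatic (`B_D` at least 0.67 under the default colour
scheme), so the package default is `T = 0.6`. A much smaller `T`
(e.g. 0.15) only removes near-invisible shadows with attenuation above
`exp(-0.15) = 0.86`; with deep shadows it leaves the shadow attached to the
feet and biases the ROI. Both `c` and `T` are exposed in the configuration;
the values here are empirical defaults for the synthetic scenes, exactly as
they would be tuned per site on real footage.

## Height by single-view metrology

With a level camera, the image of the ground plane's line at infinity is the
horizon row `Y`. For a subject standing on the ground with top and bottom
image rows `X_T`, `X_B`, the cross-ratio between the two parallel planes
(ground and camera height `H_c`) collapses to

```
O_H = H_c * |X_T - X_B| / V,    V = X_B - Y.
```

The camera height is the only reference length. The horizon row comes from
configuration, or from `calibrate_horizon()`, which inverts the equation for
reference observations of known height and averages.

Error behaviour: the formula is exact for exact inputs (the generator's
fractional ground-truth extremes invert to the true stature to machine
precision). A rasterized silhouette quantizes both rows to integers, each
within half a pixel, giving a per-frame error below `H_c * (1 px / V)` —
about 1.2 cm at the default geometry (`H_c = 120` cm, `V ≈ 103` px). An
additional 1-px error on the head-boundary row (the edge segmentation
actually gets wrong; the feet–ground contact anchors `X_B`) contributes at
most `H_c / V` per frame with zero mean, so the per-subject mean absolute
error over a 14-frame sequence stays below the same bound: writing the
constant rasterization error as `e0`, the expected MAE under symmetric
unit jitter is `(2/3) * H_c/V + |e0| / 3 < H_c/V`. This is why low frame
rate is tolerable for height: single-frame errors average out across the
sequence.

## The 13-feature body measurement vector

The silhouette is segmented into head, torso and leg regions from the
horizontal projection `P_H(j)` (per-row foreground count over the ROI
rows): the neck is the minimum of `P_H` within 10–30% of the ROI rows and
the waist the minimum within 35–70%, with ties resolved to the smallest row.
Percentages are taken over ROI rows (top = 0%), since the projection is
meaningless outside the silhouette. From this segmentation:

| #     | feature                | definition |
|-------|------------------------|------------|
| v1    | `O_H`                  | metric height (cm) |
| v2–v4 | `H_feat, T_feat, L_feat` | region pixel densities: foreground count / region row length |
| v5    | `W_feat`               | silhouette area / ROI pixel height |
| v6–v8 | `R_H, R_T, R_L`        | weighted ratios, e.g. `R_H = H_feat^2 / (T_feat + L_feat)` |
| v9–v11| `L_H, L_T, L_L`        | metric region lengths (cm) via the `H_c/V` scale |
| v12   | `W_H`                  | head width: max per-row count of the largest connected component in the middle third of the head rows |
| v13   | `W_S`                  | shoulder width: same statistic in the first 10% of the torso rows |

The metric lengths follow the printed cumulative convention
`L_L = (H_c/V) L_LP`, `L_T = (H_c/V)(L_TP + L_LP)`,
`L_H = (H_c/V)(|X_T - X_B| - (L_TP + L_LP))`; `L_T` therefore spans torso
*plus* legs, and `L_H + L_T = O_H` holds as an algebraic identity. We keep
the convention verbatim (and test the identity) rather than "correcting"
it: the regressor is indifferent to the reparametrization.

Features are min–max normalized to `[0, 1]` with parameters fitted on the
training session only; test-time values are clipped to `[0, 1]`, and a
constant training feature maps to 0.

## Weight regression

A single-hidden-layer feedforward network (logistic sigmoid hidden layer,
linear output) maps the normalized 13-vector to weight in kg. Training is
Levenberg–Marquardt on the sum of squared errors of a random 70% split,
with an explicit Jacobian of the `13 -> h -> 1` network; the damping starts
at `1e-3`, is divided by 10 on an accepted step and multiplied by 10 on a
rejected one. Training stops at the first of

1. convergence — gradient max-norm below `1e-7`, relative loss change below
   `1e-9`, or no acceptable damped step;
2. validation error increasing for 6 consecutive epochs;
3. 100 epochs.

The returned model carries the weights of the best validation epoch and a
per-epoch log recording which rule fired, so the interaction between rule 1
and the validation split is auditable. Weights initialize uniformly in
`[-0.5, 0.5]` scaled by `1/sqrt(fan-in)`, and every source of randomness
(split, initialization) is controlled by one seed; identical seeds
reproduce weights bit-identically. The hidden-node count is selected by a
sweep (the full protocol is 1–40 nodes, 10 seeded runs each, averaging MAE
per node; the test suite uses the reduced grid `{1, 5, 10, 20, 27} x 3`
runs to keep runtimes in seconds while spanning the under- to
over-parameterized range).

Two evaluation protocols are implemented: training on session 1 and testing
on a later session of the same subjects (the main protocol; appearance may
change between sessions), and a repeated random equal-half frame split
(generalization to frames unseen in training; the reference protocol runs
100 repeats, the acceptance study 20).

## Identification

Per subject, the enrolled descriptor is (mean estimated height, mean
predicted weight) over the session-1 frames; probes aggregate session-2
frames the same way. Matching is nearest-neighbour under Euclidean distance
after z-score normalization of each trait on the gallery, with ties broken
by gallery order. The matcher behind the original study is not described in
the source literature, so this standard construction is the declared
stand-in; reported rank rates are therefore indicative, not comparable
figure-for-figure. The cumulative match characteristic (rate of finding the
true identity within rank k) is non-decreasing and reaches 1 at the gallery
size by construction.

## The synthetic scene generator

No dataset with ground-truthed height, weight, silhouettes and camera
geometry is publicly available, so the package renders its own:

* **Camera**: pinhole, level (zero pitch and roll, horizon = principal
  row), 120 cm above the ground, subject plane at 700 cm — the reference
  acquisition geometry. The default image is 360 x 270 (the reference
  1440 x 1080 scaled down by 4; all geometry is linear in scale) with a
  600 px focal length, placing a 197 cm subject comfortably in view.
* **Humanoid**: a stack of axis-aligned primitives — head ellipse tapering
  into a strictly decreasing neck, shouldered torso narrowing into a waist,
  and two legs whose spread varies sinusoidally with the stride phase.
  Between retained frames the phase advances by a large incommensurate step,
  emulating 1 fps decimation of a 50 fps walk; the subject also translates
  laterally across the view. The neck and waist are genuine minima of the
  horizontal projection by construction, so the segmentation contract is
  testable (boundaries recovered within 2 rows).
* **Ground truth**: the exact (fractional) projected extreme rows, the
  silhouette mask, and the shadow region are stored per frame.
* **Appearance confounders**: a backpack (attached ellipse on the torso
  back) and loose clothes (horizontal dilation of the torso/leg silhouette)
  reproduce the documented failure mode of silhouette-based weight
  estimation — widened silhouettes bias the prediction upward.
* **Shadow and noise**: the cast shadow multiplies all three channels by an
  attenuation (default 0.6), preserving chromaticity exactly — the model
  the removal stage assumes; sensor noise is Gaussian with sd 2 intensity
  levels. Body colours (dark hair, saturated red shirt, saturated blue
  trousers on a mid-grey floor) give body pixels a chromaticity difference
  that keeps `B_D` well above `T` under noise.
* **Mass link**: true weight is `k * height_cm * mean(width_cm)` plus
  Gaussian noise (sd 2 kg), with `k = 0.0165` kg/cm² chosen once so the
  144–197 cm stature envelope crossed with the default width envelope maps
  into 40–119 kg (the corner products give 51–98 kg). This link is an
  artifact convention that makes the 13 features informative about mass;
  recovery results are stated against it, **not** against human physiology.

### What passing tests do and do not show

The generator isolates each stage's claim: projection exactness, shadow
separability, segmentation landmarks, feature formulas, optimizer and
protocol conformance, and end-to-end recovery of a known generative link.
It does not model gait dynamics, limb articulation, photorealistic texture,
outdoor illumination, or the true anthropometric height–weight relation.
Quantities that depend on those — absolute weight error on real people, or
identification rates of a real cohort — are not claims this package's tests
can support; the study's own figures on real footage are the reference for
that.

## Numerical choices and degenerate inputs

* Otsu on a constant image is an error (degenerate histogram), as is an
  empty mask for ROI extraction and a probe identity absent from the
  gallery.
* Brightness and chromaticity use an additive epsilon of one intensity
  level; zero-brightness pixels never crash the shadow stage.
* Argmin ties (Otsu level, projection minima) resolve to the smallest
  index; matcher ties to gallery order — all stages are deterministic.
* A zero-height ROI, a zero-length region, and an all-zero density triple
  are errors rather than NaNs.
* A network with more parameters than samples is rejected with a
  suggestion to reduce the node count.

## Problem sizes used by the bundled study

The acceptance study (`scripts/acceptance.R`) uses 20 subjects x 14 frames
with full RGB extraction for height, an 80-subject x 14-frame cohort for
the weight model with the reduced node grid, 20 random-half repeats for the
unknown-subject protocol, and an 80-entry gallery for identification.
These sizes mirror the reference cohort (80 subjects, 1120 frames) while
keeping the whole study within a few minutes on one CPU; the test suite
uses the same sizes for the recovery claim and smaller ones elsewhere.

## Known limitations

* The horizon row must be configured or calibrated from a reference; there
  is no automatic vanishing-line detection.
* Camera pitch and roll are assumed zero end to end.
* The weight model's accuracy under appearance change is bounded by how
  much of the silhouette change is clothing rather than body — on the
  synthetic confounders the error roughly matches the reported real-world
  degradation, but the correspondence is qualitative.
* All widths are measured fronto-parallel; self-occlusion from arm swing is
  not modelled.
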