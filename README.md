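# softbiometry

Estimation of two body-related soft-biometric traits — upright **height**
and body **weight** — from low-frame-rate video of walking subjects, plus
rank-k **identification** from the combined (height, weight) descriptor.

The package is aimed at indoor visual-surveillance settings where faces are
too small or too oblique for recognition but the full body is visible. It
implements:

* **Silhouette extraction** from an empty-background frame and a current
  frame: squared RGB differencing, Otsu thresholding with a suppression
  factor `c > 1` (loosens the cut to recover dim regions such as legs),
  cast-shadow removal from the combined brightness/chromaticity difference
  `B_D = |log(I_b/I_f)| + D_FB`, and morphological cleanup.
* **Single-view metrology height**: with a level camera at height `H_c`
  above the ground and horizon row `Y`, a subject spanning image rows
  `X_T..X_B` has height `O_H = H_c * |X_T - X_B| / V` with `V = X_B - Y`.
  The camera height is the only reference length; no intrinsic calibration
  is needed.
* **A 13-feature body-measurement vector** per frame: metric height, pixel
  densities and weighted ratios of the head/torso/leg regions (segmented at
  the neck and waist minima of the horizontal projection), silhouette size,
  metric region lengths, and head/shoulder widths.
* **Weight regression** by a single-hidden-layer feedforward network
  (logistic sigmoid hidden layer, linear output) trained with
  Levenberg–Marquardt under three stopping rules (convergence, six
  consecutive validation increases, 100 epochs), with a hidden-node sweep
  and per-subject MAE evaluation.
* **Identification**: z-score-normalized nearest-neighbour matching of
  (height, weight) across sessions and cumulative match characteristic
  (CMC) curves.
* **A ground-truthed synthetic scene generator** — parametric walking
  humanoid under a pinhole camera with cast shadows, sensor noise, and
  appearance confounders (backpack, loose clothes) — so the whole pipeline
  is testable end to end without enrolment data.

## Worked example

Render a 14-frame walk of a 178 cm subject, extract the silhouette of one
frame, and estimate height and features:

```r
library(softbiometry)

cam     <- camera_geometry()                 # H_c = 120 cm, horizon row 135
subject <- body_params("S001", height_cm = 178, mass_kg = 82)
walk    <- render_sequence(subject, cam, n_frames = 14, seed = 42)

frame <- walk$frames[[7]]
mask  <- extract_silhouette(frame$background, frame$frame)
roi   <- extract_roi(mask)
estimate_height(roi, cam)
#> Height estimate: 177.1 cm (V = 103 px)

round(compute_features(mask, cam), 2)
#> o_h_cm h_feat t_feat l_feat w_feat    r_h    r_t    r_l l_h_cm l_t_cm l_l_cm
#> 177.09  10.18  32.19  25.65  25.86   1.79  28.91  15.53  24.47 152.62  90.87
#> w_h_px w_s_px
#>  12.00  38.00
```

The ROI spans rows 86–238; with the horizon at row 135 the metrology scale
is `V = 238 - 135 = 103` px, so the 152-px silhouette maps to 177.1 cm —
0.9 cm below the true stature, i.e. within the 1-px quantization bound
`H_c / V ≈ 1.17` cm. The feature vector shows the mean region widths in
pixels (v2–v4), the metric lengths (v9–v11; `l_t_cm` is cumulative
torso+legs by the printed convention, so `l_h_cm + l_t_cm` equals `o_h_cm`
exactly), and the head/shoulder widths in pixels (v12–v13).

Aggregating the sequence compensates single-frame errors:

```r
heights <- sapply(walk$frames, function(fr) {
  m <- extract_silhouette(fr$background, fr$frame)
  estimate_height(extract_roi(m), cam)$o_h_cm
})
st <- subject_height_stats(heights, 178, "S001")
sprintf("mean %.2f cm, MAE %.2f cm, std %.2f cm over %d frames",
        st$mean_est_cm, st$mae_cm, st$std_cm, st$n_frames)
#> [1] "mean 177.09 cm, MAE 0.91 cm, std 0.00 cm over 14 frames"
```

For the full two-session study — cohort generation, weight-network
training and node sweep, per-subject MAE tables and the CMC curve — see
`session_features()`, `node_sweep()`, `evaluate_mae()`, `cmc_curve()` and
the end-to-end `run_pipeline()`. A thin command-line driver is included:

```sh
Rscript exec/softbody synth --out data --subjects 4 --frames 6 --seed 2
Rscript exec/softbody run   --data data --out results --nodes 1 --seed 3
# height MAE 0.97 cm (std 0.30), weight MAE 0.94 kg (std 0.93), rank-1 100%
```

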