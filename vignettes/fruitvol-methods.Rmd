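---
title: "Methods: calibrated two-view fruit morphometry and the stacked volume model"
author: "fruitvol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrated two-view fruit morphometry and the stacked volume model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitvol)
```

## Overview

`fruitvol` estimates the volume of roughly ellipsoidal fruit from two
calibrated silhouette views. The pipeline has four stages:

1. **Metrology.** Each view contains the fruit and a square fiducial of known
   side length $M_{mm}$ (default 30 mm). The per-frame scale factor
   $\alpha = M_{mm}/M_{px}$ converts the fruit's tight bounding-box extents
   into the four physical dimensions $W_{top}, H_{top}, W_{side}, H_{side}$
   (mm). Each view carries its own marker and its own $\alpha$; scale factors
   are never shared or averaged across views.
2. **Features.** The four dimensions are expanded into 25 physics-aware
   descriptors: the raw dimensions and mean diameter; ellipsoid volume
   proxies $V = \tfrac43\pi abc$ with three choices of the third semi-axis;
   the mean-diameter sphere volume; elliptical cross-section areas;
   Ramanujan ellipse perimeters; the Knud–Thomsen surface area
   ($p = 1.6075$); sphericity $\Psi = \pi^{1/3}(6V)^{2/3}/S$; a
   surface-to-volume ratio; per-view aspect ratios and eccentricities;
   cross-view ratios; and two area–length interaction terms.
3. **Preprocessing.** IQR capping (Tukey fences, $k = 1.5$) of all numeric
   variables including the target, fitted on training rows only; natural log
   of the strictly positive magnitude features; the target modelled as
   $y = \log(1 + \text{volume}_{mL})$ and inverted with $\exp(\hat y) - 1$
   at evaluation time; quantile-stratified $k$-fold splits (default
   $k = 5$ folds, 5 bins).
4. **Model.** Embedded feature selection (gradient-boosted gain importance,
   strictly-above-median rule) followed by a two-layer stack: three
   complementary gradient-boosted base learners produce out-of-fold
   predictions on the training data, and an L1-penalised (Lasso) linear
   meta-learner with non-negative weights combines them. The four raw dimensions and the mean diameter
   carry non-decreasing monotonicity constraints in every base learner.

## Closed-form geometry and its accuracy

The Ramanujan perimeter approximation
$P \approx \pi(A+B)\bigl(1 + 3h/(10 + \sqrt{4-3h})\bigr)$ with
$h = (A-B)^2/(A+B)^2$ is exact for circles and within $2\times10^{-4}$
relative of the complete elliptic integral for axis ratios up to 4 (the test
suite checks 500 random ellipses). The Knud–Thomsen surface area
$S \approx 4\pi\bigl((a^pb^p + a^pc^p + b^pc^p)/3\bigr)^{1/p}$ is exact for
spheres and within 1.2% of a numerical surface integral for axis ratios up
to 3 (200 random ellipsoids). Volumes are carried in mL (mm³/1000), areas in
mm², lengths in mm.

Two pairings the four dimensions leave open were fixed once: sphericity uses
the (averaged ellipsoid volume, Knud–Thomsen surface on $(a, b, c_{avg})$)
pair, and the surface-to-volume ratio divides that same surface by that same
volume. Eccentricity uses the standard ellipse definition
$e = \sqrt{1 - (\text{minor}/\text{major})^2}$.

## The synthetic population

No fruit dataset ships with the package, so a generator produces populations
with a numerical volume oracle. A fruit is a superellipsoid
$|x/a_x|^\varepsilon + |y/a_y|^\varepsilon + |z/a_z|^\varepsilon = 1$
with an optional multiplicative radial lobe
$r \mapsto r\,(1 + A\sin^2\theta\cos(m\phi + \phi_0))$ emulating localised
protrusions. Its volume is computed as
$\tfrac13\oint r^3\,d\Omega$ by Simpson/trapezoid quadrature on a
$181\times360$ angular grid; for lobe-free shapes this agrees with the
closed form $8\,a_xa_ya_z\,\Gamma(1+1/\varepsilon)^3/\Gamma(1+3/\varepsilon)$
to better than $10^{-5}$ relative, and the quadrature stands in for a
destructive water-displacement measurement.

Default population parameters (all overridable in `generator_config()`):

* **n = 150** fruit, all four dimensions inside **50–88 mm** — the
  population the package is designed around.
* **Size**: a base diameter uniform over the range; the two equatorial
  diameters add ±6% uniform anisotropy.
* **Oblateness**: the polar diameter is `flatten` times the base size,
  `flatten ~ U(0.75, 1.05)`, floored so no diameter drops below 50 mm —
  small fruit are therefore necessarily rounder than large ones, as a hard
  population floor implies.
* **Blockiness coupling**: $\varepsilon = 2 + 2.5\,(1-\text{flatten})
  + U(-0.05, 0.05)$, clipped to $[1.5, 3.5]$. Flatter fruit are blockier;
  the small jitter is irreducible shape noise that no two-view measurement
  can recover. The deviation scale was calibrated so that the best
  closed-form ellipsoid proxy explains roughly 92–94% of volume variance on
  default populations, matching the explanatory power such proxies achieve
  on real citrus; without a systematic, observable component the learning
  problem would be trivial for a geometric formula and impossible for
  everything else.
* **Orientation**: the three axis diameters are randomly permuted per fruit.
  Fruit land on a conveyor in arbitrary pose, so the flattened axis is not
  tied to the camera geometry. This matters: if the flat axis always faced
  the top camera, the $c_{avg}$-based proxy's upward bias on oblate fruit
  would almost exactly cancel its blockiness bias, and the proxy would stay
  near-oracle — an artifact, not a property of real scenes. Random
  orientation also creates the orientation-by-shape interactions that the
  cross-view ratio and eccentricity features exist to capture.
* **Measurement noise**: each observed dimension is the silhouette extent
  times $1 + N(0, 0.01)$ — a 1% relative error model for marker-calibrated
  bounding boxes; pixel quantisation applies a per-view scale factor drawn
  from 0.35–0.5 mm/px and rounds.
* **Lobe amplitude** up to 0.04: it perturbs silhouettes and volumes at the
  sub-percent level and acts as additional irreducible noise.

What the generator does **not** emulate: texture, colour, specularity or
any photometric property; camera distortion or perspective (projections are
orthographic); stem/calyx artefacts; segmentation failures; correlated
(per-session) calibration error. Passing tests therefore demonstrate the
pipeline's internal correctness and its behaviour under controlled,
known-truth shape variation — not performance on photographs.

## Numerical and procedural choices

* **Quartiles** use linear interpolation between order statistics
  (`type = 7`), so the worked capping example `[1, 2, 3, 4, 100]` gives
  $q_1 = 2$, $q_3 = 4$, fences $(-1, 7)$.
* **Winsorisation** *is* the IQR capping; there is no second percentile
  clipping layer, avoiding double-clipping ambiguity.
* **Stratified folds** deal shuffled within-bin members round-robin with a
  counter that carries across bins: fold sizes differ by at most one and
  every quantile bin is spread over all folds where counts permit.
* **Grid-search tie-break**: candidates are visited simplest-first (fewer
  trees, then shallower, then lower learning rate), so exact CV-score ties
  resolve to the simpler model. Model selection scores MSE on the log-target
  scale; reported metrics are always on the original mL scale.
* **Feature selection** retains features whose gain importance strictly
  exceeds the median importance of all 25 (never-used features count as
  zero). With distinct importances this keeps at most 12 of 25; ties at the
  median are excluded. Selection is refit inside every training fold.
* **Marker identification** in masks: squareness first
  ($|w-h|/\max(w,h) \le 0.1$), smallest area on ties (fiducials are small
  relative to produce), and a low-confidence flag rather than an error on
  ambiguity. Bounding-box extents use the inclusive convention
  $\max - \min + 1$.
* **Degenerate inputs**: constant columns cap as no-ops with a warning;
  constant truth makes $R^2$ an explicit "undefined" marker; zero-area box
  pairs give IoU 0 with a warning; all-zero paired differences make the
  Wilcoxon test report a degenerate result.
* **Wilcoxon signed-rank**: zeros dropped, tied absolute differences receive
  average ranks, exact null by convolution over sign assignments up to 25
  non-zero pairs, tie-corrected normal approximation beyond. The pairing
  unit for model comparisons is the per-sample out-of-fold absolute error
  (n = 150 pairs); five paired fold-MAEs would be too few for a meaningful
  test, though the per-fold errors are also recorded.
* **Average precision** uses continuous all-points interpolation of the
  precision envelope, with greedy score-ordered matching at IoU ≥ 0.5 and
  each ground-truth box matched at most once.

## Base-learner families

All three boosted families run on the installed gradient-boosting backend's
histogram tree builder; they differ in growth policy and sampling, mirroring
the three libraries they emulate:

* **Classic GBRT** — depth-wise trees with per-split (per-node) column
  sampling mapped from the `sqrt`/`log2` max-features convention. Tuned grid:
  trees {200, 400} × learning rate {0.05, 0.1} × depth {4, 5} × subsample
  {0.8, 0.9} × max-features {sqrt, log2} (32 candidates).
* **Regularised depth-wise GBRT** — per-tree column sampling and L2 leaf
  regularisation. Tuned grid: trees {200, 400} × learning rate
  {0.01, 0.05, 0.1} × depth {4, 5, 6} × subsample {0.8, 0.9} ×
  column sample {0.8, 0.9} (72 candidates).
* **Histogram leaf-wise GBRT** — loss-guided growth, 31 leaves, deliberately
  untuned. Its reference defaults include a 20-sample minimum leaf
  occupancy, which assumes thousands of training rows; on 120-row training
  folds that leaves ~6 leaves per tree and underfits badly (about twice the
  CV error of every alternative in a three-seed check), so the package fixes
  the occupancy at 5 with 200 rounds at learning rate 0.1. This is a
  documented deviation from "library defaults", made once.

The Lasso penalty for the meta-learner is chosen by internal
cross-validation (reusing the 10 out-of-fold construction folds) over a
log-spaced grid $10^{-4}\dots1$; the selected value is stored in the
artifact. The combination weights are constrained non-negative: the three
base predictions are strongly collinear, sign-unstable weights estimated
from 150 out-of-fold values have no sensible interpretation, and the
constraint measurably stabilises the stack's out-of-sample advantage over
its best constituent. Exhaustive grid tuning (`tune = TRUE`) is
available and used where a study budget allows; the default comparison runs
use each family's fixed mid-grid parameter set — the single-point limit of a
reduced grid — because re-tuning 104 candidates inside every outer fold
multiplies the fit count by roughly fifty.

## Study design and problem sizes

`compare_models()` evaluates the roster — best geometric proxy, ordinary
least squares on the same selected log-features, the three single base
learners, and the stack — under one shared stratified 5-fold split,
refitting transforms, selection and models inside each fold. The package's
own studies (tests and the acceptance script) use n = 150 populations,
10 replicate seeds for ordering claims, 100 rendered scenes for the
metrology round trip, and 500/200-case oracle sweeps for the closed-form
geometry; these sizes keep full runs in the minutes range while leaving the
ordering claims statistically stable.

## Known limitations

* The best-proxy baseline is selected on the evaluation set itself (lowest
  MSE among the four formulas), which flatters the baseline slightly; the
  learned models enjoy no such oracle choice.
* Under the default synthetic population the **linear** baseline is strong —
  often the best non-ensemble model — because the true log-volume mapping is
  close to additive in the selected log-features. Real fruit violate that
  additivity more strongly than the generator does: orientation controls the
  interaction structure here, whereas photographed produce adds segmentation
  noise, perspective and correlated calibration error. Ordering claims
  between the linear row and the boosted rows on real data should not be
  extrapolated from the synthetic study.
* Tree ensembles cannot extrapolate beyond the convex range of the training
  targets; predictions for fruit outside 50–88 mm are untrustworthy and the
  metrology layer flags dimensions outside 20–150 mm.
* The volume oracle is exact only for star-shaped (radial) geometries; the
  generator never produces non-star-shaped fruit.
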