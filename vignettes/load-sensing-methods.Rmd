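---
title: "Methods: simulated calibration and Bayesian-regularized load sensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated calibration and Bayesian-regularized load sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneesense)
```

## The sensing problem

An instrumented tibial insert replaces the polyethylene spacer during total
knee replacement and reports, for each compartment (medial and lateral), the
contact load and its centre of pressure. Each compartment carries three
strain gauges wired as Wheatstone half-bridges, so a contact event is
observed only through three voltage deltas. The classical estimator for a
three-point load cell — sum the three reaction forces for the load, take
their force-weighted centroid for the location — is well-posed only inside
the triangle spanned by the gauges; real devices also suffer gauge
nonlinearity, channel crosstalk and noise that the closed form cannot
absorb. The approach implemented here instead learns the voltage-to-load and
voltage-to-location maps with four small neural networks (load and location
per compartment), trained on a grid calibration protocol, which extends the
usable sensing area to the whole insert surface.

All surface coordinates are in grid units (1 unit = 5 mm); masses are in kg
and forces in N with g = 9.8 m/s², matching the calibration pairs
(5 kg ↔ 49 N, …, 20 kg ↔ 196 N).

## Synthetic forward model

No raw data from the physical sensor are available, and the voltage/load
relationship of the hardware has no closed form, so the package ships a
synthetic stand-in (`simulate_response()`). A point load at $(x, y)$ with
force $F$ is first resolved into three gauge reactions by rigid-plate
equilibrium (`solve_reactions()`): vertical force balance plus two moment
balances, whose solution equals the barycentric coordinates of the load
point times $F$. Reactions are *not* clipped at zero: outside the gauge
triangle one coordinate is negative, which is exactly why the triangulation
estimate degrades there on hardware that cannot register negative bridge
deflections — and why the networks still have usable signal.

Each channel then produces
$dv_i = \sum_j C_{ij}\,(g_j r_j + q_j r_j^2) + \varepsilon_i$, with
per-channel linear gain $g_j$, quadratic coefficient $q_j$, crosstalk matrix
$C$ (unit diagonal) and Gaussian noise of standard deviation
`noise_frac`·|signal| + `noise_floor`.

Default values are chosen once as plausible for foil strain gauges on a
polymer insert, and are deliberately imperfect for the linear inverse:

* gains around 2 mV/N, differing by ±10% between channels (real bridges are
  never matched);
* a softening quadratic term worth roughly 5–8% of the linear signal at the
  heaviest calibration load (245 N), the "mild nonlinearity" the best-fit
  curve and the networks must capture;
* 2% symmetric crosstalk;
* 1% relative noise plus a 50 µV floor, a typical signal-to-noise for an
  amplified bridge — small enough that calibration is learnable, large
  enough that the low-load regime visibly degrades.

The contact-patch size is not modelled: deformation at the gauges is
insensitive to the indenter radius at these distances, so a point load
suffices. Temperature compensation (dummy gauges) and ADC quantization are
likewise out of scope.

The gauge coordinates of the real device are unpublished. The default
layouts are therefore **synthetic fixtures**, chosen once so that the
standard test points classify inside/outside the sensing triangle exactly as
reported for the device (medial points 1, 4, 5 outside; lateral 1 and 4
outside); the unit test on `point_in_sensing_area()` pins this. Both the
triangle and the surface polygon are overridable via the YAML config.

## Calibration protocol

`build_training_grid()` enumerates the 3 × 6 calibration grid (18 medial
points; 17 lateral — the dropped node is unspecified for the device, so the
default excludes the corner farthest from the lateral gauge triangle,
configurable). `build_load_schedule("training")` applies 5, 15, 10, 20 kg at
every node; `collect_dataset()` records one row per (point, load,
repetition) with provenance `measured`. One repetition per training cell is
used (repetitions belong to the test protocol).

Preprocessing is a fixed chain, all on raw volts before normalization:

1. **Extrapolation** (`extrapolate_high_loads()`): per point and channel, a
   least-squares degree-2 polynomial of mean voltage against force is
   evaluated at 25 kg and appended (provenance `extrapolated`). Degree 2 is
   the minimal family that can follow the quadratic channel response;
   a linear channel is extended exactly, and the unit tests check that a
   quadratic generator is recovered to 1e-9. The default point filter is the
   interior grid nodes (the "centre of the sensor"); with the default 3 × 6
   grid that is the four nodes at x = 1, y = 1…4.
2. **Augmentation** (`augment_noise()`): each measured/extrapolated record is
   duplicated `copies = 3` times with every channel multiplied by
   $(1 + u)$, $u \sim U(-0.05, 0.05)$; targets unchanged, provenance
   `augmented`. Multiplicative uniform noise is used because the protocol
   perturbs "the voltage reading" by a percentage. Three copies balances
   regularization against training cost; it is a free choice, exposed in the
   config.
3. **Normalization** (`fit_normalization()`): min–max to [0, 1] per
   quantity, fitted on the training split only and stored with each network.
   Targets (kg, x, y) are normalized too — "all the values" — and inverted
   at prediction time. Out-of-range values map outside [0, 1] unclipped;
   a 3 kg test load is negative on the normalized load scale, which is the
   mechanism behind the below-range degradation studied in the evaluation.

The 85/15 split (`split_dataset()`) is drawn after augmentation; the 15% is
evaluation-only — Bayesian regularization uses no validation set.

## Bayesian-regularized training

`brnet()` trains a single-hidden-layer perceptron (tanh hidden, linear
output) by Levenberg–Marquardt on
$F = \beta E_D + \alpha E_W$, with $E_D$ the residual sum of squares and
$E_W$ the weight norm. After every accepted step the evidence-framework
updates are applied:
$\gamma = k - 2\alpha\,\mathrm{tr}(H^{-1})$ with
$H \approx 2\beta J^\top J + 2\alpha I$, then $\alpha = \gamma / 2E_W$ and
$\beta = (n - \gamma)/2E_D$, where $k$ is the weight count and $\gamma$ the
effective number of parameters ($0 \le \gamma \le k$ by construction).
"5 and 10 hidden layers" in the source protocol is read as hidden *units*
(the conventional reading for a 3-input regression trained this way):
$k = 26$ for a load network, $k = 62$ for a location network.

Numerical choices:

* weights initialized uniform on ±0.5, seeded; $\alpha_0 = 0$, $\beta_0 = 1$,
  so the first hyperparameter update follows the initial LM cycle;
* damping $\mu$ starts at 1e-3, ×10 on rejection, ×0.1 on acceptance,
  aborts at $\mu \ge 10^{10}$; stopping on gradient norm < 1e-6 or 150
  accepted steps (enough for $E_D$ to plateau at these sizes, and it keeps a
  full four-network training run under ~2 s);
* $\mathrm{tr}(H^{-1})$ uses a symmetric eigendecomposition with the
  eigenvalues floored at $k\,\epsilon\,\lambda_{max}$: near a perfect fit
  with $\alpha \to 0$ the Gauss–Newton Hessian can be numerically singular,
  and the floor keeps the $\gamma$ update finite without changing it away
  from that regime;
* $E_D$, $E_W$ are floored at machine epsilon in the hyperparameter
  denominators.

Two test hooks justify trusting the optimizer: `hidden = 0` makes the model
a penalized affine map, whose fixed-$(\alpha,\beta)$ optimum must equal the
ridge closed form $(\beta X^\top X + \alpha I)^{-1}\beta X^\top y$ on the
1-augmented design (checked to 1e-3 on random problems); and the analytic
Jacobian is checked against central differences to 1e-5. LM is a local
method: the memorization test (noise-free teacher of the same shape) uses a
small number of seeded restarts, which is standard practice and is stated in
the test.

`train_bundle()` assembles the four networks; medial networks never see
lateral records. Bundles serialize to JSON at full precision
(`write_bundle()`/`read_bundle()`), including the normalization parameters —
prediction without them is refused rather than silently mis-scaled.

## Evaluation protocol

`run_experiment()` simulates the complete study: calibrate, train, then
apply 3, 13 and 23 kg at five fixed test points per compartment, 10
repetitions each (300 trials). Per (compartment, point, load) cell it
reports, for load and location:

* **accuracy** = $100(1 - |\bar{\hat m} - m| / m)$ — one hundred minus the
  relative systematic error of the mean prediction, floored at 0% (a
  prediction more than 100% off would otherwise be negative; the floor is a
  package convention);
* **precision** = sample SD of the prediction−truth differences;
* **MSE** = mean squared difference.

Location accuracy scales the mean Euclidean miss by $d_{max}$, the distance
from the true point to the farthest surface-polygon vertex (the farthest
location a network could predict while staying on the surface); this is
exact for convex surfaces, and the default surfaces are convex. Location
precision is reported in grid units and in mm (×5); how the physical study
aggregated location precision across compartments is not stated, so the
package reports the mean of per-cell SDs.

Three group comparisons are computed on the 30 per-cell accuracy values:
medial vs lateral, inside vs outside the sensing triangle, and below vs
within the training load range (3 kg is *below* because extrapolation
extends training to 5–25 kg; 13 and 23 kg are *within*). The test statistic
is unnamed in the source protocol; a Welch two-sample t-test at
$\alpha = 0.05$ is used, with a Mann–Whitney option in
`compare_groups()`. The triangulation baseline (linear-gain inversion →
`triangulate()`) is evaluated on the same trials for the sensing-area
comparison.

```{r experiment, eval = FALSE}
report <- run_experiment(seed = 1)
report
plot(report)
```

## What the synthetic study can and cannot show

The generator reproduces the *structure* of the physical experiment — grid
calibration, mild nonlinearity, crosstalk, noise, repeated test loads inside
and outside the sensing triangle, a below-range test load — so passing tests
demonstrate that the pipeline recovers the simulator's ground truth under
those conditions: held-out grid nodes are predicted within 10% load error
and 1 grid unit, below-range accuracy reliably drops relative to
within-range, and the network path keeps near-parity inside vs outside the
triangle while the triangulation baseline shows a larger outside deficit.

They do not certify the physical device. The simulator's noise is Gaussian
and stationary; real bridges drift, hysterese and couple to temperature. Its
nonlinearity is a smooth quadratic; real slit-propagated strain fields are
not. The headline figures of the physical study (≈83% load and ≈85% location
accuracy overall) were measured on hardware whose raw data are not deposited
and are not reproduction targets here; the simulated figures land higher
because the synthetic sensor is cleaner than the real one. Degenerate inputs
are refused loudly rather than guessed at: collinear gauges, constant
normalization channels, zero total reaction force, predictions without
normalization parameters, accuracy at zero actual load.

## Problem sizes

Default runs used throughout the package: 72 (medial) / 68 (lateral)
measured records, +4 extrapolated, ×4 after augmentation (≈300 training
rows per compartment), four networks of 26–62 weights, 150 LM epochs, 300
test trials per experiment; the multi-seed recovery studies use 5 seeds.
These sizes were chosen so a complete experiment is a desk-scale computation
(seconds) while every group comparison still has the full 30-cell layout of
the protocol.
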