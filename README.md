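# kneesense

Intraoperative load sensing for total knee replacement: an instrumented
tibial insert reports the contact load and its centre of pressure in each
compartment (medial/lateral) from three strain-gauge bridge voltages.
`kneesense` implements the complete software side of such a sensor for
surgeons' balancing workflows and for sensor developers: a synthetic
forward model of the two-compartment gauge hardware, the grid-based
calibration protocol, preprocessing (best-fit-curve load extrapolation,
[0, 1] min–max normalization, ±5% multiplicative noise augmentation),
from-scratch **Bayesian-regularized Levenberg–Marquardt** training of four
small feed-forward networks (load and location per compartment), a
classical three-point **triangulation baseline**, and the full
accuracy/precision/MSE evaluation protocol with group comparisons.

## The model

Each compartment observes a point load only through three voltage deltas
`dv ∈ R³`. Four networks (tanh hidden layer, linear output) learn the
inverse maps — `dv → mass [kg]` (5 hidden units) and `dv → (x, y)` in 5 mm
grid units (10 hidden units) — by minimizing the regularized objective

    F = β E_D + α E_W,   E_D = Σ residuals²,  E_W = Σ weights²,

with Levenberg–Marquardt steps and evidence-framework hyperparameter
updates after each accepted step:

    γ = k − 2α tr(H⁻¹),  H ≈ 2β JᵀJ + 2α I,
    α = γ / (2 E_W),     β = (n − γ) / (2 E_D),

where `k` is the weight count and `γ` the effective number of parameters.
No validation set is needed. The classical baseline estimates the load as
the sum of the three gauge reactions and the location as their
force-weighted centroid — well-posed only inside the gauge triangle,
whereas the learned maps cover the whole insert surface.

## Worked example

Run the complete simulated study — calibrate both compartments on their
3 × 6 grids at 5/15/10/20 kg, extrapolate to 25 kg, augment, train the
four-network bundle, then test 3/13/23 kg at five standard points per
compartment, ten repetitions each:

```r
library(kneesense)
report <- run_experiment(seed = 1)
report
#> Simulated load-sensing experiment (seed 1)
#>   300 trials, 30 summary cells
#>   mean load accuracy     :  97.47 %
#>   mean location accuracy :  96.03 %
#>   load accuracy below / within training range: 96.10 % / 98.15 %
#>   R^2 (load): medial 0.9959, lateral 0.9983
#>   compartment     medial vs lateral: load p = 0.108, location p = 0.355
#>   sensing_area    inside vs outside: load p = 0.128, location p = 0.0174 *
#>   training_range  within vs below: load p = 0.0108 *, location p = 0.00749 *
```

Reading it: averaged over all 30 (compartment × point × load) cells the
bundle predicts the applied mass within ~2.5% and the contact point within
~4% of the farthest-on-surface distance. The two compartments are
statistically indistinguishable (p > 0.05), and the load applied *below*
the training range (3 kg) is predicted significantly worse than loads
within it — the same qualitative pattern the physical device shows, driven
by the poorer signal-to-noise at low loads and by extrapolation outside the
normalized training interval.

Predicting a single reading:

```r
lay <- default_layout("medial")
rd <- simulate_response(lay, sim_params(),
                        point_load("medial", mass_kg = 13, x = 0.5, y = 1.5),
                        seed = 42)
round(rd$dv, 5)
#> [1] 0.17946 0.01619 0.06060
predict(report$bundle, rd)
#>   mass_kg     x     y
#> 1  13.204 0.503 1.451
```

A true 13 kg load at (0.5, 1.5) is recovered as 13.2 kg at (0.50, 1.45).

A thin command-line wrapper is installed alongside the package
(`exec/kneesense`) with `simulate-calibration`, `train` and
`run-experiment` subcommands; see `inst/extdata/default_config.yaml` for
the configurable gauge layouts and simulator parameters.

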