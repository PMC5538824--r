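# cabuffer

Analysis of neuronal Ca²⁺ handling and excitability from ratiometric
fura-2 imaging and current-clamp recordings, built around the
**added-buffer method**: the indicator dye is itself a Ca²⁺ buffer, so as
it loads into a patch-clamped cell the decay of evoked Ca²⁺ transients
slows in a way that reveals the cell's own buffering. In the linear
single-compartment model

τ_transient = (1 + κ_S + κ_B) / γ,  κ_B = [B]·K_d / ([Ca²⁺]_rest + K_d)²

so a straight-line fit of decay time constants τ against the dye binding
ratio κ_B gives the endogenous Ca²⁺-binding ratio κ_S (negative
x-intercept minus one), the extrusion rate γ (inverse slope) and the
endogenous decay time constant τ_endo = (1+κ_S)/γ (y-intercept), with
uncertainty from a fixed-x residual bootstrap.

The package is aimed at cellular neurophysiologists analyzing ROI-mean
trace data (no image processing). It provides:

* **Calibration chemistry** — equilibrium speciation of
  EGTA/fura-2-containing calibration solutions with Davies
  ionic-strength and van't Hoff temperature corrections
  (`solve_free_ca()`, `apparent_kd()`).
* **Ratiometric calibration** — ratio ↔ free-Ca²⁺ conversion with a
  rig-specific effective dissociation constant, and dye tracking from the
  360 nm isosbestic channel (`ratio_to_ca()`, `effective_kd()`,
  `fit_loading_curve()`).
* **Added-buffer estimation** — transient decay fits, (κ_B, τ)
  collection, the linear fit, bootstrap and log-scale cohort comparison
  (`fit_added_buffer()`, `bootstrap_added_buffer()`).
* **Spike analysis** — detection, SAN/NSAN classification (0.5 Hz
  cutoff), spike-frequency-adaptation fits
  Y = (Y0−Plateau)·exp(−K·T)+Plateau, ramp threshold currents, F-I
  curves (`fit_sfa()`, `threshold_current_from_ramp()`, `fi_curve()`).
* **FCCP release** — baseline-normalized ratio traces and Δ(F340/F380)
  release amplitudes with cohort aggregation (`release_amplitude()`,
  `aggregate_cohort()`).
* **A forward simulator** with known ground truth for every recording
  type, including control-like and DIO-like cohort presets, so the whole
  pipeline is validated by parameter recovery (`simulate_cell()`,
  `make_cohort()`, `run_pipeline()`).

## Worked example

Free Ca²⁺ of a defined-Ca²⁺ calibration solution (4 mM EGTA, 2.7 mM
CaCl₂, 1 mM MgCl₂, 0.05 mM fura-2, pH 7.2):

```r
library(cabuffer)
sol <- read_solution_recipe(system.file("extdata", "r_def.yaml",
                                        package = "cabuffer"))
solve_free_ca(sol)
#> Calibration-solution speciation
#>   pH 7.20, 22 C, ionic strength 0.168 M
#>   free Ca2+: 0.3431 uM   free Mg2+: 0.9835 mM
#>   chelator species (mM):
#>  ligand total_mM  free_mM protonated_mM ca_bound_mM mg_bound_mM kd_app_uM
#>    EGTA     4.00 0.000161        1.3097     2.67463    0.015499    0.1680
#>  fura-2     0.05 0.020856        0.0031     0.02503    0.001013    0.3284
```

Most of the total Ca²⁺ is EGTA-bound, leaving 0.34 µM free — the
defined level used to calibrate the rig's effective dissociation
constant.

Added-buffer analysis of a simulated control-like cohort (10 cells,
truth κ_S = 497, γ = 150 s⁻¹):

```r
cells <- make_cohort("control", 10, seed = 1, what = "loading")
pts <- do.call(rbind, lapply(cells, function(cell) {
  p <- cell$truth$params
  collect_kappa_tau(cell, p$cal, p$cell_scale, p$stim_times_s,
                    cohort = "control")
}))
fit <- fit_added_buffer(pts)
fit
#> added-buffer fit (n = 120): kappa_S 506.1, gamma 150.8 1/s, tau_endo 3.362 s
boot <- bootstrap_added_buffer(fit, n_boot = 1000, seed = 2)
sd(boot$kappa_s); sd(boot$gamma_per_s)
#> [1] 14.5...
#> [1] 2.23...
```

The pooled fit recovers the generating parameters within ~2%, with
bootstrap SDs of ±15 (κ_S) and ±2.2 s⁻¹ (γ). A transient at κ_B = 0
would decay with τ_endo ≈ 3.4 s; each unit of added dye buffering
prolongs it by 1/γ.

Spike-frequency adaptation of a simulated 10-s train (truth Y0 = 35 Hz,
Plateau = 10 Hz, K = 0.5 s⁻¹):

```r
st <- simulate_spike_train(35, 10, 0.5, jitter_cv = 0.05, seed = 3)
fit_sfa(instantaneous_frequency(st$train))
#> SFA fit: Y0 35.7 Hz, plateau 10.4 Hz, K 0.564 1/s, ratio 3.43 (148 APs)
```

A ratio above 3 marks strong adaptation.

See `vignettes/added-buffer-method.Rmd` for the model, its assumptions,
parameter conventions and the simulator's scope.

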