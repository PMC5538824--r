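---
title: "Estimating endogenous Ca2+ buffering with the added-buffer method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating endogenous Ca2+ buffering with the added-buffer method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cabuffer)
```

## The problem

How strongly a neuron buffers cytosolic Ca2+, and how fast it clears it,
set the amplitude and time course of every Ca2+ signal the cell produces.
Neither quantity can be read off a single recording, because the indicator
dye used to observe Ca2+ is itself a high-affinity buffer that perturbs the
very signals it reports. The added-buffer method turns this perturbation
into the measurement: as the dye diffuses into a patch-clamped cell its
known, growing buffering capacity is titrated against the cell's unknown,
fixed one, and extrapolation to zero added buffer recovers the undisturbed
cell.

`cabuffer` implements that entire chain — calibration-solution chemistry,
ratiometric calibration, transient kinetics, the linear extrapolation with
bootstrap uncertainty — plus spike-train excitability metrics and
FCCP-evoked mitochondrial-release quantification, and a forward simulator
that generates every supported recording type with known ground truth so
the pipeline can be validated by parameter recovery.

## The single-compartment model

A brief Ca2+ influx into a small, well-mixed compartment containing a fast
endogenous buffer (binding ratio $\kappa_S$) and the indicator dye
(binding ratio $\kappa_B$) relaxes back to rest mono-exponentially, with

$$\tau_\mathrm{transient} = \frac{1 + \kappa_S + \kappa_B}{\gamma},$$

where $\gamma$ (s$^{-1}$) is a lumped linear extrusion rate. The
incremental binding ratio of the dye at resting Ca2+ is

$$\kappa_B = \frac{[B]_\mathrm{total}\,K_d}
  {([\mathrm{Ca}^{2+}]_\mathrm{rest} + K_d)^2}.$$

$\tau$ is linear in $\kappa_B$, so an ordinary least-squares line through
the per-transient points yields all three parameters at once: the negative
x-intercept is $1+\kappa_S$, the inverse slope is $\gamma$, and the
y-intercept is the endogenous decay time constant
$\tau_\mathrm{endo} = (1+\kappa_S)/\gamma$. The same algebra is used in
`fit_added_buffer()`, so the identity $\tau_\mathrm{endo} =
(1+\kappa_S)/\gamma$ holds exactly by construction.

```{r worked-line}
kb <- c(0, 150, 300, 600)
fit <- fit_added_buffer(data.frame(kappa_b = kb, tau_s = (1 + 497 + kb) / 150))
fit
```

Assumptions worth keeping in mind: buffering is fast relative to the
transient (rapid-buffer approximation), both buffers are far from
saturation so $\kappa$ values are evaluated at rest, extrusion is linear
in free Ca2+, and the cell is a single compartment (no ER/mitochondrial
flux modeling — the FCCP module quantifies mitochondrial content
empirically instead).

The model is sometimes written with an additional loading-correction term
proportional to a loading time constant. All extraction rules used here
(x-intercept, slope, y-intercept) are stated for the pure linear form, and
the loading correction has no defined parameterization in this setting, so
the package deliberately implements the pure linear model.

## From photons to parameters

**Calibration chemistry.** Absolute calibration requires solutions of
known free Ca2+. `solve_free_ca()` solves the coupled
Ca/Mg/EGTA/fura-2 mass-action system at fixed (buffered) pH, with a
shipped table of critical-compilation stability constants referenced to
ionic strength 0.1 M and 20 °C, corrected to working conditions by the
Davies equation and the van't Hoff relation. pH is treated as hydrogen-ion
*activity* (what the electrode reports) and converted to concentration via
the Davies single-ion coefficient — omitting this step biases apparent
EGTA affinity by roughly a third. EGTA purity enters as a user-supplied
scale factor (default 1.0): commercial lots vary by a few percent and the
appropriate value is lot-specific, so no titration fit is attempted.
Mass balance is verified to 1e-9 relative on every solve.

```{r speciation}
solve_free_ca(read_solution_recipe(
  system.file("extdata", "r_def.yaml", package = "cabuffer")))
```

**Ratiometric calibration.** Free Ca2+ follows from the background-
corrected 340/380 nm ratio via
$[\mathrm{Ca}^{2+}] = K_{d,\mathrm{eff}}\,(R - R_\mathrm{min})/(R_\mathrm{max} - R)$,
with the rig-specific effective dissociation constant obtained from a
defined-Ca2+ solution by `effective_kd()`. The *chemical* $K_d$ (not the
effective one) enters $\kappa_B$; both live in `calibration_result()`.
Ratios slightly below $R_\mathrm{min}$ — unavoidable noise around the zero
point — clip to 0 nM with a warning rather than erroring, so resting-level
estimates stay robust; ratios at or above $R_\mathrm{max}$ are a hard
saturation error. Dye concentration is tracked Ca-independently from the
360 nm isosbestic channel, scaled by one per-rig ADU-per-µM factor
measured by imaging the pipette solution of known dye content.

**Transient kinetics.** Each depolarization-evoked transient is fitted
from its peak with a free-baseline mono-exponential. Acceptance requires a
positive amplitude, $\tau \in [0.05, 60]$ s, and residual RMS under 20% of
the amplitude; rejected transients are flagged and excluded, never
silently dropped. Resting Ca2+ is the mean over the 5 s before each
stimulus; the dye concentration at onset is the isosbestic mean over the
last second before the stimulus (a longer window would lag the
still-loading dye).

**Uncertainty.** `bootstrap_added_buffer()` performs fixed-x residual
resampling (default 1000 replicates): the $\kappa_B$ design is kept fixed,
fitted residuals are resampled with replacement onto fitted values, and
the line is refit. Replicates with non-positive slope are counted and
excluded as non-physical. With zero residuals the distribution collapses
to a point mass, and a fixed seed reproduces distributions exactly.
Cohort distributions are compared after a natural-log transform (the
ratio-of-estimates distributions are right-skewed) with an unpaired
t-test; common rescaling of both distributions leaves the statistic
unchanged.

Whether to pool points across cells or fit per cell is genuinely open; the
package pools per cohort by default (one fit with confidence bands per
cohort), and per-cell fits remain available by calling
`fit_added_buffer()` on a single cell's points.

## Spike-train metrics

Spikes are detected as upward crossings of −20 mV with a 2 ms refractory
period. A neuron is classified "not spontaneously active" (NSAN) iff its
mean rate is strictly below 0.5 Hz. Spike-frequency adaptation over a 10-s
depolarization is quantified by fitting
$Y(T) = (Y_0 - \mathrm{Plateau})e^{-KT} + \mathrm{Plateau}$ to the
instantaneous-frequency series with $Y_0$ fixed to the first measured
instantaneous frequency. The curve is anchored at the time of that first
sample; since the mono-exponential family is shift-invariant, Plateau and
K equal their onset-referenced values while the anchor stays consistent
with the sample $Y_0$ is read from (anchoring at the onset instead would
bias K by a few percent for no benefit).

The adaptation ratio is defined as $Y_0/\mathrm{Plateau}$ — 1 means no
adaptation, larger is stronger, and a ratio above 3 marks strong
adaptation. This definition is a package choice (flagged here
prominently): it is dimensionless, reproduces the expected structure of
firing vs silent cohorts, and degrades gracefully — when the fitted
plateau falls below 0.1 Hz the cell effectively stops firing and the ratio
is reported as `Inf` with a flag rather than a misleading large number.
Threshold currents are read off ascending ramps at the first detected
spike; F-I curves count spikes per step, averaging duplicate currents.

## FCCP release

With AM (bulk ester) loading the background fluorescence is not
determinable and absolute calibration is impossible, so mitochondrial
Ca2+ release evoked by the protonophore FCCP is quantified in raw ratio
units: $\Delta R$ = peak of the 5-sample moving-averaged ratio within the
search window minus the pre-application baseline mean. No background is
subtracted for AM-loaded data. The search window extends 5 min past the
end of the application because release outlasts a brief FCCP pulse.
Baseline-normalized traces (baseline mean exactly 1, invariant to common
gain) are produced for visualization; note the documented asymmetry that
raw-ratio $\Delta R$ is rig-specific and scales with a 340-only gain
change. Cells are the statistical unit, pooled across slices; both an
unpaired t-test (default headline) and a Mann-Whitney test are reported,
since the two are legitimately interchangeable for this endpoint and can
disagree near the significance boundary.

## The simulator and what passing tests mean

`simulate_cell()` generates loading experiments in the rapid-buffering
approximation: dye fills as $B(t) = B_\mathrm{pip}(1 - e^{-t/\tau_f})$,
each stimulus adds a fixed total Ca2+ whose free increment is
$\Delta[\mathrm{Ca}]_\mathrm{free} = \mathrm{influx}/(1+\kappa_S+\kappa_B)$,
and decay uses the linear law with $\kappa_B$ frozen at its onset value
(quasi-static dye). Fluorescence is rendered through the same ratio
equation the analysis inverts, with a two-state (bright Ca-free / dim
Ca-bound) 380 nm channel, and multiplicative Gaussian noise (default CV
2%, a shot-noise proxy) applied independently per wavelength as the last
step. Stored truths satisfy the linear law exactly before noise, so
oracle tests are constructed identities, and all randomness flows from a
single seed (byte-identical cohorts per seed).

Default study conditions: control cohort $\kappa_S = 497$,
$\gamma = 150$ s$^{-1}$, resting Ca2+ 19.3 nM; DIO (diet-induced obesity)
cohort $\kappa_S = 240$, $\gamma = 111$ s$^{-1}$, resting 45.8 nM; silent
fractions 31% and 51%; FCCP $\Delta R$ 0.020 vs 0.012 at per-cell SDs
derived from the reported SEMs ($\mathrm{SD} = \mathrm{SEM}\sqrt{n}$ for
cross-cell quantities). For the pooled handling parameters the reported
spreads are bootstrap SEMs of single pooled estimates, not cross-cell
spreads, so per-cell $\kappa_S$/$\gamma$ dispersion uses the SEM/mean CV
(a few percent). The per-stimulus influx (100 µM total, giving ~200 nM
free transients at low $\kappa_B$) and the pipette dye concentration
(150 µM, spanning $\kappa_B$ up to ~600) are package choices at realistic
magnitudes; they set the operating range, not the recovered parameters.
FCCP amplitude draws are truncated at zero — non-responding cells show no
negative release.

Problem sizes used in the validation suite — 20 cells per cohort, 12
stimuli per cell, 1000 bootstrap replicates, 50–100 seeded repetitions of
the stochastic round trips — were chosen to make Monte-Carlo error small
relative to the 10% recovery tolerances.

What passing recovery tests do **not** show: the simulator emulates
neither dye bleaching, spatial gradients and compartment violations
(nuclear/ER exclusion), buffer saturation during large transients,
nonlinear or saturating extrusion, electrode series-resistance artifacts,
nor slow drifts in optics. On real data those effects bias
$\kappa_S$ and $\gamma$ in ways the recovery tests cannot detect; the
tests establish that the estimator chain is correct for the model it
assumes, not that the model is correct for any given cell.

## Numerical choices and degenerate inputs

* Speciation: nested monotone bracketing on the log-concentration scale
  plus Newton polishing; mass balance enforced to 1e-9 relative;
  Ca-free recipes short-circuit to zero free Ca2+.
* Nonlinear fits use Levenberg-Marquardt (`minpack.lm`) with bounded
  parameters; degenerate inputs (flat loading curves, flat transients,
  constant-frequency trains) are flagged rather than fitted, with raw data
  preserved.
* Ties/edges: the NSAN cutoff is strict (exactly 0.5 Hz classifies as
  active); a ratio exactly at $R_\mathrm{min}$ maps to 0 nM; duplicate F-I
  currents are averaged with a note.
* Bootstrap replicates with non-positive slope are excluded and counted;
  an all-invalid bootstrap would surface as an empty distribution rather
  than a fabricated one.

## Known limitations

Single-compartment, linear-extrusion model only; no bleaching or
background drift correction; voltage traces carry a stereotyped template
adequate for detector tests, not waveform analysis; the constants table
covers EGTA and fura-2 only; pH is fixed (no proton balance); and the
activity-coefficient model stops at the Davies equation, so ionic
strengths far above ~0.3 M are outside the validated range.
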