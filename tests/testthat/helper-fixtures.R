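# Shared fixtures, all built in code.

default_cal <- function() calibration_result(0.3, 6.0, 0.22, dyn_range = 5)

r_def_recipe <- function() {
  solution_composition(
    c(KCl = 129.5, KOH = 13, NaCl = 10.3, NaOH = 4.7, MgCl2 = 1,
      HEPES = 5, EGTA = 4, CaCl2 = 2.7, "fura-2" = 0.05),
    pH = 7.2, temperature_C = 22)
}

# Noiseless mono-exponential Ca2+ transient sampled at 10 Hz: 10 s of
# baseline, stimulus at t = 10 s, decay over `post_s`.
mono_transient <- function(amplitude_nM = 200, tau_s = 1.5, baseline_nM = 20,
                           post_s = 20, dt = 0.1) {
  t <- seq(0, 10 + post_s, by = dt)
  ca <- baseline_nM + ifelse(t >= 10, amplitude_nM * exp(-(t - 10) / tau_s), 0)
  list(time_s = t, ca_nM = ca)
}

# Collinear added-buffer points tau = (1 + kappa_s + kb)/gamma.
collinear_points <- function(kappa_s, gamma, kb = c(0, 150, 300, 600)) {
  data.frame(kappa_b = kb, tau_s = (1 + kappa_s + kb) / gamma)
}

# Regularly spiking train at `rate` Hz over `duration` s.
regular_train <- function(rate, duration = 60) {
  spike_train(seq(0, duration - 1e-9, by = 1 / rate), duration)
}
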