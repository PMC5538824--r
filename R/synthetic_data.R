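# Forward simulation of every recording type the analysis consumes, with
# stored ground truth so the whole pipeline can be validated by parameter
# recovery. The Ca2+ side uses the linear single-compartment model in the
# rapid-buffering approximation: each brief stimulus adds a fixed total
# amount of Ca2+, the free increment is attenuated by the total binding
# ratio, Delta[Ca]_free = influx / (1 + kappa_S + kappa_B), and relaxes
# back mono-exponentially with tau = (1 + kappa_S + kappa_B)/gamma. The dye
# binding ratio kappa_B is held at its stimulus-onset value within each
# transient (quasi-static dye loading).

#' Ground-truth parameter set for the single-compartment simulator
#'
#' Defaults describe a control-like cell: endogenous binding ratio 497,
#' extrusion rate 150/s, resting Ca2+ 19.3 nM, pipette fura-2 150 uM
#' filling with a 300 s time constant, stimuli every 120 s, 2% per-
#' wavelength multiplicative noise.
#'
#' @param kappa_s Endogenous Ca2+-binding ratio (dimensionless, > 0).
#' @param gamma_per_s Linear extrusion rate in 1/s.
#' @param ca_rest_nM Resting free Ca2+ in nM.
#' @param influx_uM Total Ca2+ added per stimulus in uM (before buffering).
#' @param pipette_fura_uM Pipette dye concentration in uM.
#' @param tau_fill_s Loading time constant in seconds.
#' @param kd_fura_uM Chemical K_d of the dye in uM.
#' @param cal A `calibration_result` (rig calibration used to render
#'   fluorescence).
#' @param cell_scale ADUs per uM of dye in the isosbestic channel.
#' @param noise_cv Multiplicative Gaussian noise CV per wavelength.
#' @param stim_times_s Stimulus schedule in seconds.
#' @param duration_s Recording duration; must contain the schedule.
#' @param dt_s Frame interval in seconds.
#' @param seed Optional integer seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(kappa_s = 497, gamma_per_s = 150, ca_rest_nM = 19.3,
                       influx_uM = 100, pipette_fura_uM = 150,
                       tau_fill_s = 300, kd_fura_uM = 0.22,
                       cal = calibration_result(0.3, 6.0, 0.22, dyn_range = 5),
                       cell_scale = 10, noise_cv = 0.02,
                       stim_times_s = seq(60, 1440, by = 120),
                       duration_s = 1500, dt_s = 0.1, seed = NULL) {
  .assert(kappa_s > 0 && gamma_per_s > 0 && ca_rest_nM > 0,
          "kappa_s, gamma_per_s and ca_rest_nM must be positive")
  .assert(influx_uM >= 0 && pipette_fura_uM >= 0, "influx and dye must be >= 0")
  .assert(all(stim_times_s > 0 & stim_times_s < duration_s),
          "stimulus schedule must lie within the recording")
  p <- list(kappa_s = kappa_s, gamma_per_s = gamma_per_s,
            ca_rest_nM = ca_rest_nM, influx_uM = influx_uM,
            pipette_fura_uM = pipette_fura_uM, tau_fill_s = tau_fill_s,
            kd_fura_uM = kd_fura_uM, cal = cal, cell_scale = cell_scale,
            noise_cv = noise_cv, stim_times_s = sort(stim_times_s),
            duration_s = duration_s, dt_s = dt_s, seed = seed)
  # densest admissible schedule: transients must be separated by > 5 tau
  kb_max <- kappa_b(pipette_fura_uM, kd_fura_uM, ca_rest_nM / 1000)
  tau_max <- (1 + kappa_s + kb_max) / gamma_per_s
  if (length(p$stim_times_s) > 1 && min(diff(p$stim_times_s)) < 5 * tau_max) {
    stop(structure(class = c("cabuffer_validation_error", "error", "condition"),
                   list(message = sprintf(
                     "stimulus schedule too dense: spacing %.3g s < 5 tau = %.3g s",
                     min(diff(p$stim_times_s)), 5 * tau_max),
                     call = sys.call(-1))))
  }
  structure(p, class = "sim_params")
}

#' Simulate one whole-cell fura-2 loading experiment
#'
#' Produces a `ratio_trace` with all three wavelengths (noise applied last,
#' multiplicatively and independently per wavelength) together with the
#' noiseless ground truth: the loading curve and, per stimulus, the dye
#' concentration, kappa_B, decay time constant and free-Ca2+ amplitude.
#' The stored (kappa_B, tau) truths satisfy tau = (1 + kappa_S +
#' kappa_B)/gamma exactly.
#'
#' @param params A `sim_params`.
#' @param cohort Optional cohort label carried through.
#' @return An object of class `synthetic_cell`: fields `trace`, `truth`
#'   (list with `transients` data frame, `loading` data frame, and the
#'   generating parameters) and `cohort`.
#' @export
simulate_cell <- function(params, cohort = NA_character_) {
  .assert(inherits(params, "sim_params"), "params must be a sim_params")
  with_seed(params$seed, {
    t <- seq(0, params$duration_s, by = params$dt_s)
    B <- params$pipette_fura_uM * (1 - exp(-t / params$tau_fill_s))

    stims <- params$stim_times_s
    B_on <- params$pipette_fura_uM * (1 - exp(-stims / params$tau_fill_s))
    kb <- kappa_b(B_on, params$kd_fura_uM, params$ca_rest_nM / 1000)
    denom <- 1 + params$kappa_s + kb
    tau <- denom / params$gamma_per_s
    amp_nM <- params$influx_uM * 1000 / denom

    ca <- rep(params$ca_rest_nM, length(t))
    for (j in seq_along(stims)) {
      after <- t >= stims[j]
      ca[after] <- ca[after] + amp_nM[j] * exp(-(t[after] - stims[j]) / tau[j])
    }

    R <- ca_to_ratio(ca, params$cal)
    # two-state dye fluorescence at 380 nm: bright Ca-free form, dim bound
    y <- ca / (ca + params$kd_fura_uM * 1000)
    F380 <- params$cell_scale * B * (1 - y + y / params$cal$dyn_range)
    F340 <- R * F380
    F360 <- params$cell_scale * B

    cv <- params$noise_cv
    if (cv > 0) {
      F340 <- F340 * (1 + stats::rnorm(length(t), 0, cv))
      F380 <- F380 * (1 + stats::rnorm(length(t), 0, cv))
      F360 <- F360 * (1 + stats::rnorm(length(t), 0, cv))
    }

    structure(list(
      trace = ratio_trace(t, F340, F380, F360),
      truth = list(
        transients = data.frame(stim_time_s = stims, fura_uM = B_on,
                                kappa_b = kb, tau_s = tau,
                                amplitude_nM = amp_nM),
        loading = data.frame(time_s = t, fura_uM = B),
        params = params
      ),
      cohort = cohort
    ), class = "synthetic_cell")
  })
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat(sprintf("synthetic_cell (%s): %d stimuli, kappa_S %.4g, gamma %.4g 1/s\n",
              ifelse(is.na(x$cohort), "unlabelled", x$cohort),
              nrow(x$truth$transients), x$truth$params$kappa_s,
              x$truth$params$gamma_per_s))
  invisible(x)
}

#' Simulate a 10-s adapting spike train with voltage trace
#'
#' Inter-spike intervals are generated so that the instantaneous frequency
#' 1/ISI, timestamped at the second spike of each interval, follows
#' Y(T) = (Y0 - Plateau) exp(-K T) + Plateau (each ISI solves the implicit
#' equation ISI = 1/Y(t + ISI), matching the analysis convention exactly at
#' zero jitter). Multiplicative lognormal jitter is applied per interval.
#' The voltage trace places a stereotyped action-potential template on a
#' -60 mV baseline, adequate for exercising the threshold detector.
#'
#' @param y0_hz Initial instantaneous frequency (protocol range 30-40 Hz).
#' @param plateau_hz Asymptotic frequency; must not exceed `y0_hz`.
#' @param k_per_s Inverse adaptation time constant.
#' @param duration_s Stimulus duration (default 10 s).
#' @param jitter_cv Coefficient of variation of the multiplicative ISI
#'   jitter (default 0.05; 0 = deterministic).
#' @param seed Optional integer seed.
#' @param dt_s Voltage sampling interval (default 1e-4 s = 10 kHz).
#' @param onset_s Latency of the first spike after stimulus onset (default
#'   50 ms, so the first action potential rises from baseline within the
#'   trace).
#' @return A list with `train` (a `spike_train`), `time_s`, `voltage_mV`
#'   and `truth`.
#' @export
simulate_spike_train <- function(y0_hz, plateau_hz, k_per_s, duration_s = 10,
                                 jitter_cv = 0.05, seed = NULL, dt_s = 1e-4,
                                 onset_s = 0.05) {
  .assert(y0_hz > 0 && plateau_hz >= 0, "frequencies must be non-negative")
  if (y0_hz < plateau_hz) {
    stop(structure(class = c("cabuffer_validation_error", "error", "condition"),
                   list(message = "Y0 below Plateau: frequency growth is not modeled",
                        call = sys.call(-1))))
  }
  Yfun <- function(T) (y0_hz - plateau_hz) * exp(-k_per_s * T) + plateau_hz
  with_seed(seed, {
    sdlog <- if (jitter_cv > 0) sqrt(log(1 + jitter_cv^2)) else 0
    times <- onset_s
    t <- onset_s
    repeat {
      isi <- 1 / Yfun(t)
      for (i in 1:40) isi <- 1 / Yfun(t + isi) # fixed point: 1/ISI = Y(t+ISI)
      if (sdlog > 0) isi <- isi * exp(stats::rnorm(1, 0, sdlog))
      if (t + isi >= duration_s) break
      t <- t + isi
      times <- c(times, t)
    }
    tm <- seq(0, duration_s, by = dt_s)
    v <- rep(-60, length(tm))
    for (ts in times) { # 0.3 ms gaussian depolarization to +20 mV
      near <- abs(tm - ts) < 0.002
      v[near] <- v[near] + 80 * exp(-(tm[near] - ts)^2 / (2 * 3e-4^2))
    }
    list(train = spike_train(times, duration_s, baseline_mV = -60),
         time_s = tm, voltage_mV = v,
         truth = list(y0_hz = y0_hz, plateau_hz = plateau_hz,
                      k_per_s = k_per_s, jitter_cv = jitter_cv))
  })
}

#' Simulate an ascending current-ramp response
#'
#' The model neuron is silent below its threshold current and fires at
#' `f0_hz + gain_hz_per_pA * (I - I_threshold)` above it; the first spike
#' occurs at the moment the ramp reaches threshold.
#'
#' @param i_threshold_pA Ground-truth threshold current.
#' @param ramp_rate_pA_per_s Ramp slope.
#' @param duration_s Ramp duration.
#' @param f0_hz Firing rate at threshold crossing.
#' @param gain_hz_per_pA Suprathreshold rate gain.
#' @param dt_s Sampling interval.
#' @return A list with `time_s`, `voltage_mV`, `current_pA` and `truth`.
#' @export
simulate_ramp_response <- function(i_threshold_pA, ramp_rate_pA_per_s = 5,
                                   duration_s = NULL, f0_hz = 5,
                                   gain_hz_per_pA = 0.5, dt_s = 1e-4) {
  .assert(i_threshold_pA >= 0 && ramp_rate_pA_per_s > 0,
          "threshold and ramp rate must be positive")
  if (is.null(duration_s)) duration_s <- i_threshold_pA / ramp_rate_pA_per_s + 4
  tm <- seq(0, duration_s, by = dt_s)
  current <- ramp_rate_pA_per_s * tm
  t_star <- i_threshold_pA / ramp_rate_pA_per_s
  times <- numeric(0)
  if (t_star < duration_s) {
    t <- t_star
    while (t < duration_s) {
      times <- c(times, t)
      f <- f0_hz + gain_hz_per_pA * (ramp_rate_pA_per_s * t - i_threshold_pA)
      t <- t + 1 / max(f, 1e-3)
    }
  }
  v <- rep(-60, length(tm))
  for (ts in times) {
    near <- abs(tm - ts) < 0.002
    v[near] <- v[near] + 80 * exp(-(tm[near] - ts)^2 / (2 * 3e-4^2))
  }
  list(time_s = tm, voltage_mV = v, current_pA = current,
       truth = list(i_threshold_pA = i_threshold_pA,
                    ramp_rate_pA_per_s = ramp_rate_pA_per_s))
}

#' Simulate a current-step response with linear F-I gain
#'
#' Spike count per pulse is `round(gain_per_pA * (I - I_threshold))`,
#' clipped at zero, with spikes evenly spaced over the pulse.
#'
#' @param current_pA Injected current.
#' @param i_threshold_pA Threshold current.
#' @param gain_per_pA Spikes per pA above threshold.
#' @param duration_s Pulse duration (default 10 s).
#' @param dt_s Sampling interval.
#' @return A list with `current_pA`, `time_s`, `voltage_mV` and `truth`.
#' @export
simulate_step_response <- function(current_pA, i_threshold_pA = 10,
                                   gain_per_pA = 2, duration_s = 10,
                                   dt_s = 1e-4) {
  n <- max(0, round(gain_per_pA * (current_pA - i_threshold_pA)))
  tm <- seq(0, duration_s, by = dt_s)
  v <- rep(-60, length(tm))
  times <- if (n > 0) seq(0.05, duration_s - 0.05, length.out = n) else numeric(0)
  for (ts in times) {
    near <- abs(tm - ts) < 0.002
    v[near] <- v[near] + 80 * exp(-(tm[near] - ts)^2 / (2 * 3e-4^2))
  }
  list(current_pA = current_pA, time_s = tm, voltage_mV = v,
       truth = list(n_spikes = n, i_threshold_pA = i_threshold_pA,
                    gain_per_pA = gain_per_pA))
}

#' Simulate an FCCP-release ratio trace
#'
#' Baseline ratio R0, then a difference-of-exponentials bump starting at
#' `t_on_s`, scaled so its peak equals `delta_r`; per-wavelength
#' multiplicative noise is applied to synthetic F340/F380 channels.
#'
#' @param r0 Baseline ratio.
#' @param delta_r Peak ratio increase (>= 0).
#' @param rise_s,fall_s Rise and decay time constants of the bump.
#' @param t_on_s Application onset.
#' @param duration_s Trace length.
#' @param dt_s Frame interval (default 2 s).
#' @param noise_cv Per-wavelength multiplicative noise CV.
#' @param seed Optional integer seed.
#' @return A `ratio_trace` with attribute `truth`.
#' @export
simulate_fccp_trace <- function(r0 = 0.8, delta_r = 0.02, rise_s = 30,
                                fall_s = 120, t_on_s = 120, duration_s = 600,
                                dt_s = 2, noise_cv = 0.01, seed = NULL) {
  .assert(delta_r >= 0, "delta_r must be >= 0")
  .assert(fall_s > rise_s, "fall_s must exceed rise_s")
  with_seed(seed, {
    tm <- seq(0, duration_s, by = dt_s)
    s <- pmax(tm - t_on_s, 0)
    bump <- exp(-s / fall_s) - exp(-s / rise_s)
    bump[tm < t_on_s] <- 0
    t_pk <- log(fall_s / rise_s) * rise_s * fall_s / (fall_s - rise_s)
    peak <- exp(-t_pk / fall_s) - exp(-t_pk / rise_s)
    R <- r0 + delta_r * bump / peak
    F380 <- rep(1000, length(tm))
    F340 <- R * F380
    if (noise_cv > 0) {
      F340 <- F340 * (1 + stats::rnorm(length(tm), 0, noise_cv))
      F380 <- F380 * (1 + stats::rnorm(length(tm), 0, noise_cv))
    }
    tr <- ratio_trace(tm, F340, F380)
    attr(tr, "truth") <- list(r0 = r0, delta_r = delta_r, t_on_s = t_on_s,
                              rise_s = rise_s, fall_s = fall_s)
    tr
  })
}

# Cohort presets. Means follow the study conditions for control and
# diet-induced-obesity (DIO) cohorts; per-cell dispersion of cross-cell
# quantities (resting Ca2+, rates, SFA ratios, membrane potential, release
# amplitudes) uses the cross-cell SD (SEM * sqrt(n)); the pooled handling
# parameters kappa_S and gamma carry only their estimate-level CV.
.PRESETS <- list(
  control = list(
    kappa_s = 497, kappa_s_cv = 18 / 497,
    gamma_per_s = 150, gamma_cv = 3 / 150,
    ca_rest_nM = 19.3, ca_rest_cv = 2.3 * sqrt(11) / 19.3,
    silent_fraction = 8 / 26,
    rate_hz = 3.4, rate_sd_hz = 0.7 * sqrt(26),
    sfa_ratio_firing = 2.0, sfa_ratio_firing_cv = 0.1 * sqrt(27) / 2.0,
    sfa_ratio_silent = 3.6, sfa_ratio_silent_cv = 0.3 * sqrt(22) / 3.6,
    vm_mV = -58.8, vm_sd_mV = 1.1 * sqrt(26),
    fccp_delta_r = 0.020, fccp_delta_r_sd = 0.003 * sqrt(46),
    fccp_n_slices = 10
  ),
  DIO = list(
    kappa_s = 240, kappa_s_cv = 5 / 240,
    gamma_per_s = 111, gamma_cv = 1 / 111,
    ca_rest_nM = 45.8, ca_rest_cv = 7.3 * sqrt(13) / 45.8,
    silent_fraction = 19 / 37,
    rate_hz = 1.7, rate_sd_hz = 0.4 * sqrt(37),
    sfa_ratio_firing = 2.0, sfa_ratio_firing_cv = 0.1 * sqrt(27) / 2.0,
    sfa_ratio_silent = 3.6, sfa_ratio_silent_cv = 0.3 * sqrt(22) / 3.6,
    vm_mV = -64.0, vm_sd_mV = 1.2 * sqrt(37),
    fccp_delta_r = 0.012, fccp_delta_r_sd = 0.001 * sqrt(72),
    fccp_n_slices = 11
  )
)

#' Cohort preset parameters
#'
#' @param preset `"control"` or `"DIO"`.
#' @return Named list of preset means and dispersions.
#' @export
cohort_preset <- function(preset) {
  p <- .PRESETS[[preset]]
  if (is.null(p)) {
    stop(structure(class = c("cabuffer_validation_error", "error", "condition"),
                   list(message = sprintf(
                     "unknown preset '%s'; available: %s", preset,
                     paste(names(.PRESETS), collapse = ", ")),
                     call = sys.call(-1))))
  }
  p
}

.lognormal_around <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cohort
#'
#' Draws per-cell parameters lognormally (normally for membrane potential
#' and, truncated at zero, for release amplitudes) around the preset means
#' and simulates the requested recording type for each cell. Every cell
#' receives a child seed derived from `seed`, so the whole cohort is
#' byte-identical for a fixed seed.
#'
#' @param preset `"control"` or `"DIO"`.
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed for the cohort.
#' @param what Recording type: `"loading"` (whole-cell fura-2 loading
#'   experiments), `"spikes"` (spontaneous trains plus 10-s SFA protocol)
#'   or `"fccp"` (AM-loaded release traces).
#' @param ... Overrides passed to [sim_params()] for `what = "loading"`.
#' @return A list of per-cell records; each carries its ground truth.
#' @export
make_cohort <- function(preset, n_cells, seed,
                        what = c("loading", "spikes", "fccp"), ...) {
  what <- match.arg(what)
  pr <- cohort_preset(preset)
  .assert(n_cells >= 1, "n_cells must be >= 1")
  with_seed(seed, {
    child <- sample.int(2^30, n_cells + 1)
    cells <- switch(what,
      loading = {
        ks <- .lognormal_around(n_cells, pr$kappa_s, pr$kappa_s_cv)
        gm <- .lognormal_around(n_cells, pr$gamma_per_s, pr$gamma_cv)
        rest <- .lognormal_around(n_cells, pr$ca_rest_nM, pr$ca_rest_cv)
        lapply(seq_len(n_cells), function(i) {
          p <- sim_params(kappa_s = ks[i], gamma_per_s = gm[i],
                          ca_rest_nM = rest[i], seed = child[i], ...)
          simulate_cell(p, cohort = preset)
        })
      },
      spikes = {
        silent <- stats::runif(n_cells) < pr$silent_fraction
        # spontaneous rates: silent cells below the 0.5 Hz cutoff, firing
        # cells lognormal with the overall cohort mean preserved
        rate_firing_mean <- max(
          (pr$rate_hz - mean(silent) * 0.15) / max(1 - mean(silent), 1e-6), 0.6)
        y0 <- stats::runif(n_cells, 30, 40)
        ratio_mean <- ifelse(silent, pr$sfa_ratio_silent, pr$sfa_ratio_firing)
        ratio_cv <- ifelse(silent, pr$sfa_ratio_silent_cv, pr$sfa_ratio_firing_cv)
        ratios <- vapply(seq_len(n_cells), function(i) {
          max(.lognormal_around(1, ratio_mean[i], ratio_cv[i]), 1.05)
        }, numeric(1))
        kk <- .lognormal_around(n_cells, 0.5, 0.3)
        vm <- stats::rnorm(n_cells, pr$vm_mV, pr$vm_sd_mV)
        lapply(seq_len(n_cells), function(i) {
          rate <- if (silent[i]) stats::runif(1, 0, 0.45) else {
            max(.lognormal_around(1, rate_firing_mean, 0.6), 0.55)
          }
          spont_times <- sort(stats::runif(stats::rpois(1, rate * 60), 0, 60))
          spont_times <- spont_times[c(TRUE, diff(spont_times) > 0.003)]
          sfa <- simulate_spike_train(y0[i], y0[i] / ratios[i], kk[i],
                                      seed = child[i])
          list(cell_id = sprintf("%s_%02d", preset, i), cohort = preset,
               spont = spike_train(spont_times, 60, baseline_mV = vm[i]),
               sfa = sfa,
               truth = list(silent = silent[i], rate_hz = rate,
                            sfa_ratio = ratios[i], y0_hz = y0[i],
                            k_per_s = kk[i], vm_mV = vm[i]))
        })
      },
      fccp = {
        dr <- pmax(stats::rnorm(n_cells, pr$fccp_delta_r, pr$fccp_delta_r_sd), 0)
        slice <- sort(rep_len(seq_len(pr$fccp_n_slices), n_cells))
        lapply(seq_len(n_cells), function(i) {
          tr <- simulate_fccp_trace(delta_r = dr[i], seed = child[i])
          list(cell_id = sprintf("%s_%02d", preset, i), cohort = preset,
               slice_id = sprintf("slice_%02d", slice[i]), trace = tr,
               truth = attr(tr, "truth"))
        })
      }
    )
    structure(cells, preset = preset, seed = seed, what = what)
  })
}
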