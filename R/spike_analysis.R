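# Activity and excitability metrics from current-clamp recordings: spike
# detection, spontaneous-activity classification, spike-frequency
# adaptation (SFA) fitting, ramp threshold currents and F-I curves.

#' Construct a spike train
#'
#' @param times_s Strictly increasing spike times in seconds, all within
#'   `[0, duration_s)`.
#' @param duration_s Recording duration in seconds (> 0).
#' @param baseline_mV Optional subthreshold membrane-potential baseline.
#' @return An object of class `spike_train` with the mean rate in Hz.
#' @export
spike_train <- function(times_s, duration_s, baseline_mV = NA_real_) {
  .assert(duration_s > 0, "duration must be positive")
  .assert(length(times_s) == 0 ||
            (all(times_s >= 0 & times_s < duration_s) && all(diff(times_s) > 0)),
          "spike times must be strictly increasing within [0, duration)")
  structure(list(times_s = as.numeric(times_s), duration_s = duration_s,
                 rate_hz = length(times_s) / duration_s,
                 baseline_mV = baseline_mV),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d spikes in %.2f s (%.3g Hz)\n",
              length(x$times_s), x$duration_s, x$rate_hz))
  invisible(x)
}

#' Detect action potentials by threshold crossing
#'
#' Deterministic upward-crossing detector: a spike is registered where the
#' voltage crosses `threshold_mV` from below, with subsequent crossings
#' within the refractory period ignored.
#'
#' @param time_s Sample times in seconds (strictly increasing).
#' @param voltage_mV Membrane potential samples in mV.
#' @param threshold_mV Detection threshold (default -20 mV).
#' @param refractory_s Minimum inter-spike separation (default 2 ms).
#' @return A `spike_train`; its baseline is the median of the subthreshold
#'   samples.
#' @export
detect_spikes <- function(time_s, voltage_mV, threshold_mV = -20,
                          refractory_s = 0.002) {
  .assert(length(time_s) == length(voltage_mV), "time and voltage lengths differ")
  .assert(all(diff(time_s) > 0), "time must be strictly increasing")
  above <- voltage_mV >= threshold_mV
  cross <- which(!above[-length(above)] & above[-1]) + 1L
  keep <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (time_s[i] - last >= refractory_s) {
      keep <- c(keep, time_s[i])
      last <- time_s[i]
    }
  }
  dur <- time_s[length(time_s)] - time_s[1]
  sub <- voltage_mV[voltage_mV < threshold_mV]
  spike_train(keep - time_s[1], duration_s = dur,
              baseline_mV = if (length(sub)) stats::median(sub) else NA_real_)
}

#' Classify spontaneous activity
#'
#' A neuron is "not spontaneously active" (NSAN) iff its mean firing rate is
#' strictly below 0.5 Hz; otherwise it is spontaneously active (SAN).
#'
#' @param train A `spike_train`.
#' @param cutoff_hz Classification cutoff (default 0.5 Hz, strict).
#' @return `"NSAN"` or `"SAN"`.
#' @export
classify_activity <- function(train, cutoff_hz = 0.5) {
  .assert(inherits(train, "spike_train"), "train must be a spike_train")
  if (train$rate_hz < cutoff_hz) "NSAN" else "SAN"
}

#' Instantaneous firing-frequency series
#'
#' f_i = 1/(t_{i+1} - t_i), timestamped at the second spike of each
#' interval. Fewer than two spikes yield an empty series.
#'
#' @param train A `spike_train`.
#' @return Data frame with columns `time_s` and `frequency_hz`.
#' @export
instantaneous_frequency <- function(train) {
  .assert(inherits(train, "spike_train"), "train must be a spike_train")
  ts <- train$times_s
  if (length(ts) < 2) {
    return(data.frame(time_s = numeric(0), frequency_hz = numeric(0)))
  }
  data.frame(time_s = ts[-1], frequency_hz = 1 / diff(ts))
}

#' Fit spike-frequency adaptation to an instantaneous-frequency series
#'
#' Least-squares fit of Y(T) = (Y0 - Plateau) * exp(-K T) + Plateau with Y0
#' fixed to the initial instantaneous frequency; Plateau (asymptotic
#' frequency) and K (inverse adaptation time constant) are fitted. T is
#' measured from the stimulus onset.
#'
#' The SFA ratio is defined here as Y0/Plateau (1 = no adaptation; larger
#' values = stronger adaptation; a ratio above 3 marks strong adaptation).
#' When the fitted plateau is at or below 0.1 Hz the cell effectively
#' ceases firing and the ratio is reported as `Inf` with `ceased = TRUE`.
#' A constant-frequency series has an unidentifiable K (`k_identifiable =
#' FALSE`) and ratio exactly 1.
#'
#' @param freq Data frame from [instantaneous_frequency()].
#' @param Y0 Initial instantaneous frequency in Hz (default: first value of
#'   the series).
#' @param t0_s Time at which the fixed Y0 anchors the curve. Defaults to
#'   the timestamp of the first frequency sample; because the
#'   mono-exponential family is shift-invariant this leaves Plateau and K
#'   identical to a fit referenced to the stimulus onset while keeping the
#'   anchor consistent with the sample Y0 is read from.
#' @return An object of class `sfa_fit` with `Y0_hz`, `plateau_hz`,
#'   `k_per_s`, `sfa_ratio`, `ap_count`, `rms_hz` and flags.
#' @export
fit_sfa <- function(freq, Y0 = NULL, t0_s = NULL) {
  .assert(is.data.frame(freq) && all(c("time_s", "frequency_hz") %in% names(freq)),
          "freq must have columns time_s and frequency_hz")
  .assert(nrow(freq) >= 3, "need at least 3 instantaneous-frequency samples")
  if (is.null(Y0)) Y0 <- freq$frequency_hz[1]
  if (is.null(t0_s)) t0_s <- freq$time_s[1]
  T <- freq$time_s - t0_s
  y <- freq$frequency_hz
  ap_count <- nrow(freq) + 1L # spikes spanning the series

  out <- list(Y0_hz = Y0, plateau_hz = NA_real_, k_per_s = NA_real_,
              sfa_ratio = NA_real_, ap_count = ap_count, rms_hz = NA_real_,
              k_identifiable = TRUE, ceased = FALSE)
  if (stats::sd(y) < 1e-9 * max(1, abs(mean(y)))) {
    out$plateau_hz <- mean(y)
    out$k_per_s <- NA_real_
    out$k_identifiable <- FALSE
    out$sfa_ratio <- Y0 / out$plateau_hz
    out$rms_hz <- 0
    return(structure(out, class = "sfa_fit"))
  }
  span <- max(T) - min(T)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ (Y0 - plateau) * exp(-k * T) + plateau,
      start = list(plateau = max(min(y), 0.2), k = 3 / max(span, 1e-6)),
      lower = c(plateau = 0, k = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out$reason <- "fit divergence"
    return(structure(out, class = "sfa_fit"))
  }
  cf <- stats::coef(fit)
  out$plateau_hz <- unname(cf[["plateau"]])
  out$k_per_s <- unname(cf[["k"]])
  out$rms_hz <- sqrt(mean(stats::resid(fit)^2))
  if (out$plateau_hz <= 0.1) {
    out$ceased <- TRUE
    out$sfa_ratio <- Inf
  } else {
    out$sfa_ratio <- Y0 / out$plateau_hz
  }
  structure(out, class = "sfa_fit")
}

#' @export
print.sfa_fit <- function(x, ...) {
  cat(sprintf(
    "SFA fit: Y0 %.3g Hz, plateau %.3g Hz, K %.3g 1/s, ratio %.3g (%d APs)\n",
    x$Y0_hz, x$plateau_hz, x$k_per_s, x$sfa_ratio, x$ap_count))
  invisible(x)
}

#' Threshold current from an ascending current ramp
#'
#' Returns the injected current at the time of the first detected action
#' potential during a ramp. If no spike occurs the threshold is undefined
#' and flagged.
#'
#' @param time_s,voltage_mV,current_pA Simultaneously sampled traces; the
#'   current must be non-decreasing.
#' @param threshold_mV,refractory_s Spike-detection parameters.
#' @return A list with `found`, `i_threshold_pA` and `t_first_spike_s`.
#' @export
threshold_current_from_ramp <- function(time_s, voltage_mV, current_pA,
                                        threshold_mV = -20, refractory_s = 0.002) {
  .assert(length(time_s) == length(current_pA), "time and current lengths differ")
  .assert(all(diff(current_pA) >= 0), "ramp current must be non-decreasing")
  train <- detect_spikes(time_s, voltage_mV, threshold_mV, refractory_s)
  if (length(train$times_s) == 0) {
    return(list(found = FALSE, i_threshold_pA = NA_real_,
                t_first_spike_s = NA_real_))
  }
  t_first <- train$times_s[1] + time_s[1]
  list(found = TRUE,
       i_threshold_pA = stats::approx(time_s, current_pA, xout = t_first)$y,
       t_first_spike_s = t_first)
}

#' F-I curve from current-step responses
#'
#' Counts action potentials per current step. Duplicate current values are
#' averaged (noted in the result). A linear gain estimate (spikes per pA)
#' is fitted over the suprathreshold steps.
#'
#' @param steps A list whose elements are lists with fields `current_pA`,
#'   `time_s`, `voltage_mV`.
#' @param threshold_mV,refractory_s Spike-detection parameters.
#' @return An object of class `excitability_result`: data frame `fi` with
#'   `current_pA` and `ap_count`, a `gain_hz_per_pA` estimate (NA when
#'   fewer than two suprathreshold steps), and `duplicates_averaged`.
#' @export
fi_curve <- function(steps, threshold_mV = -20, refractory_s = 0.002) {
  .assert(is.list(steps) && length(steps) >= 2, "need at least 2 current steps")
  raw <- do.call(rbind, lapply(steps, function(s) {
    tr <- detect_spikes(s$time_s, s$voltage_mV, threshold_mV, refractory_s)
    data.frame(current_pA = s$current_pA, ap_count = length(tr$times_s))
  }))
  .assert(length(unique(raw$current_pA)) >= 2, "need at least 2 distinct currents")
  dup <- anyDuplicated(raw$current_pA) > 0
  fi <- stats::aggregate(ap_count ~ current_pA, data = raw, FUN = mean)
  fi <- fi[order(fi$current_pA), ]
  rownames(fi) <- NULL
  supra <- fi[fi$ap_count > 0, ]
  gain <- if (nrow(supra) >= 2) {
    unname(stats::coef(stats::lm(ap_count ~ current_pA, data = supra))[2])
  } else NA_real_
  structure(list(fi = fi, gain_per_pA = gain, duplicates_averaged = dup),
            class = "excitability_result")
}

#' @export
print.excitability_result <- function(x, ...) {
  cat(sprintf("F-I curve over %d currents; gain %.4g spikes/pA%s\n",
              nrow(x$fi), x$gain_per_pA,
              if (x$duplicates_averaged) " (duplicate currents averaged)" else ""))
  print(x$fi, row.names = FALSE)
  invisible(x)
}
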