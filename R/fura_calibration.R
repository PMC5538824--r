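# Ratiometric fura-2 calibration: conversion between background-corrected
# 340/380 nm fluorescence ratios and free Ca2+ concentrations, and tracking
# of the intracellular dye concentration from the isosbestic (360 nm)
# channel during whole-cell loading.

#' Construct a fluorescence ratio trace
#'
#' Holds background-corrected fluorescence time series at 340 and 380 nm
#' excitation (plus the optional 360 nm isosbestic channel) for one cell.
#' The ratio R = F340/F380 is computed frame-wise and defined only where
#' F380 > 0.
#'
#' @param time_s Strictly increasing sample times in seconds.
#' @param F340,F380 Background-corrected fluorescence in ADUs.
#' @param F360 Optional isosbestic-channel fluorescence in ADUs.
#' @return An object of class `ratio_trace`.
#' @export
ratio_trace <- function(time_s, F340, F380, F360 = NULL) {
  n <- length(time_s)
  .assert(n >= 1, "trace must contain at least one sample")
  .assert(length(F340) == n && length(F380) == n,
          "time, F340 and F380 must have equal lengths")
  .assert(is.null(F360) || length(F360) == n,
          "F360 must match the trace length")
  .assert(all(is.finite(time_s)) && all(diff(time_s) > 0),
          "time must be finite and strictly increasing")
  ratio <- ifelse(F380 > 0, F340 / F380, NA_real_)
  structure(list(time_s = as.numeric(time_s), F340 = as.numeric(F340),
                 F380 = as.numeric(F380),
                 F360 = if (is.null(F360)) NULL else as.numeric(F360),
                 ratio = ratio),
            class = "ratio_trace")
}

#' @export
as.data.frame.ratio_trace <- function(x, ...) {
  df <- data.frame(time_s = x$time_s, F340 = x$F340, F380 = x$F380)
  if (!is.null(x$F360)) df$F360 <- x$F360
  df$ratio <- x$ratio
  df
}

#' @export
print.ratio_trace <- function(x, ...) {
  cat(sprintf("ratio_trace: %d samples over %.1f s%s\n", length(x$time_s),
              diff(range(x$time_s)),
              if (is.null(x$F360)) "" else " (with isosbestic channel)"))
  invisible(x)
}

#' Construct a ratiometric calibration
#'
#' Bundles the rig-specific calibration of the fura-2 ratio signal: the
#' ratios at zero (`R_min`) and saturating (`R_max`) Ca2+, the chemical
#' dissociation constant of the dye, and the 380 nm dynamic range
#' F380,min/F380,max (fluorescence of the Ca-free over the Ca-saturated
#' dye). The effective dissociation constant K_d,eff = K_d * dynamic range
#' is the constant entering the ratio equation; the chemical K_d is the one
#' entering Ca2+-binding-ratio calculations.
#'
#' @param R_min Ratio at ~0 Ca2+.
#' @param R_max Ratio at saturating Ca2+; must exceed `R_min`.
#' @param Kd_fura_uM Chemical dissociation constant of fura-2 in uM.
#' @param dyn_range F380,min/F380,max; ignored if `Kd_eff_uM` is given.
#' @param Kd_eff_uM Effective dissociation constant in uM (overrides
#'   `dyn_range` when supplied directly, e.g. from [effective_kd()]).
#' @return An object of class `calibration_result`.
#' @export
calibration_result <- function(R_min, R_max, Kd_fura_uM, dyn_range = NULL,
                               Kd_eff_uM = NULL) {
  .assert(R_min > 0 && R_max > 0 && R_min < R_max,
          "calibration requires 0 < R_min < R_max")
  .assert(Kd_fura_uM > 0, "Kd_fura_uM must be positive")
  if (is.null(Kd_eff_uM)) {
    .assert(!is.null(dyn_range) && dyn_range > 0,
            "supply either dyn_range or Kd_eff_uM")
    Kd_eff_uM <- Kd_fura_uM * dyn_range
  } else {
    dyn_range <- Kd_eff_uM / Kd_fura_uM
  }
  .assert(Kd_eff_uM > 0, "effective Kd must be positive")
  structure(list(R_min = R_min, R_max = R_max, Kd_fura_uM = Kd_fura_uM,
                 dyn_range = dyn_range, Kd_eff_uM = Kd_eff_uM),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "fura-2 calibration: R_min %.3g, R_max %.3g, Kd %.3g uM, Kd_eff %.3g uM\n",
    x$R_min, x$R_max, x$Kd_fura_uM, x$Kd_eff_uM))
  invisible(x)
}

#' Effective dissociation constant from a defined-Ca2+ ratio measurement
#'
#' Inverts the ratio equation at a solution of known free Ca2+ to obtain the
#' rig-specific effective dissociation constant:
#' K_d,eff = Ca_def * (R_max - R_def) / (R_def - R_min). The result is
#' independent of the dye concentration.
#'
#' @param R_def Measured ratio in the defined-Ca2+ solution.
#' @param R_min,R_max Calibration limit ratios.
#' @param ca_def_uM Free Ca2+ of the defined solution in uM.
#' @return Effective dissociation constant in uM.
#' @examples
#' effective_kd(R_def = 1.0, R_min = 0.3, R_max = 6.0, ca_def_uM = 0.35)
#' @export
effective_kd <- function(R_def, R_min, R_max, ca_def_uM) {
  .assert(R_min < R_max, "R_min must be below R_max")
  .assert(ca_def_uM > 0, "ca_def_uM must be positive")
  if (!(R_def > R_min && R_def < R_max)) {
    stop(structure(class = c("cabuffer_calibration_range_error", "error",
                             "condition"),
                   list(message = sprintf(
                     "R_def = %.4g outside the open calibration range (%.4g, %.4g)",
                     R_def, R_min, R_max), call = sys.call(-1))))
  }
  ca_def_uM * (R_max - R_def) / (R_def - R_min)
}

#' Convert fluorescence ratios to free Ca2+ concentrations
#'
#' [Ca2+] = K_d,eff * (R - R_min) / (R_max - R). Ratios at or above `R_max`
#' are a saturation error; ratios slightly below `R_min` (noise around the
#' zero point) are clipped to 0 nM with a warning so that resting-level
#' estimates remain robust.
#'
#' @param R Ratio value(s).
#' @param cal A `calibration_result`.
#' @return Free Ca2+ in nM (vectorized over `R`).
#' @export
ratio_to_ca <- function(R, cal) {
  .assert(inherits(cal, "calibration_result"), "cal must be a calibration_result")
  if (any(R >= cal$R_max, na.rm = TRUE)) {
    stop(structure(class = c("cabuffer_saturation_error", "error", "condition"),
                   list(message = sprintf(
                     "ratio at or above R_max = %.4g: indicator saturated",
                     cal$R_max), call = sys.call(-1))))
  }
  below <- !is.na(R) & R < cal$R_min
  if (any(below)) {
    warning(sprintf("%d ratio value(s) below R_min clipped to 0 nM", sum(below)))
  }
  ca <- cal$Kd_eff_uM * 1000 * (R - cal$R_min) / (cal$R_max - R)
  ca[below] <- 0
  ca
}

#' Convert free Ca2+ concentrations to fluorescence ratios
#'
#' Inverse of [ratio_to_ca()], used by the forward simulator:
#' R = (R_min K_d,eff + Ca R_max) / (K_d,eff + Ca), mapping [0, Inf) onto
#' [R_min, R_max).
#'
#' @param ca_nM Free Ca2+ in nM (vectorized).
#' @param cal A `calibration_result`.
#' @return Ratio value(s).
#' @export
ca_to_ratio <- function(ca_nM, cal) {
  .assert(inherits(cal, "calibration_result"), "cal must be a calibration_result")
  .assert(all(ca_nM >= 0, na.rm = TRUE), "ca_nM must be non-negative")
  kd_nM <- cal$Kd_eff_uM * 1000
  (cal$R_min * kd_nM + ca_nM * cal$R_max) / (kd_nM + ca_nM)
}

#' Intracellular fura-2 concentration from the isosbestic channel
#'
#' At the 360 nm isosbestic excitation wavelength fura-2 fluorescence is
#' independent of Ca2+, so the signal is proportional to the dye
#' concentration. The per-rig scale factor is obtained by imaging the
#' pipette solution of known dye concentration under identical optics.
#'
#' @param F360 Isosbestic fluorescence in ADUs (vectorized).
#' @param cell_scale ADUs per uM of fura-2; must be positive.
#' @return Fura-2 concentration in uM.
#' @export
fura_from_isosbestic <- function(F360, cell_scale) {
  .assert(is.numeric(cell_scale) && length(cell_scale) == 1 && cell_scale > 0,
          "cell_scale must be a positive scalar (ADU per uM)")
  F360 / cell_scale
}

#' Fit a whole-cell dye loading curve
#'
#' Least-squares fit of the pipette-loading model
#' c(t) = c_inf * (1 - exp(-t/tau_fill)) to dye-concentration samples
#' (typically one per 30 s frame at 360 nm excitation). Degenerate input
#' (flat or non-increasing signal) is flagged rather than fitted; the raw
#' points are always preserved in the result.
#'
#' @param time_s Sample times in seconds (time 0 = seal break).
#' @param conc_uM Dye concentration samples in uM.
#' @return An object of class `loading_fit` with fields `c_inf_uM`,
#'   `tau_fill_s`, `rms_uM`, `converged` and the raw data.
#' @export
fit_loading_curve <- function(time_s, conc_uM) {
  .assert(length(time_s) == length(conc_uM), "time and concentration lengths differ")
  .assert(length(time_s) >= 4, "need at least 4 loading samples")
  out <- list(time_s = time_s, conc_uM = conc_uM, c_inf_uM = NA_real_,
              tau_fill_s = NA_real_, rms_uM = NA_real_, converged = FALSE)
  rng <- diff(range(conc_uM))
  if (!is.finite(rng) || rng <= .Machine$double.eps * max(1, abs(max(conc_uM)))) {
    out$reason <- "degenerate: constant concentration samples"
    return(structure(out, class = "loading_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      conc_uM ~ c_inf * (1 - exp(-time_s / tau)),
      start = list(c_inf = max(conc_uM), tau = max(diff(range(time_s)) / 3, 1)),
      lower = c(c_inf = 0, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out$reason <- "fit failure"
    return(structure(out, class = "loading_fit"))
  }
  cf <- stats::coef(fit)
  out$c_inf_uM <- unname(cf[["c_inf"]])
  out$tau_fill_s <- unname(cf[["tau"]])
  out$rms_uM <- sqrt(mean(stats::resid(fit)^2))
  out$converged <- TRUE
  structure(out, class = "loading_fit")
}

#' @export
print.loading_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("fura-2 loading: c_inf %.4g uM, tau_fill %.4g s (RMS %.3g uM)\n",
                x$c_inf_uM, x$tau_fill_s, x$rms_uM))
  } else {
    cat(sprintf("fura-2 loading fit not converged (%s); %d raw points kept\n",
                x$reason, length(x$time_s)))
  }
  invisible(x)
}
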