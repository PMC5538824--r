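# The added-buffer estimation of endogenous Ca2+ handling. A cell is loaded
# through the patch pipette with increasing amounts of the indicator dye,
# which acts as a known exogenous Ca2+ buffer. In the linear single-
# compartment model the decay time constant of an evoked transient grows
# linearly with the dye's incremental Ca2+-binding ratio kappa_B:
#
#   tau_transient = (1 + kappa_S + kappa_B) / gamma
#
# so an ordinary least-squares line through (kappa_B, tau) points yields the
# endogenous binding ratio kappa_S (negative x-intercept minus one), the
# extrusion rate gamma (inverse slope) and the endogenous decay time
# constant tau_endo (y-intercept). Uncertainty comes from a fixed-x
# (residual) bootstrap of the linear fit.

#' Incremental Ca2+-binding ratio of the indicator dye
#'
#' kappa_B = B_total * K_d / (Ca_rest + K_d)^2: the change in dye-bound Ca2+
#' per change in free Ca2+, evaluated at the resting level. Uses the
#' chemical dissociation constant of the dye (not the effective constant of
#' the ratio equation).
#'
#' @param fura_total_uM Total dye concentration in uM (>= 0).
#' @param kd_fura_uM Chemical K_d of the dye for Ca2+ in uM.
#' @param ca_rest_uM Resting free Ca2+ in uM.
#' @return Dimensionless binding ratio (vectorized over the inputs).
#' @examples
#' kappa_b(100, 0.24, 0.02) # 355.03
#' @export
kappa_b <- function(fura_total_uM, kd_fura_uM, ca_rest_uM) {
  .assert(all(fura_total_uM >= 0), "total dye concentration must be >= 0")
  .assert(all(kd_fura_uM > 0), "kd_fura_uM must be positive")
  .assert(all(ca_rest_uM > 0), "ca_rest_uM must be positive")
  fura_total_uM * kd_fura_uM / (ca_rest_uM + kd_fura_uM)^2
}

#' Fit a mono-exponential decay to one evoked Ca2+ transient
#'
#' Fits Ca(t) = baseline + A * exp(-(t - t_peak)/tau) from the transient
#' peak onward and applies the acceptance rule: positive amplitude, tau
#' within [0.05, 60] s, and residual RMS below 20% of the amplitude.
#' Rejected transients are returned flagged, never silently dropped.
#'
#' @param time_s,ca_nM The Ca2+ time series (nM).
#' @param stim_time_s Stimulus onset in seconds.
#' @param window_s Fit window after the peak in seconds; should span at
#'   least twice the expected decay time constant.
#' @param baseline_s Span before the stimulus averaged for the resting
#'   baseline (default 5 s).
#' @param peak_search_s Window after the stimulus searched for the peak.
#' @return An object of class `transient_fit` with fields `onset_s`,
#'   `t_peak_s`, `amplitude_nM`, `tau_s`, `baseline_nM`, `rms_nM`,
#'   `accepted` and `reason`.
#' @export
fit_transient_decay <- function(time_s, ca_nM, stim_time_s, window_s,
                                baseline_s = 5, peak_search_s = 1) {
  .assert(length(time_s) == length(ca_nM), "time and Ca lengths differ")
  out <- list(onset_s = stim_time_s, t_peak_s = NA_real_,
              amplitude_nM = NA_real_, tau_s = NA_real_,
              baseline_nM = NA_real_, rms_nM = NA_real_,
              accepted = FALSE, reason = NULL)
  pre <- time_s >= (stim_time_s - baseline_s) & time_s < stim_time_s
  .assert(any(pre), "no samples in the pre-stimulus baseline window")
  out$baseline_nM <- mean(ca_nM[pre])

  search <- time_s >= stim_time_s & time_s <= stim_time_s + peak_search_s
  .assert(any(search), "no samples in the peak-search window")
  i_peak <- which(search)[which.max(ca_nM[search])]
  out$t_peak_s <- time_s[i_peak]
  amp0 <- ca_nM[i_peak] - out$baseline_nM

  dec <- time_s >= out$t_peak_s & time_s <= out$t_peak_s + window_s
  td <- time_s[dec] - out$t_peak_s
  yd <- ca_nM[dec]
  if (amp0 <= 0 || sum(dec) < 4) {
    out$reason <- "no resolvable peak above baseline"
    return(structure(out, class = "transient_fit"))
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      yd ~ b + A * exp(-td / tau),
      start = list(b = out$baseline_nM, A = amp0, tau = max(window_s / 4, 0.1)),
      lower = c(b = -Inf, A = 0, tau = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out$reason <- "fit divergence"
    return(structure(out, class = "transient_fit"))
  }
  cf <- stats::coef(fit)
  out$amplitude_nM <- unname(cf[["A"]])
  out$tau_s <- unname(cf[["tau"]])
  out$baseline_nM <- unname(cf[["b"]])
  out$rms_nM <- sqrt(mean(stats::resid(fit)^2))

  if (out$amplitude_nM <= 0) {
    out$reason <- "non-positive amplitude"
  } else if (out$tau_s < 0.05 || out$tau_s > 60) {
    out$reason <- sprintf("tau = %.3g s outside [0.05, 60] s", out$tau_s)
  } else if (out$rms_nM > 0.2 * out$amplitude_nM) {
    out$reason <- "relative fit RMS above 20% of amplitude"
  } else {
    out$accepted <- TRUE
  }
  structure(out, class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf(
      "transient at %.1f s: A %.4g nM, tau %.4g s, baseline %.4g nM (accepted)\n",
      x$onset_s, x$amplitude_nM, x$tau_s, x$baseline_nM))
  } else {
    cat(sprintf("transient at %.1f s: rejected (%s)\n", x$onset_s, x$reason))
  }
  invisible(x)
}

#' Collect (kappa_B, tau) points from one loading experiment
#'
#' For each stimulus in a whole-cell loading recording: the dye
#' concentration at the transient onset comes from the isosbestic channel,
#' the resting Ca2+ from the pre-stimulus baseline via the ratio equation,
#' and the decay time constant from a mono-exponential fit. One point per
#' accepted transient.
#'
#' @param trace A `ratio_trace` with an isosbestic (F360) channel, or a
#'   `synthetic_cell` (its trace is used).
#' @param cal A `calibration_result`.
#' @param cell_scale ADU per uM conversion for the isosbestic channel.
#' @param stim_times_s Stimulus onsets in seconds.
#' @param window_s Decay-fit window (default: up to the next stimulus or
#'   the end of the trace, minus the baseline span).
#' @param baseline_s Pre-stimulus baseline span in seconds.
#' @param cohort,cell_id Optional labels carried into the output.
#' @return A data frame of class `kappa_tau_points` with one row per
#'   stimulus, with columns `kappa_b`, `tau_s`, `amplitude_nM`,
#'   `ca_rest_nM`, `fura_uM`, `stim_time_s`, `accepted` and the labels.
#'   The attribute `n_rejected` counts rejected transients.
#' @export
collect_kappa_tau <- function(trace, cal, cell_scale, stim_times_s,
                              window_s = NULL, baseline_s = 5,
                              cohort = NA_character_, cell_id = NA_character_) {
  if (inherits(trace, "synthetic_cell")) trace <- trace$trace
  .assert(inherits(trace, "ratio_trace"), "trace must be a ratio_trace")
  if (is.null(trace$F360)) {
    stop(structure(class = c("cabuffer_missing_isosbestic", "error", "condition"),
                   list(message = paste(
                     "no isosbestic (F360) channel: the dye concentration,",
                     "and hence kappa_B, cannot be computed"),
                     call = sys.call(-1))))
  }
  stim_times_s <- sort(stim_times_s)
  ca <- suppressWarnings(ratio_to_ca(trace$ratio, cal))
  fura <- fura_from_isosbestic(trace$F360, cell_scale)

  rows <- lapply(seq_along(stim_times_s), function(j) {
    t_on <- stim_times_s[j]
    w <- if (!is.null(window_s)) window_s else {
      t_next <- if (j < length(stim_times_s)) stim_times_s[j + 1] else max(trace$time_s)
      max(t_next - t_on - baseline_s, 1)
    }
    tf <- fit_transient_decay(trace$time_s, ca, t_on, window_s = w,
                              baseline_s = baseline_s)
    # dye concentration at onset: isosbestic mean over the last second
    # before the stimulus (the dye is still loading, so a long window
    # would lag the onset concentration)
    near <- trace$time_s >= (t_on - min(1, baseline_s)) & trace$time_s < t_on
    fura_on <- mean(fura[near])
    pre <- trace$time_s >= (t_on - baseline_s) & trace$time_s < t_on
    ca_rest_uM <- mean(ca[pre]) / 1000
    kb <- if (ca_rest_uM > 0) {
      kappa_b(fura_on, cal$Kd_fura_uM, ca_rest_uM)
    } else NA_real_
    data.frame(kappa_b = kb, tau_s = tf$tau_s, amplitude_nM = tf$amplitude_nM,
               ca_rest_nM = ca_rest_uM * 1000, fura_uM = fura_on,
               stim_time_s = t_on, accepted = tf$accepted && is.finite(kb),
               cohort = cohort, cell_id = cell_id, stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows)
  out <- pts[pts$accepted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(!pts$accepted)
  class(out) <- c("kappa_tau_points", class(out))
  out
}

#' Fit the added-buffer line and extract the Ca2+-handling parameters
#'
#' Ordinary least squares tau = beta0 + beta1 * kappa_B. The parameters
#' follow from the fit algebra: kappa_S = beta0/beta1 - 1 (negative
#' x-intercept minus one), gamma = 1/beta1, tau_endo = beta0, so that
#' tau_endo = (1 + kappa_S)/gamma holds exactly.
#'
#' @param points A data frame with columns `kappa_b` and `tau_s` (e.g. from
#'   [collect_kappa_tau()], possibly pooled over cells).
#' @return An object of class `buffer_fit` with the point estimates, the
#'   underlying `lm` fit, and `n` points. Fits with two points are exact
#'   interpolations flagged `low_n`.
#' @examples
#' kb <- c(0, 150, 300, 600)
#' fit_added_buffer(data.frame(kappa_b = kb, tau_s = (1 + 497 + kb) / 150))
#' @export
fit_added_buffer <- function(points) {
  .assert(is.data.frame(points) && all(c("kappa_b", "tau_s") %in% names(points)),
          "points must contain columns kappa_b and tau_s")
  pts <- points[is.finite(points$kappa_b) & is.finite(points$tau_s), ]
  n <- nrow(pts)
  .assert(n >= 2, "need at least 2 (kappa_B, tau) points")
  .assert(diff(range(pts$kappa_b)) > 0, "kappa_B values have no spread")
  fit <- stats::lm(tau_s ~ kappa_b, data = pts)
  b <- stats::coef(fit)
  beta0 <- unname(b[1]); beta1 <- unname(b[2])
  if (beta1 <= 0) {
    cond <- structure(class = c("cabuffer_degenerate_fit", "error", "condition"),
                      list(message = sprintf(
                        "non-physical fit: slope %.4g <= 0 (intercept %.4g)",
                        beta1, beta0), call = sys.call(-1),
                        coefficients = b))
    stop(cond)
  }
  structure(list(
    kappa_s = beta0 / beta1 - 1,
    gamma_per_s = 1 / beta1,
    tau_endo_s = beta0,
    slope_s = beta1,
    intercept_s = beta0,
    x_intercept = -beta0 / beta1,
    n = n,
    low_n = n < 3,
    lm = fit,
    points = pts
  ), class = "buffer_fit")
}

#' @export
print.buffer_fit <- function(x, ...) {
  cat(sprintf(
    "added-buffer fit (n = %d%s): kappa_S %.4g, gamma %.4g 1/s, tau_endo %.4g s\n",
    x$n, if (x$low_n) ", low n" else "", x$kappa_s, x$gamma_per_s, x$tau_endo_s))
  invisible(x)
}

#' Pointwise 95% confidence band of the added-buffer line
#'
#' @param fit A `buffer_fit`.
#' @param kappa_grid kappa_B values at which to evaluate the band.
#' @param level Confidence level (default 0.95).
#' @return Data frame with `kappa_b`, `fit_s`, `lwr_s`, `upr_s`.
#' @export
added_buffer_band <- function(fit, kappa_grid, level = 0.95) {
  .assert(inherits(fit, "buffer_fit"), "fit must be a buffer_fit")
  pr <- stats::predict(fit$lm, newdata = data.frame(kappa_b = kappa_grid),
                       interval = "confidence", level = level)
  data.frame(kappa_b = kappa_grid, fit_s = pr[, "fit"],
             lwr_s = pr[, "lwr"], upr_s = pr[, "upr"])
}

#' Fixed-x residual bootstrap of the added-buffer fit
#'
#' Keeps the kappa_B design fixed, resamples the fitted residuals with
#' replacement onto the fitted values, and refits the line. Replicates with
#' a non-positive slope are recorded as invalid and excluded (counted in
#' `n_invalid`). With zero residuals every replicate equals the point
#' estimate.
#'
#' @param fit A `buffer_fit`.
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param seed Optional integer seed; fixing it makes the distributions
#'   exactly reproducible.
#' @return An object of class `buffer_boot`: a data frame of replicate
#'   (`kappa_s`, `gamma_per_s`, `tau_endo_s`) triples with attributes
#'   `n_invalid` and `seed`.
#' @export
bootstrap_added_buffer <- function(fit, n_boot = 1000, seed = NULL) {
  .assert(inherits(fit, "buffer_fit"), "fit must be a buffer_fit")
  x <- fit$points$kappa_b
  fitted <- stats::fitted(fit$lm)
  res <- stats::resid(fit$lm)
  n <- length(x)
  X <- cbind(1, x)
  reps <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    t(vapply(seq_len(n_boot), function(b) {
      y_star <- fitted + res[idx[, b]]
      stats::lm.fit(X, y_star)$coefficients
    }, numeric(2)))
  })
  beta0 <- reps[, 1]; beta1 <- reps[, 2]
  valid <- beta1 > 0
  out <- data.frame(kappa_s = beta0[valid] / beta1[valid] - 1,
                    gamma_per_s = 1 / beta1[valid],
                    tau_endo_s = beta0[valid])
  attr(out, "n_invalid") <- sum(!valid)
  attr(out, "seed") <- seed
  class(out) <- c("buffer_boot", class(out))
  out
}

#' Compare two bootstrap parameter distributions on the log scale
#'
#' Natural-log transforms both distributions (to bring the skewed bootstrap
#' distributions closer to a Gaussian) and applies an unpaired two-sided
#' t-test. Back-transformed (geometric) means are reported.
#'
#' @param dist_a,dist_b Numeric vectors of strictly positive replicates.
#' @param var_equal Passed to [stats::t.test()] (default TRUE, the classical
#'   unpaired t-test).
#' @return A list with `t`, `df`, `p`, geometric means and the log-scale
#'   means and SDs of both samples.
#' @export
compare_parameter_distributions <- function(dist_a, dist_b, var_equal = TRUE) {
  bad_a <- which(!(dist_a > 0)); bad_b <- which(!(dist_b > 0))
  if (length(bad_a) || length(bad_b)) {
    stop(structure(class = c("cabuffer_validation_error", "error", "condition"),
                   list(message = sprintf(
                     "non-positive values cannot be log-transformed (A: %s; B: %s)",
                     paste(utils::head(bad_a, 5), collapse = ","),
                     paste(utils::head(bad_b, 5), collapse = ",")),
                     call = sys.call(-1))))
  }
  la <- log(dist_a); lb <- log(dist_b)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    # both point masses: identical -> p = 1, otherwise perfectly separated
    p <- if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
    return(list(t = if (p == 1) 0 else Inf, df = NA_real_, p = p,
                geom_mean_a = exp(mean(la)), geom_mean_b = exp(mean(lb)),
                log_mean_a = mean(la), log_mean_b = mean(lb),
                log_sd_a = 0, log_sd_b = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(la, lb, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       geom_mean_a = exp(mean(la)), geom_mean_b = exp(mean(lb)),
       log_mean_a = mean(la), log_mean_b = mean(lb),
       log_sd_a = stats::sd(la), log_sd_b = stats::sd(lb),
       degenerate = FALSE)
}

#' Plot an added-buffer fit with its confidence band
#'
#' Scatter of (kappa_B, tau) points with the fitted line and the pointwise
#' 95% confidence band, extended to the negative x-intercept.
#'
#' @param x A `buffer_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.buffer_fit <- function(x, ...) {
  grid <- seq(min(0, x$x_intercept) * 1.05, max(x$points$kappa_b) * 1.05,
              length.out = 200)
  band <- added_buffer_band(x, grid)
  graphics::plot(x$points$kappa_b, x$points$tau_s,
                 xlab = expression(kappa[B]), ylab = expression(tau[transient] ~ "(s)"),
                 xlim = range(grid), ylim = c(0, max(band$upr_s, x$points$tau_s)),
                 pch = 16, ...)
  graphics::polygon(c(band$kappa_b, rev(band$kappa_b)),
                    c(band$lwr_s, rev(band$upr_s)),
                    col = grDevices::adjustcolor("steelblue", 0.25), border = NA)
  graphics::lines(band$kappa_b, band$fit_s, col = "steelblue", lwd = 2)
  graphics::abline(h = 0, v = 0, col = "grey60", lty = 3)
  graphics::points(x$x_intercept, 0, pch = 4, col = "firebrick")
  invisible(x)
}
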