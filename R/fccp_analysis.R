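# Quantification of FCCP-evoked mitochondrial Ca2+ release from AM-loaded
# fura-2 ratio traces. With bulk (AM) loading the background is not
# determinable and no absolute calibration is possible, so the primary
# statistic is the raw-ratio change Delta(F340/F380) above the
# pre-application baseline; baseline-normalized traces are used for
# visualization and comparison of time courses.

#' Normalize a ratio trace to its pre-application baseline
#'
#' Divides the ratio by the mean over the baseline window immediately
#' preceding the application, so the normalized trace has baseline mean
#' exactly 1 and is invariant to common-gain changes of both wavelengths.
#'
#' @param trace A `ratio_trace`.
#' @param t_on_s Application onset in seconds.
#' @param baseline_span_s Length of the baseline window before `t_on_s`.
#' @return An object of class `normalized_ratio_trace` with fields
#'   `time_s`, `ratio`, `normalized`, `R0` and the application onset.
#' @export
normalize_trace <- function(trace, t_on_s, baseline_span_s = 60) {
  .assert(inherits(trace, "ratio_trace"), "trace must be a ratio_trace")
  base <- trace$time_s >= (t_on_s - baseline_span_s) & trace$time_s < t_on_s
  .assert(any(base), "baseline window contains no samples")
  R0 <- mean(trace$ratio[base])
  .assert(is.finite(R0) && R0 > 0, "baseline ratio must be positive")
  structure(list(time_s = trace$time_s, ratio = trace$ratio,
                 normalized = trace$ratio / R0, R0 = R0,
                 t_on_s = t_on_s, baseline_span_s = baseline_span_s),
            class = "normalized_ratio_trace")
}

#' FCCP release amplitude of one cell
#'
#' Delta R = (peak of the smoothed ratio within the search window) minus
#' the pre-application baseline ratio, in raw-ratio units. The search
#' window runs from the application onset to `search_extra_s` past the end
#' of the application, since release typically outlasts a brief
#' application. A centered moving average (default 5 samples) suppresses
#' single-frame noise before the peak pick. Non-responding cells yield
#' Delta R near or below zero and are retained.
#'
#' @param trace A `ratio_trace`.
#' @param t_on_s,t_off_s Application window in seconds.
#' @param baseline_span_s Baseline window length before `t_on_s`.
#' @param search_extra_s Extension of the peak search past `t_off_s`
#'   (default 300 s).
#' @param smooth_k Moving-average window in samples (default 5).
#' @param cell_id,slice_id Optional labels carried into the result.
#' @return An object of class `release_amplitude` with `delta_r`,
#'   `peak_time_s`, `R0` and the labels.
#' @export
release_amplitude <- function(trace, t_on_s, t_off_s, baseline_span_s = 60,
                              search_extra_s = 300, smooth_k = 5,
                              cell_id = NA_character_, slice_id = NA_character_) {
  .assert(inherits(trace, "ratio_trace"), "trace must be a ratio_trace")
  .assert(t_off_s > t_on_s, "application window must have positive length")
  .assert(t_on_s > min(trace$time_s) && t_on_s < max(trace$time_s),
          "application window lies outside the trace")
  base <- trace$time_s >= (t_on_s - baseline_span_s) & trace$time_s < t_on_s
  .assert(any(base), "baseline window contains no samples")
  R0 <- mean(trace$ratio[base])
  sm <- moving_average(trace$ratio, smooth_k)
  win <- trace$time_s >= t_on_s & trace$time_s <= (t_off_s + search_extra_s)
  .assert(any(win), "peak search window contains no samples")
  i <- which(win)[which.max(sm[win])]
  structure(list(delta_r = sm[i] - R0, peak_time_s = trace$time_s[i],
                 R0 = R0, cell_id = cell_id, slice_id = slice_id),
            class = "release_amplitude")
}

#' @export
print.release_amplitude <- function(x, ...) {
  cat(sprintf("FCCP release: Delta R %.4g (peak at %.1f s, baseline %.4g)\n",
              x$delta_r, x$peak_time_s, x$R0))
  invisible(x)
}

#' Aggregate release amplitudes by cohort and compare two cohorts
#'
#' Per-cohort mean, SEM, number of cells and number of slices, with cells
#' pooled across slices as the statistical unit. When exactly two cohorts
#' are present, an unpaired t-test (default) and a Mann-Whitney test are
#' both reported.
#'
#' @param amplitudes Data frame with columns `cohort`, `delta_r` and
#'   optionally `cell_id`, `slice_id`; or a list of `release_amplitude`
#'   objects plus a `cohort` vector.
#' @param primary Which test supplies the headline p-value: `"t"`
#'   (unpaired t-test, default) or `"wilcox"` (Mann-Whitney).
#' @return A list with `summary` (one row per cohort), `t_test`,
#'   `mann_whitney` and `p` (primary p-value); tests are NULL unless
#'   exactly two cohorts are supplied.
#' @export
aggregate_cohort <- function(amplitudes, primary = c("t", "wilcox")) {
  primary <- match.arg(primary)
  if (!is.data.frame(amplitudes)) {
    stop("amplitudes must be a data frame with columns cohort and delta_r")
  }
  .assert(all(c("cohort", "delta_r") %in% names(amplitudes)),
          "amplitudes must contain columns cohort and delta_r")
  groups <- split(amplitudes, amplitudes$cohort)
  .assert(length(groups) >= 1 && all(vapply(groups, nrow, 1L) >= 2),
          "each cohort needs at least 2 cells")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    n_slices <- if ("slice_id" %in% names(d)) length(unique(d$slice_id)) else NA_integer_
    data.frame(cohort = g, mean_delta_r = mean(d$delta_r),
               sem_delta_r = stats::sd(d$delta_r) / sqrt(nrow(d)),
               n_cells = nrow(d), n_slices = n_slices,
               stringsAsFactors = FALSE)
  }))
  t_test <- mw <- NULL
  p <- NA_real_
  if (length(groups) == 2) {
    a <- groups[[1]]$delta_r; b <- groups[[2]]$delta_r
    t_test <- tryCatch(stats::t.test(a, b, var.equal = TRUE),
                       error = function(e) NULL) # e.g. zero-variance groups
    mw <- tryCatch(suppressWarnings(stats::wilcox.test(a, b)),
                   error = function(e) NULL)
    p <- if (primary == "t") {
      if (is.null(t_test)) NA_real_ else t_test$p.value
    } else {
      if (is.null(mw)) NA_real_ else mw$p.value
    }
  }
  list(summary = summ, t_test = t_test, mann_whitney = mw, p = p,
       stars = sig_stars(p))
}
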