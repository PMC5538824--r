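# Trace/config readers and writers, the cohort-statistics dispatcher and
# the end-to-end pipeline driver.

#' Read a recorded trace from CSV
#'
#' Expected columns: fluorescence `time_s,F340,F380[,F360]`; voltage
#' `time_s,voltage_mV[,current_pA]`; current `time_s,current_pA`. Time must
#' be strictly increasing and missing values must not exceed 1% of any
#' column.
#'
#' @param path CSV file path.
#' @param kind One of `"fluorescence"`, `"voltage"`, `"current"`.
#' @return A `ratio_trace` (fluorescence) or a data frame of class
#'   `voltage_trace`/`current_trace`.
#' @export
read_trace <- function(path, kind = c("fluorescence", "voltage", "current")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  need <- switch(kind, fluorescence = c("time_s", "F340", "F380"),
                 voltage = c("time_s", "voltage_mV"),
                 current = c("time_s", "current_pA"))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(structure(class = c("cabuffer_parse_error", "error", "condition"),
                   list(message = sprintf("missing column(s): %s",
                                          paste(missing_cols, collapse = ", ")),
                        call = sys.call(-1))))
  }
  if (any(!is.finite(df$time_s)) || any(diff(df$time_s) <= 0)) {
    stop(structure(class = c("cabuffer_parse_error", "error", "condition"),
                   list(message = "time column must be finite and strictly increasing",
                        call = sys.call(-1))))
  }
  na_frac <- vapply(df[need], function(col) mean(is.na(col)), numeric(1))
  if (any(na_frac > 0.01)) {
    stop(structure(class = c("cabuffer_parse_error", "error", "condition"),
                   list(message = sprintf(
                     "more than 1%% missing values in column(s): %s",
                     paste(need[na_frac > 0.01], collapse = ", ")),
                     call = sys.call(-1))))
  }
  if (kind == "fluorescence") {
    ratio_trace(df$time_s, df$F340, df$F380,
                F360 = if ("F360" %in% names(df)) df$F360 else NULL)
  } else {
    class(df) <- c(paste0(kind, "_trace"), class(df))
    df
  }
}

#' Write a trace to CSV
#'
#' Values are written with full double precision so a write/read round trip
#' is lossless to numerical accuracy.
#'
#' @param trace A `ratio_trace` or a data frame.
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  df <- if (inherits(trace, "ratio_trace")) {
    d <- as.data.frame(trace)
    d$ratio <- NULL # derived, recomputed on read
    d
  } else as.data.frame(trace)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort statistics dispatcher
#'
#' Standard group comparisons on a tidy metrics table, delegated to the
#' usual base-R tests: unpaired/paired t-test or Mann-Whitney for two
#' groups, one-way ANOVA with Bonferroni-corrected pairwise post hoc tests
#' for more. Reports mean, SEM and n per group plus significance stars
#' (*p<0.05, **p<0.01, ***p<0.001).
#'
#' @param table Data frame with columns `cell_id`, `cohort`, `metric`,
#'   `value`.
#' @param metric Metric name to analyze.
#' @param design `"unpaired"`, `"paired"` or `"multi"`.
#' @param test For two-group designs, `"t"` (default) or `"wilcox"`
#'   (Mann-Whitney).
#' @return A list with `summary`, `p`, `stars`, the underlying test
#'   object(s) and the design.
#' @export
cohort_stats <- function(table, metric, design = c("unpaired", "paired", "multi"),
                         test = c("t", "wilcox")) {
  design <- match.arg(design)
  test <- match.arg(test)
  .assert(all(c("cohort", "metric", "value") %in% names(table)),
          "table must contain columns cohort, metric, value")
  d <- table[table$metric == metric & is.finite(table$value), ]
  .assert(nrow(d) > 0, sprintf("metric '%s' not present", metric))
  groups <- split(d$value, d$cohort)
  .assert(length(groups) >= 2, "need at least two cohorts")
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    data.frame(cohort = g, mean = mean(v), sem = stats::sd(v) / sqrt(length(v)),
               n = length(v), stringsAsFactors = FALSE)
  }))

  if (design == "multi") {
    .assert(length(groups) >= 2, "multi design needs >= 2 groups")
    fit <- stats::aov(value ~ cohort, data = d)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    posthoc <- stats::pairwise.t.test(d$value, d$cohort,
                                      p.adjust.method = "bonferroni")
    return(list(summary = summ, p = p, stars = sig_stars(p),
                anova = fit, posthoc = posthoc, design = design))
  }

  .assert(length(groups) == 2, sprintf("%s design needs exactly 2 groups", design))
  a <- groups[[1]]; b <- groups[[2]]
  if (design == "paired") {
    if (length(a) != length(b)) {
      stop(structure(class = c("cabuffer_validation_error", "error", "condition"),
                     list(message = "paired design requires equal group sizes",
                          call = sys.call(-1))))
    }
    ht <- if (test == "t") stats::t.test(a, b, paired = TRUE)
          else suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  } else {
    ht <- if (test == "t") stats::t.test(a, b, var.equal = TRUE)
          else suppressWarnings(stats::wilcox.test(a, b))
  }
  list(summary = summ, p = ht$p.value, stars = sig_stars(ht$p.value),
       test = ht, design = design)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Simulates the configured cohorts, runs the added-buffer analysis with
#' bootstrap and log-scale comparison, the SFA/activity analysis and the
#' FCCP release comparison, and (optionally) writes versioned JSON/CSV
#' results. Deterministic for a fixed config seed; all outputs carry the
#' config hash and seed.
#'
#' @param config A list: `seed` (integer), `cohorts` (character vector of
#'   presets, default both), `n_cells` (per cohort, default 20),
#'   `n_cells_spikes`, `n_cells_fccp` (defaults 20/40), `n_boot` (default
#'   1000), `out_dir` (optional output directory).
#' @return A results bundle (list) with per-stage outputs and provenance.
#' @export
run_pipeline <- function(config) {
  .assert(is.list(config) && !is.null(config$seed), "config must name a seed")
  cohorts <- config$cohorts %||% c("control", "DIO")
  n_cells <- config$n_cells %||% 20
  n_spk <- config$n_cells_spikes %||% 20
  n_fccp <- config$n_cells_fccp %||% 40
  n_boot <- config$n_boot %||% 1000
  seed <- config$seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  buffer <- stage("added_buffer", {
    res <- lapply(seq_along(cohorts), function(ci) {
      co <- cohorts[ci]
      cells <- make_cohort(co, n_cells, seed = seed + ci, what = "loading")
      pts <- do.call(rbind, lapply(cells, function(cell) {
        p <- cell$truth$params
        collect_kappa_tau(cell, p$cal, p$cell_scale, p$stim_times_s,
                          cohort = co)
      }))
      fit <- fit_added_buffer(pts)
      boot <- bootstrap_added_buffer(fit, n_boot = n_boot, seed = seed + 100 + ci)
      list(cohort = co, points = pts, fit = fit, boot = boot)
    })
    names(res) <- cohorts
    cmp <- if (length(res) == 2) {
      list(kappa_s = compare_parameter_distributions(res[[1]]$boot$kappa_s,
                                                     res[[2]]$boot$kappa_s),
           gamma = compare_parameter_distributions(res[[1]]$boot$gamma_per_s,
                                                   res[[2]]$boot$gamma_per_s))
    } else NULL
    list(cohorts = res, comparison = cmp)
  })

  spikes <- stage("spike_analysis", {
    rows <- do.call(rbind, lapply(seq_along(cohorts), function(ci) {
      co <- cohorts[ci]
      cells <- make_cohort(co, n_spk, seed = seed + 200 + ci, what = "spikes")
      do.call(rbind, lapply(cells, function(cell) {
        fr <- instantaneous_frequency(cell$sfa$train)
        sfa <- if (nrow(fr) >= 3) fit_sfa(fr) else NULL
        data.frame(cell_id = cell$cell_id, cohort = co,
                   rate_hz = cell$spont$rate_hz,
                   class = classify_activity(cell$spont),
                   sfa_ratio = if (is.null(sfa)) NA_real_ else sfa$sfa_ratio,
                   vm_mV = cell$truth$vm_mV, stringsAsFactors = FALSE)
      }))
    }))
    nsan <- tapply(rows$class == "NSAN", rows$cohort, mean)
    list(cells = rows, nsan_fraction = nsan)
  })

  fccp <- stage("fccp_analysis", {
    amp <- do.call(rbind, lapply(seq_along(cohorts), function(ci) {
      co <- cohorts[ci]
      cells <- make_cohort(co, n_fccp, seed = seed + 300 + ci, what = "fccp")
      do.call(rbind, lapply(cells, function(cell) {
        ra <- release_amplitude(cell$trace, t_on_s = 120, t_off_s = 240,
                                cell_id = cell$cell_id, slice_id = cell$slice_id)
        data.frame(cell_id = cell$cell_id, slice_id = cell$slice_id,
                   cohort = co, delta_r = ra$delta_r, stringsAsFactors = FALSE)
      }))
    }))
    list(amplitudes = amp,
         cohort = if (length(cohorts) >= 2) aggregate_cohort(amp) else NULL)
  })

  bundle <- list(
    provenance = list(config = config, config_hash = config_hash(config),
                      seed = seed, package_version =
                        as.character(utils::packageVersion("cabuffer"))),
    added_buffer = buffer, spikes = spikes, fccp = fccp
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    summary_json <- list(
      provenance = bundle$provenance[c("config_hash", "seed", "package_version")],
      added_buffer = lapply(buffer$cohorts, function(cc) {
        list(kappa_s = cc$fit$kappa_s, gamma_per_s = cc$fit$gamma_per_s,
             tau_endo_s = cc$fit$tau_endo_s, n_points = cc$fit$n)
      }),
      nsan_fraction = as.list(spikes$nsan_fraction),
      fccp = if (!is.null(fccp$cohort)) list(
        p = fccp$cohort$p,
        means = stats::setNames(as.list(fccp$cohort$summary$mean_delta_r),
                                fccp$cohort$summary$cohort)) else NULL
    )
    jsonlite::write_json(summary_json, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(fccp$amplitudes,
                     file.path(config$out_dir, "fccp_amplitudes.csv"),
                     row.names = FALSE)
    utils::write.csv(spikes$cells, file.path(config$out_dir, "spike_metrics.csv"),
                     row.names = FALSE)
    for (co in names(buffer$cohorts)) {
      utils::write.csv(buffer$cohorts[[co]]$boot,
                       file.path(config$out_dir,
                                 sprintf("bootstrap_%s.csv", co)),
                       row.names = FALSE)
    }
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
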