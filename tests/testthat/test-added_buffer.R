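# The added-buffer chain: binding ratios, transient decay fits, the linear
# fit and its bootstrap, and the log-scale comparison.

test_that("dye binding ratio follows the incremental formula", {
  expect_equal(kappa_b(0, 0.24, 0.02), 0)
  expect_equal(kappa_b(100, 0.24, 0.02), 100 * 0.24 / 0.26^2)
  # strictly decreasing in the resting level for fixed dye
  kb <- kappa_b(100, 0.24, c(0.01, 0.02, 0.05, 0.1, 0.5))
  expect_true(all(diff(kb) < 0))
  expect_error(kappa_b(100, 0.24, 0), class = "cabuffer_validation_error")
})

test_that("transient decay fit recovers noiseless parameters exactly", {
  tr <- mono_transient(amplitude_nM = 200, tau_s = 1.5, baseline_nM = 20)
  fit <- fit_transient_decay(tr$time_s, tr$ca_nM, stim_time_s = 10, window_s = 15)
  expect_true(fit$accepted)
  expect_equal(fit$amplitude_nM, 200, tolerance = 1e-6)
  expect_equal(fit$tau_s, 1.5, tolerance = 1e-6)
  expect_equal(fit$baseline_nM, 20, tolerance = 1e-6)
})

test_that("flat segments and out-of-range decays are rejected", {
  t <- seq(0, 30, by = 0.1)
  flat <- fit_transient_decay(t, rep(20, length(t)), 10, window_s = 15)
  expect_false(flat$accepted)

  slow <- mono_transient(amplitude_nM = 200, tau_s = 80, baseline_nM = 20,
                         post_s = 40)
  fit <- fit_transient_decay(slow$time_s, slow$ca_nM, 10, window_s = 40)
  expect_false(fit$accepted) # tau outside [0.05, 60] s
})

test_that("transient tau is recovered within 10% at simulator noise levels", {
  # noise on the Ca trace equivalent to the default 2% per-wavelength CV:
  # a few nM at rest, scaled with the signal
  tr <- mono_transient(amplitude_nM = 150, tau_s = 3, baseline_nM = 20, post_s = 25)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- tr$ca_nM + rnorm(length(tr$ca_nM), 0, 4)
    f <- fit_transient_decay(tr$time_s, noisy, 10, window_s = 20)
    f$accepted && abs(f$tau_s / 3 - 1) < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("kappa-tau collection yields one increasing point per stimulus", {
  p <- sim_params(seed = 7)
  cell <- simulate_cell(p, cohort = "control")
  pts <- collect_kappa_tau(cell, p$cal, p$cell_scale, p$stim_times_s)
  expect_lte(nrow(pts) + attr(pts, "n_rejected"), length(p$stim_times_s))
  # dye keeps loading: measured binding ratios rise with stimulus order
  # (monotone trend; photon noise can swap late near-saturated neighbours)
  expect_gt(cor(pts$stim_time_s, pts$kappa_b, method = "spearman"), 0.9)
  expect_true(all(diff(cell$truth$transients$kappa_b) > 0))
  # against ground truth: binding ratios within a few percent
  truth <- cell$truth$transients
  m <- match(pts$stim_time_s, truth$stim_time_s)
  expect_equal(pts$kappa_b, truth$kappa_b[m], tolerance = 0.05)
  expect_equal(pts$tau_s, truth$tau_s[m], tolerance = 0.1)

  no_iso <- ratio_trace(cell$trace$time_s, cell$trace$F340, cell$trace$F380)
  expect_error(collect_kappa_tau(no_iso, p$cal, p$cell_scale, p$stim_times_s),
               class = "cabuffer_missing_isosbestic")
})

test_that("the added-buffer line recovers collinear cohorts to machine precision", {
  for (truth in list(c(497, 150), c(240, 111))) {
    fit <- fit_added_buffer(collinear_points(truth[1], truth[2]))
    expect_equal(fit$kappa_s, truth[1], tolerance = 1e-12)
    expect_equal(fit$gamma_per_s, truth[2], tolerance = 1e-12)
    expect_equal(fit$tau_endo_s, (1 + truth[1]) / truth[2], tolerance = 1e-12)
    expect_equal(fit$x_intercept, -(1 + truth[1]), tolerance = 1e-9)
    # internal consistency holds by fit algebra
    expect_equal(fit$tau_endo_s, (1 + fit$kappa_s) / fit$gamma_per_s)
  }
})

test_that("two points interpolate exactly but are flagged; bad slopes error", {
  fit <- fit_added_buffer(data.frame(kappa_b = c(100, 400),
                                     tau_s = (1 + 497 + c(100, 400)) / 150))
  expect_true(fit$low_n)
  expect_equal(fit$kappa_s, 497, tolerance = 1e-9)
  err <- tryCatch(
    fit_added_buffer(data.frame(kappa_b = c(0, 100, 200), tau_s = c(3, 2, 1))),
    error = function(e) e)
  expect_s3_class(err, "cabuffer_degenerate_fit")
  expect_named(err$coefficients, c("(Intercept)", "kappa_b"))
})

test_that("fixed-x bootstrap is seeded, collapses without noise, and shrinks with n", {
  fit0 <- fit_added_buffer(collinear_points(497, 150))
  b0 <- bootstrap_added_buffer(fit0, n_boot = 200, seed = 3)
  expect_true(all(abs(b0$kappa_s - 497) < 1e-6)) # zero residuals: point mass
  expect_equal(attr(b0, "n_invalid"), 0)

  set.seed(99)
  mk <- function(n) {
    kb <- seq(50, 600, length.out = n)
    data.frame(kappa_b = kb, tau_s = (1 + 497 + kb) / 150 + rnorm(n, 0, 0.15))
  }
  fit <- fit_added_buffer(mk(24))
  b1 <- bootstrap_added_buffer(fit, n_boot = 500, seed = 11)
  b2 <- bootstrap_added_buffer(fit, n_boot = 500, seed = 11)
  expect_identical(b1$kappa_s, b2$kappa_s) # seeding contract
  b3 <- bootstrap_added_buffer(fit, n_boot = 500, seed = 12)
  expect_false(identical(b1$kappa_s, b3$kappa_s))

  # bootstrap SD scales roughly as 1/sqrt(n points): quadrupling n should
  # roughly halve it (allow a factor-of-two band, Monte-Carlo)
  sd_small <- sd(bootstrap_added_buffer(fit_added_buffer(mk(12)),
                                        n_boot = 500, seed = 5)$kappa_s)
  sd_large <- sd(bootstrap_added_buffer(fit_added_buffer(mk(48)),
                                        n_boot = 500, seed = 5)$kappa_s)
  expect_lt(sd_large, sd_small)
  expect_gt(sd_small / sd_large, 1.3)
})

test_that("log-scale comparison behaves under identity, shift and scaling", {
  set.seed(1)
  a <- rlnorm(200, log(497), 0.05)
  same <- compare_parameter_distributions(a, a)
  expect_equal(same$p, 1)
  b <- rlnorm(200, log(240), 0.05)
  diff <- compare_parameter_distributions(a, b)
  expect_lt(diff$p, 1e-10)
  # common scaling is a log-shift of both samples: t unchanged
  scaled <- compare_parameter_distributions(3 * a, 3 * b)
  expect_equal(scaled$t, diff$t, tolerance = 1e-9)
  expect_error(compare_parameter_distributions(c(a, -1), b),
               class = "cabuffer_validation_error")
})

test_that("confidence band covers the fitted line and widens off-center", {
  set.seed(2)
  kb <- seq(50, 600, length.out = 20)
  pts <- data.frame(kappa_b = kb, tau_s = (1 + 497 + kb) / 150 + rnorm(20, 0, 0.1))
  fit <- fit_added_buffer(pts)
  band <- added_buffer_band(fit, c(-500, 0, 325, 650))
  expect_true(all(band$lwr_s < band$fit_s & band$fit_s < band$upr_s))
  w <- band$upr_s - band$lwr_s
  expect_gt(w[1], w[3]) # widest far from the design center
})
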