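# Ratiometric calibration and dye-loading tracking.

test_that("effective Kd from a defined-Ca measurement follows the ratio algebra", {
  expect_equal(effective_kd(R_def = 1.0, R_min = 0.3, R_max = 6.0, ca_def_uM = 0.35),
               0.35 * 5.0 / 0.7)
  # midpoint ratio: effective Kd equals the defined concentration
  expect_equal(effective_kd(3.15, 0.3, 6.0, ca_def_uM = 0.35), 0.35)
  expect_error(effective_kd(0.3, 0.3, 6.0, 0.35),
               class = "cabuffer_calibration_range_error")
  expect_error(effective_kd(6.5, 0.3, 6.0, 0.35),
               class = "cabuffer_calibration_range_error")
})

test_that("ratio-to-Ca conversion has the right fixed points and monotonicity", {
  cal <- default_cal()
  expect_equal(ratio_to_ca(cal$R_min, cal), 0)
  expect_equal(ratio_to_ca((cal$R_min + cal$R_max) / 2, cal),
               cal$Kd_eff_uM * 1000)
  rr <- seq(cal$R_min, cal$R_max - 0.01, length.out = 100)
  expect_true(all(diff(ratio_to_ca(rr, cal)) > 0))
  expect_error(ratio_to_ca(cal$R_max, cal), class = "cabuffer_saturation_error")
  expect_warning(out <- ratio_to_ca(cal$R_min - 0.01, cal), "clipped")
  expect_equal(out, 0)
})

test_that("Ca-to-ratio is the exact inverse over the working range", {
  cal <- default_cal()
  expect_equal(ca_to_ratio(0, cal), cal$R_min)
  expect_equal(ca_to_ratio(cal$Kd_eff_uM * 1000, cal),
               (cal$R_min + cal$R_max) / 2)
  expect_lt(ca_to_ratio(1e12, cal), cal$R_max)
  ca <- 10^seq(0, 4, length.out = 200) # 1 nM .. 10 uM
  back <- ratio_to_ca(ca_to_ratio(ca, cal), cal)
  expect_equal(back, ca, tolerance = 1e-9)
  # consistency: effective_kd applied to a generated ratio returns Kd_eff
  R <- ca_to_ratio(350, cal)
  expect_equal(effective_kd(R, cal$R_min, cal$R_max, ca_def_uM = 0.35),
               cal$Kd_eff_uM)
})

test_that("calibration is invariant to a common fluorescence gain", {
  cal <- default_cal()
  t <- seq(0, 10, by = 0.5)
  F380 <- 500 + 20 * sin(t)
  F340 <- 1.2 * F380
  tr1 <- ratio_trace(t, F340, F380)
  tr2 <- ratio_trace(t, 3.7 * F340, 3.7 * F380)
  expect_equal(ratio_to_ca(tr1$ratio, cal), ratio_to_ca(tr2$ratio, cal))
})

test_that("isosbestic conversion is linear and validated", {
  expect_equal(fura_from_isosbestic(0, cell_scale = 10), 0)
  expect_equal(fura_from_isosbestic(c(100, 200), 10), c(10, 20))
  expect_error(fura_from_isosbestic(100, 0), class = "cabuffer_validation_error")
})

test_that("loading-curve fit recovers noiseless and noisy fills", {
  t <- seq(30, 1500, by = 30)
  conc <- 100 * (1 - exp(-t / 300))
  fit <- fit_loading_curve(t, conc)
  expect_true(fit$converged)
  expect_equal(fit$c_inf_uM, 100, tolerance = 1e-6)
  expect_equal(fit$tau_fill_s, 300, tolerance = 1e-6)

  # degenerate constant samples are flagged, raw points preserved
  flat <- fit_loading_curve(t, rep(50, length(t)))
  expect_false(flat$converged)
  expect_equal(flat$conc_uM, rep(50, length(t)))

  # 2% multiplicative noise (the simulator default on the isosbestic
  # channel): recovery within 5% for the large majority of seeds
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- conc * (1 + rnorm(length(t), 0, 0.02))
    f <- fit_loading_curve(t, noisy)
    abs(f$c_inf_uM / 100 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_gt(mean(errs < 0.05), 0.9)
})

test_that("simulated isosbestic channel recovers the dye concentration", {
  p <- sim_params(seed = 42)
  cell <- simulate_cell(p)
  est <- fura_from_isosbestic(cell$trace$F360, p$cell_scale)
  truth <- cell$truth$loading$fura_uM
  late <- cell$truth$loading$time_s > 600
  expect_equal(mean(est[late] / truth[late]), 1, tolerance = 0.005)
})
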