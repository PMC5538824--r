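# Forward-simulator contracts: constructed identities, preset structure and
# seeding.

test_that("stored transient truths are exactly collinear before noise", {
  p <- sim_params(seed = 1)
  cell <- simulate_cell(p)
  tr <- cell$truth$transients
  fit <- fit_added_buffer(tr)
  expect_equal(fit$kappa_s, p$kappa_s, tolerance = 1e-12)
  expect_equal(fit$gamma_per_s, p$gamma_per_s, tolerance = 1e-12)
  # amplitude attenuation and decay slowing with loading
  expect_true(all(diff(tr$amplitude_nM) < 0))
  expect_true(all(diff(tr$tau_s) > 0))
})

test_that("control cells decay slower than DIO cells at low dye loads", {
  # tau = (1 + kappa_S + kappa_B)/gamma crosses between the presets at
  # kappa_B = (gamma_c (1+kS_d) - gamma_d (1+kS_c)) / (gamma_d - gamma_c)
  # ~ 490; below that control is slower, above it DIO is slower
  ctrl <- cohort_preset("control"); dio <- cohort_preset("DIO")
  tau <- function(p, kb) (1 + p$kappa_s + kb) / p$gamma_per_s
  expect_gt(tau(ctrl, 0), tau(dio, 0))
  expect_gt(tau(ctrl, 300), tau(dio, 300))
  expect_lt(tau(ctrl, 600), tau(dio, 600))
  expect_error(cohort_preset("HFD"), class = "cabuffer_validation_error")
})

test_that("zero influx gives a flat trace at rest and dense schedules error", {
  p <- sim_params(influx_uM = 0, noise_cv = 0, seed = 1)
  cell <- simulate_cell(p)
  ca <- ratio_to_ca(cell$trace$ratio, p$cal)
  ok <- is.finite(ca) # the very first frame has no dye yet (F380 = 0)
  expect_true(all(ok[-1]))
  expect_equal(ca[ok], rep(p$ca_rest_nM, sum(ok)), tolerance = 1e-9)
  expect_error(sim_params(stim_times_s = c(60, 61)),
               class = "cabuffer_validation_error")
})

test_that("adapting train has the closed-form spike count and regular limit", {
  st <- simulate_spike_train(35, 10, 0.5, duration_s = 10, jitter_cv = 0)
  # integral of Y over 10 s = 100 + 50 (1 - e^-5) ~ 149.7
  expect_lt(abs(length(st$train$times_s) - 150), 3)

  reg <- simulate_spike_train(20, 20, 1, duration_s = 2, jitter_cv = 0)
  expect_true(all(abs(diff(reg$train$times_s) - 0.05) < 1e-9))
  expect_error(simulate_spike_train(10, 20, 0.5),
               class = "cabuffer_validation_error")
})

test_that("cohorts are byte-identical per seed and follow the silent mixture", {
  c1 <- make_cohort("control", 5, seed = 9, what = "loading")
  c2 <- make_cohort("control", 5, seed = 9, what = "loading")
  expect_identical(c1, c2)
  c3 <- make_cohort("control", 5, seed = 10, what = "loading")
  expect_false(identical(c1, c3))

  # NSAN fraction across a larger synthetic cohort matches the generating
  # mixture within binomial error (3 sigma)
  cells <- make_cohort("control", 200, seed = 21, what = "spikes")
  frac <- mean(vapply(cells, function(cl) {
    classify_activity(cl$spont) == "NSAN"
  }, logical(1)))
  p0 <- cohort_preset("control")$silent_fraction
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 200))
})

test_that("FCCP generator peaks after onset and round-trips", {
  tr <- simulate_fccp_trace(delta_r = 0.015, noise_cv = 0, seed = 2)
  truth <- attr(tr, "truth")
  i_pk <- which.max(tr$ratio)
  expect_gt(tr$time_s[i_pk], truth$t_on_s)
  ra <- release_amplitude(tr, truth$t_on_s, truth$t_on_s + 120)
  expect_equal(ra$delta_r, 0.015, tolerance = 0.05)
})
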