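# Spike detection, activity classification, SFA fitting and excitability.

test_that("threshold detector finds template spikes and is sampling-stable", {
  st <- simulate_spike_train(10, 10, 0.5, duration_s = 1, jitter_cv = 0)
  det <- detect_spikes(st$time_s, st$voltage_mV)
  expect_equal(length(det$times_s), length(st$train$times_s))
  expect_true(all(abs(det$times_s - st$train$times_s) < 0.002))

  flat <- detect_spikes(seq(0, 1, by = 1e-4), rep(-60, 10001))
  expect_equal(length(flat$times_s), 0)

  st2 <- simulate_spike_train(10, 10, 0.5, duration_s = 1, jitter_cv = 0,
                              dt_s = 5e-5) # doubled sampling rate
  det2 <- detect_spikes(st2$time_s, st2$voltage_mV)
  expect_equal(length(det2$times_s), length(det$times_s))

  expect_error(detect_spikes(c(0, 2, 1), c(-60, -60, -60)),
               class = "cabuffer_validation_error")
})

test_that("activity classification uses a strict 0.5 Hz cutoff", {
  expect_equal(classify_activity(regular_train(0.4)), "NSAN")
  expect_equal(classify_activity(regular_train(0.5)), "SAN") # boundary is SAN
  expect_equal(classify_activity(regular_train(3.4)), "SAN")
  # invariant to segmentation: rate over the full duration decides
  tr <- spike_train(c(1, 2, 3), duration_s = 10) # bursty start, 0.3 Hz overall
  expect_equal(classify_activity(tr), "NSAN")
})

test_that("instantaneous frequency is the inverse ISI at the second spike", {
  tr <- spike_train(c(0, 0.1, 0.2), duration_s = 1)
  fr <- instantaneous_frequency(tr)
  expect_equal(fr$frequency_hz, c(10, 10))
  expect_equal(fr$time_s, c(0.1, 0.2))
  # geometric ISI growth -> monotone decreasing frequency
  isi <- 0.02 * 1.2^(0:20)
  tr2 <- spike_train(cumsum(c(0, isi)), duration_s = 10)
  expect_true(all(diff(instantaneous_frequency(tr2)$frequency_hz) < 0))
  expect_equal(nrow(instantaneous_frequency(spike_train(0.5, 1))), 0)
})

test_that("SFA fit recovers generator parameters and flags degenerate cases", {
  st <- simulate_spike_train(35, 10, 0.5, jitter_cv = 0)
  fit <- fit_sfa(instantaneous_frequency(st$train))
  expect_equal(fit$plateau_hz, 10, tolerance = 1e-6)
  expect_equal(fit$k_per_s, 0.5, tolerance = 1e-6)
  # Y0 is read off the first measured instantaneous frequency, one ISI
  # (plus the onset latency) into the decay, so the ratio sits just below
  # the generating 35/10
  expect_equal(fit$sfa_ratio, 3.5, tolerance = 0.05)
  expect_gt(fit$sfa_ratio, 3) # strong adaptation

  const <- data.frame(time_s = seq(0.1, 10, by = 0.1),
                      frequency_hz = rep(35, 100))
  cfit <- fit_sfa(const)
  expect_equal(cfit$plateau_hz, 35)
  expect_equal(cfit$sfa_ratio, 1.0)
  expect_false(cfit$k_identifiable)
})

test_that("silent-cohort SFA ratios recover within 15% under jitter", {
  errs <- vapply(1:30, function(s) {
    st <- simulate_spike_train(35, 35 / 3.6, 0.5, jitter_cv = 0.05, seed = s)
    fit <- fit_sfa(instantaneous_frequency(st$train))
    abs(fit$sfa_ratio / 3.6 - 1)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.15)
})

test_that("ramp threshold matches the programmed threshold current", {
  rr <- simulate_ramp_response(i_threshold_pA = 20, ramp_rate_pA_per_s = 5)
  th <- threshold_current_from_ramp(rr$time_s, rr$voltage_mV, rr$current_pA)
  expect_true(th$found)
  expect_equal(th$i_threshold_pA, 20, tolerance = 0.01)

  sub <- simulate_ramp_response(i_threshold_pA = 100, ramp_rate_pA_per_s = 5,
                                duration_s = 5) # ramp never reaches threshold
  none <- threshold_current_from_ramp(sub$time_s, sub$voltage_mV, sub$current_pA)
  expect_false(none$found)
  expect_true(is.na(none$i_threshold_pA))
})

test_that("F-I curve counts spikes per step and estimates the gain", {
  currents <- c(0, 5, 10, 15, 20, 25, 30)
  steps <- lapply(currents, function(I) {
    simulate_step_response(I, i_threshold_pA = 10, gain_per_pA = 2)
  })
  res <- fi_curve(steps)
  expect_equal(res$fi$current_pA, currents)
  expect_true(all(diff(res$fi$ap_count) >= 0))
  expect_equal(res$fi$ap_count[currents <= 10], c(0, 0, 0))
  expect_equal(res$gain_per_pA, 2, tolerance = 0.1)

  # all-subthreshold steps: zeros, no gain estimate
  sub <- fi_curve(lapply(c(0, 5), simulate_step_response, i_threshold_pA = 10,
                         gain_per_pA = 2))
  expect_true(all(sub$fi$ap_count == 0))
  expect_true(is.na(sub$gain_per_pA))
})
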