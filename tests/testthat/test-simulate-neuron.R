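test_that("noiseless suprathreshold drive fires perfectly periodically", {
  rec <- simulate_two_regime_neuron(mean_params(), duration = 2, seed = 1)
  expect_gt(length(rec$spike_times), 10)
  isi <- diff(rec$spike_times)
  expect_lt(sd(isi), 1e-12)
  cs <- cv2_sequence(rec$spike_times)
  expect_true(all(cs$values < 1e-9))   # equal up to float ulp on times
  expect_identical(rec$regime_label[1], "mean")
})

test_that("noiseless subthreshold drive emits no spikes", {
  p <- neuron_params(Im = 1, current_noise_sd = 0, duty = 1)  # 10 mV < 15
  rec <- simulate_two_regime_neuron(p, duration = 2, seed = 1)
  expect_length(rec$spike_times, 0)
  expect_true(is_fluctuation_driven_params(p))
  expect_false(is_fluctuation_driven_params(mean_params()))
})

test_that("fluctuation regime at 3-sigma distance gives irregular spiking", {
  # mean drive 3 Vm-SDs below threshold; CV2 averaged over 10 seeds
  cv <- vapply(1:10, function(s) {
    r <- simulate_two_regime_neuron(fluct_params(), 30, seed = s)
    if (length(r$spike_times) < 4) return(NA_real_)
    cv2_sequence(r$spike_times)$mean_cv2
  }, numeric(1))
  expect_gt(mean(cv, na.rm = TRUE), 0.5)
  expect_lt(mean(cv, na.rm = TRUE), 1.1)
  expect_identical(
    simulate_two_regime_neuron(fluct_params(), 2, seed = 1)$regime_label[1],
    "fluctuation")
})

test_that("same seed reproduces the recording bit-identically", {
  p <- fluct_params()
  a <- simulate_two_regime_neuron(p, 3, seed = 5)
  b <- simulate_two_regime_neuron(p, 3, seed = 5)
  expect_identical(a$trace$vm, b$trace$vm)
  expect_identical(a$spike_times, b$spike_times)
  c <- simulate_two_regime_neuron(p, 3, seed = 6)
  expect_false(identical(a$trace$vm, c$trace$vm))
})

test_that("spikes respect the refractory period and store true thresholds", {
  p <- neuron_params(Im = 2.5, current_noise_sd = 0.3, duty = 1,
                     refractory = 5)
  rec <- simulate_two_regime_neuron(p, 10, seed = 2)
  expect_gt(length(rec$spike_times), 20)
  expect_true(all(diff(rec$spike_times) >= 5 / 1000 - 1e-12))
  # no adaptation: the stored threshold is the programmed one
  expect_true(all(abs(rec$spike_thresholds - p$Vthres) < 1e-9))
})

test_that("spike count grows linearly with duration in the noiseless limit", {
  n1 <- length(simulate_two_regime_neuron(mean_params(), 5, seed = 1)$spike_times)
  n2 <- length(simulate_two_regime_neuron(mean_params(), 10, seed = 1)$spike_times)
  expect_lt(abs(n2 - 2 * n1), 2)
})

test_that("burst cycling confines spikes to the active phase", {
  p <- neuron_params(Im = 2.5, current_noise_sd = 0.2, cycle_period = 1,
                     duty = 0.5)
  rec <- simulate_two_regime_neuron(p, 4, seed = 3)
  phase <- rec$spike_times %% 1
  # peaks may spill over the phase edge by the 1 ms rise
  expect_true(all(phase < 0.5 + 2e-3))
  # interburst Vm relaxes below reset
  t <- trace_times(rec$trace)
  ib <- t %% 1 > 0.7 & t %% 1 < 0.95
  expect_lt(mean(rec$trace$vm[ib]), p$Vreset - 2)
})

test_that("invalid simulator arguments are rejected", {
  expect_error(neuron_params(Vreset = -40), "below threshold")
  expect_error(neuron_params(Rm = -1), "positive")
  expect_error(neuron_params(duty = 0), "duty")
  expect_error(simulate_two_regime_neuron(fluct_params(), -1), "positive")
  expect_error(simulate_two_regime_neuron(fluct_params(), 2, dt = 5),
               "dt must be")
  expect_error(simulate_two_regime_neuron(fluct_params(), 0.5),
               "at least one cycle")
})

test_that("OU trace has the programmed stationary mean and SD", {
  tr <- simulate_ou_trace(20, dt = 0.1, mean = -58, sd = 2.5, tau = 20,
                          seed = 9)
  expect_equal(mean(tr$vm), -58, tolerance = 0.1)
  expect_equal(sd(tr$vm), 2.5, tolerance = 0.1)
})
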