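test_that("peak detection: flat traces yield nothing, close peaks thinned", {
  expect_length(detect_spike_peaks(vm_trace(rep(-60, 1000), 20000)), 0)

  # two candidate peaks 0.5 ms apart; the taller survives
  fs <- 20000
  v <- rep(-60, 200)
  v[100] <- 10          # taller
  v[110] <- 5           # 0.5 ms later
  pk <- detect_spike_peaks(vm_trace(v, fs), min_separation = 1)
  expect_length(pk, 1)
  expect_equal(pk, 99 / fs)
})

test_that("detected peaks match simulator ground truth within one sample", {
  rec <- simulate_two_regime_neuron(fluct_params(), 30, seed = 2)
  pk <- detect_spike_peaks(rec$trace)
  expect_identical(length(pk), length(rec$spike_times))
  expect_lt(max(abs(pk - rec$spike_times)) * rec$trace$fs, 1 + 1e-9)
})

test_that("phase-plane threshold lands on the kink of a piecewise ramp", {
  fs <- 20000
  # slow approach then a steep linear rise to a peak
  slow <- seq(-60, -45, length.out = 400)       # 20 ms ramp
  fast <- seq(-45, 20, length.out = 20)[-1]     # ~1 ms upstroke
  down <- seq(20, -60, length.out = 40)[-1]
  v <- c(rep(-60, 50), slow, fast, down, rep(-60, 50))
  tr <- vm_trace(v, fs)
  pk <- detect_spike_peaks(tr)
  se <- estimate_thresholds_phase_plane(tr, pk, lowpass_hz = 0)
  expect_equal(se$threshold_mV[1], -45, tolerance = 0.5)
})

test_that("threshold estimator recovers the programmed threshold", {
  rec <- simulate_two_regime_neuron(mean_params(noise = 0.2), 10, seed = 4)
  pk <- detect_spike_peaks(rec$trace)
  se <- suppressWarnings(estimate_thresholds_phase_plane(rec$trace, pk))
  expect_gt(length(se$threshold_mV), 100)
  expect_lt(abs(se$mean_threshold - rec$params$Vthres), 1)
  expect_lte(se$threshold_q5, se$mean_threshold)
})

test_that("threshold adaptation couples spike rate to threshold height", {
  p <- neuron_params(Im = 2.5, current_noise_sd = 0.1, duty = 1,
                     mod_depth = 0.8, adapt_increment = 1.5,
                     adapt_tau = 200, cycle_period = 1)
  rec <- simulate_two_regime_neuron(p, 10, seed = 3)
  pk <- detect_spike_peaks(rec$trace)
  se <- suppressWarnings(estimate_thresholds_phase_plane(rec$trace, pk))
  rate <- 1 / diff(se$peak_times)
  ct <- correlate(rate, se$threshold_mV[-1])
  expect_gt(ct$r, 0.2)
  expect_lt(ct$p, 0.01)
  # the 5% quantile threshold sits below the adapted mean
  expect_lt(se$threshold_q5, se$mean_threshold - 1)
})

test_that("spike-triggered distribution applies the ISI selection filter", {
  fs <- 20000
  v <- rep(-60, fs)  # 1 s flat
  # plant distinct Vm values 18 ms before three spike peaks
  peaks <- c(0.3, 0.4, 0.43, 0.8)   # ISIs: 100 ms, 30 ms, 370 ms
  for (i in seq_along(peaks)) {
    j <- round((peaks[i] - 0.018) * fs) + 1
    v[j] <- -60 + i
  }
  tr <- vm_trace(v, fs)
  d <- spike_triggered_distribution(tr, peaks)
  # only spikes 2 and 3 have preceding ISI in (20, 300) ms
  expect_identical(d$n, 2L)
  expect_true(d$low_n)
  expect_equal(sort(d$values), c(-58, -57))
})

test_that("degenerate spike-triggered samples report zero skewness", {
  tr <- vm_trace(rep(-55, 20000), 20000)
  d <- spike_triggered_distribution(tr, seq(0.1, 0.9, by = 0.05))
  expect_identical(d$sd, 0)
  expect_identical(d$skewness, 0)
  expect_true(d$skewness_degenerate)
})

test_that("temporal distribution is symmetric for sinusoidal Vm", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)
  v <- -60 + 3 * sin(2 * pi * 40 * t)
  peaks <- c(0.1, 0.35, 0.6, 0.85)
  d <- temporal_distribution(vm_trace(v, fs), peaks)
  expect_lt(abs(d$skewness), 0.05)
  expect_equal(d$mean, -60, tolerance = 0.1)
})

test_that("temporal and spike-triggered means agree on stationary traces", {
  # the sigma lag (18 ms) must exceed the Vm autocorrelation time for the
  # pre-spike sample to be unconditioned; tau_m = 5 ms emulates the
  # high-conductance state of active networks
  sk <- c()
  for (s in 6:8) {
    rec <- simulate_two_regime_neuron(fluct_params(tau_m = 5), 60, seed = s)
    pk <- detect_spike_peaks(rec$trace)
    dt <- temporal_distribution(rec$trace, pk)
    ds <- spike_triggered_distribution(rec$trace, pk)
    expect_gte(ds$n, 10)
    expect_lt(abs(dt$mean - ds$mean), 1)
    sk <- c(sk, dt$skewness, ds$skewness)
  }
  # subthreshold distributions in the fluctuation regime are near-Gaussian:
  # extremes stay below ~0.5 in magnitude on average
  expect_lt(mean(abs(sk)), 0.5)
  expect_lt(max(abs(sk)), 0.8)
})

test_that("time below threshold separates the two regimes", {
  expect_identical(time_below_threshold(vm_trace(rep(-60, 1000), 20000), -50), 1)
  expect_identical(time_below_threshold(vm_trace(rep(-40, 1000), 20000), -50), 0)
  fl <- simulate_two_regime_neuron(fluct_params(), 10, seed = 2)
  # drive far above threshold so the smoothed Vm rides near the peak
  md <- simulate_two_regime_neuron(mean_params(noise = 0.2, Im = 5), 10,
                                   seed = 2)
  thr <- fl$params$Vthres
  expect_gt(time_below_threshold(fl$trace, thr), 0.5)
  expect_lt(time_below_threshold(md$trace, thr), 0.5)
})

test_that("normalized threshold distance is plain standardized arithmetic", {
  d <- new_vm_dist_for_test(mean = -60, sd = 5)
  expect_equal(normalized_threshold_distance(d, -45), -3)
  expect_equal(normalized_threshold_distance(d, -60), 0)
  d0 <- new_vm_dist_for_test(mean = -60, sd = 0)
  expect_error(normalized_threshold_distance(d0, -45), "positive")
})

test_that("programmed 3-sigma fluctuation regime recovers distance near -3", {
  dist <- vapply(1:5, function(s) {
    rec <- simulate_two_regime_neuron(fluct_params(), 60, seed = s)
    pk <- detect_spike_peaks(rec$trace)
    if (length(pk) < 4) return(NA_real_)
    d <- temporal_distribution(rec$trace, pk, isi_max = 1e5)
    (d$mean - rec$params$Vthres) / d$sd
  }, numeric(1))
  expect_equal(mean(dist, na.rm = TRUE), -3, tolerance = 0.5)
})
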