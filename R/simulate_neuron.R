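#' Parameters of the two-regime model neuron
#'
#' A stochastic leaky integrator with threshold-reset spiking, used to
#' generate ground-truth-labelled recordings in either spiking regime. The
#' regime is set by the balance between the mean drive and the threshold:
#' with leak reversal at the reset potential, the neuron is
#' *fluctuation-driven* iff `Rm * Im < Vthres - Vreset` during the active
#' phase (spikes then require a noise transient), and *mean-driven*
#' otherwise.
#'
#' Synaptic bombardment is modelled as Gaussian white current noise. The
#' noise term is scaled so that the stationary subthreshold Vm standard
#' deviation equals `Rm * current_noise_sd`, which makes the distance to
#' threshold directly programmable in units of the Vm fluctuation size.
#'
#' The drive follows a burst-cycle envelope: during the active fraction
#' (`duty`) of each `cycle_period` the mean current is `Im`, optionally
#' modulated within the cycle by a raised-cosine profile of depth
#' `mod_depth`; during the interburst gap the drive is off and Vm relaxes to
#' a hyperpolarized rest (`Vreset - interburst_drop`) with small residual
#' noise.
#'
#' @param Rm membrane resistance (MOhm).
#' @param tau_m membrane time constant (ms).
#' @param Im mean input current during the active phase (nA).
#' @param current_noise_sd SD of the white current noise (nA); the
#'   stationary Vm SD is `Rm * current_noise_sd` mV.
#' @param Vthres spike threshold (mV).
#' @param Vreset reset potential, also the leak reversal (mV); must be
#'   below `Vthres`.
#' @param refractory absolute refractory period (ms), >= 0.
#' @param adapt_increment threshold depolarization added at each spike (mV);
#'   0 disables adaptation.
#' @param adapt_tau recovery time constant of threshold adaptation (ms).
#' @param cycle_period burst-cycle period (s).
#' @param duty active fraction of each cycle, in (0, 1]; `1` gives tonic
#'   drive with no interburst gap.
#' @param mod_depth within-cycle raised-cosine modulation depth of the mean
#'   drive, in `[0, 1]`; 0 gives a flat active-phase drive.
#' @param interburst_drop hyperpolarization of the interburst rest below
#'   `Vreset` (mV).
#' @param interburst_noise_sd stationary Vm noise SD during the interburst
#'   gap (mV).
#' @return an object of class `neuron_params`.
#' @seealso [simulate_two_regime_neuron()]
#' @export
neuron_params <- function(Rm = 10, tau_m = 20, Im = 1.0,
                          current_noise_sd = 0.3,
                          Vthres = -45, Vreset = -60,
                          refractory = 2,
                          adapt_increment = 0, adapt_tau = 50,
                          cycle_period = 1.6, duty = 0.625,
                          mod_depth = 0,
                          interburst_drop = 5, interburst_noise_sd = 0.3) {
  if (Rm <= 0) stop("Rm must be positive")
  if (tau_m <= 0) stop("tau_m must be positive")
  if (refractory < 0) stop("refractory must be >= 0")
  if (cycle_period <= 0) stop("cycle_period must be positive")
  if (duty <= 0 || duty > 1) stop("duty must lie in (0, 1]")
  if (mod_depth < 0 || mod_depth > 1) stop("mod_depth must lie in [0, 1]")
  if (Vreset >= Vthres) stop("reset potential must be below threshold")
  if (current_noise_sd < 0) stop("current_noise_sd must be >= 0")
  structure(list(Rm = Rm, tau_m = tau_m, Im = Im,
                 current_noise_sd = current_noise_sd,
                 Vthres = Vthres, Vreset = Vreset,
                 refractory = refractory,
                 adapt_increment = adapt_increment, adapt_tau = adapt_tau,
                 cycle_period = cycle_period, duty = duty,
                 mod_depth = mod_depth,
                 interburst_drop = interburst_drop,
                 interburst_noise_sd = interburst_noise_sd),
            class = "neuron_params")
}

#' Is a parameter set fluctuation-driven?
#'
#' `TRUE` when the peak mean drive cannot reach threshold from the leak
#' reversal, i.e. `Rm * Im * max(envelope) < Vthres - Vreset`.
#'
#' @param params a [neuron_params()].
#' @return logical scalar.
#' @export
is_fluctuation_driven_params <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  params$Rm * params$Im < params$Vthres - params$Vreset
}

# stylized action potential: linear rise over 1 ms from threshold to
# +20 mV, then exponential repolarization (tau 0.6 ms) toward reset over
# 1.4 ms. Gives phase-plane detection a realistic acceleration profile.
.spike_peak_mV <- 20
.spike_rise_ms <- 1
.spike_fall_ms <- 1.4
.spike_fall_tau_ms <- 0.6

#' Simulate a two-regime model neuron
#'
#' Euler integration of the leaky integrator described in
#' [neuron_params()], with threshold-reset spiking and a stylized spike
#' waveform inserted at each crossing (so that peak detection and
#' phase-plane threshold estimation can be exercised on the output).
#' Threshold adaptation, when enabled, adds `adapt_increment` mV at each
#' spike and decays exponentially with `adapt_tau`.
#'
#' @param params a [neuron_params()].
#' @param duration simulated time (s); must cover at least one cycle.
#' @param dt integration step (ms); must satisfy `dt <= tau_m / 10`.
#'   The default 0.05 ms corresponds to 20 kHz sampling.
#' @param seed RNG seed; the output is bit-identical for identical
#'   arguments.
#' @return an object of class `simulated_recording`: fields `trace`
#'   ([vm_trace()]), `spike_times` (peak times, s), `onset_times`
#'   (threshold-crossing times, s), `spike_thresholds` (instantaneous
#'   threshold at each crossing, mV), `regime_label` (per cycle,
#'   `"fluctuation"` or `"mean"`), `params`, `seed`.
#' @examples
#' p <- neuron_params(Im = 2, current_noise_sd = 0, duty = 1)
#' rec <- simulate_two_regime_neuron(p, duration = 2, seed = 1)
#' length(rec$spike_times)
#' @export
simulate_two_regime_neuron <- function(params, duration, dt = 0.05,
                                       seed = 1L) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  if (dt > params$tau_m / 10)
    stop("dt must be <= tau_m / 10 for stable integration")
  if (duration < params$cycle_period)
    stop("duration must cover at least one cycle")

  p <- params
  n <- floor(duration * 1000 / dt)
  t_ms <- (seq_len(n) - 1) * dt
  fs <- 1000 / dt

  cyc_ms <- p$cycle_period * 1000
  active_ms <- p$duty * cyc_ms
  phase <- t_ms %% cyc_ms
  active <- phase < active_ms | p$duty == 1

  # raised-cosine within-cycle envelope: 1 - depth at cycle edges, 1 at mid
  env <- 1 - p$mod_depth * 0.5 * (1 + cos(2 * pi * phase / active_ms))
  mu <- ifelse(active, p$Vreset + p$Rm * p$Im * env,
               p$Vreset - p$interburst_drop)
  sig_v <- ifelse(active, p$Rm * p$current_noise_sd, p$interburst_noise_sd)

  a <- dt / p$tau_m
  step_sd <- sig_v * sqrt(2 * a)   # stationary Vm SD equals sig_v

  set.seed(as.integer(seed))
  z <- rnorm(n)

  n_rise <- max(1L, round(.spike_rise_ms / dt))
  n_fall <- max(1L, round(.spike_fall_ms / dt))
  fall_shape <- exp(-(seq_len(n_fall) * dt) / .spike_fall_tau_ms)
  n_dead <- max(round(p$refractory / dt), n_rise + n_fall)

  decay_ad <- if (p$adapt_tau > 0) exp(-dt / p$adapt_tau) else 0

  vm <- numeric(n)
  v <- mu[1]
  ad <- 0
  cross_idx <- integer(0)
  peak_idx <- integer(0)
  thr_at_cross <- numeric(0)

  i <- 1L
  while (i <= n) {
    ad <- ad * decay_ad
    v <- v + a * (mu[i] - v) + step_sd[i] * z[i]
    th <- p$Vthres + ad
    if (active[i] && v >= th) {
      # crossing: clip to the instantaneous threshold, insert waveform
      vm[i] <- th
      cross_idx <- c(cross_idx, i)
      thr_at_cross <- c(thr_at_cross, th)
      rise_to <- min(i + n_rise, n)
      if (rise_to > i)
        vm[(i + 1L):rise_to] <-
          th + (.spike_peak_mV - th) * seq_len(rise_to - i) / n_rise
      ip <- i + n_rise
      peak_idx <- c(peak_idx, ip)
      fall_to <- min(ip + n_fall, n)
      if (fall_to > ip)
        vm[(ip + 1L):fall_to] <-
          p$Vreset + (.spike_peak_mV - p$Vreset) * fall_shape[seq_len(fall_to - ip)]
      # hold at reset for the remainder of the dead time
      hold_to <- min(i + n_dead, n)
      if (hold_to > fall_to) vm[(fall_to + 1L):hold_to] <- p$Vreset
      v <- if (hold_to >= fall_to) p$Vreset else vm[hold_to]
      ad <- (ad + p$adapt_increment) * decay_ad^(hold_to - i)
      i <- hold_to + 1L
    } else {
      vm[i] <- v
      i <- i + 1L
    }
  }

  keep <- peak_idx <= n
  peak_idx <- peak_idx[keep]
  cross_idx <- cross_idx[keep]
  thr_at_cross <- thr_at_cross[keep]

  n_cycles <- max(1L, floor(duration / p$cycle_period))
  peak_drive <- p$Rm * p$Im * max(env[active])
  label <- if (peak_drive < p$Vthres - p$Vreset) "fluctuation" else "mean"

  structure(list(
    trace = vm_trace(vm, fs = fs),
    spike_times = (peak_idx - 1) / fs,
    onset_times = (cross_idx - 1) / fs,
    spike_thresholds = thr_at_cross,
    regime_label = rep(label, n_cycles),
    params = p, dt = dt, seed = as.integer(seed)),
    class = "simulated_recording")
}

#' @export
print.simulated_recording <- function(x, ...) {
  cat(sprintf("<simulated_recording> %.1f s, %d spikes, regime: %s\n",
              length(x$trace$vm) / x$trace$fs, length(x$spike_times),
              x$regime_label[1]))
  invisible(x)
}

#' Simulate a stationary Ornstein-Uhlenbeck voltage trace
#'
#' A spike-free subthreshold trace with known stationary mean and SD;
#' used for null calibrations of the return-map ratio and as the substrate
#' for hazard-driven spiking.
#'
#' @param duration trace length (s).
#' @param dt step (ms).
#' @param mean stationary mean (mV).
#' @param sd stationary SD (mV).
#' @param tau correlation time constant (ms).
#' @param seed RNG seed.
#' @return a [vm_trace()].
#' @export
simulate_ou_trace <- function(duration, dt = 0.05, mean = -60, sd = 3,
                              tau = 20, seed = 1L) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  n <- floor(duration * 1000 / dt)
  a <- dt / tau
  set.seed(as.integer(seed))
  innov <- sd * sqrt(2 * a) * rnorm(n)
  # AR(1): v[i] = v[i-1] * (1-a) + a*mean + innov
  v <- numeric(n)
  v[1] <- mean + sd * rnorm(1)
  cf <- 1 - a
  for (i in 2:n) v[i] <- v[i - 1] * cf + a * mean + innov[i]
  vm_trace(v, fs = 1000 / dt)
}

#' Draw spikes from a voltage-dependent hazard
#'
#' Inhomogeneous point process on a trace: at each sample, a spike occurs
#' with probability `hazard(Vm) * dt`. With the exponential hazard
#' `nu(V) = c0 * exp(beta * V)` this is the generative model that the
#' FV-curve estimator is designed to invert, so recovery of `(c0, beta)`
#' is a direct consistency check of [estimate_fv_curve()].
#'
#' @param trace a [vm_trace()].
#' @param c0,beta exponential hazard parameters (Hz, 1/mV).
#' @param seed RNG seed.
#' @param refractory minimal spacing between spikes (ms).
#' @return numeric vector of spike times (s).
#' @export
simulate_hazard_spikes <- function(trace, c0, beta, seed = 1L,
                                   refractory = 2) {
  stopifnot(inherits(trace, "vm_trace"))
  if (c0 <= 0) stop("c0 must be positive")
  dt_s <- 1 / trace$fs
  p <- pmin(c0 * exp(beta * trace$vm) * dt_s, 1)
  set.seed(as.integer(seed))
  hit <- which(runif(length(p)) < p)
  if (!length(hit)) return(numeric(0))
  tt <- (hit - 1) * dt_s + trace$t0
  keep <- c(TRUE, diff(tt) >= refractory / 1000)
  # greedy enforcement of the refractory spacing
  out <- tt[1]
  for (t in tt[-1]) if (t - out[length(out)] >= refractory / 1000)
    out <- c(out, t)
  out
}
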