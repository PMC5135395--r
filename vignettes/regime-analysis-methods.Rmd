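---
title: "Methods: classifying fluctuation- versus mean-driven spiking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying fluctuation- versus mean-driven spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regimescope)
```

## The two regimes and what the package measures

A neuron embedded in an active network can fire in two qualitatively
different modes. When the mean input current is strong enough that
`Rm * Im > Vthres - Vrest`, the membrane potential would, absent the spike
mechanism, ride above threshold: spiking is paced by the recharge after
each after-hyperpolarization, inter-spike intervals are regular, and the
firing-rate distribution is symmetric. This is the **mean-driven regime**.
When `Rm * Im < Vthres - Vrest`, the mean potential sits below threshold
and spikes are fired only when synaptic fluctuations carry Vm across it:
intervals are irregular, and the rate distribution is right-skewed on a
linear axis and near-symmetric on a log axis (lognormal-like). This is the
**fluctuation-driven regime**.

The package quantifies regime membership at three levels:

* **subthreshold trajectory** — the *return-map ratio* (RMR): the fraction
  of lagged pairs `(Vm(t), Vm(t + 1.5 ms))` above the unity line, over
  inter-spike segments with spikes excised (±6 ms) and interburst
  stretches (ISI > 300 ms) removed. A direct reset-to-threshold climb
  gives 1; symmetric wandering gives 0.5. Neurons with RMR < 0.7 are
  classified fluctuation-driven. Ties on the unity line are split evenly,
  which keeps the estimate unbiased for quantized voltages and preserves
  the exact identity RMR(reversed trace) = 1 − RMR.
* **spike-train irregularity** — `CV2(i) = 2 |ISI_i − ISI_{i+1}| /
  (ISI_i + ISI_{i+1})`, a local statistic that is 0 for regular firing,
  1 on average for Poisson firing, and at most 2. Per-unit occupancy of
  the fluctuation regime is the fraction of time (span-weighted) and of
  spikes with CV2 above a critical value `icrit`, 0.5 by default with 0.4
  and 0.6 as sensitivity probes. Population occupancy is summarized by
  TIF50/SIF50, the occupancy attained by at least half the units, read at
  the 50% crossing of the reverse cumulative distribution.
* **input-output nonlinearity** — the FV-curve (stochastic intensity):
  the probability of a spike in one sampling interval as a function of the
  instantaneous Vm, estimated as pre-spike-sample counts per voltage bin
  divided by the bin's residence time, with exponential
  (`nu = c exp(beta V)`) and power-law (`nu = k (V − Ea)^alpha`) fits.

Supporting statistics: the moment-estimator skewness of Vm and of
instantaneous rates (linear and natural-log axes), Lorenz/Gini
participation of pooled rates, Gaussian-kernel firing rates with a
cross-validated bandwidth, phase-plane spike-threshold estimation, the
fraction of time the smoothed Vm spends below threshold, and
inverse-square trilateration of extracellular sources.

## The synthetic-data generator

No recordings ship with the package; every analysis is exercised against
generators whose ground truth is known.

`simulate_two_regime_neuron()` integrates a leaky membrane
(Euler, `dt = 0.05` ms, i.e. 20 kHz sampling) with threshold-reset
spiking:

* drive `Im` (nA) against resistance `Rm = 10` MΩ and time constant
  `tau_m = 20` ms; the leak reversal equals the reset potential (−60 mV),
  threshold −45 mV, so the regime boundary sits at `Rm * Im = 15` mV;
* Gaussian white current noise, scaled so the stationary subthreshold Vm
  SD equals `Rm * current_noise_sd` — the distance to threshold is
  therefore programmable directly in fluctuation SDs (the canonical
  fluctuation-regime setting places the mean 3 SDs below threshold);
* a burst-cycle envelope (period 1.6 s, active fraction 0.625, i.e. a
  0.6 s interburst gap in which the drive is off and Vm relaxes ~5 mV
  below reset with small residual noise), with optional raised-cosine
  within-cycle modulation;
* a stylized action potential — linear rise over 1 ms from the
  instantaneous threshold to +20 mV, exponential repolarization
  (τ = 0.6 ms) to reset — inserted at each crossing so that peak
  detection and phase-plane threshold estimation see a realistic
  acceleration profile;
* optional threshold adaptation: an increment at each spike decaying
  exponentially, reproducing rate-dependent threshold depolarization.

`generate_population_raster()` draws per-unit within-burst rates from a
lognormal distribution (defaults: log-mean `log(10)` Hz, log-SD 1 — the
scale at which pooled-rate Gini lands near 0.5), phase-locks each unit's
gamma-renewal burst inside the active window, and records drawn rate,
phase and gamma shape per unit. Gamma shape 1 emulates
fluctuation-regime irregularity, large shapes mean-regime regularity.

`generate_amplitude_map()` places a point source near an 8×8 staggered
probe (8 shanks at 200 µm pitch; per shank two columns 20 µm apart, 30 µm
vertical spacing) and evaluates `S / r²` per electrode with rectified
Gaussian noise.

What the generators do **not** emulate: conductance-based synaptic input
(the disinhibition manipulation is represented by raising `Im`), spike
waveform diversity, electrode drift, spike-sorting errors, and any
correlation structure between units beyond shared cycle timing. Passing
tests therefore demonstrate that the estimators invert the generative
models they assume — not that those models capture every property of real
recordings.

## Numerical and design choices

* **Phase-plane threshold.** With `f = dVm/dt`, the threshold is the
  maximum of `d²f/dVm²` along the trajectory in a 10 ms window before the
  peak, after zero-phase low-pass filtering at 5 kHz
  (second-order Butterworth, skipped when the sampling rate cannot
  support the band). The search stops 0.3 ms short of the peak, where the
  slope crosses zero, and starts at the last non-positive slope so only
  the final approach is scanned; derivative ratios over voltage steps
  below 1 nV are masked. On noisy traces individual estimates scatter by
  a few mV, but the mean recovers a programmed threshold to well within
  1 mV at a hundred spikes.
* **FV-curve.** Voltage bins of 0.5 mV; the pre-spike sample defaults to
  1.7 ms before the peak (a parameter, since the sampling instant
  reasonably ranges over 1.5–1.7 ms); spikes with preceding ISI ≤ 1.7 ms
  are excluded. Fits are nonlinear least squares with each bin weighted
  by its residence time. Residence weighting is proportional to the
  inverse sampling variance of the bin's rate estimate; without it,
  bins visited for less than a millisecond (single-spike rates of
  10³ Hz) dominate the loss and parameter recovery fails even at
  ~600 spikes. An unweighted option is retained. Exact curves are
  recovered to 1e-6 either way; the power-law start point is chosen by
  profiling `Ea` over a coarse grid before the full fit.
* **TIF50/SIF50 crossing.** The reverse cumulative is evaluated at the
  Hazen plotting positions `F(x_(k)) = 1 − (k − 0.5)/n` with linear
  interpolation, which makes the 50% crossing equal the sample median
  exactly for both odd and even n; a plain step-function crossing is
  biased upward for even n.
* **CV2 spans.** The time a CV2 value represents is
  `(ISI_i + ISI_{i+1}) / 2`: each interval is shared between its two
  pairs, so spans tile the burst without double counting. For spike
  fractions each value stands for its middle spike. Two interburst
  thresholds coexist deliberately: 0.5 s for cycle-restricted CV2
  statistics, 0.3 s for Vm-linked exclusions.
* **Kernel rates.** Gaussian kernel on a grid of `bandwidth / 10`,
  truncated at ±5 bandwidths (mass error below 1e-5 of a spike). The
  automatic bandwidth minimizes the leave-one-out cross-validated MISE
  cost over a log-spaced grid from 1 ms to 1 s. For a stationary train
  the cost is minimized by the widest kernel — correct, if
  uninformative; for burst-structured trains the optimum drops to the
  burst timescale.
* **Sigma lag and the membrane time constant.** The spike-triggered
  ("sigma") distribution samples Vm 18 ms before each peak, which
  estimates the free fluctuation size only if the Vm autocorrelation time
  is shorter than that lag. With the default `tau_m = 20` ms (a free
  choice; the recordings' effective constant is not known) the pre-spike
  sample is still conditioned on the approach to threshold and sits a
  couple of mV above the temporal mean; at `tau_m = 5` ms — emulating the
  high-conductance state of an active network — the temporal and
  spike-triggered estimates agree within 1 mV, which is the regime the
  agreement property refers to.
* **Smoothing for time-below-threshold.** A centered moving average,
  default 20 ms, applied before thresholding; the reference threshold is
  the most hyperpolarized per-spike estimate.
* **Trilateration.** `S` has a closed-form profile at fixed position, so
  the search is 2-D, bounded to ±400 µm around the electrode bounding box
  (beyond that the signal is below noise), multi-started from the
  amplitude-weighted centroid and the three largest-amplitude electrodes
  (offset 7–5 µm so the `r ≥ 1 µm` clamp does not flatten the gradient).
  A later start must improve the objective strictly; for degenerate
  symmetric maps (equal amplitudes) this keeps the interior solution
  rather than the equally-good far-field limit. The fit is 2-D in the
  shank plane; out-of-plane distance is absorbed into `S`.
* **Degenerate inputs.** Skewness of samples with fewer than 3 values or
  with variation at floating-point noise level is reported as 0 with a
  `degenerate` flag rather than as an error, so population summaries
  survive pathological units; empty retained-sample sets (all ISIs
  interburst, all pairs excised) raise errors with explicit messages.

## Problem sizes

The test-suite and acceptance computations run at desk scale: single
neurons are simulated for 10–60 s at 20 kHz; the Poisson CV2 anchor uses
a 10 Hz, 1000 s train (~10⁴ intervals); the symmetric-noise return-map
anchor retains 2 × 10⁵ lagged pairs; hazard-recovery uses ~600 spikes over
60 s; population checks use 20–200 units over 8–10 burst cycles; the
trilateration noise calibration uses 100 noise draws. These sizes hold
every stochastic check well inside its stated tolerance while keeping a
full run in about a minute.

## A worked single-neuron example

```{r example}
p <- neuron_params(Im = 0.6, current_noise_sd = 0.3, duty = 1)
rec <- simulate_two_regime_neuron(p, duration = 30, seed = 2)
peaks <- detect_spike_peaks(rec$trace)

return_map_ratio(rec$trace, peaks)
cv2_sequence(peaks)$mean_cv2
se <- suppressWarnings(estimate_thresholds_phase_plane(rec$trace, peaks))
se$mean_threshold
time_below_threshold(rec$trace, se$most_hyperpolarized_threshold)
```

A drive three fluctuation-SDs below threshold yields a low RMR, CV2 near
1, a recovered threshold near the programmed −45 mV, and a smoothed Vm
that spends almost all its time below threshold — the fluctuation-driven
signature on every axis at once.

## Known limitations

The white-noise current simplification makes the subthreshold Vm an
Ornstein–Uhlenbeck process; real synaptic bombardment has heavier
temporal structure. The FV estimator assumes renewal (Poisson-like)
spiking given Vm; strong adaptation violates this. Trilateration assumes
a point source and exact inverse-square decay; real waveform amplitudes
decay with a geometry-dependent exponent. The depth profile inherits the
resolution limits of the 30 µm electrode spacing. None of these
limitations affect the internal consistency checks, but they bound how
far conclusions transfer to recorded data.
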