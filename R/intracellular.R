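#' Detect spike peaks in a membrane-potential trace
#'
#' Local maxima above `min_height`, thinned so that no two kept peaks are
#' closer than `min_separation`; when two candidates collide the larger one
#' wins. Deterministic.
#'
#' @param trace a [vm_trace()].
#' @param min_height minimal peak height (mV); spikes in these recordings
#'   overshoot 0 mV, so the default keeps subthreshold fluctuations out.
#' @param min_separation minimal peak spacing (ms).
#' @return numeric vector of peak times (s); may be empty.
#' @export
detect_spike_peaks <- function(trace, min_height = -10, min_separation = 1) {
  stopifnot(inherits(trace, "vm_trace"))
  v <- trace$vm
  n <- length(v)
  if (n < 3) return(numeric(0))
  cand <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  cand <- cand[v[cand] >= min_height]
  if (!length(cand)) return(numeric(0))
  min_gap <- min_separation / 1000 * trace$fs
  # greedy by height: tallest first, drop neighbours within the gap
  ord <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort((kept - 1) / trace$fs + trace$t0)
}

# zero-phase low-pass of a trace; skipped when the cutoff is at or above
# the usable band
lowpass_vm <- function(trace, cutoff_hz) {
  if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= trace$fs / 2.5)
    return(trace$vm)
  bf <- signal::butter(2, cutoff_hz / (trace$fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, trace$vm))
}

#' Phase-plane spike threshold estimation
#'
#' For each spike, the threshold is taken as the point of strongest
#' acceleration away from baseline on the phase-plane trajectory: with
#' `f = dVm/dt`, the maximum of the second derivative of `f` with respect
#' to `Vm` within a search window before the peak. The trace is low-pass
#' filtered (default 5 kHz) before differentiation to limit noise
#' amplification.
#'
#' @param trace a [vm_trace()].
#' @param peaks spike peak times (s), e.g. from [detect_spike_peaks()].
#' @param search_window how far before each peak to search (ms).
#' @param lowpass_hz low-pass cutoff before differentiation (Hz); ignored
#'   when the sampling rate cannot support it.
#' @return object of class `spike_events`: `peak_times`, `onset_times`,
#'   `threshold_mV` (per spike), `mean_threshold`,
#'   `most_hyperpolarized_threshold`, `threshold_q5` (5% quantile).
#'   Spikes too close to the trace start are dropped with a warning.
#' @export
estimate_thresholds_phase_plane <- function(trace, peaks,
                                            search_window = 10,
                                            lowpass_hz = 5000) {
  stopifnot(inherits(trace, "vm_trace"))
  peaks <- sort(as.numeric(peaks))
  if (!length(peaks)) stop("at least one spike peak is required")
  v <- lowpass_vm(trace, lowpass_hz)
  n <- length(v)
  dt_s <- 1 / trace$fs
  # central-difference slope f = dVm/dt (mV/s)
  f <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) / dt_s

  nw <- max(5L, round(search_window / 1000 * trace$fs))
  # stop short of the peak: the slope crosses zero there, which would
  # defeat the search for the last subthreshold trough
  margin <- max(2L, round(0.3 / 1000 * trace$fs))
  pk_idx <- time_to_index(trace, peaks)
  thr <- onset <- rep(NA_real_, length(peaks))
  dropped <- 0L
  for (k in seq_along(pk_idx)) {
    ip <- pk_idx[k] - margin
    i0 <- ip - nw
    if (i0 < 2L) { dropped <- dropped + 1L; next }
    idx <- i0:ip
    # start from the last slope minimum before the upstroke so the
    # trajectory is a single approach to the peak
    neg <- which(f[idx] <= 0)
    if (length(neg)) idx <- idx[max(neg):length(idx)]
    if (length(idx) < 5L) { dropped <- dropped + 1L; next }
    vv <- v[idx]; ff <- f[idx]
    dv <- diff(vv)
    ok <- abs(dv) > 1e-9
    g <- ifelse(ok, diff(ff) / dv, 0)            # df/dVm at midpoints
    dv2 <- (dv[-1] + dv[-length(dv)]) / 2
    ok2 <- abs(dv2) > 1e-9
    d2 <- ifelse(ok2, diff(g) / dv2, -Inf)       # d2f/dVm2 at interior pts
    if (!any(is.finite(d2))) { dropped <- dropped + 1L; next }
    j <- which.max(d2) + 1L                      # offset into idx
    thr[k] <- vv[j]
    onset[k] <- (idx[j] - 1) * dt_s + trace$t0
  }
  if (dropped > 0)
    warning(sprintf("%d spike(s) too close to the trace start were dropped",
                    dropped))
  keep <- is.finite(thr)
  structure(list(peak_times = peaks[keep], onset_times = onset[keep],
                 threshold_mV = thr[keep],
                 mean_threshold = mean(thr[keep]),
                 most_hyperpolarized_threshold = suppressWarnings(min(thr[keep])),
                 threshold_q5 = unname(quantile(thr[keep], 0.05,
                                                na.rm = TRUE, names = FALSE))),
            class = "spike_events")
}

#' @export
print.spike_events <- function(x, ...) {
  cat(sprintf(
    "<spike_events> %d spikes; threshold mean %.2f mV, min %.2f mV, Q5 %.2f mV\n",
    length(x$peak_times), x$mean_threshold,
    x$most_hyperpolarized_threshold, x$threshold_q5))
  invisible(x)
}

# accept either spike_events or a bare vector of peak times
peak_times_of <- function(spikes) {
  if (inherits(spikes, "spike_events")) spikes$peak_times
  else sort(as.numeric(spikes))
}

new_vm_distribution <- function(values, kind, binwidth = 0.5) {
  n <- length(values)
  if (n == 0) stop("no samples retained for the Vm distribution")
  edges <- seq(floor(min(values) / binwidth) * binwidth,
               ceiling(max(values) / binwidth) * binwidth + binwidth,
               by = binwidth)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  sk <- skewness(values)
  structure(list(bin_edges = edges, counts = counts,
                 mean = mean(values), sd = stats::sd(values),
                 skewness = as.numeric(sk),
                 skewness_degenerate = is_degenerate(sk),
                 n = n, low_n = n < 10, estimator_kind = kind,
                 values = values),
            class = "vm_distribution")
}

#' @export
print.vm_distribution <- function(x, ...) {
  cat(sprintf(
    "<vm_distribution:%s> n=%d, mean %.2f mV, SD %.2f mV, skewness %.3f%s\n",
    x$estimator_kind, x$n, x$mean, x$sd, x$skewness,
    if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' Spike-triggered subthreshold Vm distribution
#'
#' Distribution of Vm sampled a fixed lag before each spike peak (default
#' 18 ms), across spikes whose preceding inter-spike interval lies in
#' `(isi_min, isi_max)`. At that lag the sample sits in the diffusion
#' regime where Vm is not yet causally tied to the upcoming spike, so the
#' spread estimates the size of the synaptic fluctuations ("sigma").
#'
#' @param trace a [vm_trace()].
#' @param spikes `spike_events` or peak times (s).
#' @param lag sampling lag before each peak (ms).
#' @param isi_min,isi_max preceding-ISI inclusion window (ms).
#' @return a `vm_distribution` (estimator_kind `"spike_triggered"`); fewer
#'   than 10 qualifying spikes set the `low_n` flag.
#' @export
spike_triggered_distribution <- function(trace, spikes, lag = 18,
                                         isi_min = 20, isi_max = 300) {
  pk <- peak_times_of(spikes)
  if (length(pk) < 2) stop("need at least two spikes")
  isi_ms <- diff(pk) * 1000
  ok <- which(isi_ms > isi_min & isi_ms < isi_max) + 1L
  t_sample <- pk[ok] - lag / 1000
  ok2 <- t_sample >= trace$t0
  vals <- trace$vm[time_to_index(trace, t_sample[ok2])]
  new_vm_distribution(vals, "spike_triggered")
}

#' Temporal subthreshold Vm distribution
#'
#' Distribution of Vm over inter-spike segments, excising a window around
#' each spike peak. Only segments whose ISI lies in `(isi_min, isi_max)`
#' contribute, so interburst intervals and spike waveforms are excluded.
#'
#' @param trace a [vm_trace()].
#' @param spikes `spike_events` or peak times (s).
#' @param isi_min,isi_max ISI inclusion window (ms).
#' @param excise half-width of the spike excision window (ms).
#' @return a `vm_distribution` (estimator_kind `"temporal"`).
#' @export
temporal_distribution <- function(trace, spikes, isi_min = 6,
                                  isi_max = 300, excise = 6) {
  pk <- peak_times_of(spikes)
  if (length(pk) < 2) stop("need at least two spikes")
  segs <- retained_segments(trace, pk, excise = excise,
                            isi_min = isi_min, isi_max = isi_max)
  vals <- unlist(lapply(segs, function(ii) trace$vm[ii]), use.names = FALSE)
  if (!length(vals)) stop("no samples retained between spikes")
  new_vm_distribution(vals, "temporal")
}

# index ranges of inter-spike segments after spike excision; segments whose
# ISI falls outside (isi_min, isi_max) (ms) are dropped entirely. With no
# spikes the whole trace is one segment.
retained_segments <- function(trace, peaks, excise = 6, isi_min = 0,
                              isi_max = Inf) {
  n <- length(trace$vm)
  if (!length(peaks)) return(list(seq_len(n)))
  pk_idx <- time_to_index(trace, peaks)
  nex <- round(excise / 1000 * trace$fs)
  segs <- list()
  for (k in seq_len(length(pk_idx) - 1L)) {
    isi_ms <- (peaks[k + 1] - peaks[k]) * 1000
    if (isi_ms <= isi_min || isi_ms >= isi_max) next
    i0 <- pk_idx[k] + nex + 1L
    i1 <- pk_idx[k + 1] - nex - 1L
    if (i1 >= i0) segs[[length(segs) + 1L]] <- i0:i1
  }
  segs
}

#' Return-map ratio of the inter-spike Vm trajectory
#'
#' Plots `Vm(t)` against `Vm(t + lag)` over all retained inter-spike
#' samples and reports the fraction of points above the unity line. A
#' direct (mean-driven) trajectory from reset to threshold rises
#' monotonically, so every lagged pair lies above the line and the ratio
#' approaches 1; a fluctuation-driven trajectory wanders, giving a ratio
#' near 0.5. Points exactly on the line are split evenly between the two
#' sides. Spike waveforms are excised (`excise` ms either side of each
#' peak) and interburst segments (ISI > `interburst_ms`) removed; with no
#' spikes at all the whole trace is used.
#'
#' @param trace a [vm_trace()].
#' @param spikes `spike_events`, peak times (s), or `NULL`/empty for a
#'   spike-free trace.
#' @param lag return-map lag (ms).
#' @param excise half-width of the spike excision window (ms).
#' @param interburst_ms ISIs above this are treated as interburst and
#'   removed (ms).
#' @param cutoff classification cutoff: ratio below it is called
#'   fluctuation-driven.
#' @return object of class `regime_metrics`: `return_map_ratio`,
#'   `n_pairs`, `is_fluctuation_driven`.
#' @export
return_map_ratio <- function(trace, spikes = NULL, lag = 1.5, excise = 6,
                             interburst_ms = 300, cutoff = 0.7) {
  stopifnot(inherits(trace, "vm_trace"))
  pk <- if (is.null(spikes)) numeric(0) else peak_times_of(spikes)
  segs <- retained_segments(trace, pk, excise = excise,
                            isi_min = 0, isi_max = interburst_ms)
  L <- max(1L, round(lag / 1000 * trace$fs))
  above <- below <- ties <- 0
  for (ii in segs) {
    m <- length(ii)
    if (m <= L) next
    x <- trace$vm[ii[1:(m - L)]]
    y <- trace$vm[ii[(L + 1):m]]
    above <- above + sum(y > x)
    below <- below + sum(y < x)
    ties <- ties + sum(y == x)
  }
  tot <- above + below + ties
  if (tot == 0) stop("no retained lagged pairs between spikes")
  ratio <- (above + ties / 2) / tot
  structure(list(return_map_ratio = ratio, n_pairs = tot,
                 is_fluctuation_driven = ratio < cutoff, cutoff = cutoff),
            class = "regime_metrics")
}

#' @export
print.regime_metrics <- function(x, ...) {
  cat(sprintf("<regime_metrics> RMR = %.3f (n = %d) -> %s-driven\n",
              x$return_map_ratio, x$n_pairs,
              if (x$is_fluctuation_driven) "fluctuation" else "mean"))
  invisible(x)
}

#' Fraction of time spent below threshold
#'
#' Fraction of samples of the smoothed trace strictly below a threshold,
#' typically the most hyperpolarized spike threshold of the neuron. A
#' neuron whose smoothed Vm spends most of its time below threshold is
#' operating in the fluctuation-driven regime.
#'
#' @param trace a [vm_trace()].
#' @param threshold threshold (mV).
#' @param smoothing moving-average window (ms); 0 disables smoothing.
#' @return fraction in `[0, 1]`.
#' @export
time_below_threshold <- function(trace, threshold, smoothing = 20) {
  stopifnot(inherits(trace, "vm_trace"), is.finite(threshold))
  v <- trace$vm
  w <- round(smoothing / 1000 * trace$fs)
  if (w > 1) {
    k <- rep(1 / w, w)
    v <- as.numeric(stats::filter(v, k, sides = 2))
    v <- v[!is.na(v)]
  }
  mean(v < threshold)
}

#' Normalized subthreshold distance to threshold
#'
#' `(mean(Vm) - mean threshold) / sigma`, with sigma the SD of the
#' subthreshold Vm distribution: how many fluctuation SDs the mean
#' membrane potential sits below the spike threshold. Around -3 the
#' neuron only reaches threshold on rare transients.
#'
#' @param vm_dist a `vm_distribution`.
#' @param spikes a `spike_events` (its `mean_threshold` is used) or a
#'   numeric threshold (mV).
#' @return signed scalar (negative below threshold).
#' @export
normalized_threshold_distance <- function(vm_dist, spikes) {
  stopifnot(inherits(vm_dist, "vm_distribution"))
  thr <- if (inherits(spikes, "spike_events")) spikes$mean_threshold
         else as.numeric(spikes)
  if (!is.finite(vm_dist$sd) || vm_dist$sd <= 0)
    stop("sigma of the Vm distribution must be positive")
  (vm_dist$mean - thr) / vm_dist$sd
}
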