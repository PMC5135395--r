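#' Empirical firing rate versus membrane potential (FV-curve)
#'
#' Estimates the stochastic intensity nu(Vm): the probability of spiking in
#' one sampling interval given the instantaneous Vm, divided by that
#' interval. Operationally, Vm is sampled a fixed lag before each spike
#' peak (the pre-spike sample), the pre-spike samples are binned by
#' voltage, and each bin's count is normalized by the total time the trace
#' spends in that bin:
#' `nu(V) = (# pre-spike samples in bin) / (residence time of bin)`.
#'
#' @param trace a [vm_trace()].
#' @param spikes `spike_events` or peak times (s).
#' @param pre_lag lag of the pre-spike sample before the peak (ms). The
#'   default 1.7 ms sits just before the spike upstroke; set to 0 when the
#'   spike times already mark the hazard evaluation instant (e.g. from
#'   [simulate_hazard_spikes()]).
#' @param bin_width Vm bin width (mV).
#' @param min_isi spikes whose preceding ISI is at or below this (ms) are
#'   excluded.
#' @param exclude mask of trace samples (logical or index vector) to drop
#'   from the residence-time accounting, e.g. spike waveforms; `NULL`
#'   keeps all samples (the estimator's normalization is over all time).
#' @return object of class `fv_curve`: `vm_bin_centers`, `residence_s`,
#'   `pre_spike_counts`, `rate_hz`, `dt_s`, `n_spikes_used`. Bins with zero
#'   residence are excluded.
#' @export
estimate_fv_curve <- function(trace, spikes, pre_lag = 1.7,
                              bin_width = 0.5, min_isi = 1.7,
                              exclude = NULL) {
  stopifnot(inherits(trace, "vm_trace"))
  pk <- peak_times_of(spikes)
  if (!length(pk)) stop("at least one spike is required")
  keep <- c(TRUE, diff(pk) * 1000 > min_isi)
  t_pre <- pk[keep] - pre_lag / 1000
  t_pre <- t_pre[t_pre >= trace$t0]
  pre_v <- trace$vm[time_to_index(trace, t_pre)]

  v_all <- trace$vm
  if (!is.null(exclude)) v_all <- v_all[-which(exclude)]
  dt_s <- 1 / trace$fs
  lo <- floor(min(v_all, pre_v) / bin_width) * bin_width
  hi <- ceiling(max(v_all, pre_v) / bin_width) * bin_width + bin_width
  edges <- seq(lo, hi, by = bin_width)
  res_counts <- tabulate(findInterval(v_all, edges, rightmost.closed = TRUE),
                         nbins = length(edges) - 1L)
  pre_counts <- tabulate(findInterval(pre_v, edges, rightmost.closed = TRUE),
                         nbins = length(edges) - 1L)
  keep_bin <- res_counts > 0
  centers <- (edges[-length(edges)] + edges[-1]) / 2
  structure(list(vm_bin_centers = centers[keep_bin],
                 residence_s = res_counts[keep_bin] * dt_s,
                 pre_spike_counts = pre_counts[keep_bin],
                 rate_hz = pre_counts[keep_bin] / (res_counts[keep_bin] * dt_s),
                 dt_s = dt_s, bin_width = bin_width,
                 n_spikes_used = length(t_pre)),
            class = "fv_curve")
}

#' @export
print.fv_curve <- function(x, ...) {
  cat(sprintf(
    "<fv_curve> %d bins (%.1f..%.1f mV), %d spikes, peak rate %.1f Hz\n",
    length(x$vm_bin_centers), min(x$vm_bin_centers),
    max(x$vm_bin_centers), x$n_spikes_used, max(x$rate_hz)))
  invisible(x)
}

fv_fit_points <- function(curve, weights = "residence") {
  stopifnot(inherits(curve, "fv_curve"))
  ok <- curve$residence_s > 0
  w <- if (identical(weights, "residence"))
    curve$residence_s[ok] / max(curve$residence_s[ok])
  else rep(1, sum(ok))
  list(v = curve$vm_bin_centers[ok], nu = curve$rate_hz[ok], w = w)
}

#' Exponential fit of an FV-curve
#'
#' Nonlinear least squares of `nu(V) = c * exp(beta * V)` on the populated
#' bins of an [estimate_fv_curve()] result. `beta` (1/mV) measures the
#' expansive curvature of the subthreshold input-output nonlinearity.
#'
#' @param curve an `fv_curve`.
#' @param min_bins,min_span_mV minimal number of populated bins and Vm span
#'   required to attempt the fit.
#' @param weights `"residence"` (default) weights each bin by its
#'   residence time, which is proportional to the inverse sampling
#'   variance of the bin's rate estimate and keeps sparsely visited
#'   high-voltage bins from dominating; `"none"` gives ordinary
#'   unweighted least squares. Weighting leaves an exact (noiseless)
#'   curve's fit unchanged.
#' @return list `c`, `beta`, `converged`; on failure `converged = FALSE`
#'   and the parameters are `NA`.
#' @export
fit_fv_exponential <- function(curve, min_bins = 3, min_span_mV = 5,
                               weights = c("residence", "none")) {
  weights <- match.arg(weights)
  pts <- fv_fit_points(curve, weights)
  fail <- list(c = NA_real_, beta = NA_real_, converged = FALSE)
  if (length(pts$v) < min_bins || diff(range(pts$v)) < min_span_mV)
    return(fail)
  pos <- pts$nu > 0
  if (sum(pos) < 2) return(fail)
  # log-linear start, then least squares on the rate scale
  st <- unname(stats::coef(stats::lm(log(pts$nu[pos]) ~ pts$v[pos],
                                     weights = pts$w[pos])))
  fit <- tryCatch(
    minpack.lm::nlsLM(nu ~ c0 * exp(beta * v),
                      data = data.frame(v = pts$v, nu = pts$nu),
                      start = list(c0 = exp(st[1]), beta = st[2]),
                      weights = pts$w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  list(c = unname(cf["c0"]), beta = unname(cf["beta"]), converged = TRUE)
}

#' Power-law fit of an FV-curve
#'
#' Nonlinear least squares of `nu(V) = k * (V - Ea)^alpha` with `Ea` below
#' every fitted voltage; `alpha` is the expansive power (typically 2-5 in
#' subthreshold nonlinearities).
#'
#' @inheritParams fit_fv_exponential
#' @return list `k`, `alpha`, `Ea`, `converged`.
#' @export
fit_fv_powerlaw <- function(curve, min_bins = 3, min_span_mV = 5,
                            weights = c("residence", "none")) {
  weights <- match.arg(weights)
  pts <- fv_fit_points(curve, weights)
  fail <- list(k = NA_real_, alpha = NA_real_, Ea = NA_real_,
               converged = FALSE)
  if (length(pts$v) < min_bins || diff(range(pts$v)) < min_span_mV)
    return(fail)
  pos <- pts$nu > 0
  if (sum(pos) < 3) return(fail)
  vmin <- min(pts$v)
  # grid over Ea with log-linear profile fits for (k, alpha) start values
  best <- NULL
  for (off in c(0.5, 1, 2, 5, 10, 20, 40)) {
    ea <- vmin - off
    st <- unname(stats::coef(stats::lm(log(pts$nu[pos]) ~ log(pts$v[pos] - ea),
                                       weights = pts$w[pos])))
    pred <- exp(st[1]) * (pts$v - ea)^st[2]
    sse <- sum((pts$nu - pred)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(k = exp(st[1]), alpha = st[2], ea = ea, sse = sse)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(nu ~ k * (v - Ea)^alpha,
                      data = data.frame(v = pts$v, nu = pts$nu),
                      start = list(k = best$k, alpha = best$alpha,
                                   Ea = best$ea),
                      weights = pts$w,
                      upper = c(k = Inf, alpha = Inf, Ea = vmin - 1e-6),
                      lower = c(k = 0, alpha = 1e-6, Ea = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  list(k = unname(cf["k"]), alpha = unname(cf["alpha"]),
       Ea = unname(cf["Ea"]), converged = TRUE)
}
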