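#' Local irregularity sequence CV2
#'
#' For each pair of adjacent inter-spike intervals,
#' `CV2(i) = 2 |ISI_i - ISI_(i+1)| / (ISI_i + ISI_(i+1))`.
#' CV2 is 0 for a regular process, 1 on average for a Poisson process, and
#' bounded by 2. Unlike the global CV it is robust to slow rate drifts,
#' which is what makes it usable on burst-modulated trains.
#'
#' Each value is annotated with the time span it represents
#' (`(ISI_i + ISI_(i+1)) / 2`, used for time-weighted regime occupancy),
#' the time of its middle spike, and an interburst mask (`TRUE` when either
#' ISI reaches `interburst_s`). The mean is reported both over all pairs
#' and with interburst pairs excluded.
#'
#' @param spike_times sorted spike times (s).
#' @param interburst_s ISIs at or above this (s) are flagged interburst.
#' @return object of class `cv2_sequence`: `values`, `spans_s`, `times`
#'   (middle-spike times), `interburst`, `mean_cv2` (all pairs),
#'   `mean_cv2_within` (interburst pairs excluded), `n`. Fewer than 3
#'   spikes give an empty sequence.
#' @examples
#' cv2_sequence(c(0, 0.1, 0.4))$values  # 2*0.2/0.4 = 1
#' @export
cv2_sequence <- function(spike_times, interburst_s = 0.5) {
  st <- sort(as.numeric(spike_times))
  if (length(st) < 3) {
    return(structure(list(values = numeric(0), spans_s = numeric(0),
                          times = numeric(0), interburst = logical(0),
                          mean_cv2 = NA_real_, mean_cv2_within = NA_real_,
                          n = 0L), class = "cv2_sequence"))
  }
  isi <- diff(st)
  i1 <- isi[-length(isi)]
  i2 <- isi[-1]
  values <- 2 * abs(i1 - i2) / (i1 + i2)
  ib <- i1 >= interburst_s | i2 >= interburst_s
  structure(list(values = values, spans_s = (i1 + i2) / 2,
                 times = st[seq_along(values) + 1L], interburst = ib,
                 mean_cv2 = mean(values),
                 mean_cv2_within = if (any(!ib)) mean(values[!ib]) else NA_real_,
                 n = length(values)),
            class = "cv2_sequence")
}

#' @export
print.cv2_sequence <- function(x, ...) {
  cat(sprintf(
    "<cv2_sequence> %d pairs, mean CV2 %.3f (within-burst %.3f, %d interburst)\n",
    x$n, x$mean_cv2, x$mean_cv2_within, sum(x$interburst)))
  invisible(x)
}

#' Instantaneous firing-rate distribution of a unit
#'
#' Rates are the inverses of the inter-spike intervals, with interburst
#' intervals (ISI >= `interburst_threshold`) excluded since the quiescent
#' gaps between burst cycles sample an irrelevant part of the neuron's
#' input-output function. Reports skewness on the linear and natural-log
#' axes and a lognormal fit by moments of the log rates. A
#' fluctuation-driven unit has positive linear skewness and near-zero log
#' skewness (lognormal-like); a mean-driven unit is symmetric on the
#' linear axis.
#'
#' @param spike_times sorted spike times (s).
#' @param interburst_threshold ISI exclusion threshold (s).
#' @return object of class `rate_distribution`: `rates_hz`,
#'   `skewness_linear`, `skewness_log`, `meanlog`, `sdlog`, `n`, and
#'   degeneracy flags.
#' @export
rate_distribution <- function(spike_times, interburst_threshold = 0.3) {
  st <- sort(as.numeric(spike_times))
  isi <- diff(st)
  isi <- isi[isi > 0 & isi < interburst_threshold]
  if (length(isi) < 3)
    stop("fewer than 3 within-burst inter-spike intervals")
  r <- 1 / isi
  sk_lin <- skewness(r)
  sk_log <- skewness(log(r))
  structure(list(rates_hz = r,
                 skewness_linear = as.numeric(sk_lin),
                 skewness_log = as.numeric(sk_log),
                 degenerate = is_degenerate(sk_lin) || is_degenerate(sk_log),
                 meanlog = mean(log(r)), sdlog = stats::sd(log(r)),
                 n = length(r)),
            class = "rate_distribution")
}

#' @export
print.rate_distribution <- function(x, ...) {
  cat(sprintf(
    "<rate_distribution> n=%d, skew lin %.2f / log %.2f, lognormal(%.2f, %.2f)\n",
    x$n, x$skewness_linear, x$skewness_log, x$meanlog, x$sdlog))
  invisible(x)
}

#' Kernel estimate of the time-dependent firing rate
#'
#' Convolves the spike train with a Gaussian kernel of SD `bandwidth`.
#' With `bandwidth = "auto"` the bandwidth minimizes the leave-one-out
#' cross-validated mean integrated squared error over a log-spaced search
#' grid (the fixed-kernel cost of the Shimazaki-Shinomoto method). The
#' rate is evaluated on a uniform grid with step `bandwidth / 10`,
#' kernels truncated at 5 bandwidths; its integral over the grid equals
#' the spike count up to quadrature error.
#'
#' @param spike_times spike times (s), at least one.
#' @param bandwidth kernel SD (s), or `"auto"`.
#' @param search_range bandwidth search range (s) for `"auto"`.
#' @param n_grid_search number of candidate bandwidths.
#' @param default_bandwidth fallback (s) when optimization is impossible
#'   (single spike).
#' @return object of class `kernel_rate`: `time_s`, `rate_hz`,
#'   `bandwidth_s`, and (for auto) `search` (data.frame of candidate
#'   bandwidth and cost).
#' @export
kernel_rate <- function(spike_times, bandwidth = "auto",
                        search_range = c(0.001, 1), n_grid_search = 40,
                        default_bandwidth = 0.05) {
  st <- sort(as.numeric(spike_times))
  n <- length(st)
  if (n < 1) stop("at least one spike is required")
  search <- NULL
  if (identical(bandwidth, "auto")) {
    if (n < 2) {
      warning("single spike: falling back to the default bandwidth")
      bandwidth <- default_bandwidth
    } else {
      stu <- if (n > 4000) sort(sample(st, 4000)) else st
      d <- outer(stu, stu, "-")
      d <- d[upper.tri(d)]
      # C(w) = sum_{i,j} phi(d_ij; sqrt(2) w) - 2 sum_{i!=j} phi(d_ij; w);
      # the diagonal contributes N / (2 sqrt(pi) w), off-diagonal pairs twice
      ws <- exp(seq(log(search_range[1]), log(search_range[2]),
                    length.out = n_grid_search))
      cost <- vapply(ws, function(w)
        length(stu) / (2 * sqrt(pi) * w) +
          2 * sum(dnorm(d, sd = sqrt(2) * w) - 2 * dnorm(d, sd = w)),
        numeric(1))
      search <- data.frame(bandwidth_s = ws, cost = cost)
      bandwidth <- ws[which.min(cost)]
    }
  }
  w <- as.numeric(bandwidth)
  if (w <= 0) stop("bandwidth must be positive")
  dt <- w / 10
  grid <- seq(st[1] - 5 * w, st[n] + 5 * w, by = dt)
  rate <- numeric(length(grid))
  half <- 5 * w
  for (t in st) {
    i0 <- max(1L, ceiling((t - half - grid[1]) / dt) + 1L)
    i1 <- min(length(grid), floor((t + half - grid[1]) / dt) + 1L)
    if (i1 >= i0)
      rate[i0:i1] <- rate[i0:i1] + dnorm(grid[i0:i1] - t, sd = w)
  }
  structure(list(time_s = grid, rate_hz = rate, bandwidth_s = w,
                 n_spikes = n, search = search),
            class = "kernel_rate")
}

#' @export
print.kernel_rate <- function(x, ...) {
  cat(sprintf("<kernel_rate> %d spikes, bandwidth %.1f ms, peak %.1f Hz\n",
              x$n_spikes, 1000 * x$bandwidth_s, max(x$rate_hz)))
  invisible(x)
}

#' Integrated rate mass of a kernel estimate
#' @param kr a [kernel_rate()].
#' @return trapezoidal integral of the rate over its grid (should equal
#'   the spike count).
#' @export
kernel_rate_mass <- function(kr) {
  stopifnot(inherits(kr, "kernel_rate"))
  dt <- diff(kr$time_s)
  sum((kr$rate_hz[-1] + kr$rate_hz[-length(kr$rate_hz)]) / 2 * dt)
}

#' Sample a kernel-rate estimate at arbitrary times
#' @param kr a [kernel_rate()].
#' @param at times (s).
#' @return rates (Hz), 0 outside the estimated grid.
#' @export
kernel_rate_at <- function(kr, at) {
  stopifnot(inherits(kr, "kernel_rate"))
  out <- stats::approx(kr$time_s, kr$rate_hz, xout = at, rule = 2)$y
  out[at < kr$time_s[1] | at > kr$time_s[length(kr$time_s)]] <- 0
  out
}
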