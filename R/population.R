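#' Pooled firing-rate distribution across a population
#'
#' Per-unit spike-count firing rates over a set of episode windows, pooled
#' across units, with a lognormal fit (moments of the log rates) and
#' skewness on linear and log axes. Silent units are excluded and counted.
#'
#' @param raster named list of per-unit spike-time vectors (s).
#' @param windows two-column matrix or data.frame of episode windows
#'   (start_s, end_s); `NULL` uses the full span of the raster.
#' @return object of class `pooled_rates`: `rates_hz` (per contributing
#'   unit), `unit_id`, `n_silent`, `skewness_linear`, `skewness_log`,
#'   `meanlog`, `sdlog`.
#' @export
pooled_rate_distribution <- function(raster, windows = NULL) {
  if (is.null(names(raster))) names(raster) <- paste0("u", seq_along(raster))
  if (is.null(windows)) {
    allt <- unlist(raster, use.names = FALSE)
    if (!length(allt)) stop("raster contains no spikes")
    windows <- cbind(min(allt), max(allt) + 1e-9)
  }
  windows <- as.matrix(windows)
  total <- sum(windows[, 2] - windows[, 1])
  if (total <= 0) stop("episode windows have zero total duration")
  counts <- vapply(raster, function(st) {
    sum(vapply(seq_len(nrow(windows)), function(i)
      sum(st >= windows[i, 1] & st < windows[i, 2]), numeric(1)))
  }, numeric(1))
  act <- counts > 0
  if (sum(act) < 2) stop("need at least 2 units with spikes in the windows")
  r <- counts[act] / total
  structure(list(rates_hz = r, unit_id = names(raster)[act],
                 n_silent = sum(!act),
                 skewness_linear = as.numeric(skewness(r)),
                 skewness_log = as.numeric(skewness(log(r))),
                 meanlog = mean(log(r)), sdlog = stats::sd(log(r))),
            class = "pooled_rates")
}

#' @export
print.pooled_rates <- function(x, ...) {
  cat(sprintf(
    "<pooled_rates> %d units (%d silent), skew lin %.2f / log %.2f, lognormal(%.2f, %.2f)\n",
    length(x$rates_hz), x$n_silent, x$skewness_linear, x$skewness_log,
    x$meanlog, x$sdlog))
  invisible(x)
}

#' Lorenz curve and Gini coefficient of firing-rate participation
#'
#' Sorts the rates ascending and accumulates population and rate shares;
#' the Gini coefficient is `1 - 2 b` with `b` the trapezoidal area under
#' the Lorenz curve. 0 means every unit participates equally; values near
#' 1 mean a small minority carries almost all spikes.
#'
#' @param rates non-negative per-unit rates (Hz), at least one positive.
#' @return object of class `lorenz_curve`: `x` (cumulative population
#'   share), `y` (cumulative rate share), `area_b`, `gini`.
#' @examples
#' lorenz_gini(c(1, 1, 1, 9))$gini  # 0.5
#' @export
lorenz_gini <- function(rates) {
  r <- as.numeric(rates)
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0")
  if (all(r == 0)) stop("at least one rate must be positive")
  n <- length(r)
  s <- sort(r)
  x <- (0:n) / n
  y <- c(0, cumsum(s)) / sum(s)
  b <- sum(diff(x) * (y[-1] + y[-(n + 1)]) / 2)
  structure(list(x = x, y = y, area_b = b, gini = 1 - 2 * b),
            class = "lorenz_curve")
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat(sprintf("<lorenz_curve> n = %d, Gini = %.3f\n", length(x$x) - 1, x$gini))
  invisible(x)
}

#' Fraction of time and of spikes in the fluctuation regime
#'
#' Occupancy of the fluctuation regime for one unit, defined as local
#' irregularity above a critical value (`CV2 > icrit`). The time fraction
#' weights each CV2 value by the span it covers
#' (`(ISI_i + ISI_(i+1)) / 2`); the spike fraction counts each CV2 value
#' as its middle spike. Interburst pairs are excluded from both.
#'
#' @param cv2_seq a [cv2_sequence()].
#' @param icrit critical irregularity; 0.5 by default (0.4 and 0.6 probe
#'   sensitivity).
#' @return list `time_fraction`, `spike_fraction`, `icrit`, `n_pairs`.
#' @export
regime_fractions <- function(cv2_seq, icrit = 0.5) {
  stopifnot(inherits(cv2_seq, "cv2_sequence"))
  if (icrit <= 0 || icrit >= 2) stop("icrit must lie in (0, 2)")
  keep <- !cv2_seq$interburst
  if (!any(keep))
    return(list(time_fraction = NA_real_, spike_fraction = NA_real_,
                icrit = icrit, n_pairs = 0L))
  v <- cv2_seq$values[keep]
  w <- cv2_seq$spans_s[keep]
  list(time_fraction = sum(w * (v > icrit)) / sum(w),
       spike_fraction = mean(v > icrit),
       icrit = icrit, n_pairs = length(v))
}

#' Empirical reverse cumulative distribution of unit fractions
#'
#' `F(t)` = fraction of units whose per-unit fraction is at least `t`,
#' evaluated at the Hazen plotting positions
#' (`F(x_(k)) = 1 - (k - 0.5) / n` at the k-th order statistic) with
#' linear interpolation between them. The 50% crossing of this curve
#' equals the sample median of the fractions exactly, for odd and even n.
#'
#' @param fractions per-unit fractions in `[0, 1]`, n >= 2.
#' @param grid optional grid of `t` values on which to tabulate `F`.
#' @return object of class `reverse_cumulative`: `t`, `F` (tabulated on
#'   `grid` by direct counting), `crossing_50` (interpolated 50%
#'   crossing), `n`.
#' @export
reverse_cumulative <- function(fractions, grid = seq(0, 1, by = 0.01)) {
  x <- sort(as.numeric(fractions))
  n <- length(x)
  if (n < 2) stop("need at least 2 units")
  Fg <- vapply(grid, function(t) mean(x >= t), numeric(1))
  Fk <- 1 - (seq_len(n) - 0.5) / n
  # x may contain ties; F is strictly decreasing in k, so invert on F
  # (reversed so the abscissa is increasing)
  crossing <- stats::approx(rev(Fk), rev(x), xout = 0.5,
                            ties = "ordered")$y
  structure(list(t = grid, F = Fg, crossing_50 = crossing, n = n),
            class = "reverse_cumulative")
}

#' Population occupancy of the fluctuation regime: TIF50 and SIF50
#'
#' TIF50 is the fraction of time in the fluctuation regime attained by at
#' least half of the units, read off the 50% crossing of the reverse
#' cumulative distribution of per-unit time fractions; SIF50 is the
#' spike-weighted analogue. Both are reported as percentages.
#'
#' @param time_fractions per-unit time fractions with `CV2 > icrit`.
#' @param spike_fractions per-unit spike fractions; optional.
#' @param grid tabulation grid, see [reverse_cumulative()].
#' @return list `tif50` (percent), `sif50` (percent or `NA`),
#'   `time_curve`, `spike_curve` (reverse cumulatives).
#' @export
tif50_sif50 <- function(time_fractions, spike_fractions = NULL,
                        grid = seq(0, 1, by = 0.01)) {
  tc <- reverse_cumulative(time_fractions, grid)
  sc <- if (!is.null(spike_fractions))
    reverse_cumulative(spike_fractions, grid) else NULL
  list(tif50 = 100 * tc$crossing_50,
       sif50 = if (is.null(sc)) NA_real_ else 100 * sc$crossing_50,
       time_curve = tc, spike_curve = sc)
}

#' Time-resolved log-rate statistics across a population
#'
#' Kernel firing rates of all units are sampled on a common grid of bins;
#' in each bin with enough active units the distribution of log rates
#' across units is summarized (mean, SD, skewness), and the Pearson
#' correlation between the population log-mean and the log skewness across
#' bins is reported. A negative correlation means that epochs of high
#' population rate compress the top of the rate distribution (more
#' mean-driven), skewing the log-rate distribution negative.
#'
#' @param raster named list of per-unit spike-time vectors (s).
#' @param bin bin width (s).
#' @param bandwidth kernel bandwidth (s) passed to [kernel_rate()]; a
#'   fixed value by default so the grid is common across units.
#' @param min_active minimal number of active units for a bin to count.
#' @param active_floor_hz rate below which a unit is considered inactive
#'   in a bin.
#' @param t_range analysis span (s); default the raster span.
#' @return object of class `time_resolved_skewness`: data.frame `bins`
#'   (`t`, `n_active`, `log_mean`, `log_sd`, `skewness_log`) and
#'   `correlation` (list `r`, `p`, `n`, possibly flagged undefined).
#' @export
time_resolved_log_skewness <- function(raster, bin = 0.01,
                                       bandwidth = 0.02, min_active = 10,
                                       active_floor_hz = 0.5,
                                       t_range = NULL) {
  if (length(raster) < min_active)
    stop("fewer units than `min_active`")
  allt <- unlist(raster, use.names = FALSE)
  if (is.null(t_range)) t_range <- range(allt)
  centers <- seq(t_range[1] + bin / 2, t_range[2], by = bin)
  rate_mat <- vapply(raster, function(st) {
    if (!length(st)) return(numeric(length(centers)))
    kernel_rate_at(kernel_rate(st, bandwidth = bandwidth), centers)
  }, numeric(length(centers)))
  stats_per_bin <- apply(rate_mat, 1, function(rr) {
    act <- rr > active_floor_hz
    if (sum(act) < min_active) return(c(NA, NA, NA, sum(act)))
    lr <- log(rr[act])
    c(mean(lr), stats::sd(lr), as.numeric(skewness(lr)), sum(act))
  })
  bins <- data.frame(t = centers,
                     log_mean = stats_per_bin[1, ],
                     log_sd = stats_per_bin[2, ],
                     skewness_log = stats_per_bin[3, ],
                     n_active = stats_per_bin[4, ])
  ok <- stats::complete.cases(bins)
  if (!any(ok)) stop("no bin reached `min_active` active units")
  corr <- correlate(bins$log_mean[ok], bins$skewness_log[ok])
  structure(list(bins = bins[ok, , drop = FALSE], correlation = corr),
            class = "time_resolved_skewness")
}

#' Depth profile of spiking irregularity
#'
#' Bins units by (insertion-corrected) depth, summarizes the CV2
#' distribution per depth bin, and runs pairwise two-sample
#' Kolmogorov-Smirnov tests between bins to ask whether irregularity
#' differs along the dorsoventral axis.
#'
#' @param units data.frame with columns `mean_cv2` and `depth_um`.
#' @param bin depth bin width (um).
#' @param min_units bins with fewer units are skipped.
#' @return object of class `depth_profile`: `bins` (data.frame `depth_lo`,
#'   `depth_hi`, `n`, `mean_cv2`), `ks_D` and `ks_p` (pairwise matrices),
#'   and `groups` (per-bin CV2 vectors).
#' @export
depth_profile <- function(units, bin = 200, min_units = 5) {
  stopifnot(all(c("mean_cv2", "depth_um") %in% names(units)))
  u <- units[is.finite(units$mean_cv2) & is.finite(units$depth_um), ]
  lo <- floor(min(u$depth_um) / bin) * bin
  br <- seq(lo, max(u$depth_um) + bin, by = bin)
  idx <- findInterval(u$depth_um, br, rightmost.closed = TRUE)
  groups <- split(u$mean_cv2, idx)
  sizes <- lengths(groups)
  groups <- groups[sizes >= min_units]
  if (!length(groups)) stop("no depth bin reached `min_units` units")
  gi <- as.integer(names(groups))
  bins <- data.frame(depth_lo = br[gi], depth_hi = br[gi + 1],
                     n = lengths(groups),
                     mean_cv2 = vapply(groups, mean, numeric(1)))
  m <- length(groups)
  D <- P <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i >= j) next
    kt <- suppressWarnings(stats::ks.test(groups[[i]], groups[[j]]))
    D[i, j] <- D[j, i] <- unname(kt$statistic)
    P[i, j] <- P[j, i] <- kt$p.value
  }
  structure(list(bins = bins, ks_D = D, ks_p = P, groups = groups),
            class = "depth_profile")
}
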