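test_that("Gini matches hand-computed Lorenz areas and its limits", {
  expect_equal(lorenz_gini(rep(5, 10))$gini, 0)
  # sorted (1,1,1,9): Lorenz y = 1/12, 2/12, 3/12, 1 -> b = 0.25
  lg <- lorenz_gini(c(1, 1, 1, 9))
  expect_equal(lg$area_b, 0.25)
  expect_equal(lg$gini, 0.5)
  expect_error(lorenz_gini(c(0, 0)), "positive")
  expect_error(lorenz_gini(c(-1, 2)), ">= 0")
})

test_that("Gini is scale invariant and rises under regressive transfers", {
  set.seed(8)
  for (i in 1:5) {
    r <- rlnorm(50)
    expect_equal(lorenz_gini(r)$gini, lorenz_gini(10 * r)$gini,
                 tolerance = 1e-12)
  }
  # moving rate from a poorer to a richer unit increases dispersion
  r <- c(2, 4, 6, 8)
  r2 <- c(1, 4, 6, 9)
  expect_gt(lorenz_gini(r2)$gini, lorenz_gini(r)$gini)
})

test_that("Lorenz curve is a valid convex share curve", {
  set.seed(9)
  lc <- lorenz_gini(rlnorm(30))
  expect_equal(lc$y[1], 0)
  expect_equal(lc$y[length(lc$y)], 1)
  expect_true(all(lc$y <= lc$x + 1e-12))
  expect_true(all(diff(lc$y, differences = 2) >= -1e-12))  # convex
})

test_that("regime fractions follow their definition on crafted sequences", {
  cs <- cv2_sequence(generate_renewal_train(20, 30, shape = 1, seed = 1))
  fr <- regime_fractions(cs, icrit = 0.5)
  keep <- !cs$interburst
  expect_equal(fr$time_fraction,
               sum(cs$spans_s[keep] * (cs$values[keep] > 0.5)) /
                 sum(cs$spans_s[keep]))
  expect_equal(fr$spike_fraction, mean(cs$values[keep] > 0.5))

  all_irreg <- structure(list(values = rep(0.9, 10), spans_s = rep(0.1, 10),
                              times = 1:10, interburst = rep(FALSE, 10)),
                         class = "cv2_sequence")
  expect_equal(regime_fractions(all_irreg, 0.5)$time_fraction, 1)
  expect_equal(regime_fractions(all_irreg, 0.5)$spike_fraction, 1)
  all_reg <- all_irreg; all_reg$values <- rep(0.2, 10)
  expect_equal(regime_fractions(all_reg, 0.5)$time_fraction, 0)
})

test_that("alternating regular/irregular halves occupy half the time", {
  # first half regular (CV2 = 0), second half strongly alternating ISIs
  reg <- seq(0, 10, by = 0.1)
  irr <- 10 + cumsum(rep(c(0.03, 0.17), 50))
  cs <- cv2_sequence(c(reg, irr))
  fr <- regime_fractions(cs, icrit = 0.5)
  expect_equal(fr$time_fraction, 0.5, tolerance = 0.05)
})

test_that("reverse cumulative matches direct counting and TIF50 the median", {
  set.seed(13)
  for (n in c(5, 12, 17, 40)) {
    fr <- runif(n)
    rc <- reverse_cumulative(fr)
    # tabulated F equals direct counting at every grid point
    expect_equal(rc$F, vapply(rc$t, function(t) mean(fr >= t), numeric(1)))
    expect_true(all(diff(rc$F) <= 0))
    expect_equal(rc$crossing_50, median(fr), tolerance = 1e-12)
  }
  expect_equal(tif50_sif50(rep(1, 10))$tif50, 100)
})

test_that("TIF50 approaches 50% for uniform fractions and falls with icrit", {
  set.seed(14)
  expect_equal(tif50_sif50(runif(2000))$tif50, 50, tolerance = 3)

  out <- generate_population_raster(
    population_spec(n_units = 40, n_cycles = 10, seed = 2))
  tf <- function(ic) {
    fr <- vapply(out$raster, function(st) {
      if (length(st) < 3) return(NA_real_)
      regime_fractions(cv2_sequence(st), icrit = ic)$time_fraction
    }, numeric(1))
    tif50_sif50(fr[is.finite(fr)])$tif50
  }
  v <- c(tf(0.4), tf(0.5), tf(0.6))
  expect_true(all(diff(v) <= 0))
})

test_that("pooled rates recover the generator's lognormal scale", {
  out <- generate_population_raster(
    population_spec(n_units = 200, rate_logsd = 1, n_cycles = 10, seed = 3))
  pr <- pooled_rate_distribution(out$raster)
  expect_equal(pr$sdlog, 1, tolerance = 0.15)
  expect_gt(pr$skewness_linear, 0)
  expect_lt(abs(pr$skewness_log), 0.5)
})

test_that("pooled rates handle equal-rate and silent units", {
  raster <- list(a = c(1, 2, 3), b = c(1.5, 2.5, 3.5), c = numeric(0))
  pr <- pooled_rate_distribution(raster, windows = cbind(0, 4))
  expect_identical(pr$n_silent, 1L)
  expect_identical(pr$skewness_linear, 0)   # degenerate, flagged as 0
  expect_error(pooled_rate_distribution(list(a = 1, b = numeric(0))),
               "at least 2")
})

test_that("time-resolved log-skewness is flat for homogeneous populations", {
  r1 <- lapply(1:20, function(u) generate_renewal_train(20, 10, 1, seed = u))
  names(r1) <- paste0("u", 1:20)
  tr <- time_resolved_log_skewness(r1, bin = 0.05, bandwidth = 0.05)
  expect_lt(abs(tr$correlation$r), 0.25)
})

test_that("saturating high-rate epochs produce negative rate-skew coupling", {
  # common drive doubles the rate in half the time bins; a soft ceiling
  # compresses the top rates there, skewing log-rates negative
  base <- rlnorm(30, log(20), 0.6)
  set.seed(15)
  raster <- lapply(base, function(r0) {
    spk <- c()
    for (b in 0:19) {
      high <- b %% 2 == 1
      r <- if (high) min(r0 * 3, 60) else r0
      spk <- c(spk, generate_renewal_train(r, 0.5, shape = 1,
                                           seed = sample.int(1e6, 1),
                                           t0 = b * 0.5))
    }
    spk
  })
  names(raster) <- paste0("u", seq_along(raster))
  tr <- time_resolved_log_skewness(raster, bin = 0.1, bandwidth = 0.05,
                                   min_active = 10)
  expect_lt(tr$correlation$r, -0.2)
  expect_lt(tr$correlation$p, 0.05)
})

test_that("depth profile detects shifted bins and passes identical ones", {
  set.seed(16)
  u_same <- data.frame(mean_cv2 = rep(runif(40, 0.3, 0.9), 2),
                       depth_um = rep(c(100, 300), each = 40))
  dp <- depth_profile(u_same, bin = 200)
  expect_equal(dp$ks_D[1, 2], 0)

  u_shift <- data.frame(
    mean_cv2 = c(runif(200, 0.3, 0.9), runif(200, 0.5, 1.1)),
    depth_um = rep(c(100, 300), each = 200))
  dp2 <- depth_profile(u_shift, bin = 200)
  expect_lt(dp2$ks_p[1, 2], 0.05)

  # depth-independent irregularity: no bin pair significant (fixed seed)
  u_null <- data.frame(mean_cv2 = runif(900, 0.3, 0.9),
                       depth_um = runif(900, 0, 800))
  dp3 <- depth_profile(u_null, bin = 200)
  expect_true(all(dp3$ks_p[upper.tri(dp3$ks_p)] > 0.05))
  # small bins are skipped
  u_small <- data.frame(mean_cv2 = runif(12), depth_um = c(rep(100, 9),
                                                           rep(500, 3)))
  expect_identical(nrow(depth_profile(u_small, bin = 200)$bins), 1L)
})
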