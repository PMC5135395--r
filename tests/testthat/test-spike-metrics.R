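test_that("CV2 formula matches hand evaluation and its limits", {
  # ISIs 100 ms and 300 ms: 2 * 200 / 400 = 1
  expect_equal(cv2_sequence(c(0, 0.1, 0.4))$values, 1)
  # regular train: all values zero (up to float ulp on the times)
  expect_true(all(cv2_sequence(seq(0, 1, by = 0.1))$values < 1e-12))
  expect_true(all(cv2_sequence((0:20) * 0.05)$values < 1e-12))
  # empty below 3 spikes
  expect_identical(cv2_sequence(c(0, 1))$n, 0L)
})

test_that("CV2 lies in [0, 2] and approaches 2 for vanishing ISIs", {
  set.seed(5)
  st <- cumsum(rexp(500, 20))
  v <- cv2_sequence(st)$values
  expect_true(all(v >= 0 & v <= 2))
  near2 <- cv2_sequence(c(0, 1, 1 + 1e-9, 2))$values
  expect_gt(max(near2), 1.99)
})

test_that("CV2 is invariant under time rescaling", {
  set.seed(6)
  st <- cumsum(rexp(200, 10))
  expect_equal(cv2_sequence(st)$values, cv2_sequence(st * 3.7)$values)
})

test_that("long Poisson trains have mean CV2 near 1", {
  st <- generate_renewal_train(10, 1000, shape = 1, seed = 12)
  expect_equal(cv2_sequence(st)$mean_cv2, 1, tolerance = 0.05)
})

test_that("interburst pairs are masked out of within-burst means", {
  # two regular 10 Hz bursts separated by a 1 s gap
  st <- c(seq(0, 0.5, by = 0.1), seq(1.5, 2, by = 0.1))
  cs <- cv2_sequence(st)
  expect_true(any(cs$interburst))
  expect_lt(cs$mean_cv2_within, 1e-12)
  expect_gt(cs$mean_cv2, 0.1)
})

test_that("rate distributions separate the regimes by log-skewness", {
  irregular <- generate_renewal_train(30, 120, shape = 1, seed = 2)
  regular <- generate_renewal_train(30, 120, shape = 16, seed = 2)
  ri <- rate_distribution(irregular)
  rr <- rate_distribution(regular)
  expect_gt(ri$skewness_linear, 0)
  expect_lt(rr$skewness_log, ri$skewness_log)
})

test_that("lognormal ISIs give symmetric log-rates", {
  set.seed(3)
  isi <- rlnorm(5000, meanlog = log(0.02), sdlog = 0.5)
  rd <- rate_distribution(cumsum(isi))
  expect_lt(abs(rd$skewness_log), 0.1)
  expect_equal(rd$meanlog, -log(0.02), tolerance = 0.05)
})

test_that("degenerate and all-interburst rate inputs are handled", {
  cs <- rate_distribution(seq(0, 1, by = 0.1))
  expect_true(cs$degenerate)
  expect_identical(cs$skewness_linear, 0)
  expect_error(rate_distribution(c(0, 1, 2, 3)), "fewer than 3")
})

test_that("kernel rate conserves spike mass", {
  expect_equal(kernel_rate_mass(kernel_rate(1, bandwidth = 0.05)), 1,
               tolerance = 1e-5)
  st <- generate_renewal_train(20, 20, shape = 1, seed = 4)
  kr <- kernel_rate(st, bandwidth = 0.03)
  expect_equal(kernel_rate_mass(kr), length(st), tolerance = 1e-5)
})

test_that("stationary Poisson rate is recovered by the kernel estimate", {
  st <- generate_renewal_train(20, 100, shape = 1, seed = 7)
  kr <- kernel_rate(st, bandwidth = "auto")
  inside <- kr$time_s >= 0 & kr$time_s <= 100
  expect_equal(mean(kr$rate_hz[inside]), 20, tolerance = 2)
  expect_s3_class(kr, "kernel_rate")
  expect_false(is.null(kr$search))
})

test_that("auto bandwidth prefers narrow kernels for bursty trains", {
  # 1 s cycles with 100 ms bursts: optimal bandwidth well below 1 s
  st <- unlist(lapply(0:9, function(c)
    generate_renewal_train(80, 0.1, shape = 1, seed = c + 1, t0 = c)))
  kr <- kernel_rate(st, bandwidth = "auto")
  expect_lt(kr$bandwidth_s, 0.2)
})

test_that("single spike with auto bandwidth falls back with a warning", {
  expect_warning(kr <- kernel_rate(0.5, bandwidth = "auto"), "default")
  expect_equal(kr$bandwidth_s, 0.05)
})
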