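test_that("time normalization preserves ramps, endpoints, and identity", {
  ramp <- seq(0, 1, length.out = 50)
  for (np in c(64, 34, 10)) {
    y <- time_normalize(ramp, np)
    expect_length(y, np)
    expect_equal(y[1], 0, tolerance = 1e-6)
    expect_equal(y[np], 1, tolerance = 1e-6)
    expect_equal(y, seq(0, 1, length.out = np), tolerance = 1e-6)
  }
  x <- rnorm(64)
  expect_lt(max(abs(time_normalize(x, 64) - x)), 1e-9)
  expect_error(time_normalize(1, 10), "at least 2")
  expect_error(time_normalize(1:10, 1), "n_points")
  expect_equal(phase_points("lift"), 64L)
  expect_equal(phase_points("aerial"), 34L)
  expect_equal(phase_points("land"), 64L)
})

test_that("the DWT matrix is orthogonal and reconstructs exactly", {
  for (fam in c("haar", "db2", "coif3")) {
    for (n in c(32, 64)) {
      W <- dwt_matrix(n, fam)
      expect_lt(max(abs(W %*% t(W) - diag(n))), 1e-10)
      set.seed(n)
      x <- rnorm(n)
      expect_lt(max(abs(t(W) %*% (W %*% x) - x)), 1e-8)
    }
  }
  # a constant loads only the approximation coefficient
  W <- dwt_matrix(64, "coif3")
  cw <- as.numeric(W %*% rep(3, 64))
  expect_equal(cw[1], 3 * sqrt(64), tolerance = 1e-9)
  expect_lt(max(abs(cw[-1])), 1e-9)
})

test_that("round-trip through the 34-point resampling path is faithful", {
  set.seed(4)
  # smooth waveform at 34 points: resample to 32, transform, invert, restore
  x <- as.numeric(gaussian_smooth(rnorm(34), 34, 4))
  x32 <- time_normalize(x, 32)
  W <- dwt_matrix(32, "coif3")
  back <- time_normalize(as.numeric(t(W) %*% (W %*% x32)), 34)
  expect_lt(max(abs(back - x)) / diff(range(x)), 0.02)
  # the power-of-2 core itself is exact
  expect_lt(max(abs(t(W) %*% (W %*% x32) - x32)), 1e-8)
})

test_that("identical groups give a null result", {
  set.seed(10)
  pre <- matrix(rnorm(12 * 64), 12)
  r <- wavelet_paired_test(pre, pre)
  expect_true(all(r$contrast == 0))
  expect_false(any(r$mask))
  expect_false(any(r$coeff_table$significant))
})

test_that("an injected constant offset is recovered in sign and size", {
  set.seed(11)
  pre <- matrix(rnorm(20 * 64), 20)
  post <- pre + 0.5 + matrix(rnorm(20 * 64, 0, 0.05), 20)
  r <- wavelet_paired_test(pre, post)
  # approximation coefficient significant; contrast ~ -0.5 (PRE - POST)
  expect_true(r$coeff_table$significant[1])
  expect_equal(mean(r$contrast[r$mask]), -0.5, tolerance = 0.05)
  # 34-point path
  pre34 <- matrix(rnorm(20 * 34), 20)
  post34 <- pre34 + 0.5 + matrix(rnorm(20 * 34, 0, 0.05), 20)
  r34 <- wavelet_paired_test(pre34, post34)
  expect_equal(mean(r34$contrast[r34$mask]), -0.5, tolerance = 0.05)
})

test_that("scaling both groups scales the contrast exactly", {
  set.seed(12)
  pre <- matrix(rnorm(15 * 64), 15)
  post <- pre + 0.4 + matrix(rnorm(15 * 64, 0, 0.1), 15)
  r1 <- wavelet_paired_test(pre, post)
  r5 <- wavelet_paired_test(5 * pre, 5 * post)
  expect_equal(r5$contrast, 5 * r1$contrast, tolerance = 1e-12)
  expect_equal(r5$mask, r1$mask)
})

test_that("the mask invariant holds by construction (fuzz)", {
  set.seed(13)
  for (i in 1:20) {
    pre <- matrix(rnorm(10 * 64), 10)
    post <- pre + matrix(rnorm(10 * 64, 0, 0.3), 10) +
      (i %% 3 == 0) * 0.4
    r <- wavelet_paired_test(pre, post)
    peak <- max(abs(r$contrast))
    if (peak > 0) {
      expect_true(all(abs(r$contrast[r$mask]) >= 0.10 * peak))
      expect_true(all(abs(r$contrast[!r$mask]) < 0.10 * peak))
    } else {
      expect_false(any(r$mask))
    }
  }
})

test_that("zero-variance coefficient differences follow the t-limit rule", {
  pre <- matrix(rep(seq(0, 1, length.out = 64), each = 5), 5, byrow = FALSE)
  # exactly identical -> not significant
  r0 <- wavelet_paired_test(pre, pre)
  expect_false(any(r0$coeff_table$significant))
  # exact nonzero common difference -> significant with p = 0
  r1 <- wavelet_paired_test(pre, pre + 1)
  expect_true(r1$coeff_table$significant[1])
  expect_equal(r1$coeff_table$p[1], 0)
})

test_that("null per-coefficient false-positive rate is near alpha", {
  set.seed(14)
  fps <- replicate(200, {
    a <- matrix(rnorm(20 * 64), 20)
    b <- matrix(rnorm(20 * 64), 20)
    mean(wavelet_paired_test(a, b)$coeff_table$significant)
  })
  # 200 x 64 coefficient tests; binomial SE of the mean ~ 0.002
  expect_lt(abs(mean(fps) - 0.05), 0.01)
})

test_that("power is monotone non-decreasing in injected effect size", {
  set.seed(15)
  power_at <- function(eff) {
    mean(replicate(40, {
      a <- matrix(rnorm(20 * 64), 20)
      b <- a + eff + matrix(rnorm(20 * 64, 0, 0.5), 20)
      any(wavelet_paired_test(a, b)$coeff_table$significant)
    }))
  }
  p <- vapply(c(0, 0.3, 0.8), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], 0.9)
})

test_that("shape and pairing errors are rejected", {
  a <- matrix(rnorm(5 * 64), 5)
  expect_error(wavelet_paired_test(a, a[, 1:32]), "identically shaped")
  expect_error(wavelet_paired_test(a[1:2, ], a[1:2, ]), "at least 3")
  b <- a; b[1, 1] <- NA
  expect_error(wavelet_paired_test(a, b), "missing")
})
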