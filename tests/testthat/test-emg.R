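test_that("preprocessing rejects DC, preserves sinusoid scale, and is symmetric", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  # DC rejection
  expect_lt(max(abs(emg_preprocess(rep(0.5, length(t)), fs))), 1e-3)
  # 100 Hz sinusoid: rectified mean of |sin| is 2/pi
  x <- sin(2 * pi * 100 * t)
  r <- emg_preprocess(x, fs)
  mid <- r[500:(length(r) - 500)]
  expect_equal(mean(mid), 2 / pi, tolerance = 0.02)
  # rectification symmetry
  set.seed(1)
  y <- rnorm(2000)
  expect_equal(emg_preprocess(y, fs), emg_preprocess(-y, fs))
})

test_that("sub-Nyquist corners are clamped with a warning", {
  expect_warning(emg_preprocess(rnorm(500), fs = 500), "Nyquist")
})

test_that("normalization peak follows window arithmetic", {
  fs <- 1000
  # constant maps to itself
  expect_equal(normalization_peak(rep(0.3, 1000), fs), 0.3)
  # single impulse of height h: 100 ms window mean = h / 101 (101-sample window)
  x <- numeric(1000); x[500] <- 5
  expect_equal(normalization_peak(x, fs), 5 / 101, tolerance = 1e-12)
  # max over trials
  trials <- list(rep(0.1, 500), rep(0.4, 500), rep(0.2, 500))
  expect_equal(normalization_peak(trials, fs), 0.4)
  expect_error(normalization_peak(rep(0, 500), fs), "silent")
})

test_that("onset detector recovers step bursts and applies the gates", {
  fs <- 1000
  n <- 2000
  lo <- 1000L; td <- 1500L   # 500 ms aerial window
  mk <- function(onset_ms, amp = 0.3) {
    x <- numeric(n)
    start <- td - round(onset_ms * fs / 1000)
    x[start:td] <- amp
    x[(td + 1):n] <- amp
    x
  }
  # step burst 100 ms before touchdown
  r <- detect_onset(mk(100), fs, lo, td)
  expect_true(r$included)
  expect_equal(r$onset_ms_before_landing, 100, tolerance = 5)
  # step burst 200 ms before touchdown -> too early
  r2 <- detect_onset(mk(200), fs, lo, td)
  expect_false(r2$included)
  expect_equal(r2$exclusion_rule, "too-early")
  # all-zero EMG -> absence of preactivation
  r3 <- detect_onset(numeric(n), fs, lo, td)
  expect_false(r3$included)
  expect_equal(r3$exclusion_rule, "sub-1-percent")
  # tiny burst below 1% of maximum
  r4 <- detect_onset(mk(100, amp = 0.005), fs, lo, td)
  expect_false(r4$included)
  expect_equal(r4$exclusion_rule, "sub-1-percent")
  # burst in mid-flight, silent at landing -> no late local maximum
  x5 <- numeric(n)
  x5[1050:1150] <- 0.4
  r5 <- detect_onset(x5, fs, lo, td)
  expect_false(r5$included)
  expect_equal(r5$exclusion_rule, "no-late-max")
})

test_that("chord-deviation elbow equals a brute-force per-sample scan", {
  fs <- 1000
  set.seed(21)
  for (i in 1:100) {
    n <- 400
    lo <- 1L; td <- as.integer(n)
    x <- abs(rnorm(n, 0, 0.02))
    start <- sample(260:390, 1)
    x[start:n] <- x[start:n] + runif(1, 0.2, 0.6)
    tt <- (seq_len(n) - 1) / fs
    # oracle: independent per-sample trapezoid integrals, explicit loop
    C <- numeric(n)
    for (k in 2:n) C[k] <- riemann_oracle(tt[1:k], x[1:k])
    chord <- C[1] + (C[n] - C[1]) * (tt - tt[1]) / (tt[n] - tt[1])
    k_star <- max(which((C - chord) == min(C - chord)))
    r <- detect_onset(x, fs, lo, td)
    expect_equal(r$onset_idx, k_star)
  }
})

test_that("onset, magnitude and iemg are invariant to raw channel scaling", {
  fs <- 1000
  tr <- fixture_trial("PRE")
  peaks <- fixture_norm_peaks()
  raw <- tr$emg$MG_dom
  lo <- 1020L; td <- as.integer(round(tr$truth$touchdown * fs) + 1)
  base_rect <- emg_preprocess(raw, fs)
  base_pk <- normalization_peak(base_rect, fs)
  base <- detect_onset(base_rect / base_pk, fs, lo, td)
  for (k in c(0.001, 7, 1e4)) {
    rect <- emg_preprocess(raw * k, fs)
    pk <- normalization_peak(rect, fs)
    r <- detect_onset(rect / pk, fs, lo, td)
    expect_equal(r$onset_idx, base$onset_idx)
    expect_equal(r$magnitude, base$magnitude, tolerance = 1e-9)
    expect_equal(r$iemg, base$iemg, tolerance = 1e-9)
  }
})

test_that("included results satisfy the preactivation invariants (fuzz)", {
  fs <- 1000
  set.seed(33)
  for (i in 1:60) {
    n <- 1200
    lo <- 400L; td <- 1000L
    x <- abs(rnorm(n, 0, runif(1, 0, 0.05)))
    if (runif(1) < 0.7) {
      start <- sample(850:995, 1)
      x[start:n] <- x[start:n] + runif(1, 0, 0.5)
    }
    r <- detect_onset(x, fs, lo, td)
    if (r$included) {
      expect_gte(r$onset_ms_before_landing, 0)
      expect_lte(r$onset_ms_before_landing, 150)
      expect_gte(r$magnitude, 0.01)
    } else {
      expect_true(r$exclusion_rule %in%
                    c("no-late-max", "too-early", "sub-1-percent"))
    }
  }
})

test_that("preactivation metrics reproduce rectangle and ramp areas", {
  fs <- 1000
  x <- numeric(1000)
  x[501:601] <- 0.2
  m <- preactivation_metrics(x, fs, 501L, 601L)
  expect_equal(m$magnitude, 0.2)
  expect_equal(m$iemg, 0.02, tolerance = 1e-12)
  # ramp 0 -> 0.4 over 100 ms: mean 0.2, integral 0.02
  x2 <- numeric(1000)
  x2[501:601] <- seq(0, 0.4, length.out = 101)
  m2 <- preactivation_metrics(x2, fs, 501L, 601L)
  expect_equal(m2$magnitude, 0.2)
  expect_equal(m2$iemg, 0.02, tolerance = 1e-12)
})

test_that("triceps surae preactivity averages three muscles or goes missing", {
  expect_equal(triceps_surae_preactivity(0.03, 0.02, 0.01)$tsp, 0.02)
  expect_equal(triceps_surae_preactivity(0.5, 0.5, 0.5)$tsp, 0.5)
  r <- triceps_surae_preactivity(0.03, NA, 0.01,
                                 rules = c("none", "too-early", "none"))
  expect_true(is.na(r$tsp))
  expect_match(r$tsp_rule, "too-early")
  r2 <- triceps_surae_preactivity(0.03, NA, 0.01, allow_partial = TRUE)
  expect_equal(r2$tsp, 0.02)
})

test_that("onset recovery on generated trials is within 10 ms at low noise", {
  cfg <- cohort_config(emg_noise_sd = 0.02)
  p <- fixture_participant(cfg = cfg)
  maxt <- lapply(1:3, function(j) generate_trial(p, "MAX", 600 + j, cfg))
  peaks <- normalization_peaks(maxt)
  errs <- c()
  for (s in 1:12) {
    tr <- generate_trial(p, "PRE", 700 + s, cfg)
    kin <- analyze_trial_kinetics(tr)
    em <- analyze_trial_emg(tr, peaks, kin$liftoff_t, kin$touchdown_t)
    truth <- tr$truth$onset_ms[paste(em$muscle, em$leg, sep = "_")]
    errs <- c(errs, em$onset_ms[em$included] - truth[em$included])
  }
  expect_gt(length(errs), 60)
  expect_lt(max(abs(errs)), 10)
})
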