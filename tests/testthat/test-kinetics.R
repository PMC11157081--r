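test_that("a constant force trace (no jump) raises 'no aerial phase'", {
  expect_error(segment_phases(rep(700, 2000), 700, 1000), "no aerial phase")
})

test_that("segmentation matches a brute-force scan on a trapezoid trial", {
  fs <- 1000
  bw <- 700
  # BW plateau, unload dip, cosine ramp to 2 BW, drop to 0, spike, settle
  grf <- c(rep(bw, 800),
           bw - 0.5 * bw * sin(pi * seq(0, 1, length.out = 200)),
           bw + (2 * bw - bw) * (1 - cos(pi * seq(0, 1, length.out = 300))) / 2,
           seq(2 * bw, 0, length.out = 50),
           rep(0, 300),
           seq(0, 3 * bw, length.out = 30),
           seq(3 * bw, bw / 2, length.out = 200),
           rep(bw / 2, 100))
  ph <- segment_phases(grf, bw, fs)

  # oracle: exhaustive sample scan of the stated crossing rules
  below <- which(grf < 25)
  runs <- split(below, cumsum(c(1, diff(below) != 1)))
  longest <- runs[[which.max(lengths(runs))]]
  lo <- longest[1]; td <- longest[length(longest)] + 1
  peak_push <- which.max(grf[1:(lo - 1)])
  ls <- max(which(grf[1:(peak_push - 1)] < bw & grf[2:peak_push] >= bw))
  peak_land <- td - 1 + which.max(grf[td:length(grf)])
  le <- min(which(grf[peak_land:(length(grf) - 1)] >= bw &
                    grf[(peak_land + 1):length(grf)] < bw)) + peak_land - 1

  expect_identical(ph$liftoff, as.integer(lo))
  expect_identical(ph$touchdown, as.integer(td))
  expect_identical(ph$lift_start, as.integer(ls))
  expect_identical(ph$land_end, as.integer(le))
})

test_that("phase ordering invariant holds on generated trials", {
  for (seed in c(11, 12, 13)) {
    tr <- fixture_trial("PRE", seed = seed, noise = TRUE)
    grf_f <- filter_zerophase(tr$grf$grf_z, tr$fs$grf, 25, "low")
    ph <- segment_phases(grf_f, tr$body_weight, tr$fs$grf)
    expect_true(ph$lift_start < ph$liftoff)
    expect_true(ph$liftoff < ph$touchdown)
    expect_true(ph$touchdown < ph$land_end)
    expect_lte(ph$land_end, nrow(tr$grf))
  }
})

test_that("segmented flight duration matches ground truth within one sample", {
  for (cond in c("PRE", "ADAPT")) {
    tr <- fixture_trial(cond)
    ph <- segment_phases(tr$grf$grf_z, tr$body_weight, tr$fs$grf)
    flight <- (ph$touchdown - ph$liftoff) / tr$fs$grf
    expect_lte(abs(flight - tr$truth$flight), 1 / tr$fs$grf)
  }
})

test_that("impulses reproduce closed-form areas and the Riemann oracle", {
  fs <- 1000
  # rectangle: 700 N over exactly 0.5 s
  grf <- c(rep(700, 701), rep(0, 400), rep(700, 300))
  ph <- structure(list(lift_start = 1L, liftoff = 501L, touchdown = 800L,
                       land_end = 1000L, fs = fs), class = "jump_phases")
  imp <- compute_impulses(grf, ph)
  expect_equal(imp$lift_impulse, 350, tolerance = 1e-12)

  # triangle: peak 1000 N, base 0.2 s -> 100 N s
  tri <- c(seq(0, 1000, length.out = 101), seq(1000, 0, length.out = 101)[-1])
  ph2 <- structure(list(lift_start = 1L, liftoff = 201L, touchdown = 100L,
                        land_end = 201L, fs = fs), class = "jump_phases")
  imp2 <- compute_impulses(tri, ph2)
  expect_equal(imp2$lift_impulse, 100, tolerance = 1e-12)

  # random signals vs the independent Riemann oracle
  set.seed(99)
  for (i in 1:100) {
    n <- sample(50:200, 1)
    y <- runif(n, 0, 2000)
    i0 <- sample(1:10, 1); i1 <- sample((n - 10):n, 1)
    ph3 <- structure(list(lift_start = i0, liftoff = i1, touchdown = i0,
                          land_end = i1, fs = fs), class = "jump_phases")
    got <- compute_impulses(y, ph3)$lift_impulse
    want <- riemann_oracle((i0:i1 - 1) / fs, y[i0:i1])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("net impulse subtracts body weight", {
  fs <- 100
  grf <- rep(800, 201)
  ph <- structure(list(lift_start = 1L, liftoff = 101L, touchdown = 101L,
                       land_end = 201L, fs = fs), class = "jump_phases")
  gross <- compute_impulses(grf, ph)$lift_impulse
  net <- compute_impulses(grf, ph, net = TRUE, body_weight = 600)$lift_impulse
  expect_equal(gross, 800)
  expect_equal(net, 200)
})

test_that("jump metrics follow the marker arithmetic and degenerate flag", {
  fs_m <- 100
  ph <- structure(list(liftoff = 1001L, touchdown = 1501L, fs = 1000),
                  class = "jump_phases")
  z <- rep(1.6, 301)
  z[101:151] <- 1.6 + 0.3 * sin(pi * seq(0, 1, length.out = 51))
  m <- jump_metrics(z, fs_m, ph, standing_height = 1.6, target_height = 0.25)
  expect_equal(m$jump_height, 0.3, tolerance = 1e-6)
  expect_equal(m$target_error, 0.05, tolerance = 1e-6)
  expect_equal(m$abs_target_error, 0.05, tolerance = 1e-6)
  expect_false(m$flag_nonpositive)

  flat <- jump_metrics(rep(1.5, 301), fs_m, ph, 1.6, 0.25)
  expect_true(flat$flag_nonpositive)
})

test_that("jump height at zero noise matches ground truth within 1 mm", {
  tr <- fixture_trial("PRE")
  kin <- analyze_trial_kinetics(tr)
  expect_lt(abs(kin$jump_height - tr$truth$jump_height), 1e-3)
})

test_that("aerial acceleration recovers the parabola coefficient exactly", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  ph <- structure(list(liftoff = 1001L, touchdown = 2001L, fs = 1000),
                  class = "jump_phases")
  for (g in c(9.81, 4.905)) {
    z <- 1.6 + 2 * (t - 1) - 0.5 * g * (t - 1)^2
    expect_equal(aerial_acceleration(z, fs, ph), -g, tolerance = 1e-9)
  }
  tr <- fixture_trial("ADAPT")
  kin <- analyze_trial_kinetics(tr)
  expect_equal(kin$aerial_g, -0.508 * 9.81, tolerance = 1e-3)
})

test_that("fall-time analytics reproduce the ballistic timing numbers", {
  expect_equal(round(fall_time(0.273, 9.81), 3), 0.236)
  expect_equal(round(fall_time(0.273, 0.508 * 9.81), 3), 0.331)
  expect_equal(round(delay_prediction(0.273, 9.81, 0.508 * 9.81), 3), 0.095)
  expect_equal(fall_time(0, 9.81), 0)
  expect_equal(delay_prediction(0.273, 9.81, 9.81), 0)
  # g_alt = g_ref / 4 doubles the fall time, so the delay equals fall_time
  expect_equal(delay_prediction(0.273, 9.81, 9.81 / 4),
               fall_time(0.273, 9.81), tolerance = 1e-12)
  expect_equal(delay_mitigation_percent(0.095, 0.026), 72.63, tolerance = 1e-2)
  expect_equal(delay_mitigation_percent(0.1, 0.1), 0)
  expect_equal(delay_mitigation_percent(0.1, 0), 100)
  expect_error(fall_time(0.3, 0), "g must be")
  expect_error(delay_mitigation_percent(0, 0.01), "predicted")
})

test_that("fall_time is monotone decreasing in g and increasing in height", {
  set.seed(5)
  h <- sort(runif(50, 0.01, 2))
  g <- sort(runif(50, 0.5, 15))
  expect_true(all(diff(fall_time(0.5, g)) < 0))
  expect_true(all(diff(fall_time(h, 9.81)) > 0))
})

test_that("flight-time height agrees with marker height within 1% at zero noise", {
  for (cond in c("PRE", "ADAPT")) {
    tr <- fixture_trial(cond)
    kin <- analyze_trial_kinetics(tr)
    g <- tr$truth$effective_g
    h_ft <- g * kin$flight_time^2 / 8
    expect_equal(h_ft, kin$jump_height, tolerance = 0.01)
  }
})
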