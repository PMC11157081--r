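#' Configuration for a synthetic jump cohort
#'
#' Builds the study-design configuration consumed by [generate_trial()] and
#' [simulate_cohort()]. Defaults emulate the protocol the analysis assumes:
#' 20 participants, 10 targeted countermovement jumps at normal gravity (PRE),
#' 50 jumps in simulated hypogravity at 0.508 g (ADAPT), and 10 jumps back at
#' normal gravity (POST); the jump target is 75% of each participant's maximum
#' vertical displacement. Injected condition effects carry the ground truth
#' that downstream recovery tests check: preactivation onset defaults to
#' 100 ms before landing and is delayed (moved closer to landing) by
#' `onset_delay_post_ms` at POST, and preactivation burst amplitude is scaled
#' by `magnitude_scale` per condition.
#'
#' @param n_participants number of simulated participants.
#' @param jumps_per_condition named integer vector `c(PRE=, ADAPT=, POST=)`.
#' @param effective_g named numeric, effective gravitational acceleration
#'   \[m/s^2\] per condition; must lie in (0, 9.81].
#' @param body_mass_mean,body_mass_sd body mass distribution \[kg\].
#' @param target_height_frac jump target as a fraction of the participant's
#'   maximum jump height, in (0, 1].
#' @param onset_truth_ms named numeric, injected preactivation onset
#'   \[ms before touchdown\] per condition.
#' @param onset_delay_post_ms POST onset delay \[ms\]; used to build the
#'   default `onset_truth_ms["POST"]` as `onset_truth_ms["PRE"] - delay`
#'   (a delayed onset is *closer* to landing).
#' @param onset_jitter_ms per-trial SD of onset around its condition mean \[ms\].
#' @param magnitude_scale named numeric, preactivation burst amplitude scaling
#'   per condition (PRE = 1).
#' @param emg_noise_sd additive EMG noise SD in normalized units (fraction of
#'   the normalization peak).
#' @param grf_noise_sd additive force-plate noise SD \[N\].
#' @param height_bias named numeric, systematic jump-height offset from the
#'   target \[m\] per condition (POST defaults to an undershoot).
#' @param height_jitter_sd per-trial jump-height SD \[m\].
#' @param sample_rates named list/vector with elements `grf`, `emg`, `marker`,
#'   `mtj` \[Hz\].
#' @param include_mtj logical; also synthesize muscle-tendon-junction,
#'   probe and ankle-torque channels.
#' @param seed integer master seed; every trial seed derives from it.
#' @return a list of class `hypojump_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          jumps_per_condition = c(PRE = 10, ADAPT = 50, POST = 10),
                          effective_g = c(PRE = 9.81, ADAPT = 0.508 * 9.81, POST = 9.81),
                          body_mass_mean = 61.2, body_mass_sd = 11.6,
                          target_height_frac = 0.75,
                          onset_truth_ms = NULL,
                          onset_delay_post_ms = 26,
                          onset_jitter_ms = 5,
                          magnitude_scale = c(PRE = 1, ADAPT = 0.5, POST = 0.6),
                          emg_noise_sd = 0.01,
                          grf_noise_sd = 2,
                          height_bias = c(PRE = 0, ADAPT = 0, POST = -0.03),
                          height_jitter_sd = 0.015,
                          sample_rates = list(grf = 1000, emg = 1000, marker = 100, mtj = 60),
                          include_mtj = FALSE,
                          seed = 1L) {
  if (is.null(onset_truth_ms)) {
    onset_truth_ms <- c(PRE = 100, ADAPT = 100, POST = 100 - onset_delay_post_ms)
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    jumps_per_condition = jumps_per_condition,
    effective_g = effective_g,
    body_mass_mean = body_mass_mean, body_mass_sd = body_mass_sd,
    target_height_frac = target_height_frac,
    onset_truth_ms = onset_truth_ms,
    onset_delay_post_ms = onset_delay_post_ms,
    onset_jitter_ms = onset_jitter_ms,
    magnitude_scale = magnitude_scale,
    emg_noise_sd = emg_noise_sd,
    grf_noise_sd = grf_noise_sd,
    height_bias = height_bias,
    height_jitter_sd = height_jitter_sd,
    sample_rates = as.list(sample_rates),
    include_mtj = isTRUE(include_mtj),
    seed = as.integer(seed)
  )
  class(cfg) <- "hypojump_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  conds <- c("PRE", "ADAPT", "POST")
  if (!all(conds %in% names(cfg$jumps_per_condition))) {
    abort("jumps_per_condition must name PRE, ADAPT and POST")
  }
  if (any(cfg$effective_g <= 0) || any(cfg$effective_g > 9.81)) {
    abort("effective_g must lie in (0, 9.81]")
  }
  if (any(cfg$magnitude_scale < 0)) abort("magnitude_scale must be >= 0")
  if (any(unlist(cfg$sample_rates) <= 0)) abort("sample_rates must be > 0")
  if (cfg$target_height_frac <= 0 || cfg$target_height_frac > 1) {
    abort("target_height_frac must lie in (0, 1]")
  }
  if (cfg$n_participants < 1) abort("need at least one participant")
  if (cfg$emg_noise_sd < 0 || cfg$grf_noise_sd < 0) abort("noise SDs must be >= 0")
  invisible(cfg)
}

# muscle channel names: triceps surae of both legs
MUSCLES <- c("LG_dom", "MG_dom", "SOL_dom", "LG_nd", "MG_nd", "SOL_nd")

#' Draw participant-level parameters
#'
#' Samples anthropometrics (mass, standing sternum height, maximum jump
#' height), per-muscle raw EMG scale \[V\], and resting medial-gastrocnemius
#' length for one simulated participant. The jump target is
#' `target_height_frac` of the maximum jump.
#'
#' @param config a [cohort_config()].
#' @param id participant identifier (integer or string).
#' @param seed integer seed for this participant's draws.
#' @return a list of class `hypojump_participant`.
#' @export
participant_params <- function(config, id, seed) {
  withr::with_seed(as.integer(seed), {
    mass <- max(40, rnorm(1, config$body_mass_mean, config$body_mass_sd))
    standing_height <- rnorm(1, 1.39, 0.06)            # sternum marker, standing [m]
    max_jump <- max(0.2, rnorm(1, 0.36, 0.04))          # sternum displacement [m]
    emg_scale <- setNames(exp(rnorm(length(MUSCLES), log(4e-4), 0.2)), MUSCLES)
    l0 <- rnorm(1, 0.27, 0.015)                         # resting MG length [m]
  })
  structure(list(
    id = as.character(id), mass = mass, standing_height = standing_height,
    max_jump = max_jump, target_height = config$target_height_frac * max_jump,
    emg_scale = emg_scale, l0 = l0
  ), class = "hypojump_participant")
}

# --- ground-reaction-force / center-of-mass trajectory model ---------------
#
# One jump = quiet stance, countermovement unload dip (force below standing
# weight), push-off rise to a force peak, steep drop to zero at liftoff,
# ballistic flight under the effective gravity, and a landing modeled as an
# underdamped spring-damper leg (force spike, one oscillation through body
# weight, settle). The push-off amplitude is solved so the center of mass
# reaches exactly the requested marker height; all invariants (impulse-
# momentum, flight parabola) then hold by construction.
#
# Returns force F(t), COM displacement z(t) on the GRF clock, plus the exact
# liftoff/touchdown times and takeoff state.
grf_profile <- function(mass, g, height, fs) {
  if (height <= 0) abort("infeasible config: requested jump height <= 0")
  t_q <- 0.4                       # quiet stance [s]
  # unload / push rise / push fall [s]; movement slows as effective gravity
  # drops (pendulum-like time scaling), which also keeps the countermovement
  # able to cancel the takeoff offset in hypogravity
  slow <- sqrt(9.81 / g)
  T1 <- 0.25 * slow; T2 <- 0.25 * slow; T3 <- 0.12 * slow
  F_knee <- 50                     # residual toe force at the liftoff instant [N];
                                   # dropping 50 N -> 0 in one sample pins the
                                   # 25 N aerial threshold to the true boundary
  bw <- mass * g
  dt <- 1 / fs
  Tp <- T1 + T2 + T3

  # force shape s(tau) on [0, Tp] for push peak s_max and dip s_min (x BW)
  shape <- function(s_max, s_min, tau) {
    s <- numeric(length(tau))
    i1 <- tau < T1
    s[i1] <- s_min + (1 - s_min) * (1 + cos(pi * tau[i1] / T1)) / 2
    i2 <- tau >= T1 & tau < T1 + T2
    s[i2] <- s_min + (s_max - s_min) * (1 - cos(pi * (tau[i2] - T1) / T2)) / 2
    i3 <- tau >= T1 + T2
    x <- (tau[i3] - T1 - T2) / T3
    s_end <- F_knee / bw
    s[i3] <- s_end + (s_max - s_end) * (1 + cos(pi * x)) / 2
    s
  }
  tau <- seq(0, Tp, by = dt)
  # two free shape parameters: push peak s_max sets takeoff velocity (so the
  # flight apex hits the requested height) and unload depth s_min is solved
  # so the center of mass passes through standing height exactly at takeoff
  solve_push <- function(s_min) {
    achieved <- function(s_max) {
      a <- g * (shape(s_max, s_min, tau) - 1)
      v <- cumtrapz_int(tau, a)
      z <- cumtrapz_int(tau, v)
      v0 <- v[length(v)]
      if (v0 <= 0) return(-height)
      z[length(z)] + v0^2 / (2 * g) - height
    }
    if (achieved(10) < 0) abort("infeasible config: jump height unreachable")
    stats::uniroot(achieved, c(1.01, 10), tol = 1e-10)$root
  }
  z_takeoff <- function(s_min) {
    s_max <- solve_push(s_min)
    a <- g * (shape(s_max, s_min, tau) - 1)
    v <- cumtrapz_int(tau, a)
    z <- cumtrapz_int(tau, v)
    z[length(z)]
  }
  lo <- 0.05; hi <- 0.92
  if (z_takeoff(lo) * z_takeoff(hi) < 0) {
    s_min <- stats::uniroot(z_takeoff, c(lo, hi), tol = 1e-9)$root
  } else {
    # cannot null the takeoff offset for this geometry; use the default dip
    s_min <- 0.45
  }
  s_max <- solve_push(s_min)
  a <- g * (shape(s_max, s_min, tau) - 1)
  v <- cumtrapz_int(tau, a)
  z_push <- cumtrapz_int(tau, v)
  v0 <- v[length(v)]
  z_to <- z_push[length(z_push)]

  t_lo <- t_q + Tp
  T_f <- 2 * v0 / g                # land at takeoff height
  t_td <- t_lo + T_f

  # landing: underdamped spring-damper leg; w = deflection about equilibrium
  omega <- 22; zeta <- 0.55
  k <- mass * omega^2; cc <- 2 * zeta * omega * mass
  om_d <- omega * sqrt(1 - zeta^2)
  u_eq <- -bw / k
  T_land <- 1.0; T_tail <- 0.3
  t_total <- t_td + T_land + T_tail
  t <- seq(0, t_total, by = dt)
  n <- length(t)

  F <- numeric(n); z <- numeric(n)
  F[t < t_q] <- bw
  ip <- t >= t_q & t < t_lo
  F[ip] <- bw * shape(s_max, s_min, t[ip] - t_q)
  z[ip] <- approx(tau, z_push, xout = t[ip] - t_q, rule = 2)$y
  ifl <- t >= t_lo & t < t_td
  tf <- t[ifl] - t_lo
  z[ifl] <- z_to + v0 * tf - g * tf^2 / 2
  ila <- t >= t_td
  tl <- t[ila] - t_td
  w0 <- -u_eq; wd0 <- -v0
  A <- w0; B <- (wd0 + zeta * omega * w0) / om_d
  w <- exp(-zeta * omega * tl) * (A * cos(om_d * tl) + B * sin(om_d * tl))
  wdot <- exp(-zeta * omega * tl) *
    ((-zeta * omega * A + om_d * B) * cos(om_d * tl) +
       (-zeta * omega * B - om_d * A) * sin(om_d * tl))
  Fl <- pmax(0, -k * (w + u_eq) - cc * wdot)
  # settle smoothly to standing force over the last 300 ms of the land window
  wgt <- pmin(1, pmax(0, (tl - (T_land - 0.3)) / 0.3))
  wgt <- (1 - cos(pi * wgt)) / 2
  F[ila] <- Fl * (1 - wgt) + bw * wgt
  z[ila] <- (z_to + u_eq + w) * (1 - wgt) + (z_to + u_eq) * wgt

  list(t = t, F = F, z = z, t_move = t_q, t_lo = t_lo, t_td = t_td,
       v0 = v0, z_to = z_to, flight = T_f,
       jump_height = z_to + v0^2 / (2 * g))
}

# --- EMG model ---------------------------------------------------------------
#
# Rectifiable band-limited (20-450 Hz) unit-RMS noise carrier multiplied by a
# burst envelope in normalized units: tonic stance baseline, a lift burst
# ending exactly at liftoff, silence through the aerial phase, and a
# preactivation burst starting exactly `onset_s` before touchdown (half-cosine
# rise, plateau through landing, decay). The envelope is identically zero
# between liftoff and preactivation onset so the injected onset is exact.
emg_envelope <- function(t, t_lo, t_td, onset_s, amp_pre, amp_lift = 0.85,
                         baseline = 0.05) {
  env <- numeric(length(t))
  env[t < t_lo] <- baseline
  lb <- t >= (t_lo - 0.3) & t < t_lo
  x <- (t[lb] - (t_lo - 0.3)) / 0.3
  env[lb] <- env[lb] + amp_lift * (1 - cos(2 * pi * x)) / 2
  t_on <- t_td - onset_s
  rise <- 0.01   # rapid initial recruitment; burst reaches plateau in 10 ms
  ir <- t >= t_on & t < t_on + rise
  env[ir] <- amp_pre * (1 - cos(pi * (t[ir] - t_on) / rise)) / 2
  ipl <- t >= t_on + rise & t < t_td + 0.1
  env[ipl] <- amp_pre
  idc <- t >= t_td + 0.1 & t < t_td + 0.25
  x <- (t[idc] - t_td - 0.1) / 0.15
  env[idc] <- baseline + (amp_pre - baseline) * (1 + cos(pi * x)) / 2
  env[t >= t_td + 0.25] <- baseline
  env
}

band_noise <- function(n, fs, lo = 20, hi = 450) {
  x <- rnorm(n)
  x <- filter_zerophase(x, fs, c(lo, min(hi, 0.9 * fs / 2)), "pass")
  x / sd(x)
}

#' Generate one synthetic jump trial
#'
#' Synthesizes a fully synchronized countermovement-jump recording -- vertical
#' ground reaction force, six triceps-surae EMG channels, sternum marker
#' height, and optionally muscle-tendon-junction pixel/probe/ankle-torque
#' channels -- together with the ground truth of every injected quantity.
#' The trial is reproducible bit-for-bit from its seed.
#'
#' @param participant a [participant_params()] object.
#' @param condition `"PRE"`, `"ADAPT"`, `"POST"`, or `"MAX"` (maximum jump,
#'   used for EMG normalization; always at normal gravity, burst amplitude 1).
#' @param seed integer seed for this trial.
#' @param config a [cohort_config()].
#' @return a `jump_trial`: list with tibbles `grf` (`time`, `grf_z` \[N\]),
#'   `emg` (`time` + one column per muscle \[V\]), `marker` (`time`, `z` \[m\]),
#'   optional `mtj` and `torque`, scalar metadata (`body_weight` = standing
#'   plate force \[N\], `body_mass`, `effective_g`, `standing_height`,
#'   `target_height`, `fs`, `condition`), and a `truth` list (liftoff,
#'   touchdown, takeoff velocity, jump height, per-muscle onset \[ms\] and
#'   burst amplitude, and -- with `include_mtj` -- the true MG length series).
#' @export
generate_trial <- function(participant, condition, seed,
                           config = cohort_config()) {
  stopifnot(inherits(participant, "hypojump_participant"))
  is_max <- identical(condition, "MAX")
  g <- if (is_max) 9.81 else config$effective_g[[condition]]
  withr::with_seed(as.integer(seed), {
    if (is_max) {
      h <- participant$max_jump
      onset_mean <- 100
      mag <- 1
      amp_lift <- 1
    } else {
      h <- participant$target_height + config$height_bias[[condition]] +
        rnorm(1, 0, config$height_jitter_sd)
      onset_mean <- config$onset_truth_ms[[condition]]
      mag <- config$magnitude_scale[[condition]]
      amp_lift <- 0.85
    }
    if (h <= 0) abort("infeasible config: jump height <= 0")
    fs <- config$sample_rates
    prof <- grf_profile(participant$mass, g, h, fs$grf)

    grf_z <- prof$F + rnorm(length(prof$F), 0, config$grf_noise_sd)

    # EMG clock
    t_emg <- seq(0, prof$t[length(prof$t)], by = 1 / fs$emg)
    onset_ms <- pmin(150, pmax(20, rnorm(length(MUSCLES), onset_mean,
                                         config$onset_jitter_ms)))
    names(onset_ms) <- MUSCLES
    amp_pre <- setNames(rep(0.35 * mag, length(MUSCLES)), MUSCLES)
    if (is_max) amp_pre[] <- 0.5
    emg <- lapply(MUSCLES, function(m) {
      carrier <- band_noise(length(t_emg), fs$emg)
      env <- emg_envelope(t_emg, prof$t_lo, prof$t_td, onset_ms[[m]] / 1000,
                          amp_pre[[m]], amp_lift = amp_lift)
      vscale <- participant$emg_scale[[m]]
      sig <- env * carrier * vscale
      if (config$emg_noise_sd > 0) {
        sig <- sig + config$emg_noise_sd * sqrt(2 / pi) * vscale *
          band_noise(length(t_emg), fs$emg)
      }
      sig
    })
    names(emg) <- MUSCLES

    # marker clock (sternum = COM displacement + standing height)
    t_mk <- seq(0, prof$t[length(prof$t)], by = 1 / fs$marker)
    z_mk <- participant$standing_height +
      approx(prof$t, prof$z, xout = t_mk, rule = 2)$y

    mtj <- NULL; torque <- NULL; truth_mtj <- NULL
    if (config$include_mtj) {
      mt <- synth_mtj_channels(participant, prof, t_mk, fs$mtj)
      mtj <- mt$mtj; torque <- mt$torque; truth_mtj <- mt$truth
    }
  })

  truth <- c(list(
    t_move = prof$t_move, liftoff = prof$t_lo, touchdown = prof$t_td,
    flight = prof$flight, v_takeoff = prof$v0,
    jump_height = prof$jump_height, effective_g = g,
    onset_ms = onset_ms, burst_amplitude = amp_pre,
    target_height = participant$target_height
  ), truth_mtj)

  structure(list(
    participant = participant$id, condition = condition,
    body_mass = participant$mass, body_weight = participant$mass * g,
    effective_g = g, standing_height = participant$standing_height,
    target_height = participant$target_height,
    fs = config$sample_rates,
    grf = tibble(time = prof$t, grf_z = grf_z),
    emg = as_tibble(c(list(time = t_emg), emg)),
    marker = tibble(time = t_mk, z = z_mk),
    mtj = mtj, torque = torque,
    truth = truth, seed = as.integer(seed)
  ), class = "jump_trial")
}

# muscle-tendon-junction, probe and torque channels (dominant-leg MG).
# Geometry: knee center at the origin, MTU along +x; the insertion marker
# moves so that true MG length follows a phase-locked shorten(push)/
# stretch(land) profile; MTJ sits on the MTU line plus a fixed off-axis
# offset that the projection removes. Pixel columns encode the rolling
# shutter: each frame is sampled at frame time + (u/width) * frame_period.
synth_mtj_channels <- function(participant, prof, t_mk, fs_mtj) {
  l0 <- participant$l0
  lt0 <- 0.055   # resting tendon length [m]
  # phase-locked length profile kept inside the 6 Hz analysis passband
  dl <- function(tt) {
    d <- numeric(length(tt))
    lb <- tt >= (prof$t_lo - 0.6) & tt < prof$t_lo
    x <- (tt[lb] - (prof$t_lo - 0.6)) / 0.6
    d[lb] <- -0.018 * (1 - cos(2 * pi * x)) / 2
    la <- tt >= prof$t_td & tt < prof$t_td + 0.6
    x <- (tt[la] - prof$t_td) / 0.6
    d[la] <- 0.012 * (1 - cos(2 * pi * x)) / 2
    d
  }
  l_mg_true <- l0 + dl(t_mk)

  image_width <- 512L
  frame_period <- 1 / fs_mtj
  fov_w <- 0.06; fov_h <- 0.04      # probe field of view [m]
  x_probe0 <- l0 - 0.03             # lab x of pixel column 0
  off <- c(0.010, 0.004)            # fixed off-axis MTJ offset [m] (y, z)

  t_frame <- seq(0, t_mk[length(t_mk)], by = frame_period)
  # rolling shutter: solve per-frame acquisition time (one fixed-point pass)
  x_at <- function(tt) l0 + dl(tt)
  u <- (x_at(t_frame) - x_probe0) / fov_w * image_width
  t_acq <- t_frame + pmin(pmax(u, 0), image_width) / image_width * frame_period
  u <- (x_at(t_acq) - x_probe0) / fov_w * image_width
  v <- rep(off[1] / fov_h * image_width, length(u))

  mtj <- tibble(
    time = t_frame, u = u, v = v,
    image_width = image_width, frame_period = frame_period,
    knee_x = 0, knee_y = 0, knee_z = 0,
    insertion_x = l0 + lt0, insertion_y = 0, insertion_z = 0,
    ankle_x = l0 + lt0, ankle_y = -0.04, ankle_z = 0,
    probe_x0 = x_probe0, probe_fov_w = fov_w, probe_fov_h = fov_h,
    probe_off_y = off[1], probe_off_z = off[2]
  )
  arm <- 0.04
  grf_mk <- approx(prof$t, prof$F, xout = t_mk, rule = 2)$y
  torque <- tibble(time = t_mk, ankle_torque = 0.12 * grf_mk)
  list(mtj = mtj, torque = torque,
       truth = list(l_mg = tibble(time = t_mk, l_mg = l_mg_true),
                    l0 = l0, moment_arm = arm))
}

#' Simulate a full cohort of jump trials
#'
#' Generates `n_participants` simulated participants, each with three
#' maximum-jump trials (for EMG normalization) and the configured block of
#' PRE / ADAPT / POST targeted jumps. All randomness derives from
#' `config$seed`, so the same configuration reproduces the same cohort.
#'
#' @param config a [cohort_config()].
#' @param out_dir optional directory; when given, every trial is written as a
#'   headered TSV via [write_trial_tsv()] and a JSON manifest with per-trial
#'   ground truth is written alongside (see [write_cohort_manifest()]).
#' @return a `jump_cohort`: list with `participants`, `trials` (list of
#'   `jump_trial`), `max_trials`, a `manifest` tibble (participant, condition,
#'   jump index, seed, truth scalars, file path if written), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  validate_config(config)
  conds <- c("PRE", "ADAPT", "POST")
  n_tr <- sum(config$jumps_per_condition[conds])
  withr::with_seed(config$seed, {
    p_seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
    t_seeds <- matrix(
      sample.int(.Machine$integer.max - 1L, config$n_participants * (n_tr + 3)),
      nrow = config$n_participants
    )
  })
  participants <- lapply(seq_len(config$n_participants), function(i) {
    participant_params(config, sprintf("P%02d", i), p_seeds[i])
  })

  trials <- list(); max_trials <- list(); rows <- list()
  for (i in seq_len(config$n_participants)) {
    p <- participants[[i]]
    ks <- 0L
    max_trials[[p$id]] <- lapply(1:3, function(j) {
      generate_trial(p, "MAX", t_seeds[i, j], config)
    })
    ks <- 3L
    for (cond in conds) {
      for (j in seq_len(config$jumps_per_condition[[cond]])) {
        ks <- ks + 1L
        tr <- generate_trial(p, cond, t_seeds[i, ks], config)
        key <- sprintf("%s_%s_%02d", p$id, cond, j)
        trials[[key]] <- tr
        rows[[key]] <- tibble(
          participant = p$id, condition = cond, jump = j, key = key,
          seed = t_seeds[i, ks],
          true_liftoff = tr$truth$liftoff, true_touchdown = tr$truth$touchdown,
          true_jump_height = tr$truth$jump_height,
          true_effective_g = tr$truth$effective_g,
          true_onset_ms_MG_dom = tr$truth$onset_ms[["MG_dom"]],
          true_burst_amplitude = tr$truth$burst_amplitude[["MG_dom"]]
        )
      }
    }
  }
  manifest <- bind_rows(rows)
  cohort <- structure(list(
    participants = participants, trials = trials, max_trials = max_trials,
    manifest = manifest, config = config
  ), class = "jump_cohort")
  if (!is.null(out_dir)) {
    write_cohort(cohort, out_dir)
    cohort$manifest$file <- file.path(out_dir, paste0(manifest$key, ".tsv"))
  }
  cohort
}

#' @export
print.jump_cohort <- function(x, ...) {
  cat("<jump_cohort> ", length(x$participants), " participants, ",
      length(x$trials), " trials (+", 3 * length(x$participants),
      " max-jump trials)\n", sep = "")
  print(dplyr::count(x$manifest, .data$condition))
  invisible(x)
}

#' @export
print.jump_trial <- function(x, ...) {
  cat(sprintf("<jump_trial> %s %s  mass %.1f kg  g_eff %.2f m/s^2  %0.2f s\n",
              x$participant, x$condition, x$body_mass, x$effective_g,
              max(x$grf$time)))
  invisible(x)
}
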