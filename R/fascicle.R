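#' Rolling-shutter time offsets for ultrasound frames
#'
#' Ultrasound images are acquired column by column, so the pixel column of
#' the tracked muscle-tendon junction determines when within the frame it was
#' actually sampled: offset = (u / image_width) * frame_period, added to the
#' frame timestamp before interpolating onto the kinematic clock.
#'
#' @param u_px horizontal MTJ pixel position per frame.
#' @param image_width image width \[px\].
#' @param frame_period frame interval \[s\].
#' @return per-frame time offsets \[s\], always in \[0, frame_period\];
#'   out-of-range `u` is clamped with a warning.
#' @export
rolling_shutter_offsets <- function(u_px, image_width, frame_period) {
  stopifnot(image_width > 0, frame_period > 0)
  if (any(u_px < 0 | u_px > image_width, na.rm = TRUE)) {
    warn("MTJ pixel positions outside [0, image_width]; clamped")
    u_px <- pmin(pmax(u_px, 0), image_width)
  }
  (u_px / image_width) * frame_period
}

#' Muscle and tendon lengths from an MTJ point
#'
#' Projects the lab-frame muscle-tendon-junction position orthogonally onto
#' the muscle-tendon-unit line (knee joint center to Achilles insertion).
#' MG muscle length is the distance from the knee center to the projected
#' point; tendon length is from the projection to the insertion. For
#' projections inside the segment the two lengths sum exactly to the MTU
#' length.
#'
#' @param mtj_lab,knee_center,insertion numeric length-3 points \[m\], or
#'   n-by-3 matrices of per-frame points.
#' @return tibble with `l_mg`, `l_tendon`, `l_mtu` \[m\] and
#'   `out_of_segment` (TRUE when the orthogonal foot falls outside the
#'   knee--insertion segment; lengths are still reported, not truncated).
#' @export
project_mtj <- function(mtj_lab, knee_center, insertion) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  P <- as_mat(mtj_lab); K <- as_mat(knee_center); I <- as_mat(insertion)
  n <- max(nrow(P), nrow(K), nrow(I))
  rep_rows <- function(M) if (nrow(M) == n) M else M[rep(1, n), , drop = FALSE]
  P <- rep_rows(P); K <- rep_rows(K); I <- rep_rows(I)
  D <- I - K
  l_mtu <- sqrt(rowSums(D^2))
  if (any(l_mtu == 0)) abort("knee and insertion coincide")
  s <- rowSums((P - K) * D) / l_mtu^2
  proj <- K + D * s
  tibble(
    l_mg = sqrt(rowSums((proj - K)^2)),
    l_tendon = sqrt(rowSums((proj - I)^2)),
    l_mtu = l_mtu,
    out_of_segment = s < 0 | s > 1
  )
}

#' Filtered muscle length and lengthening velocity
#'
#' Zero-phase 6 Hz low-pass of the raw length series, then the first time
#' derivative by central differences (one-sided at the record edges).
#' Lengthening is positive.
#'
#' @param l_raw muscle length series \[m\].
#' @param fs sampling rate \[Hz\]; must exceed 12 Hz.
#' @param cutoff low-pass corner \[Hz\].
#' @return tibble with `l_filt` \[m\] and `v` \[m/s\].
#' @export
lengths_and_velocity <- function(l_raw, fs, cutoff = 6) {
  if (length(l_raw) < 5) abort("length series too short")
  if (fs <= 2 * cutoff) abort("sampling rate must exceed twice the cutoff")
  lf <- filter_zerophase(l_raw, fs, cutoff, "low")
  n <- length(lf)
  v <- numeric(n)
  v[2:(n - 1)] <- (lf[3:n] - lf[1:(n - 2)]) * fs / 2
  v[1] <- (lf[2] - lf[1]) * fs
  v[n] <- (lf[n] - lf[n - 1]) * fs
  tibble(l_filt = lf, v = v)
}

#' Group-Ia afferent firing-rate estimate
#'
#' Spindle population model driven by muscle lengthening velocity, length
#' relative to rest, and fusimotor drive tied to muscle activation:
#' \deqn{R_{Ia} = 65 (V/L_0)^{0.5} + 200 (L - L_0)/L_0 + k_u^{max} u + R_{Ia0}}
#' with the velocity term clamped at zero for shortening (the model responds
#' to lengthening velocity) and the total rate floored at zero. `k_u_max` is
#' the percentage maximal recruitment (100) and `u` the EMG activation
#' relative to maximal (0--1); the resting rate `R_Ia0` defaults to 0.
#'
#' The printed lineage of this model is ambiguous about whether the length
#' term is normalized by the resting length; `variant = "normalized"`
#' (default) uses \eqn{200 (L - L_0)/L_0}, `variant = "literal"` uses
#' \eqn{200 (L - L_0)} with lengths in meters. Both are exercised in the test
#' suite; neither is asserted as uniquely correct.
#'
#' @param v_mg lengthening velocity \[m/s\] (negative = shortening).
#' @param l_mg muscle length \[m\].
#' @param l0 resting muscle length \[m\], > 0.
#' @param u normalized activation in \[0, 1\].
#' @param k_u_max percentage maximal recruitment (default 100).
#' @param r_ia0 resting firing rate \[impulses/s\] (default 0).
#' @param variant length-term normalization, see Details.
#' @return firing rate \[impulses/s\], vectorized, floored at 0.
#' @examples
#' ia_rate(0, 0.27, 0.27, 0)                 # rest -> 0
#' ia_rate(0.27, 0.27 * 1.1, 0.27, 0.5)      # 65 + 20 + 50 = 135
#' @export
ia_rate <- function(v_mg, l_mg, l0, u, k_u_max = 100, r_ia0 = 0,
                    variant = c("normalized", "literal")) {
  variant <- match.arg(variant)
  if (any(l0 <= 0)) abort("resting length l0 must be > 0")
  if (any(u < 0 | u > 1)) abort("activation u must lie in [0, 1]")
  vel_term <- 65 * sqrt(pmax(v_mg, 0) / l0)
  len_term <- if (variant == "normalized") 200 * (l_mg - l0) / l0
              else 200 * (l_mg - l0)
  pmax(0, vel_term + len_term + k_u_max * u + r_ia0)
}

#' Ankle moment arm of the muscle-tendon unit
#'
#' Orthogonal distance from the ankle joint center to the MTU line
#' (knee center to insertion), per frame.
#'
#' @param ankle_center,knee_center,insertion length-3 points or n-by-3
#'   matrices \[m\].
#' @return moment arm \[m\], vectorized.
#' @export
mtu_moment_arm <- function(ankle_center, knee_center, insertion) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  A <- as_mat(ankle_center); K <- as_mat(knee_center); I <- as_mat(insertion)
  n <- max(nrow(A), nrow(K), nrow(I))
  rep_rows <- function(M) if (nrow(M) == n) M else M[rep(1, n), , drop = FALSE]
  A <- rep_rows(A); K <- rep_rows(K); I <- rep_rows(I)
  D <- I - K
  l <- sqrt(rowSums(D^2))
  if (any(l == 0)) abort("knee and insertion coincide")
  s <- rowSums((A - K) * D) / l^2
  foot <- K + D * s
  sqrt(rowSums((A - foot)^2))
}

#' Muscle force from ankle torque
#'
#' The force the MTU must carry to produce the measured ankle torque about
#' its moment arm: F = torque / arm. Arms below 1 mm are numerically
#' unreliable and flagged.
#'
#' @param ankle_torque \[N m\].
#' @param moment_arm \[m\], > 0.
#' @return tibble with `force` \[N\] and `flag_unreliable`.
#' @export
muscle_force <- function(ankle_torque, moment_arm) {
  if (any(moment_arm <= 0)) abort("moment arm must be > 0")
  tibble(
    force = ankle_torque / moment_arm,
    flag_unreliable = moment_arm < 1e-3
  )
}

#' Muscle-state reconstruction for one trial
#'
#' End-to-end fascicle pipeline on a trial's MTJ channels: rolling-shutter
#' timestamp correction, pixel-to-lab mapping via the stored probe
#' calibration, cubic interpolation onto the kinematic clock, orthogonal
#' projection onto the MTU line, 6 Hz filtering and differentiation,
#' activation from the normalized MG EMG (100 ms envelope), muscle force
#' from ankle torque, and the group-Ia firing-rate estimate.
#'
#' @param trial a `jump_trial` generated with `include_mtj = TRUE`.
#' @param norm_peaks per-muscle normalization peaks \[V\] (needs `MG_dom`).
#' @param l0 resting MG length \[m\]; defaults to the trial's standing value
#'   (median of the first 0.3 s of reconstructed length).
#' @param variant passed to [ia_rate()].
#' @return tibble on the kinematic clock: `time`, `l_mg`, `l_tendon`,
#'   `l_mtu`, `v_mg`, `u`, `force`, `moment_arm`, `r_ia`.
#' @export
muscle_state <- function(trial, norm_peaks, l0 = NULL,
                         variant = "normalized") {
  if (is.null(trial$mtj)) abort("trial has no MTJ channels")
  mt <- trial$mtj
  fs_k <- trial$fs$marker
  t_k <- trial$torque$time

  off <- rolling_shutter_offsets(mt$u, mt$image_width[1], mt$frame_period[1])
  t_acq <- mt$time + off
  # pixel -> lab (probe calibration stored with the synthetic channels)
  x_lab <- mt$probe_x0[1] + mt$u / mt$image_width[1] * mt$probe_fov_w[1]
  y_lab <- mt$probe_off_y[1]
  z_lab <- mt$probe_off_z[1]
  x_i <- spline(t_acq, x_lab, xout = t_k, method = "natural")$y
  P <- cbind(x_i, y_lab, z_lab)
  K <- cbind(mt$knee_x[1], mt$knee_y[1], mt$knee_z[1])
  I <- cbind(mt$insertion_x[1], mt$insertion_y[1], mt$insertion_z[1])
  A <- cbind(mt$ankle_x[1], mt$ankle_y[1], mt$ankle_z[1])
  geo <- project_mtj(P, K, I)
  lv <- lengths_and_velocity(geo$l_mg, fs_k)
  if (is.null(l0)) l0 <- median(lv$l_filt[t_k <= 0.3])

  fs_e <- trial$fs$emg
  rect <- emg_preprocess(trial$emg$MG_dom, fs_e) / norm_peaks[["MG_dom"]]
  env <- moving_average(rect, fs_e, 0.1)
  u <- approx(trial$emg$time, env, xout = t_k, rule = 2)$y
  u <- pmin(1, pmax(0, u))

  arm <- mtu_moment_arm(A, K, I)
  arm <- rep(arm, length.out = length(t_k))
  frc <- muscle_force(trial$torque$ankle_torque, arm)

  tibble(
    time = t_k,
    l_mg = lv$l_filt, l_tendon = geo$l_tendon, l_mtu = geo$l_mtu,
    v_mg = lv$v, u = u, force = frc$force, moment_arm = arm,
    r_ia = ia_rate(lv$v, lv$l_filt, l0, u, variant = variant)
  )
}
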