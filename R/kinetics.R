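#' Segment a countermovement jump into lift, aerial, and landing phases
#'
#' Phase boundaries follow force-plate conventions: the aerial phase is the
#' longest contiguous run of vertical force below 25 N; liftoff is its first
#' sample and touchdown the first sample at or above 25 N after it. The lift
#' phase begins at the last upward crossing of body weight before the
#' push-off force peak (so the countermovement unload dip lies inside the
#' search window but the rising crossing is chosen), and the landing phase
#' ends at the first downward crossing of body weight after the landing
#' peak. Crossing indices are reported as the sample bounding the crossing
#' from below (floor); ties at exactly body weight resolve to the earliest
#' sample.
#'
#' The caller is responsible for supplying a force trace whose noise does not
#' defeat the thresholds (typically 25 Hz low-pass filtered; see
#' [filter_zerophase()]).
#'
#' @param grf_z vertical ground reaction force \[N\], summed over plates.
#' @param body_weight standing plate force \[N\] for this trial (with
#'   body-weight support engaged, this is the *effective* weight).
#' @param fs sampling rate \[Hz\].
#' @param aerial_threshold force threshold defining the aerial phase \[N\].
#' @return object of class `jump_phases`: sample indices `lift_start`,
#'   `liftoff`, `touchdown`, `land_end`, plus `fs` and the two force peaks.
#' @export
segment_phases <- function(grf_z, body_weight, fs, aerial_threshold = 25) {
  stopifnot(is.numeric(grf_z), length(grf_z) > 10, body_weight > 0, fs > 0)
  below <- grf_z < aerial_threshold
  r <- rle(below)
  if (!any(r$values)) abort("no aerial phase")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  k <- runs[which.max(r$lengths[runs])]
  liftoff <- starts[k]
  touchdown <- ends[k] + 1L
  if (touchdown > length(grf_z)) abort("no aerial phase")

  if (liftoff < 3L) abort("degenerate trial")
  peak_push <- which.max(grf_z[seq_len(liftoff - 1L)])
  up <- which(grf_z[seq_len(peak_push - 1L)] < body_weight &
                grf_z[2:peak_push] >= body_weight)
  if (length(up) == 0) abort("degenerate trial")
  lift_start <- max(up)

  peak_land <- touchdown - 1L + which.max(grf_z[touchdown:length(grf_z)])
  idx <- peak_land:(length(grf_z) - 1L)
  down <- idx[grf_z[idx] >= body_weight & grf_z[idx + 1L] < body_weight]
  if (length(down) == 0) abort("degenerate trial")
  land_end <- min(down)

  stopifnot(lift_start < liftoff, liftoff < touchdown, touchdown < land_end)
  structure(list(
    lift_start = lift_start, liftoff = liftoff, touchdown = touchdown,
    land_end = land_end, fs = fs, peak_push = peak_push, peak_land = peak_land
  ), class = "jump_phases")
}

#' @export
print.jump_phases <- function(x, ...) {
  cat(sprintf(
    "<jump_phases> lift %d-%d, aerial %d-%d, land %d-%d (fs %g Hz, flight %.3f s)\n",
    x$lift_start, x$liftoff, x$liftoff, x$touchdown, x$touchdown, x$land_end,
    x$fs, (x$touchdown - x$liftoff) / x$fs
  ))
  invisible(x)
}

#' Lift and landing impulses
#'
#' Trapezoidal time integral of the vertical force over the lift window
#' (lift start to liftoff) and the landing window (touchdown to landing end).
#' The default is the gross impulse (area under the force curve); set
#' `net = TRUE` to subtract body weight first, which is the quantity entering
#' impulse--momentum checks.
#'
#' @param grf_z vertical force \[N\] (raw, unfiltered is fine).
#' @param phases a [segment_phases()] result.
#' @param fs sampling rate \[Hz\] (defaults to `phases$fs`).
#' @param net subtract `body_weight` before integrating?
#' @param body_weight required when `net = TRUE`.
#' @return tibble with `lift_impulse` and `land_impulse` \[N s\].
#' @export
compute_impulses <- function(grf_z, phases, fs = phases$fs, net = FALSE,
                             body_weight = NULL) {
  stopifnot(inherits(phases, "jump_phases"))
  if (net && is.null(body_weight)) abort("net impulse needs body_weight")
  f <- grf_z - if (net) body_weight else 0
  win <- function(i0, i1) {
    if (i1 <= i0) abort("empty integration window")
    idx <- i0:i1
    trapz_int((idx - 1) / fs, f[idx])
  }
  tibble(
    lift_impulse = win(phases$lift_start, phases$liftoff),
    land_impulse = win(phases$touchdown, phases$land_end)
  )
}

#' Jump height and target error from the sternum marker
#'
#' Jump height is the peak marker height during the aerial phase minus the
#' standing reference height; target error is jump height minus the target.
#'
#' @param marker_z sternum marker height \[m\] (25 Hz low-passed upstream).
#' @param fs_marker marker sampling rate \[Hz\].
#' @param phases a [segment_phases()] result (force-plate clock; converted to
#'   the marker clock by time).
#' @param standing_height standing sternum height \[m\].
#' @param target_height target jump height \[m\].
#' @return tibble with `jump_height`, `target_error`, `abs_target_error`
#'   \[m\] and `flag_nonpositive` (TRUE when the marker never exceeded
#'   standing height).
#' @export
jump_metrics <- function(marker_z, fs_marker, phases, standing_height,
                         target_height) {
  t_lo <- (phases$liftoff - 1) / phases$fs
  t_td <- (phases$touchdown - 1) / phases$fs
  t_mk <- (seq_along(marker_z) - 1) / fs_marker
  idx <- which(t_mk >= t_lo & t_mk <= t_td)
  if (length(idx) == 0) abort("aerial window empty on marker clock")
  h <- max(marker_z[idx]) - standing_height
  tibble(
    jump_height = h,
    target_error = h - target_height,
    abs_target_error = abs(h - target_height),
    flag_nonpositive = h <= 0
  )
}

#' Aerial-phase vertical acceleration of a marker
#'
#' Least-squares quadratic fit of marker height against time over the aerial
#' window; returns twice the quadratic coefficient, i.e. the (signed)
#' constant acceleration, negative downward. Used to verify the effective
#' gravity imposed on the body during flight.
#'
#' @inheritParams jump_metrics
#' @param trim fraction of the aerial window trimmed at each end before
#'   fitting (default 0; use a small trim on filtered data to avoid edge
#'   transients).
#' @return acceleration \[m/s^2\].
#' @export
aerial_acceleration <- function(marker_z, fs_marker, phases, trim = 0) {
  t_lo <- (phases$liftoff - 1) / phases$fs
  t_td <- (phases$touchdown - 1) / phases$fs
  span <- t_td - t_lo
  t_mk <- (seq_along(marker_z) - 1) / fs_marker
  idx <- which(t_mk >= t_lo + trim * span & t_mk <= t_td - trim * span)
  if (length(idx) < 5) abort("aerial window too short for acceleration fit")
  tt <- t_mk[idx] - mean(t_mk[idx])
  fit <- lm(marker_z[idx] ~ tt + I(tt^2))
  2 * unname(coef(fit)[3])
}

#' Ballistic fall time and preactivation-delay analytics
#'
#' `fall_time()` is the time to fall a given height from rest,
#' `sqrt(2 h / g)`. `delay_prediction()` is the change in fall time when the
#' same height is dropped under an alternative gravity -- the delay in
#' landing time a jumper should expect if their motor system still assumes
#' `g_alt` applies. `delay_mitigation_percent()` expresses how much of that
#' predicted delay an observed delay fails to show,
#' `100 (predicted - observed) / predicted`.
#'
#' @param height drop height \[m\], >= 0.
#' @param g,g_ref,g_alt gravitational acceleration \[m/s^2\], > 0.
#' @param predicted,observed delays \[s\] (or any common unit).
#' @return seconds (percent for `delay_mitigation_percent()`); vectorized.
#' @examples
#' fall_time(0.273, 9.81)                      # ~0.236 s
#' fall_time(0.273, 0.508 * 9.81)              # ~0.331 s
#' delay_prediction(0.273, 9.81, 0.508 * 9.81) # ~0.095 s
#' delay_mitigation_percent(0.095, 0.026)      # ~72.6 %
#' @export
fall_time <- function(height, g) {
  if (any(height < 0)) abort("height must be >= 0")
  if (any(g <= 0)) abort("g must be > 0")
  sqrt(2 * height / g)
}

#' @rdname fall_time
#' @export
delay_prediction <- function(height, g_ref, g_alt) {
  fall_time(height, g_alt) - fall_time(height, g_ref)
}

#' @rdname fall_time
#' @export
delay_mitigation_percent <- function(predicted, observed) {
  if (any(predicted <= 0)) abort("predicted delay must be > 0")
  100 * (predicted - observed) / predicted
}

#' Kinetic analysis of one trial
#'
#' Full per-trial kinetics: low-pass filters force and marker at 25 Hz,
#' segments the phases on the filtered force, refines the two aerial
#' boundaries on the raw force (the 25 N threshold is timed against the
#' unsmeared signal so touchdown is not biased early by the zero-phase
#' filter's pre-ring), then computes impulses, jump height, target error and
#' the aerial acceleration estimate.
#'
#' @param trial a `jump_trial`.
#' @param filter_hz kinetics low-pass corner \[Hz\].
#' @return one-row tibble of per-jump metrics (impulses \[N s\], heights and
#'   errors \[m\], `aerial_g` \[m/s^2\], `flight_time` \[s\], liftoff /
#'   touchdown times \[s\]), with the `jump_phases` object attached as
#'   attribute `"phases"`.
#' @export
analyze_trial_kinetics <- function(trial, filter_hz = 25) {
  stopifnot(inherits(trial, "jump_trial"))
  fs <- trial$fs$grf
  grf_raw <- trial$grf$grf_z
  grf_f <- filter_zerophase(grf_raw, fs, filter_hz, "low")
  ph <- segment_phases(grf_f, trial$body_weight, fs)
  ph <- refine_aerial_bounds(ph, grf_raw, fs)

  mk <- filter_zerophase(trial$marker$z, trial$fs$marker, filter_hz, "low")
  imp <- compute_impulses(grf_raw, ph, fs)
  jm <- jump_metrics(mk, trial$fs$marker, ph, trial$standing_height,
                     trial$target_height)
  ag <- tryCatch(
    aerial_acceleration(mk, trial$fs$marker, ph, trim = 0.1),
    error = function(e) NA_real_
  )
  out <- dplyr::bind_cols(
    tibble(participant = trial$participant, condition = trial$condition),
    imp, jm,
    tibble(
      aerial_g = ag,
      flight_time = (ph$touchdown - ph$liftoff) / fs,
      liftoff_t = (ph$liftoff - 1) / fs,
      touchdown_t = (ph$touchdown - 1) / fs
    )
  )
  attr(out, "phases") <- ph
  out
}

# re-time the 25 N liftoff/touchdown crossings on the raw force trace: the
# zero-phase low-pass smears the landing step backwards in time, so the
# filtered trace crosses the threshold several ms before the foot actually
# hits. Search within +-60 ms of the filtered boundaries, requiring the
# threshold condition to hold for a 20 ms guard window.
refine_aerial_bounds <- function(phases, grf_raw, fs, aerial_threshold = 25) {
  guard <- max(1L, round(0.02 * fs))
  w <- round(0.06 * fs)
  n <- length(grf_raw)
  holds_below <- function(i) all(grf_raw[i:min(n, i + guard)] < aerial_threshold)
  lo_cand <- max(1L, phases$liftoff - w):min(n, phases$liftoff + w)
  lo_cand <- lo_cand[grf_raw[lo_cand] < aerial_threshold]
  lo_cand <- lo_cand[vapply(lo_cand, holds_below, TRUE)]
  if (length(lo_cand)) phases$liftoff <- min(lo_cand)

  holds_above <- function(i) all(grf_raw[i:min(n, i + guard)] >= aerial_threshold)
  td_cand <- max(phases$liftoff + 1L, phases$touchdown - w):min(n, phases$touchdown + w)
  td_cand <- td_cand[grf_raw[td_cand] >= aerial_threshold]
  td_cand <- td_cand[vapply(td_cand, holds_above, TRUE)]
  if (length(td_cand)) phases$touchdown <- min(td_cand)
  phases
}
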