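#' EMG preprocessing: band-limit and rectify
#'
#' Zero-phase high-pass at 5 Hz and low-pass at 450 Hz (4th-order
#' Butterworth, forward--backward), then full-wave rectification. Corners at
#' or above Nyquist are clamped to 0.45 fs with a warning, so channels
#' sampled below 900 Hz degrade gracefully.
#'
#' @param raw raw EMG \[V\].
#' @param fs sampling rate \[Hz\].
#' @param band filter band \[Hz\].
#' @return rectified series, same length as `raw`.
#' @export
emg_preprocess <- function(raw, fs, band = c(5, 450)) {
  x <- filter_zerophase(raw, fs, band[1], "high")
  x <- filter_zerophase(x, fs, band[2], "low")
  abs(x)
}

#' EMG normalization peak from maximum-jump trials
#'
#' The peak of a 100 ms centered sliding-window average of the rectified EMG,
#' taken over all supplied maximum-jump trials; all subsequent rectified EMG
#' for that muscle is divided by this peak.
#'
#' @param rectified one rectified series, or a list of them (one per
#'   maximum-jump trial).
#' @param fs sampling rate \[Hz\].
#' @param window_s sliding window width \[s\].
#' @return the normalization peak \[V\].
#' @export
normalization_peak <- function(rectified, fs, window_s = 0.1) {
  if (!is.list(rectified)) rectified <- list(rectified)
  stopifnot(length(rectified) >= 1)
  peaks <- vapply(rectified, function(x) {
    stopifnot(length(x) >= window_s * fs)
    max(moving_average(x, fs, window_s))
  }, numeric(1))
  pk <- max(peaks)
  if (pk <= 0) abort("silent reference channel: normalization peak is zero")
  pk
}

# local maxima of a series with plateau handling: equal-value runs are
# compressed; a run flanked by strictly lower runs (record boundaries count
# as -Inf) is a maximum and contributes its *last* sample index.
local_maxima_idx <- function(x) {
  r <- rle(x)
  v <- c(-Inf, r$values, -Inf)
  ends <- cumsum(r$lengths)
  is_max <- r$values > v[seq_along(r$values)] &
    r$values > v[seq_along(r$values) + 2L]
  ends[is_max]
}

#' Preactivation onset by cumulative integration, with exclusion gates
#'
#' Locates the time during the aerial phase at which rectified EMG most
#' rapidly increases -- the preactivation onset -- as the point of maximum
#' downward deviation of the cumulative integral of the rectified signal
#' from the chord joining its values at liftoff and touchdown (the "elbow"
#' of the cumulative trace). Onset is reported in ms before touchdown.
#'
#' Three gates accommodate the very low activation seen during and after
#' body-weight-supported jumping:
#' \describe{
#'   \item{no-late-max}{the rectified trace is low-passed at 1 Hz and its
#'     local maxima extracted; if the latest local maximum inside the aerial
#'     window is not within 150 ms of touchdown, there is no landing-directed
#'     burst and the trial is excluded.}
#'   \item{too-early}{onsets more than 150 ms before touchdown are outside
#'     the physiological preactivation range (e.g. a burst during ascent)
#'     and are excluded.}
#'   \item{sub-1-percent}{if mean normalized activity between onset and
#'     touchdown is below 0.01 (1% of the maximum activation), preactivation
#'     is absent and the trial is excluded.}
#' }
#' Both 150 ms gates are inclusive (<= 150 ms passes). Ties in the deviation
#' minimum take the latest sample.
#'
#' @param rectified_norm rectified, normalization-peak-scaled EMG (unitless).
#' @param fs sampling rate \[Hz\].
#' @param liftoff,touchdown aerial-window sample indices on the EMG clock.
#' @param max_onset_ms the 150 ms gate \[ms\].
#' @param min_magnitude the 1% magnitude gate (normalized units).
#' @param method `"chord"` (deviation from chord, default) or
#'   `"second-diff"` (maximum second difference of the smoothed cumulative
#'   integral; sensitivity alternative).
#' @return a one-row tibble of class `preactivation_result`:
#'   `onset_ms_before_landing`, `onset_idx`, `magnitude`, `iemg`,
#'   `included`, `exclusion_rule` (`"none"` when included).
#' @export
detect_onset <- function(rectified_norm, fs, liftoff, touchdown,
                         max_onset_ms = 150, min_magnitude = 0.01,
                         method = c("chord", "second-diff")) {
  method <- match.arg(method)
  stopifnot(liftoff >= 1, touchdown <= length(rectified_norm))
  if (touchdown <= liftoff) abort("empty aerial window")
  if ((touchdown - liftoff) / fs < 0.05) abort("aerial window < 50 ms")
  win <- liftoff:touchdown
  x <- rectified_norm[win]
  t <- (win - 1) / fs

  res <- function(onset_idx, rule) {
    included <- identical(rule, "none")
    if (is.na(onset_idx)) {
      mag <- NA_real_; ie <- NA_real_; onset_ms <- NA_real_
    } else {
      onset_ms <- (touchdown - onset_idx) / fs * 1000
      pm <- preactivation_metrics(rectified_norm, fs, onset_idx, touchdown)
      mag <- pm$magnitude; ie <- pm$iemg
    }
    out <- tibble(
      onset_ms_before_landing = onset_ms, onset_idx = onset_idx,
      magnitude = mag, iemg = ie,
      included = included, exclusion_rule = rule
    )
    class(out) <- c("preactivation_result", class(out))
    out
  }

  # gate 1: latest 1 Hz-smoothed local maximum must fall within 150 ms of td.
  # Smoothing is applied to the aerial trace itself (so the lift burst ending
  # at liftoff cannot smear into the gate) with a zero-phase Gaussian kernel
  # at a 1 Hz equivalent cutoff, which stays exact on short windows.
  smooth <- gaussian_smooth(x, fs, 1)
  lm_idx <- local_maxima_idx(round(smooth, 12))
  if (length(lm_idx) == 0 ||
      (length(x) - max(lm_idx)) / fs * 1000 > max_onset_ms) {
    return(res(NA_integer_, "no-late-max"))
  }

  # core: elbow of the cumulative integral over the aerial window
  C <- cumtrapz_int(t, x)
  if (method == "chord") {
    chord <- C[1] + (C[length(C)] - C[1]) * (t - t[1]) / (t[length(t)] - t[1])
    dev <- C - chord
    k <- max(which(dev == min(dev)))          # ties -> latest
  } else {
    Cs <- if (length(C) > 20) filter_zerophase(C, fs, 10, "low") else C
    d2 <- diff(Cs, differences = 2)
    k <- max(which(d2 == max(d2))) + 1L
  }
  onset_idx <- win[k]
  onset_ms <- (touchdown - onset_idx) / fs * 1000

  if (onset_ms > max_onset_ms) return(res(onset_idx, "too-early"))

  mag <- preactivation_metrics(rectified_norm, fs, onset_idx, touchdown)$magnitude
  if (mag < min_magnitude) return(res(onset_idx, "sub-1-percent"))
  res(onset_idx, "none")
}

#' Preactivation magnitude and integrated EMG
#'
#' Magnitude is the mean of the rectified normalized EMG between
#' preactivation onset and ground contact; iEMG is the trapezoidal time
#' integral over the same window (normalized units times seconds).
#'
#' @inheritParams detect_onset
#' @param onset_idx,touchdown sample indices, onset < touchdown.
#' @return tibble with `magnitude` and `iemg`.
#' @export
preactivation_metrics <- function(rectified_norm, fs, onset_idx, touchdown) {
  if (onset_idx > touchdown) abort("onset after touchdown")
  idx <- onset_idx:touchdown
  if (length(idx) == 1L) {
    return(tibble(magnitude = rectified_norm[idx], iemg = 0))
  }
  tibble(
    magnitude = mean(rectified_norm[idx]),
    iemg = trapz_int((idx - 1) / fs, rectified_norm[idx])
  )
}

#' Triceps Surae Preactivity
#'
#' Arithmetic mean of the preactivation iEMG over the three triceps-surae
#' muscles (MG, LG, SOL) of one leg for one jump -- a comprehensive
#' per-leg preactivation metric. If any member muscle was excluded by an
#' onset gate the value is reported missing (`NA`) with the first exclusion
#' reason attached, unless `allow_partial = TRUE`, in which case the mean of
#' the included muscles is returned.
#'
#' @param iemg_mg,iemg_lg,iemg_sol per-muscle iEMG (NA when excluded).
#' @param rules optional character vector of per-muscle exclusion rules, used
#'   to propagate the reason when a value is missing.
#' @param allow_partial average over the available muscles instead of
#'   reporting missing.
#' @return one-row tibble with `tsp` and `tsp_rule`.
#' @export
triceps_surae_preactivity <- function(iemg_mg, iemg_lg, iemg_sol,
                                      rules = NULL, allow_partial = FALSE) {
  v <- c(iemg_mg, iemg_lg, iemg_sol)
  if (anyNA(v) && !allow_partial) {
    reason <- if (!is.null(rules)) {
      paste(unique(rules[is.na(v) | rules != "none"]), collapse = ";")
    } else "member-muscle-excluded"
    return(tibble(tsp = NA_real_, tsp_rule = reason))
  }
  tibble(tsp = mean(v, na.rm = allow_partial), tsp_rule = "none")
}

#' Per-muscle EMG normalization peaks for one participant
#'
#' Runs [emg_preprocess()] and [normalization_peak()] over the participant's
#' maximum-jump trials for every muscle channel.
#'
#' @param max_trials list of `jump_trial`s (condition `"MAX"`).
#' @return named numeric vector of peaks \[V\], one per muscle.
#' @export
normalization_peaks <- function(max_trials) {
  fs <- max_trials[[1]]$fs$emg
  muscles <- setdiff(names(max_trials[[1]]$emg), "time")
  vapply(muscles, function(m) {
    rect <- lapply(max_trials, function(tr) emg_preprocess(tr$emg[[m]], fs))
    normalization_peak(rect, fs)
  }, numeric(1))
}

#' EMG analysis of one trial
#'
#' Preprocesses and normalizes every muscle channel, maps the kinetic
#' liftoff/touchdown times onto the EMG clock (nearest sample), and runs the
#' onset detector and preactivation metrics.
#'
#' @param trial a `jump_trial`.
#' @param norm_peaks named per-muscle normalization peaks \[V\] from
#'   [normalization_peaks()].
#' @param liftoff_t,touchdown_t aerial-phase boundary times \[s\] from the
#'   kinetic analysis.
#' @param ... passed to [detect_onset()].
#' @return tibble, one row per muscle: participant, condition, leg, muscle,
#'   onset_ms, magnitude, iemg, included, exclusion_rule.
#' @export
analyze_trial_emg <- function(trial, norm_peaks, liftoff_t, touchdown_t, ...) {
  fs <- trial$fs$emg
  t_emg <- trial$emg$time
  lo <- which.min(abs(t_emg - liftoff_t))
  td <- which.min(abs(t_emg - touchdown_t))
  muscles <- setdiff(names(trial$emg), "time")
  rows <- lapply(muscles, function(m) {
    rect <- emg_preprocess(trial$emg[[m]], fs) / norm_peaks[[m]]
    r <- detect_onset(rect, fs, lo, td, ...)
    parts <- strsplit(m, "_", fixed = TRUE)[[1]]
    dplyr::bind_cols(
      tibble(participant = trial$participant, condition = trial$condition,
             muscle = parts[1], leg = parts[2]),
      as_tibble(r)[c("onset_ms_before_landing", "magnitude", "iemg",
                     "included", "exclusion_rule")]
    )
  })
  out <- bind_rows(rows)
  rename(out, onset_ms = "onset_ms_before_landing")
}
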