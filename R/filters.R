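#' Zero-phase Butterworth filtering
#'
#' All stated filter corners in the pipeline (25 Hz kinetics/markers, 5--450 Hz
#' EMG band, 1 Hz onset-gate envelope, 6 Hz muscle length) are realized as a
#' 4th-order Butterworth applied forward--backward (`signal::filtfilt`), i.e.
#' zero-phase, so filtering never shifts onset or phase-boundary timing.
#'
#' Corners at or above Nyquist are clamped to 0.45 * fs with a warning; this
#' keeps the 450 Hz EMG low-pass meaningful when a channel was sampled slower
#' than 1000 Hz.
#'
#' @param x numeric vector, one uniformly sampled channel.
#' @param fs sampling rate \[Hz\].
#' @param cutoff corner frequency \[Hz\]; length 1 for `"low"`/`"high"`,
#'   length 2 `c(lo, hi)` for `"pass"`.
#' @param type `"low"`, `"high"`, or `"pass"`.
#' @param order filter order of the underlying Butterworth design (the
#'   forward--backward pass doubles the effective order).
#' @return filtered numeric vector, same length as `x`.
#' @examples
#' fs <- 1000
#' t <- seq(0, 1, by = 1 / fs)
#' x <- sin(2 * pi * 2 * t) + sin(2 * pi * 200 * t)
#' y <- filter_zerophase(x, fs, 25, "low")  # keeps the 2 Hz component
#' @export
filter_zerophase <- function(x, fs, cutoff, type = c("low", "high", "pass"),
                             order = 4L) {
  type <- match.arg(type)
  stopifnot(is.numeric(x), fs > 0, all(cutoff > 0))
  nyq <- fs / 2
  if (any(cutoff >= nyq)) {
    warn(sprintf(
      "filter corner %s Hz at or above Nyquist (%g Hz); clamped to %g Hz",
      paste(cutoff[cutoff >= nyq], collapse = ", "), nyq, 0.45 * fs
    ))
    cutoff[cutoff >= nyq] <- 0.45 * fs
  }
  bf <- signal::butter(order, cutoff / nyq, type = type)
  # odd-reflection padding so the forward-backward transients decay outside
  # the record instead of corrupting its edges
  n <- length(x)
  pad <- min(n - 1, ceiling(8 * fs / min(cutoff)))
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    y <- signal::filtfilt(bf, c(left, x, right))
    as.numeric(y[(pad + 1):(pad + n)])
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Centered moving average with edge truncation
#'
#' Sliding-window mean used for the EMG normalization peak: a centered window
#' of `width_s` seconds whose effective width shrinks near the boundaries
#' (the mean is always over the samples actually inside the record).
#'
#' @param x numeric vector.
#' @param fs sampling rate \[Hz\].
#' @param width_s window width \[s\] (default 0.1, i.e. 100 ms).
#' @return numeric vector of windowed means, same length as `x`.
#' @export
moving_average <- function(x, fs, width_s = 0.1) {
  stopifnot(length(x) >= 1, fs > 0, width_s > 0)
  half <- max(0L, floor(width_s * fs / 2))
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# trapezoidal integral of y(t); thin wrapper so the integration rule is
# stated once
trapz_int <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  pracma::trapz(t, y)
}

# cumulative trapezoidal integral, C[1] = 0
cumtrapz_int <- function(t, y) {
  stopifnot(length(t) == length(y))
  if (length(y) < 2) return(rep(0, length(y)))
  as.numeric(pracma::cumtrapz(t, y))
}

#' Zero-phase Gaussian smoother with a stated cutoff
#'
#' Kernel smoother used where an IIR low-pass is transient-dominated (very
#' low corners on short windows, e.g. the 1 Hz onset-gate envelope): a
#' Gaussian kernel with sigma = 0.1325 / cutoff seconds (matching the -3 dB
#' point of the equivalent low-pass), truncated at 4 sigma and renormalized
#' at the record edges so constants pass through exactly.
#'
#' @inheritParams filter_zerophase
#' @param cutoff -3 dB cutoff \[Hz\].
#' @return smoothed numeric vector, same length as `x`.
#' @export
gaussian_smooth <- function(x, fs, cutoff) {
  stopifnot(fs > 0, cutoff > 0)
  sigma <- 0.1325 / cutoff * fs          # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  n <- length(x)
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k, sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}
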