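#' Time-normalize a phase waveform to a fixed number of points
#'
#' Resamples one phase of one trial onto `n_points` equally spaced points via
#' cubic-spline interpolation on the sample-index grid. Endpoints are
#' preserved exactly and linear trends are reproduced without ringing, which
#' matters for nonperiodic jump-phase waveforms. Defaults for the jump phases
#' are 64 points (lift, land) and 34 points (aerial); see
#' [phase_points()].
#'
#' @param x numeric series (length >= 2).
#' @param n_points target length (>= 2).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, n_points) {
  if (length(x) < 2) abort("need at least 2 samples to time-normalize")
  if (n_points < 2) abort("n_points must be >= 2")
  if (length(x) == n_points) return(as.numeric(x))
  idx <- seq(1, length(x), length.out = n_points)
  spline(seq_along(x), x, xout = idx, method = "natural")$y
}

#' @rdname time_normalize
#' @param phase `"lift"`, `"aerial"`, or `"land"`.
#' @export
phase_points <- function(phase = c("lift", "aerial", "land")) {
  phase <- match.arg(phase)
  c(lift = 64L, aerial = 34L, land = 64L)[[phase]]
}

#' Wavelet-domain functional paired t-test
#'
#' Compares paired waveform samples (participants x time points, PRE vs
#' POST) in the wavelet domain: each waveform is decomposed with a full-depth
#' orthogonal periodized DWT, each coefficient is tested with a paired
#' two-tailed t-test at `alpha`, significant coefficients carry their mean
#' paired difference (PRE - POST) as a contrast while all others are zeroed,
#' and the contrast is reconstructed back into the time domain. Time-domain
#' significance is flagged where the absolute contrast reaches
#' `mask_threshold_frac` (10%) of its peak.
#'
#' Waveform lengths that are not a power of 2 (the 34-point aerial phase)
#' are internally resampled to the nearest power of 2, decomposed and
#' tested there, and the reconstructed contrast is resampled back.
#'
#' Coefficients whose paired differences have zero variance are judged in
#' the t-statistic limit: significant when the common difference is nonzero,
#' not significant when it is identically zero.
#'
#' @param pre,post numeric matrices, participants x time points, identically
#'   shaped, paired by row; at least 3 participants; no missing cells.
#' @param alpha per-coefficient significance level (no multiplicity
#'   correction by default, `p_adjust = "holm"` for a corrected variant).
#' @param family wavelet family, see [dwt_matrix()].
#' @param mask_threshold_frac fraction of the peak contrast required for the
#'   time-domain significance mask.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return object of class `functional_ttest`: `contrast` (length =
#'   `ncol(pre)`), logical `mask`, `coeff_table` (label, band, mean
#'   difference, t, p, significant), and metadata (`alpha`, `family`,
#'   `n`, `sign_convention = "PRE - POST"`).
#' @export
wavelet_paired_test <- function(pre, post, alpha = 0.05, family = "coif3",
                                mask_threshold_frac = 0.10,
                                p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!identical(dim(pre), dim(post))) abort("pre/post must be identically shaped")
  if (nrow(pre) < 3) abort("need at least 3 paired participants")
  if (anyNA(pre) || anyNA(post)) abort("missing cells are not allowed")
  np <- ncol(pre)
  n2 <- 2^round(log2(np))
  resample <- np != n2
  to_n2 <- function(M) t(apply(M, 1, time_normalize, n_points = n2))
  A <- if (resample) to_n2(pre) else pre
  B <- if (resample) to_n2(post) else post

  W <- dwt_matrix(n2, family)
  CA <- A %*% t(W)
  CB <- B %*% t(W)
  D <- CA - CB
  n <- nrow(D)
  mdiff <- colMeans(D)
  sdiff <- apply(D, 2, sd)
  tstat <- ifelse(sdiff > 0, mdiff / (sdiff / sqrt(n)),
                  ifelse(mdiff != 0, Inf, NaN))
  pval <- ifelse(sdiff > 0, 2 * pt(-abs(mdiff / (sdiff / sqrt(n))), n - 1),
                 ifelse(mdiff != 0, 0, 1))
  if (p_adjust == "holm") pval <- stats::p.adjust(pval, "holm")
  sig <- pval <= alpha

  contrast_w <- ifelse(sig, mdiff, 0)
  contrast <- as.numeric(t(W) %*% contrast_w)
  if (resample) contrast <- time_normalize(contrast, np)
  peak <- max(abs(contrast))
  mask <- if (peak > 0) abs(contrast) >= mask_threshold_frac * peak
          else rep(FALSE, np)

  structure(list(
    contrast = contrast, mask = mask,
    coeff_table = tibble(
      coefficient = attr(W, "labels"), band = attr(W, "band"),
      mean_difference = mdiff, t = tstat, p = pval, significant = sig
    ),
    alpha = alpha, family = family, n = n, n_points = np,
    mask_threshold_frac = mask_threshold_frac, p_adjust = p_adjust,
    sign_convention = "PRE - POST"
  ), class = "functional_ttest")
}

#' @export
print.functional_ttest <- function(x, ...) {
  cat(sprintf(
    "<functional_ttest> n = %d pairs, %d points, %s wavelet; %d/%d coefficients significant (alpha = %.2f)\n",
    x$n, x$n_points, x$family, sum(x$coeff_table$significant),
    nrow(x$coeff_table), x$alpha
  ))
  cat(sprintf("  contrast (%s): peak %.4g; mask covers %d/%d points\n",
              x$sign_convention, max(abs(x$contrast)), sum(x$mask),
              length(x$mask)))
  invisible(x)
}

#' @rdname wavelet_paired_test
#' @param x a `functional_ttest`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.functional_ttest <- function(x, ...) x$coeff_table

#' @rdname wavelet_paired_test
#' @exportS3Method generics::glance
glance.functional_ttest <- function(x, ...) {
  tibble(
    n = x$n, n_points = x$n_points, n_coefficients = nrow(x$coeff_table),
    n_significant = sum(x$coeff_table$significant),
    peak_contrast = max(abs(x$contrast)),
    masked_points = sum(x$mask),
    alpha = x$alpha, family = x$family
  )
}

#' @rdname wavelet_paired_test
#' @param object a `functional_ttest`.
#' @exportS3Method ggplot2::autoplot
autoplot.functional_ttest <- function(object, ...) {
  df <- tibble(
    point = seq_along(object$contrast),
    contrast = object$contrast,
    significant = object$mask
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$point, y = .data$contrast)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_area(
      data = function(d) dplyr::mutate(d, contrast = ifelse(d$significant, d$contrast, 0)),
      fill = "grey80"
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(
      x = "normalized time point",
      y = sprintf("contrast (%s)", object$sign_convention),
      title = sprintf("Wavelet functional paired t-test (%s, alpha = %.2f)",
                      object$family, object$alpha)
    ) +
    ggplot2::theme_minimal()
}
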