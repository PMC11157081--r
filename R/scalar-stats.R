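#' Hedges g_av effect size for paired designs
#'
#' Standardized mean difference using the average of the two condition
#' standard deviations, with small-sample bias correction:
#' d_av = mean(x - y) / ((sd(x) + sd(y)) / 2), g_av = J * d_av with
#' J = 1 - 3 / (4 (n - 1) - 1). Comparison tables conventionally print the
#' magnitude; set `signed = TRUE` for the signed value.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param signed return the signed value instead of the magnitude.
#' @return g_av (scalar); `NA` with a warning when both SDs are zero.
#' @examples
#' hedges_g_av(c(1, 2, 3), c(2, 3, 4), signed = TRUE)  # ~ -0.571
#' @export
hedges_g_av <- function(x, y, signed = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  s <- (sd(x) + sd(y)) / 2
  if (s == 0) {
    warn("zero pooled SD: g_av undefined")
    return(NA_real_)
  }
  J <- 1 - 3 / (4 * (n - 1) - 1)
  g <- J * mean(x - y) / s
  if (signed) g else abs(g)
}

# Wilcoxon signed-rank z statistic (normal approximation with continuity
# correction and tie correction); zero differences dropped beforehand
wilcoxon_z <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(0)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(0)
  (v - mu - 0.5 * sign(v - mu)) / sqrt(sig2)
}

#' Gated paired comparison: t-test or Wilcoxon signed-rank
#'
#' The per-metric comparison used throughout the condition tables: normality
#' of the paired differences is tested with Shapiro-Wilk and equality of
#' variances with Levene's test (median-centered, on the two condition
#' vectors); if both pass at `alpha` a two-tailed paired t-test is used
#' (reporting t and df = n - 1), otherwise a two-tailed Wilcoxon signed-rank
#' test (reporting z; exact distribution for n <= 25 without ties, normal
#' approximation with continuity correction otherwise). Hedges g_av is
#' always reported.
#'
#' Degenerate inputs: all differences exactly zero gives p = 1; differences
#' with zero variance but nonzero mean are an exact effect and reported
#' significant with p = 0; both are flagged.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped
#'   (pairwise-complete), n >= 3 required after dropping.
#' @param alpha gate and test level.
#' @param shapiro_on `"differences"` (default; the quantity whose normality
#'   the paired t assumes) or `"groups"` (minimum p over the two vectors).
#' @return one-row tibble of class `paired_comparison`: `n`, `df`,
#'   `test_used` (`"t"` / `"wilcoxon"`), `statistic` (t), `z`, `p`, `g_av`
#'   (magnitude), `g_av_signed`, `shapiro_p`, `levene_p`, `degenerate`.
#' @export
paired_compare <- function(x, y, alpha = 0.05,
                           shapiro_on = c("differences", "groups")) {
  shapiro_on <- match.arg(shapiro_on)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  d <- x - y

  out <- function(test_used, statistic, z, p, sw, lv, degenerate = "none") {
    g_s <- tryCatch(hedges_g_av(x, y, signed = TRUE),
                    warning = function(w) NA_real_)
    res <- tibble(
      n = n, df = n - 1L, test_used = test_used,
      statistic = statistic, z = z, p = p,
      g_av = abs(g_s), g_av_signed = g_s,
      shapiro_p = sw, levene_p = lv, degenerate = degenerate
    )
    class(res) <- c("paired_comparison", class(res))
    res
  }

  if (all(d == 0)) {
    return(out("t", NA_real_, NA_real_, 1, NA_real_, NA_real_, "all-zero"))
  }
  if (sd(d) == 0) {
    return(out("t", sign(d[1]) * Inf, NA_real_, 0, NA_real_, NA_real_,
               "zero-variance"))
  }

  sw <- if (shapiro_on == "differences") shapiro.test(d)$p.value
        else min(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
  lv <- tryCatch({
    df_l <- data.frame(
      value = c(x, y),
      group = factor(rep(c("x", "y"), each = n))
    )
    car::leveneTest(value ~ group, data = df_l, center = median)[1, "Pr(>F)"]
  }, error = function(e) NA_real_)

  if (!is.na(sw) && sw > alpha && !is.na(lv) && lv > alpha) {
    tt <- t.test(x, y, paired = TRUE)
    out("t", unname(tt$statistic), NA_real_, tt$p.value, sw, lv)
  } else {
    d_nz <- d[d != 0]
    exact <- length(d_nz) <= 25 && !any(duplicated(abs(d_nz)))
    wt <- suppressWarnings(
      wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE)
    )
    out("wilcoxon", NA_real_, wilcoxon_z(d), wt$p.value, sw, lv)
  }
}

#' Condition-comparison battery over a tidy metrics table
#'
#' Runs [paired_compare()] for every metric at every comparison timepoint
#' against PRE, mirroring the standard statistical summary table layout
#' (metric, timepoint, df, t, z, p, effect size).
#'
#' @param metrics tidy tibble with columns `participant`, `timepoint`,
#'   `metric`, `value`; the `"PRE"` timepoint is the reference.
#' @param reference reference timepoint label.
#' @param alpha passed to [paired_compare()].
#' @return tibble, one row per metric x timepoint: `metric`, `timepoint`,
#'   `n`, `df`, `test_used`, `statistic`, `z`, `p`, `g_av`, `significant`.
#' @export
compare_conditions <- function(metrics, reference = "PRE", alpha = 0.05) {
  stopifnot(all(c("participant", "timepoint", "metric", "value") %in%
                  names(metrics)))
  tps <- setdiff(unique(metrics$timepoint), reference)
  combos <- tidyr::expand_grid(metric = unique(metrics$metric),
                               timepoint = tps)
  purrr::pmap_dfr(combos, function(metric, timepoint) {
    wide <- metrics %>%
      filter(.data$metric == .env$metric,
             .data$timepoint %in% c(reference, .env$timepoint)) %>%
      select("participant", "timepoint", "value") %>%
      tidyr::pivot_wider(names_from = "timepoint", values_from = "value")
    if (!all(c(reference, timepoint) %in% names(wide))) return(NULL)
    x <- wide[[reference]]; y <- wide[[timepoint]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      return(tibble(metric = metric, timepoint = timepoint, n = sum(ok),
                    df = NA_integer_, test_used = NA_character_,
                    statistic = NA_real_, z = NA_real_, p = NA_real_,
                    g_av = NA_real_, significant = NA))
    }
    pc <- paired_compare(x, y, alpha = alpha)
    tibble(metric = metric, timepoint = timepoint, n = pc$n, df = pc$df,
           test_used = pc$test_used, statistic = pc$statistic, z = pc$z,
           p = pc$p, g_av = pc$g_av, significant = pc$p <= alpha)
  })
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> n = %d, %s test: %s = %.3f, p = %.4g, g_av = %.3f%s\n",
    x$n, x$test_used,
    if (x$test_used == "t") "t" else "z",
    if (x$test_used == "t") x$statistic else x$z,
    x$p, x$g_av,
    if (x$degenerate != "none") paste0(" [", x$degenerate, "]") else ""
  ))
  invisible(x)
}

#' @rdname paired_compare
#' @param x a `paired_comparison`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.paired_comparison <- function(x, ...) as_tibble(x)

#' @rdname paired_compare
#' @exportS3Method generics::glance
glance.paired_comparison <- function(x, ...) {
  as_tibble(x)[c("n", "test_used", "p", "g_av")]
}
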