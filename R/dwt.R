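# Orthogonal periodized discrete wavelet transform.
#
# Implemented as an explicit orthogonal matrix: at each level the decimated
# circular shifts of the scaling/wavelet filter pair form orthonormal rows,
# and periodization preserves orthonormality at every dyadic length, so the
# full-depth analysis operator W satisfies W %*% t(W) == I and synthesis is
# simply the transpose. Signal lengths here are small (<= 64), where the
# dense-matrix form is both the fastest and the easiest to verify.

# orthonormal scaling (low-pass) filters; sum(h^2) == 1, sum(h) == sqrt(2)
dwt_scaling_filter <- function(family = c("coif3", "db2", "haar")) {
  family <- match.arg(family)
  switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = {
      s <- sqrt(3)
      c(1 + s, 3 + s, 3 - s, 1 - s) / (4 * sqrt(2))
    },
    coif3 = c(
      -3.459977283621256e-05, -7.098330313814125e-05, 4.662169601128863e-04,
      1.117518770891152e-03, -2.574517688750142e-03, -9.007976136662441e-03,
      1.588054486362912e-02, 3.455502757306163e-02, -8.230192710688598e-02,
      -7.179982161931202e-02, 4.284834763776168e-01, 7.937772226256206e-01,
      4.051769024096169e-01, -6.112339000267287e-02, -6.577191128186478e-02,
      2.345269614184190e-02, 7.782596427325418e-03, -3.793512864491014e-03
    )
  )
}

# one analysis level on current length m: rows are h (approx) and g (detail)
# circularly shifted by 2k, with g the quadrature mirror of h
dwt_level_op <- function(m, h) {
  stopifnot(m %% 2 == 0)
  L <- length(h)
  g <- (-1)^(0:(L - 1)) * rev(h)
  A <- matrix(0, m / 2, m)
  D <- matrix(0, m / 2, m)
  for (k in 0:(m / 2 - 1)) {
    for (j in 0:(L - 1)) {
      n <- (2 * k + j) %% m + 1
      A[k + 1, n] <- A[k + 1, n] + h[j + 1]
      D[k + 1, n] <- D[k + 1, n] + g[j + 1]
    }
  }
  rbind(A, D)
}

#' Orthogonal DWT analysis matrix
#'
#' Builds the full-depth (or `level`-deep) periodized discrete wavelet
#' transform of a length-`n` signal as an `n` x `n` orthogonal matrix `W`:
#' coefficients are `W %*% x`, reconstruction is `t(W) %*% coefs`
#' (exact, since `W` is orthogonal). Coefficient order is approximation
#' first, then detail bands coarsest to finest; labels are attached as
#' `attr(W, "labels")` and levels as `attr(W, "band")`.
#'
#' @param n signal length; must be a power of 2 for full depth.
#' @param family wavelet family: `"coif3"` (third-order coiflet, default),
#'   `"db2"`, or `"haar"`.
#' @param level decomposition depth; default maximal (`log2(n)`).
#' @return orthogonal matrix with attributes `labels` and `band`.
#' @export
dwt_matrix <- function(n, family = "coif3", level = NULL) {
  h <- dwt_scaling_filter(family)
  max_level <- 0L
  m <- n
  while (m %% 2 == 0 && m >= 2) { max_level <- max_level + 1L; m <- m / 2 }
  if (is.null(level)) level <- max_level
  stopifnot(level >= 1, level <= max_level)
  W <- diag(n)
  m <- n
  for (l in seq_len(level)) {
    op <- dwt_level_op(m, h)
    full <- diag(n)
    full[1:m, 1:m] <- op
    W <- full %*% W
    m <- m / 2
  }
  napp <- n / 2^level
  # band 0 = approximation; detail band l (1 = finest) has n / 2^l coefficients
  bands <- c(rep(0L, napp), unlist(lapply(seq(level, 1), function(l)
    rep(l, n / 2^l))))
  labels <- c(sprintf("a%d.%d", level, seq_len(napp)),
              unlist(lapply(seq(level, 1), function(l)
                sprintf("d%d.%d", l, seq_len(n / 2^l)))))
  attr(W, "labels") <- labels
  attr(W, "band") <- bands
  attr(W, "family") <- family
  attr(W, "level") <- level
  W
}
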