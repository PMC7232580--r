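# Periodized orthogonal discrete wavelet transform.
#
# Implemented directly (no wavelet package in the stack): at each level the
# signal is circularly filtered with the scaling/wavelet pair and
# downsampled by two, so a length-2^J input yields exactly 2^J coefficients
# at any level up to J and the transform is orthonormal (Parseval holds and
# the inverse is exact).

wavelet_filters <- function(family) {
  h <- switch(family,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.23037781330885523, 0.71484657055254153,
            0.63088076792959036, -0.02798376941698385,
            -0.18703481171888114, 0.03084138183598697,
            0.03288301166698295, -0.01059740178499728),
    rlang::abort(sprintf(
      "unknown wavelet family '%s' (available: haar, db2, db4)", family))
  )
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror
  list(h = h, g = g, L = L)
}

dwt_step <- function(x, flt) {
  n <- length(x)
  half <- n / 2
  idx <- outer(2 * (seq_len(half) - 1), seq_len(flt$L) - 1, `+`) %% n + 1
  xm <- matrix(x[idx], nrow = half)
  list(a = drop(xm %*% flt$h), d = drop(xm %*% flt$g))
}

idwt_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2 * half
  x <- numeric(n)
  # accumulate per tap: for fixed m the target positions are distinct,
  # which keeps the scatter-add correct even when n < filter length
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_len(flt$L)) {
    pos <- (base + m - 1) %% n + 1
    x[pos] <- x[pos] + flt$h[m] * a + flt$g[m] * d
  }
  x
}

#' Periodized discrete wavelet transform
#'
#' Decomposes a dyadic-length signal into approximation and detail
#' coefficients over `level` scales using circular (periodized) boundary
#' handling, so the total coefficient count always equals the input length.
#'
#' @param x Numeric vector; length must be a power of two.
#' @param level Decomposition depth; at most `log2(length(x))`.
#' @param family Wavelet family: `"haar"`, `"db2"` or `"db4"` (default).
#' @return A list of class `ecg_dwt` with elements `approx` (coarsest
#'   approximation), `details` (list, coarsest first), `level`, `family`.
#' @examples
#' w <- dwt_periodized(sin(seq_len(256) / 8), level = 6)
#' sum(lengths(w$details)) + length(w$approx)  # 256
#' @export
dwt_periodized <- function(x, level, family = "db4") {
  n <- length(x)
  if (n < 2 || bitwAnd(n, n - 1L) != 0) {
    rlang::abort("input length must be a power of two >= 2")
  }
  maxlev <- as.integer(log2(n))
  if (level < 1 || level > maxlev) {
    rlang::abort(sprintf(
      "level must be in 1..%d for a %d-point input", maxlev, n))
  }
  flt <- wavelet_filters(family)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step(a, flt)
    a <- st$a
    details[[level - j + 1]] <- st$d  # store coarsest first
  }
  structure(list(approx = a, details = details, level = level,
                 family = family), class = "ecg_dwt")
}

#' Inverse periodized discrete wavelet transform
#'
#' @param w An `ecg_dwt` object from [dwt_periodized()].
#' @return The reconstructed signal (exact up to floating-point error).
#' @export
idwt_periodized <- function(w) {
  flt <- wavelet_filters(w$family)
  a <- w$approx
  for (j in seq_len(w$level)) {
    a <- idwt_step(a, w$details[[j]], flt)
  }
  a
}

#' Flatten DWT coefficients into one vector
#'
#' Order: approximation at the coarsest level, then details from coarsest to
#' finest. The length always equals the input length.
#'
#' @param w An `ecg_dwt` object.
#' @return Numeric coefficient vector.
#' @export
dwt_coefficients <- function(w) {
  c(w$approx, unlist(w$details, use.names = FALSE))
}
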