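# Shared fixtures and independent oracles used across test files.

# -- independent RBP oracle: literal triple-loop over the definition -------
rbp_oracle <- function(x, m) {
  n <- length(x)
  bits <- integer(n - 1)
  for (i in seq_len(n - 1)) bits[i] <- if (x[i + 1] > x[i]) 1L else 0L
  words <- integer(length(bits) - m + 1)
  for (k in seq_along(words)) {
    w <- 0L
    for (j in 0:(m - 1)) w <- w * 2L + bits[k + j]
    words[k] <- w
  }
  freq <- numeric(2^m)
  for (w in words) freq[w + 1] <- freq[w + 1] + 1
  freq / length(words)
}

# -- exhaustive k-means oracle: minimum E over all assignments -------------
kmeans_bruteforce <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  assign <- rep(1L, n)
  repeat {
    if (length(unique(assign)) == k) {
      e <- 0
      for (j in unique(assign)) {
        m <- assign == j
        ctr <- colMeans(x[m, , drop = FALSE])
        e <- e + sum((x[m, , drop = FALSE] -
                        matrix(ctr, sum(m), ncol(x), byrow = TRUE))^2)
      }
      if (e < best) best <- e
    }
    # next assignment vector in base-k counting
    i <- n
    while (i >= 1) {
      if (assign[i] < k) { assign[i] <- assign[i] + 1L; break }
      assign[i] <- 1L; i <- i - 1
    }
    if (i == 0) break
  }
  best
}

# -- discrete Fourier magnitude argmax (frequency of the dominant peak) ----
dominant_freq <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  sp[1] <- 0  # ignore DC
  (which.max(sp) - 1) * fs / n
}

# -- shared small cohort (built once per test run) -------------------------
.test_env <- new.env()
std_cohort <- function() {
  if (is.null(.test_env$coh)) {
    .test_env$coh <- suppressWarnings(
      generate_cohort(cohort_config(n = 12, fs = 500, duration = 8, seed = 11)))
  }
  .test_env$coh
}

# match detected peak indices to true times (s); tolerance in seconds
match_peaks <- function(detected, true_s, fs, tol_s = 0.05) {
  det_s <- (detected - 1) / fs
  matched_true <- vapply(true_s, function(tt) any(abs(det_s - tt) <= tol_s),
                         logical(1))
  matched_det <- vapply(det_s, function(dd) any(abs(true_s - dd) <= tol_s),
                        logical(1))
  list(sensitivity = mean(matched_true), ppv = mean(matched_det))
}
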