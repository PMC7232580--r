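# Reduced binary pattern (RBP) features: consecutive-sample
# increase/decrease bits, sliding m-bit words, word relative frequencies.

#' Binarize a signal by consecutive-sample comparison
#'
#' Bit i is 1 when sample i+1 exceeds sample i, else 0 (ties count as a
#' decrease). A length-N signal yields N-1 bits. The result depends only on
#' the sign of the differences, so it is invariant to positive rescaling and
#' offsets.
#'
#' @param signal An [ecg_signal()] or numeric vector of length >= 2.
#' @return Integer vector of 0/1 bits, length N-1.
#' @examples
#' binarize(c(1, 2, 3, 2))  # 1 1 0
#' @export
binarize <- function(signal) {
  x <- if (inherits(signal, "ecg_signal")) signal$samples else as.numeric(signal)
  if (length(x) < 2) rlang::abort("need at least 2 samples to binarize")
  as.integer(diff(x) > 0)
}

#' Collect sliding m-bit words from a bit sequence
#'
#' Stride-1 windows of `m` consecutive bits, each converted to its decimal
#' value with the first (earliest) bit most significant. A bit sequence of
#' length L yields L - m + 1 words.
#'
#' @param bits Integer 0/1 vector.
#' @param m Word length in bits, 1..16.
#' @return Integer vector of words in `[0, 2^m - 1]`.
#' @examples
#' to_words(c(1, 0, 1), m = 2)  # 2 1
#' @export
to_words <- function(bits, m) {
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) rlang::abort("`bits` must be 0/1")
  if (m < 1 || m > 16) rlang::abort("m must be in 1..16")
  if (m > length(bits)) {
    rlang::abort(sprintf("m = %d exceeds bit-sequence length %d", m, length(bits)))
  }
  if (m == 1) return(bits)
  # embed() rows are reversed windows: [y_{k+m-1}, ..., y_k]
  win <- stats::embed(bits, m)
  pw <- 2^(0:(m - 1))  # embed column j holds bit y_{k+m-j}, weight 2^(j-1)
  as.integer(win %*% pw)
}

#' Relative-frequency histogram of RBP words
#'
#' Bin t (t = 0..2^m - 1) holds the fraction of words equal to t; the
#' vector has exactly 2^m entries and sums to one.
#'
#' @param words Integer word vector from [to_words()].
#' @param m Word length used to build the words.
#' @return Numeric vector of length `2^m` (named by word value), class
#'   `rbp_histogram` with attribute `m`.
#' @export
rbp_histogram <- function(words, m) {
  if (!length(words)) rlang::abort("empty word sequence")
  if (any(words < 0 | words >= 2^m)) {
    rlang::abort(sprintf("words out of range for m = %d", m))
  }
  counts <- tabulate(words + 1L, nbins = 2^m)
  freq <- counts / length(words)
  names(freq) <- 0:(2^m - 1)
  structure(freq, m = m, class = "rbp_histogram")
}

#' Full RBP feature vector of one signal
#'
#' Convenience composition of [binarize()], [to_words()] and
#' [rbp_histogram()].
#'
#' @param signal An [ecg_signal()] or numeric vector.
#' @param m Word length (bits); default 8 gives a 256-dimensional feature.
#' @return An `rbp_histogram` of length `2^m`.
#' @export
rbp_feature <- function(signal, m = 8) {
  rbp_histogram(to_words(binarize(signal), m), m)
}

#' RBP features for a cohort
#'
#' Computes the RBP relative-frequency vector per subject on the (optionally
#' denoised) full record.
#'
#' @param cohort Cohort tibble with `id` and `signal` columns.
#' @param m Word length (bits).
#' @param denoise_first Band-pass each record with [denoise()] first.
#' @param spec [filter_spec()] used when `denoise_first` is `TRUE`.
#' @return A tibble: `id` plus `2^m` columns `rbp_0 ... rbp_<2^m - 1>`.
#' @export
rbp_features <- function(cohort, m = 8, denoise_first = TRUE,
                         spec = filter_spec()) {
  feats <- lapply(cohort$signal, function(sig) {
    if (denoise_first) sig <- denoise(sig, spec)
    as.numeric(rbp_feature(sig, m))
  })
  mat <- do.call(rbind, feats)
  colnames(mat) <- paste0("rbp_", 0:(2^m - 1))
  dplyr::bind_cols(tibble::tibble(id = cohort$id), tibble::as_tibble(mat))
}
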