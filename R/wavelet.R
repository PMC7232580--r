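# Wavelet features: R-R cycles resampled to 256-point segments (first 169 +
# last 85 samples, edge-padded by 2), grouped by four, each segment
# decomposed by a periodized DWT, and the four coefficient vectors
# concatenated into one group vector.

SEG_HEAD <- 169L
SEG_TAIL <- 85L
SEG_LEN <- 256L

#' Build 256-point segments from R-R cycles
#'
#' Each R-R cycle (the span from one R peak to the next, taken from the
#' leading cycle of each segmented beat) contributes its first 169 and last
#' 85 samples; the 254 values are padded to 256 by repeating the final value
#' twice (edge replication; `strict_254 = TRUE` keeps the raw 254 instead).
#' Cycles shorter than 254 samples are skipped; the number skipped is
#' attached as attribute `n_skipped`.
#'
#' @param beats Beats tibble from [segment_beats()].
#' @param strict_254 Skip the 2-sample padding and emit 254-point segments.
#' @return A list of numeric segments (attribute `n_skipped`).
#' @export
build_segments <- function(beats, strict_254 = FALSE) {
  cycles <- lapply(seq_len(nrow(beats)), function(i) {
    beats$beat[[i]][seq_len(beats$rr_prev[i])]
  })
  min_len <- SEG_HEAD + SEG_TAIL
  ok <- vapply(cycles, function(cy) length(cy) >= min_len, logical(1))
  n_skip <- sum(!ok)
  if (!any(ok)) {
    rlang::warn("all R-R cycles shorter than 254 samples; no segments")
    return(structure(list(), n_skipped = n_skip))
  }
  segs <- lapply(cycles[ok], function(cy) {
    n <- length(cy)
    seg <- c(cy[seq_len(SEG_HEAD)], cy[(n - SEG_TAIL + 1):n])
    if (!strict_254) seg <- c(seg, rep(seg[length(seg)], SEG_LEN - min_len))
    seg
  })
  structure(segs, n_skipped = n_skip)
}

#' Wavelet vector of one group of four segments
#'
#' Decomposes each of the four 256-point segments with an n-level
#' periodized DWT and concatenates the four coefficient vectors.
#'
#' @param group List of exactly 4 segments of 256 samples each.
#' @param n Decomposition level (1..8 for 256-point segments).
#' @param family Wavelet family (`"haar"`, `"db2"`, `"db4"`).
#' @return Numeric vector of length 4 * 256 with attributes `level`,
#'   `family` and `subband_lengths`.
#' @export
dwt_features <- function(group, n = 6, family = "db4") {
  if (length(group) != 4) rlang::abort("a segment group holds exactly 4 segments")
  if (!all(lengths(group) == SEG_LEN)) {
    rlang::abort(sprintf("all segments must have %d samples", SEG_LEN))
  }
  maxlev <- as.integer(log2(SEG_LEN))
  if (n < 1 || n > maxlev) {
    rlang::abort(sprintf("level n must be in 1..%d for %d-point segments",
                         maxlev, SEG_LEN))
  }
  ws <- lapply(group, dwt_periodized, level = n, family = family)
  vec <- unlist(lapply(ws, dwt_coefficients), use.names = FALSE)
  structure(vec, level = n, family = family,
            subband_lengths = c(approx = length(ws[[1]]$approx),
                                stats::setNames(lengths(ws[[1]]$details),
                                                paste0("d", n:1))))
}

#' Subject-level wavelet feature vector
#'
#' Segments the record at its R peaks, forms consecutive groups of four
#' 256-point segments, computes each group's wavelet vector and averages
#' them. Subjects with fewer than four usable segments are unusable
#' (`NULL` with a warning).
#'
#' @param signal An [ecg_signal()].
#' @param peaks R-peak indices from [detect_qrs()].
#' @param n Decomposition level.
#' @param family Wavelet family.
#' @return Numeric vector of length 1024, or `NULL` if unusable.
#' @export
subject_wavelet_feature <- function(signal, peaks, n = 6, family = "db4") {
  beats <- segment_beats(signal, peaks)
  if (!nrow(beats)) return(NULL)
  segs <- build_segments(beats)
  if (length(segs) < 4) {
    rlang::warn(sprintf("subject %s: only %d usable segments (need 4); excluded",
                        signal$id, length(segs)))
    return(NULL)
  }
  n_groups <- length(segs) %/% 4
  vecs <- lapply(seq_len(n_groups), function(g) {
    as.numeric(dwt_features(segs[(4 * g - 3):(4 * g)], n = n, family = family))
  })
  Reduce(`+`, vecs) / n_groups
}

#' Wavelet features for a cohort
#'
#' @param cohort Cohort tibble with `id` and `signal` columns.
#' @param n Decomposition level.
#' @param family Wavelet family.
#' @param denoise_first Band-pass each record with [denoise()] first.
#' @param spec [filter_spec()] for denoising.
#' @param ... Arguments forwarded to [detect_qrs()].
#' @return A tibble: `id` plus columns `wav_1 ... wav_1024`. Unusable
#'   subjects are omitted.
#' @export
wavelet_features <- function(cohort, n = 6, family = "db4",
                             denoise_first = TRUE, spec = filter_spec(), ...) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    sig <- cohort$signal[[i]]
    if (denoise_first) sig <- denoise(sig, spec)
    pk <- detect_qrs(sig, ...)
    v <- subject_wavelet_feature(sig, pk, n = n, family = family)
    if (is.null(v)) return(NULL)
    c(id = cohort$id[i], v)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) rlang::abort("no usable subjects for wavelet features")
  mat <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  colnames(mat) <- paste0("wav_", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(id = vapply(rows, `[[`, character(1), "id")),
    tibble::as_tibble(mat))
}
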