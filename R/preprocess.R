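# Signal preprocessing: band-pass denoising, derivative-based QRS detection
# with amplitude-floor and refractory suppression, and R-R beat
# segmentation.

#' Denoising filter specification
#'
#' @param low,high Band-pass cutoffs (Hz), `0 < low < high < fs/2`.
#' @param notch Optional mains notch frequency (Hz); `NULL` disables.
#' @param order FIR order; default `round(4 * fs / low)` at apply time.
#' @param shrinkage Apply wavelet soft-threshold shrinkage after filtering.
#' @param shrink_family,shrink_level Wavelet family/level for shrinkage.
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.5, high = 40, notch = NULL, order = NULL,
                        shrinkage = FALSE, shrink_family = "db4",
                        shrink_level = 4) {
  if (low <= 0 || high <= low) rlang::abort("need 0 < low < high")
  structure(list(low = low, high = high, notch = notch, order = order,
                 shrinkage = shrinkage, shrink_family = shrink_family,
                 shrink_level = shrink_level),
            class = "filter_spec")
}

#' Denoise an ECG signal
#'
#' Zero-phase linear-phase FIR band-pass (removing baseline wander below the
#' low edge and EMG/white noise above the high edge), optional narrow mains
#' notch, and optional wavelet soft-threshold shrinkage. Length and sampling
#' rate are preserved.
#'
#' @param signal An [ecg_signal()].
#' @param spec A [filter_spec()].
#' @return The denoised [ecg_signal()].
#' @export
denoise <- function(signal, spec = filter_spec()) {
  assert_signal(signal)
  if (!inherits(spec, "filter_spec")) rlang::abort("`spec` must be a <filter_spec>")
  fs <- signal$fs
  if (spec$high >= fs / 2) {
    rlang::abort(sprintf("high cutoff %g Hz is at or above Nyquist (%g Hz)",
                         spec$high, fs / 2))
  }
  h <- fir_design(fs, spec$low, spec$high, order = spec$order)
  x <- fir_apply(signal$samples, h)
  if (!is.null(spec$notch)) {
    # narrow band-stop built as identity minus a narrow band-pass
    bw <- 2
    hb <- fir_design(fs, spec$notch - bw / 2, spec$notch + bw / 2,
                     order = round(6 * fs / bw))
    x <- x - fir_apply(x, hb)
  }
  if (isTRUE(spec$shrinkage)) {
    x <- wavelet_shrink(x, spec$shrink_family, spec$shrink_level)
  }
  out <- ecg_signal(x, fs = fs, lead = signal$lead, id = signal$id)
  attr(out, "r_times_s") <- attr(signal, "r_times_s")
  out
}

# soft-threshold wavelet shrinkage on power-of-two chunks (universal
# threshold from the finest-detail MAD noise estimate)
wavelet_shrink <- function(x, family, level) {
  n <- length(x)
  n2 <- 2^floor(log2(n))
  head_x <- x[seq_len(n2)]
  w <- dwt_periodized(head_x, level = min(level, as.integer(log2(n2))),
                      family = family)
  fine <- w$details[[length(w$details)]]
  sigma <- stats::median(abs(fine)) / 0.6745
  thr <- sigma * sqrt(2 * log(n2))
  w$details <- lapply(w$details, function(d) sign(d) * pmax(abs(d) - thr, 0))
  y <- idwt_periodized(w)
  c(y, x[seq_len(n - n2) + n2])
}

#' Detect QRS complexes (R peaks)
#'
#' Candidates are positive-to-negative zero crossings of the first-order
#' derivative of a QRS-band (matched-band) filtered copy of the signal. Two
#' non-linear suppressions are then applied: candidates below
#' `min_amplitude_fraction` of a running median of accepted peak amplitudes
#' are discarded (low-amplitude noise), and any candidate within
#' `refractory_ms` of an accepted peak is discarded. Accepted peaks are
#' refined to the local maximum of the input signal.
#'
#' @param signal An [ecg_signal()], ideally denoised or band-limited.
#' @param refractory_ms Minimum spacing between accepted peaks (ms).
#' @param min_amplitude_fraction Amplitude floor as a fraction of the
#'   running median of accepted peak amplitudes.
#' @param qrs_band Pass band (Hz) of the internal QRS-emphasis filter.
#' @return An integer vector of R-peak sample indices (class `rpeak_list`
#'   with attribute `fs`), strictly increasing, pairwise gaps >= refractory.
#' @export
detect_qrs <- function(signal, refractory_ms = 200,
                       min_amplitude_fraction = 0.3,
                       qrs_band = c(5, 25)) {
  assert_signal(signal)
  fs <- signal$fs
  n <- length(signal$samples)
  refr <- round(refractory_ms / 1000 * fs)
  if (n < refr || n < fs) {
    rlang::warn("signal shorter than one refractory interval; no peaks")
    return(structure(integer(0), class = "rpeak_list", fs = fs))
  }
  hi <- min(qrs_band[2], 0.45 * fs)
  h <- fir_design(fs, qrs_band[1], hi, order = round(2 * fs / qrs_band[1]))
  det <- fir_apply(signal$samples, h)
  # derivative zero crossings + -> - at local maxima of the detection signal
  d <- diff(det)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[det[cand] > 0]
  if (!length(cand)) return(structure(integer(0), class = "rpeak_list", fs = fs))
  # initial amplitude estimate: median of per-2s block maxima
  blk <- ceiling(seq_along(det) / (2 * fs))
  amp_est <- stats::median(tapply(det, blk, max))
  accepted <- integer(0)
  acc_amp <- numeric(0)
  last <- -Inf
  for (i in cand) {
    a <- det[i]
    if (a < min_amplitude_fraction * amp_est) next
    if (i - last < refr) next
    accepted <- c(accepted, i)
    acc_amp <- c(acc_amp, a)
    last <- i
    k <- length(acc_amp)
    amp_est <- stats::median(acc_amp[max(1, k - 7):k])
  }
  # refine to the raw-signal local maximum near each detection
  half <- as.integer(round(0.04 * fs))
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi2 <- min(n, i + half)
    as.integer(lo + which.max(signal$samples[lo:hi2]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement could in principle collapse spacing; re-enforce refractory
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) >= refr)
    peaks <- peaks[keep]
  }
  structure(as.integer(peaks), class = "rpeak_list", fs = fs)
}

#' Segment a signal into R-R beats
#'
#' One beat per interior R peak: the window runs from the previous R peak up
#' to (but excluding) the next R peak, so consecutive beats tile the span
#' between the first and last peak. The first and last peaks have no
#' complete cycle and are dropped.
#'
#' @param signal An [ecg_signal()].
#' @param peaks An `rpeak_list` from [detect_qrs()] (or an integer vector of
#'   R indices).
#' @return A tibble with one row per beat: `beat` (list of sample vectors),
#'   `r_index` (R position within the window), `start_index` (window start
#'   in the full signal), `rr_prev`, `rr_next` (samples).
#' @export
segment_beats <- function(signal, peaks) {
  assert_signal(signal)
  peaks <- as.integer(peaks)
  if (length(peaks) < 3) {
    if (length(peaks) < 2) rlang::warn("fewer than 2 peaks; no beats")
    return(tibble::tibble(beat = list(), r_index = integer(),
                          start_index = integer(), rr_prev = integer(),
                          rr_next = integer()))
  }
  k <- length(peaks)
  idx <- 2:(k - 1)
  tibble::tibble(
    beat = lapply(idx, function(j) {
      signal$samples[peaks[j - 1]:(peaks[j + 1] - 1L)]
    }),
    r_index = vapply(idx, function(j) peaks[j] - peaks[j - 1] + 1L, integer(1)),
    start_index = peaks[idx - 1],
    rr_prev = vapply(idx, function(j) peaks[j] - peaks[j - 1], integer(1)),
    rr_next = vapply(idx, function(j) peaks[j + 1] - peaks[j], integer(1))
  )
}
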