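# FIR filter design and zero-phase application.
#
# No DSP package ships in this stack, so the windowed-sinc design and the
# FFT-based zero-phase convolution are implemented here. The filters are
# symmetric (linear phase); applying one pass and discarding the exact group
# delay gives a zero-phase result with the designed magnitude response.

# normalized sinc: sin(pi x)/(pi x), sinc(0) = 1
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Design a windowed-sinc FIR filter
#'
#' Hamming-windowed ideal band-pass (or low-/high-pass when one edge is
#' open). Taps are symmetric, so the filter has exactly linear phase.
#'
#' @param fs Sampling rate (Hz).
#' @param low Lower cutoff (Hz); `0` or `NULL` for a low-pass.
#' @param high Upper cutoff (Hz); `NULL` or `>= fs/2` for a high-pass.
#' @param order Filter order (number of taps minus one). Forced even so the
#'   tap count is odd and the delay is an integer. Default scales with
#'   `fs / low` so the transition band resolves the low edge.
#' @return Numeric vector of filter taps (odd length, symmetric).
#' @keywords internal
#' @export
fir_design <- function(fs, low = NULL, high = NULL, order = NULL) {
  nyq <- fs / 2
  lo <- if (is.null(low)) 0 else low
  hi <- if (is.null(high)) nyq else high
  if (lo < 0 || hi <= lo) rlang::abort("need 0 <= low < high")
  if (hi > nyq) rlang::abort(sprintf(
    "upper cutoff %g Hz is at or above Nyquist (%g Hz)", hi, nyq))
  if (is.null(order)) {
    base <- if (lo > 0) lo else hi
    order <- round(4 * fs / base)
  }
  order <- max(10, 2 * ceiling(order / 2))  # even order, odd tap count
  m <- order / 2
  n <- seq(-m, m)
  f1 <- lo / fs  # cycles per sample
  f2 <- hi / fs
  h <- 2 * f2 * sinc(2 * f2 * n) - 2 * f1 * sinc(2 * f1 * n)
  w <- 0.54 + 0.46 * cos(pi * n / m)  # Hamming
  h <- h * w
  # normalize passband gain to 1 at band centre (geometric mean frequency)
  fc <- if (f1 > 0) sqrt(f1 * f2) else 0
  gain <- sum(h * cos(2 * pi * fc * n))
  h / gain
}

#' Apply a symmetric FIR filter with zero phase
#'
#' Forward-backward application (the filter is convolved with itself, so the
#' magnitude response is squared and the phase is exactly zero), via FFT
#' with odd-reflection padding at both ends; the output is aligned with and
#' the same length as the input.
#'
#' @param x Numeric signal.
#' @param h Symmetric FIR taps of odd length.
#' @return Filtered signal, `length(x)` samples.
#' @keywords internal
#' @export
fir_apply <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (L %% 2 != 1) rlang::abort("filter length must be odd")
  pad <- min(n - 1, L)
  # reflect about the end points to limit edge transients
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  m <- length(xp)
  nfft <- stats::nextn(m + 2 * L - 2, 2)
  X <- stats::fft(c(xp, numeric(nfft - m)))
  H <- stats::fft(c(h, numeric(nfft - L)))
  # forward-backward: |H|^2, guaranteed real and zero-phase
  y <- Re(stats::fft(X * H * Conj(H), inverse = TRUE)) / nfft
  y[(pad + 1):(pad + n)]
}

#' Frequency response magnitude of an FIR filter
#'
#' @param h Filter taps.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate (Hz).
#' @return Magnitude response |H(f)| at each frequency.
#' @keywords internal
#' @export
fir_response <- function(h, f, fs) {
  L <- length(h)
  n <- seq_len(L) - 1
  vapply(f, function(fi) {
    Mod(sum(h * exp(-2i * pi * fi / fs * n)))
  }, numeric(1))
}
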