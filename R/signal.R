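#' ECG signal container
#'
#' A lightweight container for a single-lead sampled voltage trace. Samples
#' are in millivolts, the sampling rate in Hz, and all sample indexing in the
#' package is 1-based (R convention) with times in seconds.
#'
#' @param samples Numeric vector of voltages (mV), length >= 2, no missing
#'   values.
#' @param fs Sampling rate in Hz (> 0).
#' @param lead Lead label, e.g. `"I"` or `"synthetic"`.
#' @param id Subject identifier.
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs`, `lead` and `id`.
#' @examples
#' sig <- ecg_signal(sin(seq(0, 2 * pi, length.out = 500)), fs = 250)
#' sig
#' @export
ecg_signal <- function(samples, fs, lead = "synthetic", id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    rlang::abort("`samples` must contain at least 2 values.")
  }
  if (anyNA(samples)) {
    rlang::abort("`samples` must not contain missing values.")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    rlang::abort("`fs` must be a single positive number (Hz).")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         lead = as.character(lead), id = as.character(id)),
    class = "ecg_signal"
  )
}

#' @export
print.ecg_signal <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_signal> id=%s lead=%s fs=%g Hz n=%d (%.2f s)\n",
              x$id, x$lead, x$fs, length(x$samples), dur))
  cat(sprintf("  range [%.3f, %.3f] mV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Convert an ECG signal to a tibble
#'
#' @param x An [ecg_signal()].
#' @param ... Unused.
#' @return A tibble with columns `time_s` and `voltage_mv`.
#' @method as_tibble ecg_signal
#' @export
as_tibble.ecg_signal <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$fs,
    voltage_mv = x$samples
  )
}

#' Plot an ECG signal trace
#'
#' @param object An [ecg_signal()].
#' @param max_seconds Plot at most this many seconds from the start.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecg_signal
#' @export
autoplot.ecg_signal <- function(object, max_seconds = 10, ...) {
  df <- as_tibble.ecg_signal(object)
  df <- df[df$time_s <= max_seconds, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$voltage_mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)",
                  title = sprintf("ECG %s, lead %s", object$id, object$lead))
}

# internal: check an object is an ecg_signal
assert_signal <- function(x, arg = "signal") {
  if (!inherits(x, "ecg_signal")) {
    rlang::abort(sprintf("`%s` must be an <ecg_signal>.", arg))
  }
  invisible(x)
}
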