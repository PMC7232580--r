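# Waveform (fiducial) features: locate P, Q, R, S, T within each beat and
# derive the 24-element descriptor — 5 positions, 10 amplitude differences,
# 5 durations, 3 slopes, and the QRS triangle area.

#' Names of the 24 waveform features, in their fixed order
#' @return Character vector of length 24.
#' @export
waveform_feature_names <- function() {
  c(paste0("pos_", c("P", "Q", "R", "S", "T")),
    paste0("amp_", c("PQ", "RQ", "TQ", "RT", "PS", "RP", "TS", "RS", "PT", "QS")),
    paste0("dur_", c("QS", "PR", "QR", "ST", "QT")),
    paste0("slope_", c("RS", "ST", "QR")),
    "area_QRS")
}

#' Locate fiducial points within one beat
#'
#' Standard physiological search windows around the known R apex: Q is the
#' minimum in (R-80 ms, R); S the minimum in (R, R+80 ms); P the maximum in
#' (R-300 ms, R-80 ms); T the extremum of |signal - baseline| in
#' (S+80 ms, S+400 ms). Windows are truncated at the beat edges; a window
#' that truncates to nothing flags the beat unusable (`NULL`).
#'
#' @param beat Numeric sample window containing the beat.
#' @param r_index Index of the R peak within `beat`.
#' @param fs Sampling rate (Hz).
#' @param windows_ms Named list overriding the search windows
#'   (`q = 80, s = 80, p = c(300, 80), t = c(80, 400)`).
#' @return A tibble with columns `point`, `index`, `time_ms` (R-relative)
#'   and `amp_mv`, or `NULL` if the beat is unusable.
#' @export
locate_fiducials <- function(beat, r_index, fs,
                             windows_ms = list(q = 80, s = 80,
                                               p = c(300, 80), t = c(80, 400))) {
  n <- length(beat)
  if (r_index < 1 || r_index > n) rlang::abort("r_index outside beat window")
  ms <- function(x) round(x / 1000 * fs)
  win <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (lo > hi) return(NULL)
    lo:hi
  }
  q_w <- win(r_index - ms(windows_ms$q), r_index - 1L)
  s_w <- win(r_index + 1L, r_index + ms(windows_ms$s))
  p_w <- win(r_index - ms(windows_ms$p[1]), r_index - ms(windows_ms$p[2]))
  if (is.null(q_w) || is.null(s_w) || is.null(p_w)) return(NULL)
  q_i <- q_w[which.min(beat[q_w])]
  s_i <- s_w[which.min(beat[s_w])]
  p_i <- p_w[which.max(beat[p_w])]
  baseline <- stats::median(beat)
  t_w <- win(s_i + ms(windows_ms$t[1]), s_i + ms(windows_ms$t[2]))
  if (is.null(t_w)) return(NULL)
  t_i <- t_w[which.max(abs(beat[t_w] - baseline))]
  idx <- c(P = p_i, Q = q_i, R = r_index, S = s_i, T = t_i)
  if (is.unsorted(idx, strictly = TRUE)) return(NULL)
  tibble::tibble(
    point = names(idx),
    index = as.integer(idx),
    time_ms = (as.integer(idx) - r_index) / fs * 1000,
    amp_mv = beat[idx]
  )
}

#' The 24 waveform features of one beat
#'
#' Positions are R-relative times (ms); amplitude features are signed
#' differences amp(X) - amp(Y) in mV; durations are |t(X) - t(Y)| in ms;
#' slopes are amplitude difference over signed time difference (mV/ms);
#' the area is the shoelace area of the Q-R-S triangle in mV*ms.
#'
#' @param points Fiducial tibble from [locate_fiducials()].
#' @return Named numeric vector of length 24 (order of
#'   [waveform_feature_names()]), or `NULL` when fiducial times coincide.
#' @export
extract_waveform_features <- function(points) {
  t <- stats::setNames(points$time_ms, points$point)
  a <- stats::setNames(points$amp_mv, points$point)
  pair <- function(s) c(substr(s, 1, 1), substr(s, 2, 2))
  amp_pairs <- c("PQ", "RQ", "TQ", "RT", "PS", "RP", "TS", "RS", "PT", "QS")
  dur_pairs <- c("QS", "PR", "QR", "ST", "QT")
  slope_pairs <- c("RS", "ST", "QR")
  for (s in slope_pairs) {
    xy <- pair(s)
    if (t[xy[1]] == t[xy[2]]) return(NULL)  # coincident fiducials
  }
  amps <- vapply(amp_pairs, function(s) {
    xy <- pair(s); a[[xy[1]]] - a[[xy[2]]]
  }, numeric(1))
  durs <- vapply(dur_pairs, function(s) {
    xy <- pair(s); abs(t[[xy[1]]] - t[[xy[2]]])
  }, numeric(1))
  slopes <- vapply(slope_pairs, function(s) {
    xy <- pair(s); (a[[xy[1]]] - a[[xy[2]]]) / (t[[xy[1]]] - t[[xy[2]]])
  }, numeric(1))
  area <- 0.5 * abs(
    t[["Q"]] * (a[["R"]] - a[["S"]]) +
    t[["R"]] * (a[["S"]] - a[["Q"]]) +
    t[["S"]] * (a[["Q"]] - a[["R"]]))
  out <- c(t[c("P", "Q", "R", "S", "T")], amps, durs, slopes, area)
  names(out) <- waveform_feature_names()
  out
}

#' Subject-level waveform feature vector
#'
#' Locates fiducials and extracts the 24 features for every segmented beat,
#' then aggregates by the element-wise median (robust to occasional
#' mis-delineation).
#'
#' @param signal An [ecg_signal()].
#' @param peaks R-peak indices from [detect_qrs()].
#' @param windows_ms Search windows, see [locate_fiducials()].
#' @return Named numeric vector of length 24, or `NULL` if no beat is
#'   usable.
#' @export
subject_waveform_feature <- function(signal, peaks,
                                     windows_ms = list(q = 80, s = 80,
                                                       p = c(300, 80),
                                                       t = c(80, 400))) {
  beats <- segment_beats(signal, peaks)
  if (!nrow(beats)) return(NULL)
  rows <- lapply(seq_len(nrow(beats)), function(i) {
    fp <- locate_fiducials(beats$beat[[i]], beats$r_index[i], signal$fs,
                           windows_ms = windows_ms)
    if (is.null(fp)) return(NULL)
    extract_waveform_features(fp)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    rlang::warn(sprintf("subject %s: no usable beats; excluded", signal$id))
    return(NULL)
  }
  apply(do.call(rbind, rows), 2, stats::median)
}

#' Waveform features for a cohort
#'
#' @param cohort Cohort tibble with `id` and `signal` columns.
#' @param denoise_first Band-pass each record with [denoise()] first.
#' @param spec [filter_spec()] for denoising.
#' @param ... Arguments forwarded to [detect_qrs()].
#' @return A tibble: `id` plus the 24 named feature columns. Unusable
#'   subjects are omitted.
#' @export
waveform_features <- function(cohort, denoise_first = TRUE,
                              spec = filter_spec(), ...) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    sig <- cohort$signal[[i]]
    if (denoise_first) sig <- denoise(sig, spec)
    pk <- detect_qrs(sig, ...)
    subject_waveform_feature(sig, pk)
  })
  ok <- !vapply(rows, is.null, logical(1))
  if (!any(ok)) rlang::abort("no usable subjects for waveform features")
  mat <- do.call(rbind, rows[ok])
  dplyr::bind_cols(tibble::tibble(id = cohort$id[ok]), tibble::as_tibble(mat))
}
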