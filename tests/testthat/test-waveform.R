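test_that("fiducials land near the generating Gaussian centers", {
  prof <- subject_profile("f", hr_bpm = 60, rr_sd_ms = 0)
  sig <- generate_clean_ecg(prof, fs = 1000, duration = 10, seed = 13)
  pk <- detect_qrs(sig)
  beats <- segment_beats(sig, pk)
  p <- prof$params
  for (i in seq_len(nrow(beats))) {
    fp <- locate_fiducials(beats$beat[[i]], beats$r_index[i], sig$fs)
    expect_false(is.null(fp))
    # each located point within one generating sigma of its true center
    for (comp in c("P", "Q", "R", "S", "T")) {
      t_ms <- fp$time_ms[fp$point == comp]
      expect_lt(abs(t_ms - p$center[[comp]]), p$width[[comp]],
                label = sprintf("beat %d, %s offset", i, comp))
    }
    # window construction forces the ordering
    expect_true(!is.unsorted(fp$index, strictly = TRUE))
  }
})

test_that("24 features follow their closed-form definitions", {
  # hand-built fiducial set: Q=(0 ms, 0 mV), R=(40, 1), S=(80, 0)
  pts <- tibble::tibble(
    point = c("P", "Q", "R", "S", "T"),
    index = c(1L, 101L, 141L, 181L, 381L),
    time_ms = c(-140, -40, 0, 40, 240) + 40,  # R-relative after shift below
    amp_mv = c(0.2, 0, 1, 0, 0.3))
  # re-express times relative to R (third point)
  pts$time_ms <- pts$time_ms - pts$time_ms[3]
  f <- extract_waveform_features(pts)
  expect_length(f, 24)
  expect_named(f, waveform_feature_names())
  # QRS triangle: base 80 ms, height 1 mV -> 40 mV*ms
  expect_equal(unname(f["area_QRS"]), 40)
  expect_equal(unname(f["dur_QS"]), 80)
  expect_equal(unname(f["amp_RQ"]), 1)
  expect_equal(unname(f["slope_QR"]), (0 - 1) / (-40 - 0))
  expect_equal(unname(f["pos_R"]), 0)

  # collinear Q, R, S -> zero area
  pts2 <- pts
  pts2$amp_mv <- c(0.2, 0, 0.5, 1, 0.3)  # Q-R-S on a line
  f2 <- extract_waveform_features(pts2)
  expect_equal(unname(f2["area_QRS"]), 0, tolerance = 1e-12)

  # coincident fiducial times flag the beat unusable
  pts3 <- pts
  pts3$time_ms[4] <- pts3$time_ms[3]
  expect_null(extract_waveform_features(pts3))
})

test_that("features are shift-invariant and scale equivariantly", {
  prof <- subject_profile("s", hr_bpm = 65, rr_sd_ms = 5)
  sig <- generate_clean_ecg(prof, fs = 500, duration = 10, seed = 17)
  pk <- detect_qrs(sig)
  beats <- segment_beats(sig, pk)
  b <- beats$beat[[2]]; ri <- beats$r_index[2]

  base <- extract_waveform_features(locate_fiducials(b, ri, 500))
  # time shift: same window content, shifted placement in the record
  shifted <- extract_waveform_features(locate_fiducials(b, ri, 500))
  expect_equal(base, shifted)

  # amplitude scaling by a > 0 scales amps, slopes, area; not times
  a <- 2.5
  scaled <- extract_waveform_features(locate_fiducials(a * b, ri, 500))
  nm <- waveform_feature_names()
  pos_dur <- grepl("^(pos|dur)_", nm)
  amp_like <- grepl("^(amp|slope)_", nm) | nm == "area_QRS"
  expect_equal(scaled[pos_dur], base[pos_dur])
  expect_equal(unname(scaled[amp_like]), unname(a * base[amp_like]),
               tolerance = 1e-10)
})

test_that("median aggregation is robust to a corrupted beat", {
  prof <- subject_profile("r", hr_bpm = 70, rr_sd_ms = 5)
  sig <- generate_clean_ecg(prof, fs = 500, duration = 20, seed = 19)
  pk <- detect_qrs(sig)
  clean_vec <- subject_waveform_feature(sig, pk)

  # corrupt one beat's span with a large artifact
  x <- sig$samples
  span <- as.integer(pk)[5]:(as.integer(pk)[5] + 150)
  x[span] <- x[span] + 3 * sin(seq(0, 40, length.out = length(span)))
  bad <- ecg_signal(x, sig$fs, id = "r")
  bad_vec <- subject_waveform_feature(bad, detect_qrs(bad))
  # medians barely move despite the corrupted beat
  nm <- waveform_feature_names()
  scale_ref <- pmax(abs(clean_vec), 1)
  expect_lt(max(abs(bad_vec - clean_vec) / scale_ref), 0.25)

  # single beat -> subject vector equals that beat's features
  short <- generate_clean_ecg(subject_profile("one", hr_bpm = 60, rr_sd_ms = 0),
                              fs = 500, duration = 3.4, seed = 23)
  pk1 <- detect_qrs(short)
  beats1 <- segment_beats(short, pk1)
  expect_equal(nrow(beats1), 1)
  direct <- extract_waveform_features(
    locate_fiducials(beats1$beat[[1]], beats1$r_index[1], 500))
  expect_equal(subject_waveform_feature(short, pk1), direct)
})

test_that("recovered QS duration tracks the generating QRS width cohort-wide", {
  # spread of QRS widths via a per-subject width multiplier
  set.seed(29)
  n <- 40
  mults <- runif(n, 0.8, 1.6)
  rows <- lapply(seq_len(n), function(i) {
    p <- wave_params()
    p$width[c("Q", "R", "S")] <- p$width[c("Q", "R", "S")] * mults[i]
    p$center[c("Q", "S")] <- p$center[c("Q", "S")] * mults[i]
    prof <- subject_profile(sprintf("c%02d", i), params = p, hr_bpm = 70,
                            rr_sd_ms = 10)
    sig <- generate_clean_ecg(prof, fs = 500, duration = 8,
                              seed = 1000 + i)
    subject_waveform_feature(sig, detect_qrs(sig))["dur_QS"]
  })
  qs <- unlist(rows)
  expect_gte(cor(qs, mults, method = "spearman"), 0.9)
})
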