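test_that("segment builder slices 169 + last 85 and pads to 256", {
  # a synthetic beat table with one 1000-sample cycle of values 0..999
  beats <- tibble::tibble(
    beat = list(c(0:999, 0:999)), r_index = 1001L, start_index = 1L,
    rr_prev = 1000L, rr_next = 1000L)
  segs <- build_segments(beats)
  expect_length(segs, 1)
  seg <- segs[[1]]
  expect_length(seg, 256)
  expect_equal(seg, c(0:168, 915:999, 999, 999))

  # strict mode keeps the raw 254 values
  seg254 <- build_segments(beats, strict_254 = TRUE)[[1]]
  expect_length(seg254, 254)
  expect_equal(seg254, c(0:168, 915:999))

  # a 253-sample cycle is skipped
  short <- tibble::tibble(
    beat = list(rep(0, 500)), r_index = 254L, start_index = 1L,
    rr_prev = 253L, rr_next = 247L)
  expect_warning(none <- build_segments(short), "shorter")
  expect_length(none, 0)
  expect_equal(attr(none, "n_skipped"), 1)
})

test_that("periodized DWT reconstructs exactly and conserves energy", {
  set.seed(5)
  for (family in c("haar", "db2", "db4")) {
    for (lev in c(1, 4, 6, 8)) {
      x <- rnorm(256)
      w <- dwt_periodized(x, level = lev, family = family)
      coef <- dwt_coefficients(w)
      expect_length(coef, 256)
      # perfect reconstruction
      expect_lt(max(abs(idwt_periodized(w) - x)), 1e-8)
      # Parseval: orthonormal transform conserves energy
      expect_lt(abs(sum(coef^2) - sum(x^2)) / sum(x^2), 1e-8)
    }
  }
})

test_that("constant segments put everything in the approximation", {
  x <- rep(3.7, 256)
  w <- dwt_periodized(x, level = 6, family = "db4")
  expect_lt(max(abs(unlist(w$details))), 1e-10)
  expect_equal(sum(w$approx^2), sum(x^2), tolerance = 1e-10)
})

test_that("group feature vector concatenates four 256-coefficient blocks", {
  set.seed(9)
  group <- replicate(4, rnorm(256), simplify = FALSE)
  v <- dwt_features(group, n = 6, family = "db4")
  expect_length(v, 1024)
  # block g is the transform of segment g
  w1 <- dwt_coefficients(dwt_periodized(group[[1]], 6, "db4"))
  expect_equal(as.numeric(v[1:256]), w1)

  expect_error(dwt_features(group[1:3], 6), "exactly 4")
  expect_error(dwt_features(group, 9), "1..8")
  expect_error(dwt_periodized(rnorm(256), 6, family = "nope"),
               "unknown wavelet family")
})

test_that("subject vector averages groups and ignores their order", {
  prof <- subject_profile("w", hr_bpm = 70, rr_sd_ms = 10)
  sig <- generate_clean_ecg(prof, fs = 500, duration = 16, seed = 31)
  pk <- detect_qrs(sig)
  v <- subject_wavelet_feature(sig, pk, n = 6)
  expect_length(v, 1024)

  # with exactly 4 segments the subject vector equals the group vector
  beats <- segment_beats(sig, pk)
  segs <- build_segments(beats)[1:4]
  expect_equal(v_len <- length(dwt_features(segs, 6)), 1024)

  # 8 identical segments -> subject vector equals either group's vector
  fake <- tibble::tibble(
    beat = rep(list(c(sin(1:400 / 20), sin(1:400 / 20))), 8),
    r_index = 401L, start_index = 1L, rr_prev = 400L, rr_next = 400L)
  segs8 <- build_segments(fake)
  g1 <- as.numeric(dwt_features(segs8[1:4], 6))
  g2 <- as.numeric(dwt_features(segs8[5:8], 6))
  expect_equal(g1, g2)

  # dimension is independent of record duration
  sig2 <- generate_clean_ecg(prof, fs = 500, duration = 30, seed = 32)
  v2 <- subject_wavelet_feature(sig2, detect_qrs(sig2), n = 6)
  expect_length(v2, 1024)

  # fewer than 4 usable segments -> NULL with a warning
  sig3 <- generate_clean_ecg(prof, fs = 500, duration = 4, seed = 33)
  expect_warning(v3 <- subject_wavelet_feature(sig3, detect_qrs(sig3), n = 6),
                 "usable segments")
  expect_null(v3)
})
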