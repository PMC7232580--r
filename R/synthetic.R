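# Synthetic labeled ECG cohort.
#
# Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) placed at RR
# intervals drawn per subject; condition flags are Bernoulli at configured
# prevalence and flagged subjects receive multiplicative/additive morphology
# deltas. All randomness flows from one master seed through fixed-arithmetic
# child seeds, so every subject and noise stream is independently
# reproducible.

# deterministic child-seed derivation, kept under 2^31
child_seed <- function(master, i) {
  (as.numeric(master) * 48271 + as.numeric(i) * 16807) %% 2147483647
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Per-component beat morphology parameters
#'
#' Amplitudes in mV, centers as signed offsets from the R apex in ms,
#' widths as Gaussian sigmas in ms. Defaults describe a typical adult
#' lead-II-like beat; the component order P < Q < R < S < T is enforced.
#'
#' @param amp Named numeric vector of amplitudes (mV) for P, Q, R, S, T.
#' @param center Named numeric vector of centers (ms, offset from R).
#' @param width Named numeric vector of Gaussian sigmas (ms), all > 0.
#' @return A list of class `wave_params`.
#' @export
wave_params <- function(amp = c(P = 0.15, Q = -0.12, R = 1.1, S = -0.18, T = 0.30),
                        center = c(P = -180, Q = -35, R = 0, S = 35, T = 280),
                        width = c(P = 25, Q = 12, R = 16, S = 12, T = 60)) {
  comp <- c("P", "Q", "R", "S", "T")
  for (v in list(amp, center, width)) {
    if (!all(comp %in% names(v))) rlang::abort("wave params need P,Q,R,S,T entries")
  }
  amp <- amp[comp]; center <- center[comp]; width <- width[comp]
  if (any(width <= 0)) rlang::abort("wave widths must be > 0")
  if (amp[["R"]] <= 0) rlang::abort("R amplitude must be > 0")
  if (is.unsorted(center, strictly = TRUE)) {
    rlang::abort("wave centers must be ordered P < Q < R < S < T")
  }
  structure(list(amp = amp, center = center, width = width),
            class = "wave_params")
}

#' Noise model specification
#'
#' The five contamination classes of ambulatory ECG: baseline wander
#' (low-frequency drift, 0.05-2.00 Hz by default), power-line interference,
#' EMG (broadband muscle) noise, sparse electrode-motion transients, and
#' extraneous white noise. Zero amplitudes switch a class off; the all-zero
#' spec is the identity.
#'
#' @param baseline_amp Baseline wander amplitude (mV).
#' @param baseline_band Baseline wander frequency band (Hz), default
#'   `c(0.05, 2)`.
#' @param powerline_hz Mains frequency (Hz).
#' @param powerline_amp Mains amplitude (mV).
#' @param emg_band EMG noise band (Hz); truncated at Nyquist when applied.
#' @param emg_amp EMG noise RMS amplitude (mV).
#' @param motion_rate Electrode-motion transient rate (events/minute).
#' @param motion_amp Transient peak amplitude (mV).
#' @param white_sd White noise standard deviation (mV).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0, baseline_band = c(0.05, 2),
                       powerline_hz = 50, powerline_amp = 0,
                       emg_band = c(20, 120), emg_amp = 0,
                       motion_rate = 0, motion_amp = 0,
                       white_sd = 0) {
  amps <- c(baseline_amp, powerline_amp, emg_amp, motion_amp, white_sd)
  if (any(amps < 0)) rlang::abort("noise amplitudes must be >= 0")
  if (baseline_band[1] < 0 || baseline_band[2] <= baseline_band[1]) {
    rlang::abort("invalid baseline band")
  }
  structure(list(baseline_amp = baseline_amp, baseline_band = baseline_band,
                 powerline_hz = powerline_hz, powerline_amp = powerline_amp,
                 emg_band = emg_band, emg_amp = emg_amp,
                 motion_rate = motion_rate, motion_amp = motion_amp,
                 white_sd = white_sd),
            class = "noise_spec")
}

#' Subject profile for signal generation
#'
#' @param id Subject identifier.
#' @param age Age in years.
#' @param sex `"M"` or `"F"`.
#' @param diabetes,obesity,hypertension,smoker Condition flags (logical).
#' @param params Realized [wave_params()] for this subject.
#' @param hr_bpm Mean heart rate (beats/minute), in `[30, 200]`.
#' @param rr_sd_ms RR-interval standard deviation (ms).
#' @return A list of class `subject_profile`.
#' @export
subject_profile <- function(id, age = 60, sex = "M",
                            diabetes = FALSE, obesity = FALSE,
                            hypertension = FALSE, smoker = FALSE,
                            params = wave_params(),
                            hr_bpm = 72, rr_sd_ms = 25) {
  if (hr_bpm < 30 || hr_bpm > 200) rlang::abort("hr_bpm must be in [30, 200]")
  structure(list(id = as.character(id), age = age, sex = sex,
                 diabetes = diabetes, obesity = obesity,
                 hypertension = hypertension, smoker = smoker,
                 params = params, hr_bpm = hr_bpm, rr_sd_ms = rr_sd_ms),
            class = "subject_profile")
}

#' Generate a clean (noise-free) synthetic ECG
#'
#' Sums five Gaussian bumps per beat at RR intervals drawn from
#' Normal(60000/hr, rr_sd) ms, clipped to stay positive. Deterministic given
#' `seed`. True R-peak times are attached as attribute `r_times_s`.
#'
#' @param profile A [subject_profile()].
#' @param fs Sampling rate (Hz), >= 100.
#' @param duration Record length (s); must cover at least 2 beats.
#' @param seed Integer seed for the RR stream.
#' @return An [ecg_signal()] with attribute `r_times_s` (true R times, s).
#' @export
generate_clean_ecg <- function(profile, fs = 500, duration = 10, seed = 1) {
  if (!is.numeric(fs) || fs < 100) rlang::abort("fs must be >= 100 Hz")
  rr_mean <- 60 / profile$hr_bpm
  if (!is.numeric(duration) || duration < 2 * rr_mean) {
    rlang::abort("duration must cover at least 2 beats")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  # lay out R times: first beat ~0.4 RR in, then draw RR intervals
  r_times <- with_seed(seed, {
    out <- numeric(0)
    cur <- 0.4 * rr_mean
    while (cur < duration - 0.1 * rr_mean) {
      out <- c(out, cur)
      rr <- stats::rnorm(1, rr_mean, profile$rr_sd_ms / 1000)
      rr <- max(rr, 0.3)
      cur <- cur + rr
    }
    out
  })
  x <- numeric(n)
  p <- profile$params
  for (r in r_times) {
    for (comp in c("P", "Q", "R", "S", "T")) {
      mu <- r + p$center[[comp]] / 1000
      sg <- p$width[[comp]] / 1000
      lo <- max(1L, floor((mu - 5 * sg) * fs) + 1L)
      hi <- min(n, ceiling((mu + 5 * sg) * fs) + 1L)
      if (lo > hi) next
      seg <- lo:hi
      x[seg] <- x[seg] + p$amp[[comp]] * exp(-((t[seg] - mu)^2) / (2 * sg^2))
    }
  }
  sig <- ecg_signal(x, fs = fs, lead = "synthetic", id = profile$id)
  attr(sig, "r_times_s") <- r_times
  sig
}

#' Add the five noise classes to an ECG signal
#'
#' Adds baseline wander (a sum of low-frequency sinusoids with random phase
#' within the configured band), a power-line sinusoid, band-limited EMG
#' noise, sparse electrode-motion transients and white noise. Length and
#' sampling rate are unchanged; an all-zero spec returns the input
#' unchanged.
#'
#' @param signal An [ecg_signal()].
#' @param spec A [noise_spec()].
#' @param seed Integer seed for the noise streams.
#' @return The contaminated [ecg_signal()].
#' @export
add_noise <- function(signal, spec, seed = 1) {
  assert_signal(signal)
  if (!inherits(spec, "noise_spec")) rlang::abort("`spec` must be a <noise_spec>")
  n <- length(signal$samples)
  fs <- signal$fs
  t <- (seq_len(n) - 1) / fs
  noise <- numeric(n)
  with_seed(seed, {
    if (spec$baseline_amp > 0) {
      nf <- 5L
      freqs <- stats::runif(nf, spec$baseline_band[1], spec$baseline_band[2])
      phases <- stats::runif(nf, 0, 2 * pi)
      w <- stats::runif(nf); w <- w / sum(w)
      for (j in seq_len(nf)) {
        noise <- noise + spec$baseline_amp * w[j] *
          sin(2 * pi * freqs[j] * t + phases[j])
      }
    }
    if (spec$powerline_amp > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      noise <- noise + spec$powerline_amp * sin(2 * pi * spec$powerline_hz * t + phase)
    }
    if (spec$emg_amp > 0) {
      wn <- stats::rnorm(n)
      hi <- min(spec$emg_band[2], 0.45 * fs)
      h <- fir_design(fs, low = spec$emg_band[1], high = hi,
                      order = round(2 * fs / spec$emg_band[1]))
      em <- fir_apply(wn, h)
      em <- em / stats::sd(em) * spec$emg_amp
      noise <- noise + em
    }
    if (spec$motion_amp > 0 && spec$motion_rate > 0) {
      n_ev <- stats::rpois(1, spec$motion_rate * n / fs / 60)
      if (n_ev > 0) {
        centers <- stats::runif(n_ev, 0, n / fs)
        signs <- sample(c(-1, 1), n_ev, replace = TRUE)
        for (j in seq_len(n_ev)) {
          # ~150 ms one-sided bump
          noise <- noise + signs[j] * spec$motion_amp *
            exp(-((t - centers[j])^2) / (2 * 0.075^2))
        }
      }
    }
    if (spec$white_sd > 0) {
      noise <- noise + stats::rnorm(n, 0, spec$white_sd)
    }
  })
  out <- ecg_signal(signal$samples + noise, fs = fs,
                    lead = signal$lead, id = signal$id)
  attr(out, "r_times_s") <- attr(signal, "r_times_s")
  out
}

# recognized per-condition effect keys
.effect_keys <- c("amp_mult", "r_amp_mult", "p_amp_mult", "t_amp_mult",
                  "qrs_width_mult", "hr_add", "hr_mult")

#' Default disease/habit effect map
#'
#' Plausibility defaults for how each condition shifts beat morphology:
#' diabetes widens the QRS complex and flattens the T wave, hypertension
#' raises the R amplitude (ventricular hypertrophy), smoking raises heart
#' rate, obesity attenuates all amplitudes (body-habitus damping). These are
#' configurable stand-ins, not measured clinical effect sizes.
#'
#' @return Named list of per-condition effect lists.
#' @export
default_effects <- function() {
  list(
    diabetes = list(qrs_width_mult = 1.4, t_amp_mult = 0.7),
    hypertension = list(r_amp_mult = 1.3),
    smoker = list(hr_add = 15),
    obesity = list(amp_mult = 0.8)
  )
}

apply_effects <- function(params, hr, flags, effects) {
  for (cond in names(effects)) {
    if (!isTRUE(flags[[cond]])) next
    eff <- effects[[cond]]
    bad <- setdiff(names(eff), .effect_keys)
    if (length(bad)) {
      rlang::abort(sprintf(
        "unknown effect key(s) %s for condition '%s' (known: %s)",
        paste(bad, collapse = ", "), cond, paste(.effect_keys, collapse = ", ")))
    }
    if (!is.null(eff$amp_mult))   params$amp <- params$amp * eff$amp_mult
    if (!is.null(eff$r_amp_mult)) params$amp[["R"]] <- params$amp[["R"]] * eff$r_amp_mult
    if (!is.null(eff$p_amp_mult)) params$amp[["P"]] <- params$amp[["P"]] * eff$p_amp_mult
    if (!is.null(eff$t_amp_mult)) params$amp[["T"]] <- params$amp[["T"]] * eff$t_amp_mult
    if (!is.null(eff$qrs_width_mult)) {
      m <- eff$qrs_width_mult
      params$width[c("Q", "R", "S")] <- params$width[c("Q", "R", "S")] * m
      params$center[c("Q", "S")] <- params$center[c("Q", "S")] * m
    }
    if (!is.null(eff$hr_add))  hr <- hr + eff$hr_add
    if (!is.null(eff$hr_mult)) hr <- hr * eff$hr_mult
  }
  list(params = params, hr = min(max(hr, 30), 200))
}

#' Cohort generation configuration
#'
#' @param n Number of subjects (>= 1).
#' @param prevalence Named fractions in `[0, 1]` for `diabetes`, `obesity`,
#'   `hypertension`, `smoker`. Defaults follow the diagnostic-class
#'   proportions of the 268 clinically summarized PTB subjects.
#' @param effects Per-condition effect map, see [default_effects()].
#' @param fs Sampling rate (Hz), >= 100.
#' @param duration Record duration (s).
#' @param noise A [noise_spec()] applied to every record; default is gentle
#'   contamination (SNR well above 20 dB).
#' @param seed Master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 100,
                          prevalence = c(diabetes = 29 / 268, obesity = 20 / 268,
                                         hypertension = 63 / 268, smoker = 73 / 268),
                          effects = default_effects(),
                          fs = 500, duration = 10,
                          noise = noise_spec(baseline_amp = 0.05,
                                             emg_amp = 0.01, white_sd = 0.01),
                          seed = 1) {
  if (n < 1) rlang::abort("n must be >= 1")
  if (fs < 100) rlang::abort("fs must be >= 100 Hz")
  if (any(prevalence < 0 | prevalence > 1)) {
    rlang::abort("prevalences must be in [0, 1]")
  }
  # validate effect keys up front
  for (cond in names(effects)) {
    bad <- setdiff(names(effects[[cond]]), .effect_keys)
    if (length(bad)) {
      rlang::abort(sprintf("unknown effect key(s) %s for condition '%s'",
                           paste(bad, collapse = ", "), cond))
    }
  }
  structure(list(n = n, prevalence = prevalence, effects = effects,
                 fs = fs, duration = duration, noise = noise, seed = seed),
            class = "cohort_config")
}

#' Generate a labeled synthetic ECG cohort
#'
#' Draws per-subject condition flags at the configured prevalence, realizes
#' per-subject beat morphology (base lognormal/normal variability plus
#' condition effect deltas), and synthesizes one noisy single-lead record
#' per subject. Fully reproducible from the master seed.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per subject: `id`, `age`, `sex`, the four
#'   condition flags, `hr_bpm`, `rr_sd_ms`, and list-columns `params`
#'   (realized [wave_params()]), `signal` ([ecg_signal()]) and `r_times_s`
#'   (true R-peak times in seconds).
#' @examples
#' coh <- generate_cohort(cohort_config(n = 3, duration = 6, fs = 250))
#' coh[, c("id", "age", "diabetes", "smoker")]
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    rlang::abort("`config` must be a <cohort_config>")
  }
  n <- config$n
  conds <- c("diabetes", "obesity", "hypertension", "smoker")
  flags <- with_seed(child_seed(config$seed, 0), {
    out <- lapply(conds, function(cn) {
      p <- if (cn %in% names(config$prevalence)) config$prevalence[[cn]] else 0
      stats::runif(n) < p
    })
    names(out) <- conds
    # demographics loosely matching an adult clinical cohort
    list(flags = out,
         age = round(stats::rnorm(n, 57, 13)),
         sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.72, 0.28)))
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    si <- with_seed(child_seed(config$seed, i), {
      base <- wave_params()
      amp <- base$amp * stats::rlnorm(5, 0, 0.08)
      amp[["R"]] <- abs(amp[["R"]])
      width <- base$width * stats::rlnorm(5, 0, 0.06)
      center <- base$center + c(stats::rnorm(1, 0, 8), stats::rnorm(1, 0, 3), 0,
                                stats::rnorm(1, 0, 3), stats::rnorm(1, 0, 8))
      names(amp) <- names(width) <- names(center) <- c("P", "Q", "R", "S", "T")
      # keep ordering valid under jitter
      center <- sort(center)
      names(center) <- c("P", "Q", "R", "S", "T")
      hr <- min(max(stats::rnorm(1, 72, 8), 45), 120)
      list(params = wave_params(amp, center, width), hr = hr)
    })
    fl <- lapply(flags$flags, `[`, i)
    adj <- apply_effects(si$params, si$hr, fl, config$effects)
    prof <- subject_profile(
      id = sprintf("s%03d", i), age = flags$age[i], sex = flags$sex[i],
      diabetes = fl$diabetes, obesity = fl$obesity,
      hypertension = fl$hypertension, smoker = fl$smoker,
      params = adj$params, hr_bpm = adj$hr, rr_sd_ms = 25)
    clean <- generate_clean_ecg(prof, fs = config$fs,
                                duration = config$duration,
                                seed = child_seed(config$seed, 100000 + i))
    noisy <- add_noise(clean, config$noise,
                       seed = child_seed(config$seed, 200000 + i))
    subjects[[i]] <- list(profile = prof, signal = noisy,
                          r_times = attr(clean, "r_times_s"))
  }
  tibble::tibble(
    id = vapply(subjects, function(s) s$profile$id, character(1)),
    age = vapply(subjects, function(s) s$profile$age, numeric(1)),
    sex = vapply(subjects, function(s) s$profile$sex, character(1)),
    diabetes = flags$flags$diabetes,
    obesity = flags$flags$obesity,
    hypertension = flags$flags$hypertension,
    smoker = flags$flags$smoker,
    hr_bpm = vapply(subjects, function(s) s$profile$hr_bpm, numeric(1)),
    rr_sd_ms = 25,
    params = lapply(subjects, function(s) s$profile$params),
    signal = lapply(subjects, function(s) s$signal),
    r_times_s = lapply(subjects, function(s) s$r_times)
  )
}

#' Extract the medical-record table from a cohort
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return A tibble with columns `id`, `age`, `sex` and the four condition
#'   flags (logical; `NA` = unknown).
#' @export
cohort_records <- function(cohort) {
  cohort[, c("id", "age", "sex", "diabetes", "obesity", "hypertension", "smoker")]
}
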