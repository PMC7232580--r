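# On-disk formats: two-column signal text, records CSV, cohort manifest,
# and a read-only WFDB (.hea/.dat) decoder for format-16 single-segment
# records so real archive data can stand in for the synthetic cohort.

#' Read a two-column signal file
#'
#' Expects whitespace- or comma-separated numeric text with columns
#' `time_s`, `voltage_mv` (header optional). The sampling rate is inferred
#' from the median time step.
#'
#' @param path File path.
#' @param lead,id Metadata attached to the returned signal.
#' @return An [ecg_signal()].
#' @export
read_signal_csv <- function(path, lead = "unknown", id = NA_character_) {
  df <- utils::read.csv(path, header = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  # tolerate a header row
  if (!is.numeric(df[[1]]) && nrow(df) > 0 &&
      suppressWarnings(is.na(as.numeric(df[1, 1])))) {
    df <- df[-1, , drop = FALSE]
  }
  if (ncol(df) < 2) rlang::abort(sprintf("%s: expected two columns", path))
  tm <- suppressWarnings(as.numeric(df[[1]]))
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(tm) || anyNA(v)) {
    bad <- which(is.na(tm) | is.na(v))[1]
    rlang::abort(sprintf("%s: non-numeric value at data row %d", path, bad))
  }
  if (length(tm) < 2) rlang::abort(sprintf("%s: need at least 2 samples", path))
  dt <- diff(tm)
  if (any(dt <= 0)) {
    rlang::abort(sprintf("%s: time column not strictly increasing at row %d",
                         path, which(dt <= 0)[1] + 1))
  }
  fs <- 1 / stats::median(dt)
  ecg_signal(v, fs = fs, lead = lead, id = id)
}

#' Write a signal as two-column text
#'
#' @param signal An [ecg_signal()].
#' @param path Output path.
#' @param digits Significant digits for formatting.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path, digits = 9) {
  assert_signal(signal)
  df <- as_tibble.ecg_signal(signal)
  utils::write.table(
    data.frame(time_s = signif(df$time_s, digits),
               voltage_mv = signif(df$voltage_mv, digits)),
    path, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_flag <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "TRUE", "True", "T")] <- TRUE
  out[x %in% c("0", "false", "FALSE", "False", "F")] <- FALSE
  as.logical(out)
}

#' Read a medical-records table
#'
#' CSV with header `id,age,sex,diabetes,obesity,hypertension,smoker`. Flags
#' may be `1/0`, `true/false` or empty; empty cells become `NA` (unknown)
#' and such subjects are excluded from that condition's association
#' denominators downstream.
#'
#' @param path File path.
#' @return A tibble of medical records.
#' @export
read_records_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "diabetes", "obesity", "hypertension", "smoker")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    rlang::abort(sprintf("%s: missing column(s) %s", path,
                         paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(df$id)) {
    rlang::abort(sprintf("%s: duplicated subject id '%s'", path,
                         df$id[duplicated(df$id)][1]))
  }
  tibble::tibble(
    id = df$id,
    age = if ("age" %in% names(df)) suppressWarnings(as.numeric(df$age)) else NA_real_,
    sex = if ("sex" %in% names(df)) df$sex else NA_character_,
    diabetes = parse_flag(df$diabetes),
    obesity = parse_flag(df$obesity),
    hypertension = parse_flag(df$hypertension),
    smoker = parse_flag(df$smoker)
  )
}

#' Write a medical-records table
#'
#' @param records Records tibble (as from [cohort_records()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  df <- as.data.frame(records)
  for (cn in c("diabetes", "obesity", "hypertension", "smoker")) {
    df[[cn]] <- ifelse(is.na(df[[cn]]), "", ifelse(df[[cn]], "1", "0"))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' One two-column signal file per subject, one records CSV, and a JSON
#' manifest holding the generating configuration and seed.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param config The [cohort_config()] used, stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(cohort))) {
    write_signal_csv(cohort$signal[[i]],
                     file.path(dir, paste0(cohort$id[i], ".csv")))
  }
  write_records_csv(cohort_records(cohort), file.path(dir, "records.csv"))
  if (!is.null(config)) {
    man <- list(n = config$n, prevalence = as.list(config$prevalence),
                effects = config$effects, fs = config$fs,
                duration = config$duration, seed = config$seed)
    jsonlite::write_json(man, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Parse a WFDB header (.hea) file
#'
#' Supports the single-segment dialect used by clinical ECG archives:
#' a record line `name n_sig fs n_samples` followed by one signal line per
#' lead (`file format gain(baseline)/units ... description`).
#'
#' @param path Path to the `.hea` file.
#' @return A list with `record`, `n_sig`, `fs`, `n_samples` and a tibble
#'   `signals` (file, format, gain, baseline, units, label).
#' @export
read_wfdb_header <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("header not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 3) rlang::abort(sprintf("%s: malformed record line", path))
  if (grepl("/", rec[1], fixed = TRUE)) {
    rlang::abort(sprintf("%s: multi-segment records are not supported", path))
  }
  n_sig <- as.integer(rec[2])
  fs <- as.numeric(sub("/.*$", "", rec[3]))
  n_samples <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig_lines <- lines[seq_len(n_sig) + 1]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    fmt_raw <- f[2]
    fmt <- as.integer(sub("[x:+].*$", "", fmt_raw))
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.eE]+).*$", "\\1", gain_field))
    baseline <- 0
    if (grepl("\\(", gain_field)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    }
    units <- if (grepl("/", gain_field)) sub("^.*/", "", gain_field) else "mV"
    label <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else NA_character_
    list(file = f[1], format = fmt, gain = ifelse(is.na(gain) || gain == 0, 200, gain),
         baseline = baseline, units = units, label = label)
  }
  sigs <- lapply(sig_lines, parse_sig)
  list(
    record = rec[1], n_sig = n_sig, fs = fs, n_samples = n_samples,
    signals = tibble::tibble(
      file = vapply(sigs, `[[`, character(1), "file"),
      format = vapply(sigs, `[[`, numeric(1), "format"),
      gain = vapply(sigs, `[[`, numeric(1), "gain"),
      baseline = vapply(sigs, `[[`, numeric(1), "baseline"),
      units = vapply(sigs, `[[`, character(1), "units"),
      label = vapply(sigs, `[[`, character(1), "label")
    )
  )
}

#' Read a WFDB format-16 record
#'
#' Decodes the interleaved 16-bit little-endian sample file named in the
#' header into millivolts using each lead's gain and baseline:
#' `mV = (raw - baseline) / gain`. Only storage format 16 single-segment
#' records are supported; anything else raises an explicit error.
#'
#' @param hea_path Path to the `.hea` file.
#' @param lead Lead to extract: label (string) or index; default first lead.
#' @return An [ecg_signal()] for the requested lead.
#' @export
read_wfdb_signal <- function(hea_path, lead = 1) {
  hdr <- read_wfdb_header(hea_path)
  if (any(hdr$signals$format != 16)) {
    rlang::abort(sprintf(
      "unsupported WFDB storage format %s (only format 16 is supported)",
      paste(unique(hdr$signals$format[hdr$signals$format != 16]), collapse = ",")))
  }
  idx <- if (is.character(lead)) match(lead, hdr$signals$label) else as.integer(lead)
  if (is.na(idx) || idx < 1 || idx > hdr$n_sig) {
    rlang::abort(sprintf("lead '%s' not found in record %s", lead, hdr$record))
  }
  dat_path <- file.path(dirname(hea_path), hdr$signals$file[idx])
  if (!file.exists(dat_path)) {
    rlang::abort(sprintf("sample file not found: %s", dat_path))
  }
  raw <- readBin(dat_path, what = "integer", size = 2, signed = TRUE,
                 endian = "little", n = file.size(dat_path) / 2)
  # samples are interleaved across the n_sig leads
  lead_raw <- raw[seq(idx, length(raw), by = hdr$n_sig)]
  mv <- (lead_raw - hdr$signals$baseline[idx]) / hdr$signals$gain[idx]
  ecg_signal(mv, fs = hdr$fs,
             lead = ifelse(is.na(hdr$signals$label[idx]),
                           as.character(idx), hdr$signals$label[idx]),
             id = hdr$record)
}
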