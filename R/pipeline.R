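# End-to-end orchestration: preprocessing -> feature extraction ->
# k-means clustering -> crosstab + association metrics, over any
# combination of feature sets and k values.

#' Run the full clustering pipeline
#'
#' For each requested feature set and each k: extract per-subject features
#' (denoising and QRS detection included), cluster with [kmeans_lloyd()],
#' cross-tabulate against the medical records and compute ratio and
#' concentricity metrics. Standardization defaults to "auto": on for the
#' mixed-unit waveform features, off for RBP (already relative
#' frequencies) and wavelet coefficients.
#'
#' @param cohort Cohort tibble (from [generate_cohort()] or assembled from
#'   [read_signal_csv()] records) with `id` and `signal` columns.
#' @param records Medical-records tibble; defaults to the cohort's own
#'   label columns when present.
#' @param features Character subset of `c("rbp", "waveform", "wavelet")`.
#' @param k Integer vector of cluster counts (default 2, 4, 8).
#' @param seed Seed governing k-means initialization.
#' @param m RBP word length.
#' @param level,family Wavelet decomposition level and family.
#' @param nstart Random restarts per k-means fit.
#' @param standardize `"auto"`, `TRUE` or `FALSE`.
#' @return A tibble of class `ecg_pipeline_result` with one row per
#'   (feature set, k): columns `feature_set`, `k`, `n_subjects`, `sse`,
#'   and list-columns `model`, `crosstab`, `ratios`, `concentricity`.
#' @export
run_pipeline <- function(cohort, records = NULL,
                         features = c("rbp", "waveform", "wavelet"),
                         k = c(2, 4, 8), seed = 1, m = 8,
                         level = 6, family = "db4", nstart = 10,
                         standardize = "auto") {
  features <- match.arg(features, several.ok = TRUE)
  if (is.null(records)) {
    if (!all(CONDITIONS %in% names(cohort))) {
      rlang::abort("`records` is required when the cohort has no label columns")
    }
    records <- cohort_records(cohort)
  }
  feat_tables <- list()
  for (fs_name in features) {
    feat_tables[[fs_name]] <- switch(fs_name,
      rbp = rbp_features(cohort, m = m),
      waveform = waveform_features(cohort),
      wavelet = wavelet_features(cohort, n = level, family = family))
  }
  rows <- list()
  for (fs_name in features) {
    ft <- feat_tables[[fs_name]]
    std <- if (identical(standardize, "auto")) fs_name == "waveform" else isTRUE(standardize)
    for (kk in k) {
      if (kk > nrow(ft)) {
        rlang::abort(sprintf("stage cluster[%s,k=%d]: only %d usable subjects",
                             fs_name, kk, nrow(ft)))
      }
      fit <- kmeans_lloyd(ft, k = kk, seed = child_seed(seed, kk),
                          nstart = nstart, standardize = std)
      tab <- crosstab(fit, records)
      met <- association_metrics(tab)
      rows[[length(rows) + 1]] <- tibble::tibble(
        feature_set = fs_name, k = kk, n_subjects = nrow(ft),
        sse = fit$sse, model = list(fit), crosstab = list(tab),
        ratios = list(met$ratios), concentricity = list(met$concentricity))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ecg_pipeline_result", class(out))
  out
}

#' Render a pipeline result as aligned text tables
#'
#' One block per (feature set, k) mirroring the published crosstab layout:
#' group, size, and per-condition positive counts.
#'
#' @param result Tibble from [run_pipeline()].
#' @return A character vector of lines, invisibly; printed to the console.
#' @export
report_text <- function(result) {
  lines <- character(0)
  for (i in seq_len(nrow(result))) {
    tab <- result$crosstab[[i]]
    lines <- c(lines, sprintf("== %s features, k = %d (E = %.4g) ==",
                              result$feature_set[i], result$k[i],
                              result$sse[i]))
    hdr <- sprintf("%-8s %7s %8s %7s %13s %9s", "Group", "Number",
                   "Obesity", "Smoker", "Hypertension", "Diabetes")
    lines <- c(lines, hdr)
    for (g in tab$group) {
      r <- tab[tab$group == g, ]
      lines <- c(lines, sprintf("%-8s %7d %8d %7d %13d %9d",
                                paste0("Group ", g), r$n, r$obesity,
                                r$smoker, r$hypertension, r$diabetes))
    }
    conc <- result$concentricity[[i]]
    for (j in seq_len(nrow(conc))) {
      if (is.na(conc$concentricity[j])) next
      lines <- c(lines, sprintf("  concentricity %-13s %5.2f%% (group %d)",
                                conc$condition[j],
                                100 * conc$concentricity[j], conc$group[j]))
    }
    lines <- c(lines, "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Serialize a pipeline result to JSON
#'
#' Deterministic (byte-identical for identical configurations) JSON holding
#' per-(feature, k) cluster sizes, assignments, E, crosstab and metrics.
#'
#' @param result Tibble from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(result, path) {
  payload <- lapply(seq_len(nrow(result)), function(i) {
    fit <- result$model[[i]]
    list(
      feature_set = result$feature_set[i],
      k = result$k[i],
      n_subjects = result$n_subjects[i],
      sse = fit$sse,
      iterations = fit$iter,
      assignments = stats::setNames(as.list(fit$cluster), fit$ids),
      crosstab = as.data.frame(result$crosstab[[i]]),
      ratios = as.data.frame(result$ratios[[i]]),
      concentricity = as.data.frame(result$concentricity[[i]])
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, na = "null")
  invisible(path)
}
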