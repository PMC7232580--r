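# Cluster-association metrics: per-group/condition cross-tabulation, the
# ratio criterion (fraction of a group positive for a condition; > 50% read
# as a significant correlation) and the concentricity criterion (largest
# single-group share of all positives for a condition).

CONDITIONS <- c("obesity", "smoker", "hypertension", "diabetes")

#' Cross-tabulate cluster assignments against condition flags
#'
#' One row per cluster with the group size and, for each condition, the
#' count of positives and the count of members whose flag is known.
#' Subjects with an unknown (`NA`) flag are excluded from that condition's
#' counts and denominators only.
#'
#' @param model An `ecg_kmeans` fit (carrying subject ids), or an integer
#'   assignment vector.
#' @param records Medical-records tibble with `id` and the four condition
#'   flags; every clustered subject must appear.
#' @param ids Subject ids matching the assignment vector (not needed when
#'   `model` is an `ecg_kmeans` with ids).
#' @return A tibble of class `ecg_crosstab`: `group`, `n`, then
#'   `<condition>` (positive count) and `<condition>_known` per condition.
#' @export
crosstab <- function(model, records, ids = NULL) {
  if (inherits(model, "ecg_kmeans")) {
    cluster <- model$cluster
    k <- model$k
    ids <- ids %||% model$ids
  } else {
    cluster <- as.integer(model)
    k <- max(cluster)
  }
  if (is.null(ids)) rlang::abort("subject ids are required for a crosstab")
  pos <- match(ids, records$id)
  if (anyNA(pos)) {
    rlang::abort(sprintf("no medical record for subject '%s'",
                         ids[is.na(pos)][1]))
  }
  rec <- records[pos, ]
  out <- tibble::tibble(group = seq_len(k),
                        n = tabulate(cluster, k))
  for (cond in CONDITIONS) {
    fl <- rec[[cond]]
    out[[cond]] <- vapply(seq_len(k), function(g) {
      sum(fl[cluster == g], na.rm = TRUE)
    }, numeric(1))
    out[[paste0(cond, "_known")]] <- vapply(seq_len(k), function(g) {
      sum(!is.na(fl[cluster == g]))
    }, numeric(1))
  }
  class(out) <- c("ecg_crosstab", class(out))
  out
}

#' Build a crosstab directly from printed per-group counts
#'
#' Convenience for reproducing published cluster statistics tables: supply
#' group sizes and per-condition positive counts (flags assumed known for
#' all members).
#'
#' @param n Integer vector of group sizes.
#' @param ... Named integer vectors of per-group positive counts, e.g.
#'   `diabetes = c(8, 21)`.
#' @return An `ecg_crosstab` tibble.
#' @examples
#' crosstab_from_counts(n = c(140, 150), diabetes = c(8, 21))
#' @export
crosstab_from_counts <- function(n, ...) {
  counts <- list(...)
  bad <- setdiff(names(counts), CONDITIONS)
  if (length(bad)) {
    rlang::abort(sprintf("unknown condition(s): %s", paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(group = seq_along(n), n = as.numeric(n))
  for (cond in names(counts)) {
    if (length(counts[[cond]]) != length(n)) {
      rlang::abort(sprintf("'%s' needs one count per group", cond))
    }
    out[[cond]] <- as.numeric(counts[[cond]])
    out[[paste0(cond, "_known")]] <- as.numeric(n)
  }
  class(out) <- c("ecg_crosstab", class(out))
  out
}

#' Ratio criterion for one (condition, group)
#'
#' Fraction of the group's members (with known flag) positive for the
#' condition. A ratio above 0.5 is flagged as a significant correlation.
#'
#' @param tab An `ecg_crosstab`.
#' @param condition One of `"obesity"`, `"smoker"`, `"hypertension"`,
#'   `"diabetes"`.
#' @param group Group index.
#' @return One-row tibble: `condition`, `group`, `positives`, `known`,
#'   `ratio`, `significant`. `ratio` is `NA` for an empty group.
#' @examples
#' tab <- crosstab_from_counts(n = c(21, 9), smoker = c(11, 7))
#' ratio(tab, "smoker", 1)$ratio  # 11/21
#' @export
ratio <- function(tab, condition, group) {
  condition <- match.arg(condition, CONDITIONS)
  if (!condition %in% names(tab)) {
    rlang::abort(sprintf("crosstab has no counts for '%s'", condition))
  }
  row <- tab[tab$group == group, ]
  if (!nrow(row)) rlang::abort(sprintf("no group %s in crosstab", group))
  known <- row[[paste0(condition, "_known")]]
  r <- if (known > 0) row[[condition]] / known else NA_real_
  tibble::tibble(condition = condition, group = group,
                 positives = row[[condition]], known = known,
                 ratio = r, significant = !is.na(r) & r > 0.5)
}

#' Concentricity criterion for one condition
#'
#' The largest single-group share of all known positives for the condition,
#' with the achieving group. High concentricity means the condition's
#' subjects concentrate in one cluster even when no group ratio exceeds
#' 50%.
#'
#' @param tab An `ecg_crosstab`.
#' @param condition Condition name.
#' @return One-row tibble: `condition`, `group` (arg-max), `positives`
#'   (in that group), `total` (cohort positives), `concentricity`.
#'   `NA` concentricity when the cohort has no known positives.
#' @examples
#' tab <- crosstab_from_counts(n = c(140, 150), diabetes = c(8, 21))
#' concentricity(tab, "diabetes")  # 21/29 in group 2
#' @export
concentricity <- function(tab, condition) {
  condition <- match.arg(condition, CONDITIONS)
  if (!condition %in% names(tab)) {
    rlang::abort(sprintf("crosstab has no counts for '%s'", condition))
  }
  counts <- tab[[condition]]
  total <- sum(counts)
  if (total == 0) {
    return(tibble::tibble(condition = condition, group = NA_integer_,
                          positives = 0, total = 0,
                          concentricity = NA_real_))
  }
  g <- which.max(counts)
  tibble::tibble(condition = condition, group = tab$group[g],
                 positives = counts[g], total = total,
                 concentricity = counts[g] / total)
}

#' All association metrics of a crosstab
#'
#' Ratios for every (condition, group) pair and concentricity for every
#' condition present in the table.
#'
#' @param tab An `ecg_crosstab`.
#' @return A list with tibbles `ratios` and `concentricity`.
#' @export
association_metrics <- function(tab) {
  conds <- intersect(CONDITIONS, names(tab))
  ratios <- dplyr::bind_rows(lapply(conds, function(cond) {
    dplyr::bind_rows(lapply(tab$group, function(g) ratio(tab, cond, g)))
  }))
  conc <- dplyr::bind_rows(lapply(conds, concentricity, tab = tab))
  list(ratios = ratios, concentricity = conc)
}

#' Plot a crosstab as per-group condition ratios
#'
#' @param tab An `ecg_crosstab`.
#' @return A ggplot bar chart of condition ratio by group, with the 50%
#'   significance line.
#' @export
plot_crosstab <- function(tab) {
  m <- association_metrics(tab)$ratios
  ggplot2::ggplot(m, ggplot2::aes(x = factor(.data$group), y = .data$ratio,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "cluster", y = "ratio (positives / known members)")
}
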