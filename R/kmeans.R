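# Native Lloyd k-means on Euclidean distance, with the square-error
# objective E = sum over clusters of squared distances of members to their
# cluster mean. Initial centers are k data points drawn at random (the
# classical scheme); k-means++ seeding is available but off by default.

#' Euclidean distance between two feature vectors
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar distance.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort(sprintf("dimension mismatch: %d vs %d", length(a), length(b)))
  }
  sqrt(sum((a - b)^2))
}

# squared distances from every row of x to every center (n x k)
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, `+`) - 2 * x %*% t(centers)
  pmax(d2, 0)
}

sse_of <- function(x, centers, cluster) {
  sum((x - centers[cluster, , drop = FALSE])^2)
}

lloyd_once <- function(x, k, init_idx, max_iter, tol) {
  centers <- x[init_idx, , drop = FALSE]
  n <- nrow(x)
  cluster <- rep(0L, n)
  sse_path <- numeric(0)
  sse_prev <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centers(x, centers)
    new_cluster <- max.col(-d2, ties.method = "first")
    # recompute centers as member means; re-seed empty clusters at the
    # point farthest from its nearest center
    for (j in seq_len(k)) {
      members <- new_cluster == j
      if (!any(members)) {
        nearest <- d2[cbind(seq_len(n), new_cluster)]
        far <- which.max(nearest)
        centers[j, ] <- x[far, ]
        new_cluster[far] <- j
        members <- new_cluster == j
      }
      centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
    sse <- sse_of(x, centers, new_cluster)
    sse_path <- c(sse_path, sse)
    converged_assign <- identical(new_cluster, cluster)
    cluster <- new_cluster
    if (converged_assign || abs(sse_prev - sse) < tol || iter >= max_iter) break
    sse_prev <- sse
  }
  withinss <- vapply(seq_len(k), function(j) {
    m <- cluster == j
    if (!any(m)) return(0)
    sum((x[m, , drop = FALSE] -
           matrix(centers[j, ], sum(m), ncol(x), byrow = TRUE))^2)
  }, numeric(1))
  list(centers = centers, cluster = cluster, sse = sse, iter = iter,
       sse_path = sse_path, withinss = withinss)
}

#' K-means clustering by Lloyd iteration
#'
#' Assigns each row to its nearest center by Euclidean distance and
#' recomputes centers as member means until assignments stop changing, the
#' square error E changes by less than `tol`, or `max_iter` is reached.
#' Initial centers are `k` distinct rows sampled at random (seeded);
#' `nstart > 1` repeats with fresh draws and keeps the lowest-E fit. An
#' empty cluster is re-seeded at the point farthest from its nearest
#' center.
#'
#' @param features Feature tibble/data frame (first column `id` if
#'   character) or numeric matrix.
#' @param k Number of clusters, `1 <= k <=` number of rows.
#' @param seed Integer seed for initialization.
#' @param max_iter Maximum Lloyd iterations per start.
#' @param tol Convergence tolerance on E.
#' @param nstart Number of random restarts.
#' @param init `"sample"` (k random data points, classical) or
#'   `"plusplus"` (distance-weighted seeding).
#' @param init_idx Optional integer vector of `k` row indices to use as the
#'   initial centers; overrides `init`/`nstart` (single deterministic run).
#' @param standardize Z-score columns before clustering (zero-variance
#'   columns become all-zero). Recommended for mixed-unit features.
#' @return An object of class `ecg_kmeans`: list with `centers`
#'   (k x p matrix, on the clustering scale), `cluster` (assignments),
#'   `sse` (E), `sse_path`, `iter`, `k`, `ids`, `standardized`.
#' @export
kmeans_lloyd <- function(features, k, seed = 1, max_iter = 300, tol = 1e-8,
                         nstart = 1, init = c("sample", "plusplus"),
                         init_idx = NULL, standardize = FALSE) {
  init <- match.arg(init)
  ids <- NULL
  if (is.data.frame(features)) {
    if ("id" %in% names(features) && !is.numeric(features$id)) {
      ids <- as.character(features$id)
      features <- features[, setdiff(names(features), "id"), drop = FALSE]
    }
    features <- as.matrix(features)
  }
  x <- unname(as.matrix(features))
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (k < 1) rlang::abort("k must be >= 1")
  if (k > n) rlang::abort(sprintf("k = %d exceeds number of rows (%d)", k, n))
  if (anyNA(x)) rlang::abort("features must not contain missing values")
  if (standardize) x <- standardize_columns(x)
  best <- NULL
  if (!is.null(init_idx)) {
    if (length(init_idx) != k || anyDuplicated(init_idx) ||
        any(init_idx < 1 | init_idx > n)) {
      rlang::abort("`init_idx` must be k distinct row indices")
    }
    best <- lloyd_once(x, k, as.integer(init_idx), max_iter, tol)
  } else {
    with_seed(seed, {
      for (s in seq_len(nstart)) {
        start_idx <- if (init == "sample") sample.int(n, k) else kpp_seed(x, k)
        fit <- lloyd_once(x, k, start_idx, max_iter, tol)
        if (is.null(best) || fit$sse < best$sse) best <- fit
      }
    })
  }
  structure(list(centers = best$centers, cluster = best$cluster,
                 sse = best$sse, sse_path = best$sse_path, iter = best$iter,
                 withinss = best$withinss, k = k, seed = seed, ids = ids,
                 standardized = standardize),
            class = "ecg_kmeans")
}

# k-means++ style distance-weighted seeding
kpp_seed <- function(x, k) {
  n <- nrow(x)
  idx <- sample.int(n, 1)
  while (length(idx) < k) {
    d2 <- dist2_to_centers(x, x[idx, , drop = FALSE])
    nearest <- apply(d2, 1, min)
    nearest[idx] <- 0
    if (sum(nearest) == 0) {
      idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    } else {
      idx <- c(idx, sample.int(n, 1, prob = nearest / sum(nearest)))
    }
  }
  idx
}

# z-score columns; all-constant columns map to zero
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  scale(x, center = mu, scale = sd)[, , drop = FALSE]
}

#' @export
print.ecg_kmeans <- function(x, ...) {
  cat(sprintf("<ecg_kmeans> k=%d, n=%d, E=%.6g, %d iteration(s)\n",
              x$k, length(x$cluster), x$sse, x$iter))
  cat("cluster sizes:", tabulate(x$cluster, x$k), "\n")
  invisible(x)
}

#' Tidy a k-means fit: one row per cluster
#'
#' @param x An `ecg_kmeans` object.
#' @param ... Unused.
#' @return A tibble with `cluster`, `size` and `withinss`.
#' @method tidy ecg_kmeans
#' @export
tidy.ecg_kmeans <- function(x, ...) {
  tibble::tibble(
    cluster = seq_len(x$k),
    size = tabulate(x$cluster, x$k),
    withinss = x$withinss
  )
}

#' One-row summary of a k-means fit
#'
#' @param x An `ecg_kmeans` object.
#' @param ... Unused.
#' @return A tibble with `k`, `sse`, `iter`, `n`.
#' @method glance ecg_kmeans
#' @export
glance.ecg_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, sse = x$sse, iter = x$iter,
                 n = length(x$cluster))
}

#' Attach cluster assignments to data
#'
#' @param x An `ecg_kmeans` object.
#' @param data Data frame with rows in the clustering order (optional; if
#'   omitted and the fit carries ids, those are returned).
#' @param ... Unused.
#' @return `data` (or an id tibble) with a `.cluster` factor column.
#' @method augment ecg_kmeans
#' @export
augment.ecg_kmeans <- function(x, data = NULL, ...) {
  cl <- factor(x$cluster, levels = seq_len(x$k))
  if (is.null(data)) {
    data <- tibble::tibble(id = x$ids %||% seq_along(x$cluster))
  }
  if (nrow(data) != length(x$cluster)) {
    rlang::abort("`data` must have one row per clustered subject")
  }
  dplyr::mutate(tibble::as_tibble(data), .cluster = cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
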