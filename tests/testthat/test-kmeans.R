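test_that("euclidean distance is the plain L2 norm", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(1:4, 1:4), 0)
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
    expect_equal(euclidean_distance(a, b), sqrt(sum((a - b)^2)))
  }
  expect_error(euclidean_distance(1:3, 1:4), "dimension mismatch")
})

test_that("closed-form cases: k = 1 mean center, k = n zero error", {
  set.seed(11)
  x <- matrix(rnorm(40), 10, 4)
  f1 <- kmeans_lloyd(x, 1, seed = 1)
  expect_equal(as.numeric(f1$centers), colMeans(x))
  expect_equal(f1$sse, sum(scale(x, scale = FALSE)^2))

  fn <- kmeans_lloyd(x, 10, seed = 2, nstart = 20)
  expect_equal(fn$sse, 0, tolerance = 1e-12)

  expect_error(kmeans_lloyd(x, 11, seed = 1), "exceeds")
  expect_error(kmeans_lloyd(x, 0, seed = 1), "k must be")
})

test_that("two well-separated blobs are recovered at the brute-force optimum", {
  set.seed(21)
  x <- rbind(matrix(rnorm(6, 0, 0.2), 3, 2), matrix(rnorm(6, 10, 0.2), 3, 2))
  fit <- kmeans_lloyd(x, 2, seed = 5, nstart = 10)
  expect_equal(sort(tabulate(fit$cluster, 2)), c(3, 3))
  expect_true(length(unique(fit$cluster[1:3])) == 1)
  expect_true(length(unique(fit$cluster[4:6])) == 1)
  expect_equal(fit$sse, kmeans_bruteforce(x, 2), tolerance = 1e-9)
})

test_that("E is non-increasing across Lloyd iterations", {
  set.seed(31)
  for (rep in 1:10) {
    x <- matrix(rnorm(60 * 3), 60, 3)
    fit <- kmeans_lloyd(x, sample(2:5, 1), seed = rep)
    expect_true(all(diff(fit$sse_path) <= 1e-9),
                label = sprintf("rep %d monotone E", rep))
  }
})

test_that("final centers are the means of their members", {
  set.seed(41)
  x <- matrix(rnorm(50 * 2), 50, 2)
  fit <- kmeans_lloyd(x, 4, seed = 3, nstart = 5)
  for (j in seq_len(4)) {
    members <- x[fit$cluster == j, , drop = FALSE]
    expect_equal(as.numeric(fit$centers[j, ]), colMeans(members),
                 tolerance = 1e-9)
  }
  # E equals the objective evaluated on the final state
  e <- sum(vapply(seq_len(4), function(j) {
    m <- fit$cluster == j
    sum((x[m, , drop = FALSE] -
           matrix(fit$centers[j, ], sum(m), 2, byrow = TRUE))^2)
  }, numeric(1)))
  expect_equal(fit$sse, e, tolerance = 1e-12)
})

test_that("seeded runs are deterministic; stats::kmeans agrees as cross-check", {
  set.seed(51)
  x <- matrix(rnorm(200), 50, 4)
  f1 <- kmeans_lloyd(x, 3, seed = 9, nstart = 10)
  f2 <- kmeans_lloyd(x, 3, seed = 9, nstart = 10)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$sse, f2$sse)
  ref <- stats::kmeans(x, 3, nstart = 25, iter.max = 100)
  expect_equal(f1$sse, ref$tot.withinss, tolerance = 0.02)
})

test_that("standardized clustering is invariant to per-column affine maps", {
  set.seed(61)
  x <- cbind(rnorm(40), rnorm(40, 0, 100), rnorm(40, 50, 0.01))
  y <- sweep(sweep(x, 2, c(2, 0.01, 300), `*`), 2, c(5, -3, 40), `+`)
  fx <- kmeans_lloyd(x, 3, seed = 4, nstart = 10, standardize = TRUE)
  fy <- kmeans_lloyd(y, 3, seed = 4, nstart = 10, standardize = TRUE)
  expect_identical(fx$cluster, fy$cluster)
  expect_equal(fx$sse, fy$sse, tolerance = 1e-9)
})

test_that("broom-style accessors expose the fit", {
  set.seed(71)
  x <- tibble::as_tibble(matrix(rnorm(30), 10, 3), .name_repair = "unique")
  x <- dplyr::bind_cols(tibble::tibble(id = sprintf("s%d", 1:10)), x)
  fit <- kmeans_lloyd(x, 2, seed = 1, nstart = 5)
  td <- generics::tidy(fit)
  expect_equal(sum(td$size), 10)
  expect_equal(sum(td$withinss), fit$sse, tolerance = 1e-12)
  gl <- generics::glance(fit)
  expect_equal(gl$k, 2)
  ag <- generics::augment(fit)
  expect_equal(nrow(ag), 10)
  expect_true(all(levels(ag$.cluster) == c("1", "2")))
  expect_identical(ag$id, sprintf("s%d", 1:10))
})
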