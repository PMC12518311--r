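test_that("largest-remainder apportionment is exact", {
  expect_identical(largest_remainder_allocation(c(60, 40), 50), c(30L, 20L))
  expect_identical(sum(largest_remainder_allocation(c(7, 5, 3), 10)), 10L)
  alloc <- largest_remainder_allocation(c(1, 1, 100), 3)
  expect_true(all(alloc <= c(1, 1, 100)))
  expect_identical(sum(alloc), 3L)
})

test_that("cluster balancing selects within the majority class, exactly to size", {
  sim <- simulate_fingerprint_dataset(90, 30, n_majority_clusters = 3,
                                      seed = 5)
  maj <- sim$bits[sim$labels == 1, ]
  sel <- balance_by_clustering(maj, 30, seed = 5)
  expect_length(sel, 30L)
  expect_identical(anyDuplicated(sel), 0L)
  expect_true(all(sel >= 1 & sel <= nrow(maj)))
  expect_identical(attr(sel, "k_star"), 3L)
  expect_identical(sum(attr(sel, "allocation")), 30L)
  # size contract at the tightest margin
  tight <- balance_by_clustering(maj[1:31, ], 30, seed = 5)
  expect_length(tight, 30L)
  # rejections and degenerate fallback
  expect_error(balance_by_clustering(maj, 1, seed = 1), "at least 2")
  expect_error(balance_by_clustering(maj[1:10, ], 30, seed = 1), "larger")
  flat <- matrix(1L, nrow = 20, ncol = 16)
  fb <- balance_by_clustering(flat, 5, seed = 1)
  expect_length(fb, 5L)
  expect_true(attr(fb, "fallback"))
})

test_that("silhouette scan recovers the planted cluster count", {
  hits <- vapply(1:3, function(s) {
    sim <- simulate_fingerprint_dataset(120, 40, n_majority_clusters = 3,
                                        seed = 200 + s)
    sel <- balance_by_clustering(sim$bits[sim$labels == 1, ], 40, seed = s)
    attr(sel, "k_star") == 3L
  }, logical(1))
  expect_true(all(hits))
})

test_that("splits honor the 60/20/20 ratios within one compound", {
  p100 <- split_dataset(100, seed = 1)
  expect_identical(as.integer(table(p100)), c(60L, 20L, 20L))
  p101 <- split_dataset(101, seed = 1)
  tab <- table(p101)
  expect_identical(sum(tab), 101L)
  expect_true(all(abs(tab - 101 * c(0.6, 0.2, 0.2)) <= 1))
  expect_identical(split_dataset(57, seed = 9), split_dataset(57, seed = 9))
  expect_error(split_dataset(9), "at least 10")
})

test_that("variance filter removes constant and rare columns by p(1-p)", {
  X <- cbind(
    rep(0L, 100),                      # constant: variance 0
    rep(c(1L, 0L), c(10, 90)),         # p = 0.10 -> 0.09, kept
    rep(c(1L, 0L), c(5, 95)),          # p = 0.05 -> 0.0475, removed
    rep(c(1L, 0L), c(50, 50))          # p = 0.50 -> 0.25, kept
  )
  kept <- variance_filter(X)
  expect_identical(kept, c(2L, 4L))
  expect_error(variance_filter(matrix(0L, 10, 3)), "every column")
})

test_that("applicability domain matches explicit matrix arithmetic on a toy case", {
  set.seed(42)
  X <- matrix(rnorm(20), nrow = 5, ncol = 4)
  ad <- fit_applicability_domain(X)
  # oracle: eigen decomposition of the covariance, by hand
  ctr <- colMeans(X)
  eg <- eigen(stats::cov(X), symmetric = TRUE)
  cum <- cumsum(eg$values) / sum(eg$values)
  nc <- which(cum > 0.9)[1]
  expect_identical(ad$n_components, nc)
  scores <- sweep(X, 2, ctr) %*% eg$vectors[, 1:nc, drop = FALSE]
  d_train <- sqrt(rowSums(sweep(scores, 2, colMeans(scores))^2))
  expect_equal(ad$max_distance, max(d_train), tolerance = 1e-10)
  # displaced query: distance agrees with the hand computation
  q <- matrix(ctr + 10 * eg$vectors[, 1], nrow = 1)
  res <- apply_applicability_domain(ad, q)
  qs <- sweep(q, 2, ctr) %*% eg$vectors[, 1:nc, drop = FALSE]
  expect_equal(res$distance,
               sqrt(sum((qs - colMeans(scores))^2)), tolerance = 1e-8)
  expect_false(res$in_domain)
  # the training mean projects to the centroid: distance 0, in-domain
  ctr_res <- apply_applicability_domain(ad, matrix(ctr, nrow = 1))
  expect_equal(ctr_res$distance, 0, tolerance = 1e-10)
  expect_true(ctr_res$in_domain)
  expect_error(apply_applicability_domain(ad, matrix(0, 1, 3)), "columns")
})

test_that("every training compound is in its own domain; decisions ignore row order", {
  sim <- simulate_fingerprint_dataset(40, 40, seed = 8)
  ds <- build_dataset(sim$bits, sim$labels, seed = 8)
  tr <- ds$partition == "train"
  expect_true(all(ds$in_domain[tr]))
  q <- sim$bits[, ds$kept_columns, drop = FALSE]
  fwd <- apply_applicability_domain(ds$ad, q)
  rev <- apply_applicability_domain(ds$ad, q[nrow(q):1, , drop = FALSE])
  expect_identical(fwd$in_domain, rev$in_domain[nrow(q):1])
})

test_that("a dataset bundle round-trips through its text serialization", {
  sim <- simulate_fingerprint_dataset(30, 30, n_bits = 64, seed = 4)
  ds <- build_dataset(sim$bits, sim$labels, cell_line = "AGS", seed = 4)
  dir <- tempfile("bundle")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  save_dataset(ds, dir)
  back <- load_dataset(dir)
  expect_identical(back$bits, ds$bits)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$partition, ds$partition)
  expect_identical(back$kept_columns, ds$kept_columns)
  expect_equal(back$ad$max_distance, ds$ad$max_distance, tolerance = 1e-12)
  q <- ds$bits[, ds$kept_columns, drop = FALSE]
  expect_equal(apply_applicability_domain(back$ad, q)$distance,
               apply_applicability_domain(ds$ad, q)$distance,
               tolerance = 1e-9)
})
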