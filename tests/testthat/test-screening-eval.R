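test_that("RIE and BEDROC match brute-force exponential sums on small lists", {
  cases <- list(
    list(ranks = c(1L, 5L), N = 10L, alpha = 20),
    list(ranks = c(2L, 3L, 9L), N = 12L, alpha = 8),
    list(ranks = c(1L, 2L, 19L, 20L), N = 20L, alpha = 160.9),
    list(ranks = c(4L, 8L, 15L), N = 18L, alpha = 1.5)
  )
  for (cs in cases) {
    scr <- screen_from_ranks(cs$ranks, cs$N)
    expect_equal(rie(scr, cs$alpha), oracle_rie(cs$ranks, cs$N, cs$alpha),
                 tolerance = 1e-9)
    expect_equal(bedroc(scr, cs$alpha),
                 oracle_bedroc(cs$ranks, cs$N, cs$alpha), tolerance = 1e-9)
  }
})

test_that("BEDROC attains 1 and 0 at the perfect and worst rankings", {
  top <- screen_from_ranks(1:4, 20)
  bottom <- screen_from_ranks(17:20, 20)
  for (a in c(5, 20, 160.9)) {
    expect_equal(bedroc(top, a), 1, tolerance = 1e-9)
    expect_equal(bedroc(bottom, a), 0, tolerance = 1e-9)
  }
})

test_that("BEDROC stays in [0,1] and improves when an active moves up", {
  set.seed(3)
  for (rep in 1:20) {
    N <- sample(10:60, 1)
    n <- sample(2:(N - 2), 1)
    ranks <- sort(sample.int(N, n))
    b <- bedroc(screen_from_ranks(ranks, N), 20)
    expect_gte(b, 0); expect_lte(b, 1)
    # exchange an active with the inactive directly above it
    movable <- ranks[ranks > 1 & !(ranks - 1) %in% ranks]
    if (length(movable)) {
      r2 <- sort(c(setdiff(ranks, movable[1]), movable[1] - 1L))
      expect_gt(bedroc(screen_from_ranks(r2, N), 20), b)
    }
  }
})

test_that("metrics are invariant to strictly monotone score transforms", {
  set.seed(11)
  scores <- rnorm(50)
  labels <- rbinom(50, 1, 0.3)
  labels[1] <- 1L; labels[2] <- 0L
  s1 <- ranked_screen(scores, labels)
  s2 <- ranked_screen(exp(scores) + 5, labels)
  expect_equal(bedroc(s1, 20), bedroc(s2, 20), tolerance = 1e-12)
  expect_equal(enrichment_factor(s1, 0.1), enrichment_factor(s2, 0.1))
})

test_that("alpha calibration inverts the exponential weight-mass relation", {
  expect_equal(alpha_for_mass_fraction(0.01, 0.8), 160.9, tolerance = 0.05)
  expect_equal(alpha_for_mass_fraction(0.5, 1 - exp(-1)), 2, tolerance = 1e-12)
  expect_equal(alpha_for_mass_fraction(0.05, 0.8), 32.19, tolerance = 0.005)
  # mutual inverses to 1e-9 across a grid
  for (chi in c(0.005, 0.01, 0.1, 0.5)) {
    for (mass in c(0.2, 0.5, 0.8, 0.99)) {
      a <- alpha_for_mass_fraction(chi, mass)
      expect_equal(mass_fraction_for_alpha(a, chi), mass, tolerance = 1e-9)
    }
  }
  expect_error(alpha_for_mass_fraction(0, 0.8), "chi")
  expect_error(alpha_for_mass_fraction(0.01, 1), "mass")
})

test_that("enrichment factor counts the top window per its definition", {
  # all actives inside the window: forced maximum 1/chi
  scr <- screen_from_ranks(1:5, 100)
  expect_equal(enrichment_factor(scr, 0.1), 10)
  # none inside
  expect_equal(enrichment_factor(screen_from_ranks(96:100, 100), 0.05), 0)
  # the published screening composition: 14 of 86 actives in the top 1%
  # of 4,535 ranked molecules
  set.seed(1)
  ranks <- c(sort(sample(1:45, 14)), sort(sample(46:4535, 72)))
  scr <- screen_from_ranks(ranks, 4535L)
  expect_equal(enrichment_factor(scr, 0.01), 14 / (0.01 * 86),
               tolerance = 1e-12)
  expect_equal(round(enrichment_factor(scr, 0.01), 2), 16.28)
  expect_error(enrichment_factor(scr, 0), "chi")
  expect_error(enrichment_factor(screen_from_ranks(2, 10), 0.05), "window")
})

test_that("tie handling is seeded and unbiased in expectation", {
  # heavy ties: constant scores = pure random ranking
  labels <- c(rep(1L, 10), rep(0L, 190))
  scr <- ranked_screen(rep(0, 200), labels)
  efs <- vapply(1:200, function(s) enrichment_factor(scr, 0.1, tie_seed = s),
                numeric(1))
  expect_equal(mean(efs), 1, tolerance = 0.15)
  expect_identical(enrichment_factor(scr, 0.1, tie_seed = 4),
                   enrichment_factor(scr, 0.1, tie_seed = 4))
})

test_that("the screening ledger merge deduplicates by key", {
  evaluation <- data.frame(key = sprintf("K%04d", 1:178),
                           label = rep(c(1L, 0L), c(86, 92)))
  decoys <- data.frame(key = sprintf("D%04d", 1:4357))
  ledger <- build_screening_ledger(evaluation, decoys)
  expect_identical(nrow(ledger), 4535L)
  expect_identical(sum(ledger$label), 86L)
  # overlapping keys keep the evaluation entry
  decoys2 <- data.frame(key = c("K0001", sprintf("D%04d", 1:50)))
  l2 <- build_screening_ledger(evaluation, decoys2)
  expect_identical(nrow(l2), 178L + 50L)
  expect_identical(l2$origin[l2$key == "K0001"], "evaluation")
})

test_that("combination search enumerates every family choice and favors the planted better family", {
  cells <- list(
    A = cell_line_setup("A", seed = 71),
    B = cell_line_setup("B", seed = 72)
  )
  # replace one family in each cell line by a no-signal model (trained on
  # permuted labels) so the planted ranking is known
  for (cl in names(cells)) {
    ds <- cells[[cl]]$dataset
    bad <- ds
    set.seed(1000)
    bad$labels <- sample(bad$labels)
    cells[[cl]]$models$KNN <- train_model(model_spec("KNN", 30:40, seed = 1),
                                          bad)
  }
  scr <- simulate_fingerprint_dataset(30, 90, seed = 99)
  cs <- combination_search(cells, scr$bits, scr$labels,
                           alpha_grid = c(20, 160.9), chi_grid = c(0.05, 0.1))
  expect_length(cs$results, 16L)  # 4 families ^ 2 cell lines
  choices <- vapply(cs$results, function(r)
    paste(r$choice, collapse = "+"), character(1))
  expect_identical(anyDuplicated(choices), 0L)
  # the all-degraded combination must rank below the best
  worst <- which(choices == "KNN+KNN")
  expect_gt(cs$results[[1]]$anchor_bedroc,
            cs$results[[worst]]$anchor_bedroc)
  # identical per-cell probabilities average to themselves
  one <- cs$results[[1]]$consensus_scores
  expect_true(all(one >= 0 & one <= 1))
})

test_that("consensus hit intersection matches brute-force set arithmetic", {
  set.seed(5)
  keys <- sprintf("C%04d", 1:1000)
  a <- stats::setNames(runif(1000), keys)
  b <- stats::setNames(runif(1000), sample(keys))
  out <- select_consensus_hits(a, b, thresholds = c(0.5, 0.55, 0.6))
  for (t in c("0.5", "0.55", "0.6")) {
    tt <- as.numeric(t)
    brute <- intersect(names(a)[a > tt], names(b)[b > tt])
    expect_setequal(out$hits[[t]], brute)
  }
  expect_identical(out$counts$n_both,
                   unname(vapply(out$hits, length, integer(1))))
  # disjoint exceedance sets give an empty intersection
  a2 <- stats::setNames(c(0.9, 0.1), c("x", "y"))
  b2 <- stats::setNames(c(0.1, 0.9), c("x", "y"))
  expect_length(select_consensus_hits(a2, b2, 0.5)$hits[["0.5"]], 0L)
  # one model entirely below the smallest threshold empties everything
  b3 <- stats::setNames(c(0.2, 0.3), c("x", "y"))
  expect_length(select_consensus_hits(a2, b3, 0.5)$hits[["0.5"]], 0L)
  expect_error(select_consensus_hits(a2, stats::setNames(0.5, "z")),
               "universe")
})
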