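test_that("features are volume fractions with fixed components dropped", {
  specs <- list(component_spec("A", 100), component_spec("B", 200),
                component_spec("H", 1000, fixed_value = 100))
  expect_equal(normalize_features(c(A = 100, B = 0, H = 100), specs)[1, ],
               c(A = 1, B = 0))
  # a level at 100% of standard when the max sits at 125% maps to 0.8
  expect_equal(unname(normalize_features(c(A = 80, B = 50, H = 100), specs)[1, 1]),
               0.8)
  expect_error(normalize_features(c(A = 120, B = 0, H = 100), specs), "maximum")
})

test_that("expected improvement matches its closed form", {
  # deterministic limits
  expect_equal(expected_improvement(1, 0, y_best = 2, xi = 0), 0)
  expect_equal(expected_improvement(4, 0, y_best = 2, xi = 0), 2)
  # at the incumbent with unit sd: EI = dnorm(0)
  expect_equal(expected_improvement(2, 1, y_best = 2, xi = 0), dnorm(0),
               tolerance = 1e-12)
  # general closed form at a few points
  for (m in c(-1, 0, 2)) {
    z <- (m - 1) / 0.5
    expect_equal(expected_improvement(m, 0.5, y_best = 1, xi = 0),
                 (m - 1) * pnorm(z) + 0.5 * dnorm(z))
  }
  expect_error(expected_improvement(0, -1, 0), "non-negative")
})

test_that("EI is non-negative and monotone in the predictive mean", {
  set.seed(1)
  for (i in 1:20) {
    means <- sort(rnorm(50))
    sd <- runif(1, 0, 2)
    ei <- expected_improvement(means, rep(sd, 50), y_best = rnorm(1), xi = 0.01)
    expect_true(all(ei >= 0))
    expect_true(all(diff(ei) >= -1e-12))
  }
})

test_that("candidate pools are unique, grid-valid, reproducible, and exhaust", {
  specs <- eu_specs()
  p1 <- generate_candidate_pool(specs, size = 1000, seed = 7)
  p2 <- generate_candidate_pool(specs, size = 1000, seed = 7)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 1000)
  expect_equal(anyDuplicated(p1), 0)
  for (s in specs) expect_true(all(p1[[s$name]] %in% s$grid))

  tiny <- tiny_specs()   # 3 x 3 = 9 compositions
  tested <- generate_candidate_pool(tiny, size = 4, seed = 1)
  rest <- generate_candidate_pool(tiny, size = 1000, exclude = tested, seed = 2)
  expect_equal(nrow(rest), 5)
  expect_equal(anyDuplicated(rbind(tested, rest)), 0)
  expect_error(generate_candidate_pool(tiny, size = 10,
                                       exclude = rbind(tested, rest)),
               "exhausted")
})

test_that("top-n selection is a stable EI sort", {
  pool <- data.frame(A = 1:6)
  ei <- c(0.5, 0.9, 0.5, 0.1, 0.9, 0.2)
  expect_equal(select_val(pool, ei, 3), c(2, 5, 1))
  expect_equal(select_val(pool, rep(1, 6), 4), 1:4)     # ties: pool order
  expect_setequal(select_val(pool, ei, 6), 1:6)
  expect_error(select_val(pool, ei, 7), "pool")
  # matches a brute-force sort on random pools
  set.seed(3)
  for (i in 1:10) {
    e <- runif(50)
    expect_equal(select_val(data.frame(x = 1:50), e, 10),
                 order(-e)[1:10])
  }
})

test_that("average-linkage clustering agrees with brute-force agglomeration", {
  set.seed(11)
  for (i in 1:8) {
    n <- sample(5:10, 1)
    X <- matrix(runif(2 * n), n, 2)
    k <- sample(2:(n - 1), 1)
    expect_true(same_partition(hac_average_linkage(X, k),
                               brute_force_hac_average(X, k)),
                info = sprintf("case %d (n=%d, k=%d)", i, n, k))
  }
  X <- matrix(runif(10), 5, 2)
  expect_equal(sort(unique(hac_average_linkage(X, 5))), 1:5)  # singletons
  expect_equal(unique(hac_average_linkage(X, 1)), 1)          # one cluster
  expect_error(hac_average_linkage(X, 0), "at least 1")
})

test_that("cluster-margin serves smaller buckets first, round-robin", {
  # 6 kept candidates in 3 clusters of sizes 1 / 2 / 3, batch of 3:
  # exactly one point per bucket, smallest bucket first
  X <- rbind(c(0, 0),                       # cluster 1 (size 1)
             c(0.5, 0.5), c(0.5, 0.52),     # cluster 2 (size 2)
             c(1, 1), c(1, 0.98), c(0.98, 1))  # cluster 3 (size 3)
  pool <- data.frame(A = 1:6)
  ei <- c(0.1, 0.6, 0.5, 0.9, 0.8, 0.7)
  sel <- select_cluster_margin(pool, ei, X, m_top = 6, n_batch = 3, k = 3)
  expect_length(sel, 3)
  expect_equal(sel[1], 1)          # singleton bucket served first
  expect_equal(sel[2], 2)          # best-EI member of the pair
  expect_equal(sel[3], 4)          # best-EI member of the triple
})

test_that("cluster-margin degenerates to top-n with one bucket and covers all buckets before repeats", {
  X_one <- matrix(rep(c(0.5, 0.5), each = 6), 6, 2) +
    matrix(runif(12, -0.01, 0.01), 6, 2)
  pool <- data.frame(A = 1:6)
  ei <- c(0.3, 0.9, 0.1, 0.8, 0.2, 0.4)
  sel <- select_cluster_margin(pool, ei, X_one, m_top = 6, n_batch = 3, k = 1)
  expect_equal(sort(sel), sort(select_val(pool, ei, 3)))

  # round-robin coverage: with n_batch >= #buckets every non-empty bucket
  # contributes before any bucket contributes twice
  set.seed(4)
  X <- matrix(runif(60), 30, 2)
  ei2 <- runif(30)
  k <- 5
  labels <- hac_average_linkage(X, k)
  sel2 <- select_cluster_margin(data.frame(A = 1:30), ei2, X,
                                m_top = 20, n_batch = 8, k = k)
  kept <- order(-ei2, 1:30)[1:20]
  nonempty <- unique(labels[kept])
  first_picks <- labels[sel2[seq_along(nonempty)]]
  expect_setequal(first_picks, nonempty)
  # per-bucket take is balanced after one full cycle
  takes <- table(labels[sel2])
  expect_lte(max(takes) - min(takes), ceiling(8 / length(nonempty)))
  expect_error(select_cluster_margin(data.frame(A = 1:30), ei2, X,
                                     m_top = 5, n_batch = 6), "m_top")
})

test_that("CM batches are always subsets of the VAL pre-selection", {
  specs <- eu_specs()
  pool <- generate_candidate_pool(specs, size = 200, seed = 5)
  X <- normalize_features(pool, specs)
  set.seed(5)
  ei <- runif(200)
  for (k in c(4, 10, 30)) {
    sel <- select_cluster_margin(pool, ei, X, m_top = 30, n_batch = 15, k = k)
    expect_length(sel, 15)
    expect_true(all(sel %in% select_val(pool, ei, 30)))
  }
})

test_that("convergence triggers on a plateau of best-so-far values", {
  expect_true(check_convergence(c(1, 5, 9, 9.05), tol = 0.01, patience = 1))
  expect_false(check_convergence(c(1, 2, 4, 8, 16), tol = 0.01, patience = 1))
  expect_false(check_convergence(5, tol = 0.01, patience = 1))
  expect_false(check_convergence(c(1, 5, 9, 9.05), tol = 0.01, patience = 3))
  expect_true(check_convergence(c(1, 9, 9.01, 9.02, 9.05), tol = 0.01, patience = 3))
})

test_that("propose_batch returns grid-valid untested compositions for all methods", {
  specs <- eu_specs()
  set.seed(6)
  tested <- generate_candidate_pool(specs, size = 30, seed = 6)
  y <- true_yield(tested, eu_landscape())
  for (m in c("VAL", "CM", "random")) {
    prop <- propose_batch(tested, y, specs, method = m, n_batch = 10,
                          m_top = 20, pool_size = 300, seed = 8)
    expect_equal(nrow(prop$batch), 10)
    expect_equal(anyDuplicated(rbind(tested, prop$batch)), 0)
    if (m != "random") expect_true(all(is.finite(prop$ei) & prop$ei >= 0))
  }
})
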