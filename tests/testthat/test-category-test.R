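test_that("genome rates are ratios of sums, not means of ratios", {
  one <- genome_rates(data.frame(gene_id = "g1", a = 2, A = 100, s = 3, S = 50))
  expect_equal(one$ka, 0.02)
  expect_equal(one$ks, 0.06)

  two <- genome_rates(data.frame(gene_id = c("g1", "g2"),
                                 a = c(1, 3), A = c(100, 100),
                                 s = c(1, 3), S = c(100, 100)))
  expect_equal(two$ka, 0.02)
  expect_equal(two$ks, 0.02)

  zero_a <- genome_rates(data.frame(gene_id = "g", a = 0, A = 10, s = 1, S = 10))
  expect_equal(zero_a$ka, 0)
  expect_error(genome_rates(data.frame(gene_id = "g", a = 1, A = 10, s = 0, S = 10)),
               "ks is zero")
})

test_that("expected non-synonymous proportion follows the rate-weighted sites", {
  counts <- tiny_counts()
  rates <- genome_rates(counts)
  # whole universe: P_A reduces to sum(a) / (sum(a) + sum(s))
  expect_equal(expected_nonsyn_proportion(sum(counts$A), sum(counts$S), rates),
               sum(counts$a) / (sum(counts$a) + sum(counts$s)))
  # equal rates: P_A is the site proportion
  eq <- structure(list(ka = 0.05, ks = 0.05), class = "genome_rates")
  expect_equal(expected_nonsyn_proportion(30, 70, eq), 0.3)
  # direct evaluation
  r <- structure(list(ka = 0.02, ks = 0.06), class = "genome_rates")
  expect_equal(expected_nonsyn_proportion(200, 100, r), 0.4)
})

test_that("binomial tails hit their closed-form anchors", {
  expect_equal(tail_probability(0, 5, 0.3, "rapid"), 1)
  expect_equal(tail_probability(2, 0, 0.5, "rapid"), 0.25)
  expect_equal(tail_probability(3, 0, 0.2, "slow"), 1)
  expect_warning(deg <- tail_probability(2, 1, 0, "rapid"), "degenerate")
  expect_equal(deg, 0)
  expect_error(tail_probability(-1, 2, 0.5, "rapid"), "non-negative")
  expect_error(tail_probability(0, 0, 0.5, "rapid"), "positive")
})

test_that("incomplete-beta tails equal direct summation at integer counts", {
  set.seed(11)
  for (k in 1:200) {
    a <- sample(0:150, 1)
    s <- sample(0:150, 1)
    if (a + s == 0) s <- 1
    p <- runif(1, 0.02, 0.98)
    expect_equal(tail_probability(a, s, p, "rapid"),
                 oracle_binom_tail(a, s, p, "rapid"), tolerance = 1e-10)
    expect_equal(tail_probability(a, s, p, "slow"),
                 oracle_binom_tail(a, s, p, "slow"), tolerance = 1e-10)
  }
})

test_that("both tails include the observed value and are monotone", {
  set.seed(12)
  for (k in 1:50) {
    n <- sample(5:120, 1)
    a <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95)
    up <- tail_probability(a, n - a, p, "rapid")
    lo <- tail_probability(a, n - a, p, "slow")
    expect_gte(up + lo, 1)
  }
  # p_rapid non-increasing in a at fixed total and expectation
  n <- 60; p <- 0.35
  pr <- tail_probability(0:n, n:0, p, "rapid")
  expect_true(all(diff(pr) <= 1e-12))
})

test_that("category testing sums members and drops genes without counts", {
  counts <- tiny_counts()
  rates <- genome_rates(counts)
  cats <- structure(list(all = c("g1", "g2", "g3"),
                         dup = c("g1", "g2", "g3"),
                         short = c("g1", "g2", "ghost")),
                    class = "go_categories", min_genes = 3L)
  expect_message(res <- test_categories(counts, cats, rates), "without a counts")
  # the ghost gene shrinks 'short' below min_genes: dropped
  expect_setequal(res$term_id, c("all", "dup"))
  whole <- res[res$term_id == "all", ]
  expect_equal(whole$a_C, sum(counts$a))
  expect_equal(whole$s_C, sum(counts$s))
  expect_gt(whole$p_rapid, 0)
  expect_lt(whole$p_rapid, 1)
  # identical membership, identical result
  dup <- res[res$term_id == "dup", -1]
  rownames(dup) <- rownames(whole) <- NULL
  expect_equal(dup, whole[-1])
})

test_that("outlier counting uses a strict threshold", {
  res <- data.frame(p_rapid = c(0.05, 0.049, 0.2), p_slow = c(0.5, 0.5, 0.04))
  expect_equal(count_outliers(res, 0.05, "rapid"), 1L)
  expect_equal(count_outliers(res, 0.05, "slow"), 1L)
  expect_equal(count_outliers(data.frame(p_rapid = rep(0.01, 3),
                                         p_slow = rep(0.01, 3)), 0.01, "rapid"), 0L)
  expect_equal(count_outliers(res[0, ], 0.05, "rapid"), 0L)
})

test_that("the permutation fast path equals the naive permute-and-retest route", {
  set.seed(33)
  n <- 40
  genes <- sprintf("g%02d", 1:n)
  counts <- data.frame(gene_id = genes,
                       a = rpois(n, 6), A = runif(n, 200, 400),
                       s = rpois(n, 10), S = runif(n, 100, 200))
  sets <- lapply(1:n, function(i) {
    if (i <= 12) "GO:P" else if (i <= 20) c("GO:P", "GO:Q") else
      if (i <= 32) "GO:Q" else character()
  })
  ann <- go_annotation(setNames(sets, genes), genes)
  thresholds <- c(0.5, 0.2, 0.05)
  seed <- 909
  fast <- permutation_null(counts, ann, thresholds, n_permutations = 25,
                           seed = seed, min_genes = 5)
  pc <- attr(fast, "perm_counts")

  # replay the same RNG stream through the naive route
  set.seed(seed)
  perms <- replicate(25, sample.int(n), simplify = FALSE)
  rates <- genome_rates(counts)
  grid <- expand.grid(direction = c("rapid", "slow"), threshold = thresholds,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$direction, -grid$threshold), ]
  for (r in seq_along(perms)) {
    sets_p <- ann$sets[perms[[r]]]
    names(sets_p) <- genes
    ann_p <- go_annotation(sets_p, genes)
    res_p <- test_categories(counts, build_categories(ann_p, 5), rates)
    for (k in seq_len(nrow(grid))) {
      expect_equal(pc[r, k],
                   count_outliers(res_p, grid$threshold[k], grid$direction[k]))
    }
  }
})

test_that("permutation null is reproducible and degenerate on one gene", {
  counts <- tiny_counts()
  ann <- go_annotation(list(g1 = "T1", g2 = c("T1", "T2"), g3 = "T2"),
                       counts$gene_id)
  a <- permutation_null(counts, ann, c(0.3, 0.1), n_permutations = 50,
                        seed = 5, min_genes = 1)
  b <- permutation_null(counts, ann, c(0.3, 0.1), n_permutations = 50,
                        seed = 5, min_genes = 1)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "perm_counts"), attr(b, "perm_counts"))

  single <- permutation_null(counts[1, ], go_annotation(list(g1 = "T1"), "g1"),
                             0.5, n_permutations = 20, seed = 1, min_genes = 1)
  expect_true(all(single$global_p == 1))
  expect_equal(single$expected, single$observed)
})

test_that("exhaustive permutation matches direct enumeration of assignments", {
  counts <- tiny_counts()
  sets <- list(g1 = "T1", g2 = c("T1", "T2"), g3 = "T2")
  ann <- go_annotation(sets, counts$gene_id)
  thresholds <- c(0.4, 0.15)
  got <- permutation_null(counts, ann, thresholds, min_genes = 1,
                          exhaustive = TRUE)
  expect_equal(unique(got$n_permutations), 6L)

  # independent enumeration: every assignment of the three term sets
  rates <- genome_rates(counts)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  tally <- matrix(0, 6, 2 * length(thresholds))
  for (i in seq_along(perms)) {
    assigned <- sets[perms[[i]]]
    members <- function(term) {
      counts$gene_id[vapply(assigned, function(s) term %in% s, logical(1))]
    }
    col <- 0
    for (dir in c("rapid", "slow")) {
      for (t in sort(thresholds, decreasing = TRUE)) {
        col <- col + 1
        n_below <- 0
        for (term in c("T1", "T2")) {
          m <- match(members(term), counts$gene_id)
          a_C <- sum(counts$a[m]); s_C <- sum(counts$s[m])
          p_a <- rates$ka * sum(counts$A[m]) /
            (rates$ka * sum(counts$A[m]) + rates$ks * sum(counts$S[m]))
          p <- oracle_binom_tail(a_C, s_C, p_a, dir)
          if (p < t) n_below <- n_below + 1
        }
        tally[i, col] <- n_below
      }
    }
  }
  expect_equal(got$expected, colMeans(tally), tolerance = 1e-12)
})
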