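test_that("two-set intersection test reduces to the hypergeometric tail", {
  u <- sprintf("x%02d", 1:10)
  res <- multiset_intersection_test(list(u[1:5], u[2:5]), n_universe = 10)
  expect_equal(res$observed, 4)
  expect_equal(res$expected, 2.0)
  expect_equal(res$fold, 2.0)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)

  # fuzzed two-set instances agree with phyper to 1e-10 relative
  set.seed(31)
  for (i in 1:30) {
    N <- sample(20:200, 1)
    n1 <- sample.int(N, 1); n2 <- sample.int(N, 1)
    univ <- sprintf("e%03d", 1:N)
    s1 <- sample(univ, n1); s2 <- sample(univ, n2)
    obs <- length(intersect(s1, s2))
    got <- multiset_intersection_test(list(s1, s2), N)$p
    ref <- stats::phyper(obs - 1, n1, N - n1, n2, lower.tail = FALSE)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("multi-set p is monotone in the observed overlap", {
  # p computed at each possible observed value by reusing the exact null
  N <- 40; sizes <- c(15, 12, 10)
  univ <- sprintf("e%02d", 1:N)
  base <- lapply(sizes, function(k) univ[1:k])
  ps <- vapply(0:8, function(obs) {
    # construct sets with exactly `obs` common elements
    s <- list(univ[1:15],
              c(univ[seq_len(obs)], univ[16:(16 + 12 - obs - 1)]),
              c(univ[seq_len(obs)], univ[(28):(28 + 10 - obs - 1)]))
    multiset_intersection_test(s, N)$p
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("three-set test matches a direct Monte-Carlo oracle", {
  N <- 30; sizes <- c(12, 10, 8)
  univ <- sprintf("e%02d", 1:N)
  sets <- list(univ[1:12], univ[c(1:6, 13:16)], univ[c(1:6, 17, 18)])
  res <- multiset_intersection_test(sets, N)
  expect_equal(res$observed, 6)
  n_draws <- 200000
  p_mc <- mc_multiset_tail(sizes, N, res$observed, n_draws, seed = 11)
  se <- sqrt(p_mc * (1 - p_mc) / n_draws)
  expect_lt(abs(res$p - p_mc), 3 * se)
})

test_that("multiset test validates its inputs", {
  expect_error(multiset_intersection_test(list(c("a", "b")), 10))
  expect_error(multiset_intersection_test(list("a", "b"), 0),
               "positive")
  expect_error(
    multiset_intersection_test(list(c("a", "z"), c("a")),
                               universe = c("a", "b")),
    "not contained")
  # observed == expected gives fold 1
  u <- sprintf("x%02d", 1:16)
  res <- multiset_intersection_test(list(u[1:8], u[c(1:4, 9:12)]), 16)
  expect_equal(res$fold, 1)
})

test_that("observed/expected chi-square matches the closed forms", {
  res <- observed_expected_chi2(matrix(c(30, 70, 10, 190), 2, byrow = TRUE))
  expect_equal(res$expected[1, 1], 40 * 100 / 300, tolerance = 1e-12)
  expect_equal(res$oe_ratio, 30 / (40 * 100 / 300), tolerance = 1e-12)
  expect_equal(res$chi2, 36.05625, tolerance = 1e-4)

  flat <- observed_expected_chi2(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$oe_ratio, 1)

  set.seed(5)
  for (i in 1:40) {
    tab <- matrix(as.numeric(sample(1:200, 4, replace = TRUE)), 2)
    got <- observed_expected_chi2(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    ref <- (a * d - b * c_)^2 * n /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(got$chi2, ref, tolerance = 1e-10)
    ref_test <- stats::chisq.test(tab, correct = FALSE)
    expect_equal(got$chi2, unname(ref_test$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref_test$p.value, tolerance = 1e-10)
    # simultaneous row+column swap leaves chi2 unchanged
    swapped <- observed_expected_chi2(tab[2:1, 2:1])
    expect_equal(swapped$chi2, got$chi2, tolerance = 1e-12)
  }
  expect_error(observed_expected_chi2(matrix(c(0, 0, 3, 4), 2,
                                             byrow = TRUE)),
               "zero margin")
})

test_that("over-representation test follows the hypergeometric closed form", {
  univ <- sprintf("u%02d", 1:20)
  res <- ora_test(univ[1:5], univ[1:5], univ)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)

  all_in <- ora_test(univ, univ, univ)
  expect_equal(all_in$overlap, 20)
  expect_equal(all_in$p, 1)

  none <- ora_test(univ[1:5], univ[6:10], univ)
  expect_equal(none$overlap, 0)
  expect_equal(none$fold, 0)
  expect_equal(none$p, 1)

  expect_error(ora_test("a", "a", character()), "empty universe")
  coll <- list(A = univ[1:5], B = univ[6:15])
  tab <- ora_collection(univ[1:5], coll, univ)
  expect_equal(tab$adj_p, bh_adjust(tab$p))
})

test_that("enrichment score matches the hand-computed running sum", {
  scores <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2)
  res <- gsea_preranked(scores, c("g1", "g2"), n_perm = 100, seed = 1)
  expect_equal(res$es, 1.0, tolerance = 1e-12)

  # negative-side set: hits at the bottom of the ranking
  res2 <- gsea_preranked(scores, c("g4", "g5"), n_perm = 100, seed = 1)
  expect_lt(res2$es, 0)

  # ES is invariant to a positive rescaling of the scores
  res3 <- gsea_preranked(scores * 7, c("g1", "g2"), n_perm = 100, seed = 1)
  expect_equal(res3$es, res$es, tolerance = 1e-12)

  # degenerate set covering the whole list
  allg <- gsea_preranked(scores, names(scores))
  expect_true(allg$degenerate)
  expect_equal(allg$es, 1)

  expect_error(gsea_preranked(scores, "absent"), "no genes")
})

test_that("enrichment scores agree with an independent implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  for (i in 1:20) {
    n <- 50
    scores <- sort(rnorm(n), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", 1:n)
    hit_idx <- sort(sample.int(n, 8))
    ours <- gsea_preranked(scores, names(scores)[hit_idx],
                           n_perm = 10, seed = 1)$es
    ref <- fgsea::calcGseaStat(scores, selectedStats = hit_idx,
                               gseaParam = 1)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("gsea p-values carry the +1 permutation correction", {
  set.seed(2)
  scores <- rnorm(100)
  names(scores) <- sprintf("g%03d", 1:100)
  res <- gsea_preranked(scores, names(scores)[1:10], n_perm = 200,
                        seed = 5)
  expect_gt(res$p, 0)
  expect_lte(res$p, 1)
})

test_that("spearman correlation matches hand and reference computations", {
  x <- 1:12
  expect_equal(spearman_cor(x, 2 * x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_equal(spearman_cor(x, 2 * x)$p, 0)

  # ranks of y are (2,1,4,3,5): sum(d^2) = 4, rho = 1 - 24/120 = 0.8
  hand <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(hand$rho, 0.8, tolerance = 1e-12)
  expect_equal(hand$method, "exact permutation")
  ref <- stats::cor.test(1:5, c(2, 1, 4, 3, 5), method = "spearman")
  expect_equal(hand$rho, unname(ref$estimate), tolerance = 1e-12)

  set.seed(3)
  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  ours <- spearman_cor(x2, y2)
  ref2 <- stats::cor.test(x2, y2, method = "spearman", exact = FALSE)
  expect_equal(ours$rho, unname(ref2$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref2$p.value, tolerance = 1e-6)

  expect_error(spearman_cor(rep(1, 10), 1:10), "constant")
  expect_error(spearman_cor(1:2, 1:2), "length")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_by_definition(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})
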