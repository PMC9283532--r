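test_that("segmentation separates well-separated blobs and is deterministic", {
  set.seed(10)
  H <- rbind(matrix(rnorm(40 * 3, sd = 1), 40, 3),
             matrix(rnorm(40 * 3, mean = 20, sd = 1), 40, 3))
  truth <- rep(0:1, each = 40)
  # communities cannot straddle the disconnected blobs; a low resolution (or
  # target_k) recovers exactly the two components, since modularity at
  # resolution 1 legitimately subdivides each blob's sparse kNN graph
  lab <- segment_domains(H, n_neighbors = 5, resolution = 0.01, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(adjusted_rand_index(lab, truth), 1)
  expect_identical(lab, segment_domains(H, n_neighbors = 5,
                                        resolution = 0.01, seed = 1))
  labk <- segment_domains(H, n_neighbors = 5, target_k = 2, seed = 1)
  expect_equal(adjusted_rand_index(labk, truth), 1)
  # labels are 0..K-1 ordered by decreasing size
  lab2 <- segment_domains(H[c(1:40, 41:60), ], n_neighbors = 5,
                          target_k = 2, seed = 1)
  expect_equal(sort(unique(lab2)), 0:1)
  expect_gte(sum(lab2 == 0), sum(lab2 == 1))
})

test_that("target_k bisection reaches the requested cluster count or errors", {
  set.seed(11)
  centers <- matrix(rnorm(4 * 3, sd = 30), 4, 3)
  H <- centers[rep(1:4, each = 30), ] + matrix(rnorm(120 * 3), 120, 3)
  lab <- segment_domains(H, n_neighbors = 8, target_k = 4, seed = 2)
  expect_equal(length(unique(lab)), 4)
  expect_equal(adjusted_rand_index(lab, rep(1:4, each = 30)), 1)
  expect_error(segment_domains(H, n_neighbors = 8, target_k = 80, seed = 2),
               "unreachable")
})

test_that("root selection matches the brute-force distance sums", {
  expect_equal(select_root(matrix(5, 1, 2)), 1L)
  # sums for 1-D points (0,1,2) are (3,2,3); the tie goes to the lowest index
  expect_equal(select_root(matrix(c(0, 1, 2), 3, 1)), 1L)
  set.seed(12)
  for (rep in 1:5) {
    H <- matrix(rnorm(50 * 4), 50, 4)
    expect_equal(select_root(H), oracle_root(H))
  }
})

test_that("diffusion pseudotime orders a 1-D chain and fixes the root at 0", {
  set.seed(13)
  H <- cbind(0:99 + rnorm(100, sd = 1e-3), rnorm(100, sd = 1e-3))
  psm <- compute_psm(H, root = 1, n_neighbors = 10)
  expect_equal(psm[1], 0)
  expect_equal(cor(psm, 1:100, method = "spearman"), 1)
  expect_true(all(psm >= 0 & psm <= 1))
  expect_equal(max(psm), 1)
  # constant embeddings: degenerate, all zero
  expect_equal(compute_psm(matrix(1, 30, 2), root = 3, n_neighbors = 5),
               rep(0, 30))
  # rotation of the embedding leaves pseudotime unchanged
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  expect_equal(compute_psm(H %*% R, root = 1, n_neighbors = 10), psm)
})

test_that("pseudotime handles disconnected embedding graphs", {
  set.seed(14)
  H <- rbind(matrix(rnorm(30 * 2), 30, 2),
             matrix(rnorm(10 * 2, mean = 1000), 10, 2))
  expect_warning(psm <- compute_psm(H, root = 1, n_neighbors = 3),
                 "disconnected")
  expect_equal(psm[1], 0)
  expect_true(all(psm[31:40] == 1))
})

test_that("marker ranking agrees with exact rank-sum enumeration and BH", {
  # identical groups: no effect, p ~ 1 under the normal approximation
  expr <- cbind(g1 = rep(c(5, 7, 9), 4))
  labels <- rep(0:1, each = 6)
  mt <- rank_markers(expr, labels, alpha = 0.01)
  expect_true(all(mt$p > 0.99))

  # 3-vs-3 shifted samples: exact enumeration over C(6,3) = 20 assignments
  # gives p = 0.1; wilcox.test confirms; the normal-approximation p is close
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(oracle_wilcoxon_exact_p(x, y), 0.1)
  expect_equal(wilcox.test(x, y, exact = TRUE)$p.value, 0.1)
  mt2 <- rank_markers(matrix(c(x, y), 6, 1), rep(0:1, each = 3), alpha = 0.5)
  expect_lt(abs(mt2$p[1] - 0.1), 0.06)
  expect_equal(mt2$direction[mt2$domain == 0], -1L)

  # BH step-up on raw p's (0.01, 0.02, 0.04) must give (0.03, 0.03, 0.04);
  # the adjusted column equals a hand application of the rule to raw p's
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(15)
  expr3 <- matrix(rnbinom(40 * 6, mu = 3, size = 1), 40, 6)
  expr3[1:20, 1] <- expr3[1:20, 1] + 10
  mt3 <- rank_markers(expr3, rep(0:1, each = 20))
  d0 <- mt3[mt3$domain == 0, ]
  m <- nrow(d0)
  hand <- d0$p[order(d0$p)] * m / seq_len(m)
  hand <- rev(cummin(rev(pmin(hand, 1))))
  expect_equal(sort(d0$adj_p), hand)
  expect_true(all(mt3$adj_p >= mt3$p))
  expect_true(all(diff(d0$adj_p) >= 0))  # sorted within domain
})

test_that("marker ranking matches wilcox.test p-values across random genes", {
  set.seed(16)
  expr <- matrix(rnorm(60 * 8), 60, 8)
  labels <- rep(0:2, each = 20)
  mt <- rank_markers(expr, labels)
  for (d in 0:2) {
    for (g in 1:8) {
      ref <- wilcox.test(expr[labels == d, g], expr[labels != d, g],
                         exact = FALSE, correct = FALSE)$p.value
      got <- mt$p[mt$domain == d & mt$gene == as.character(g)]
      expect_equal(got, ref, tolerance = 1e-10)
    }
  }
})

test_that("adjusted Rand index has its closed-form values and invariances", {
  a <- c(0, 0, 1, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(5, 5, 9, 9, 7, 7)), 1)  # relabeling
  # crossed 2x2 design: closed-form ARI is -1/2
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)), -0.5)
  set.seed(17)
  for (rep in 1:5) {
    x <- sample(0:3, 40, replace = TRUE)
    y <- sample(0:2, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), oracle_ari(x, y))
    perm <- sample(0:3)
    expect_equal(adjusted_rand_index(perm[x + 1], y),
                 adjusted_rand_index(x, y))
  }
  skip_if_not_installed("mclust")
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 0, 1)),
               mclust::adjustedRandIndex(c(0, 0, 1, 1), c(0, 1, 0, 1)))
})
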