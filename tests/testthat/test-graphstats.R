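test_that("degree centralities sum the right axes and conserve the
           off-diagonal total", {
  v <- matrix(0, 3, 3)
  v[1, 2] <- 0.6; v[3, 2] <- 0.4
  expect_equal(in_degree(v), c(0, 1, 0))
  expect_equal(out_degree(v), c(0.6, 0, 0.4))
  expect_equal(in_degree(matrix(0, 3, 3)), rep(0, 3))

  set.seed(9)
  r <- matrix(abs(rnorm(25)), 5); diag(r) <- 0
  expect_equal(sum(in_degree(r)), sum(out_degree(r)))
  expect_equal(sum(in_degree(r)), sum(r))
  rs <- r + t(r)
  expect_equal(in_degree(rs), out_degree(rs))
  rn <- normalize_gc(r)
  expect_equal(sum(in_degree(rn)), 1, tolerance = 1e-12)
  expect_equal(sum(out_degree(rn)), 1, tolerance = 1e-12)
  expect_error(in_degree(diag(3)), "diagonal")
})

test_that("exact Wilcoxon agrees with enumeration and wilcox.test", {
  # n = 6, all positive differences: the two extreme assignments of 64
  r <- wilcoxon_signed_rank(1:6)
  expect_equal(r$p.value, 2 / 64)
  expect_equal(r$statistic, 21)
  expect_equal(r$method, "exact")

  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(6:15, 1))
    expect_equal(wilcoxon_signed_rank(x)$p.value,
                 wilcox.test(x, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("approximate Wilcoxon matches the tie-corrected normal
           approximation", {
  set.seed(15)
  for (i in 1:20) {
    x <- round(rnorm(sample(20:40, 1)), 1)
    x <- x[x != 0]
    if (length(x) < 16) next
    expect_equal(wilcoxon_signed_rank(x)$p.value,
                 suppressWarnings(
                   wilcox.test(x, exact = FALSE, correct = TRUE)$p.value),
                 tolerance = 1e-10)
  }
})

test_that("Wilcoxon degenerate and undersized inputs are handled", {
  expect_warning(r <- wilcoxon_signed_rank(rep(2, 8), rep(2, 8)),
                 "all differences")
  expect_equal(r$p.value, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2, 3)), ">= 5")
})

test_that("BH step-up matches the hand-computed rule and is monotone", {
  r <- bh_fdr(c(0.001, 0.02, 0.8), alpha = 0.05)
  # by hand: sorted p * m / rank, cumulative minimum from the largest rank
  expect_equal(r$adjusted, c(0.003, 0.03, 0.8))
  expect_equal(r$rejected, c(TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5))$rejected, rep(FALSE, 5))
  expect_equal(bh_fdr(numeric(0))$rejected, logical(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  # lowering any raw p never removes a rejection
  set.seed(6)
  for (i in 1:20) {
    p <- runif(16)
    rej1 <- bh_fdr(p)$rejected
    k <- sample(16, 1)
    p2 <- p; p2[k] <- p2[k] * runif(1)
    rej2 <- bh_fdr(p2)$rejected
    expect_true(all(rej2[rej1]))
  }
})

test_that("paired permutation test attains the minimum p under a strong
           shift and is seed-reproducible", {
  a <- rnorm(20) + 10
  b <- rnorm(20)
  r <- paired_permutation_test(a, b, n_perm = 5000, seed = 3)
  expect_equal(r$p.value, 1 / 5001)
  r2 <- paired_permutation_test(a, b, n_perm = 5000, seed = 3)
  expect_identical(r$p.value, r2$p.value)
  expect_equal(paired_permutation_test(rep(1, 8), rep(1, 8),
                                       n_perm = 100)$p.value, 1)
  expect_error(paired_permutation_test(1:3, 4:6), ">= 6")
})

test_that("cluster permutation finds a planted boxcar and nothing under
           the null", {
  set.seed(22)
  n <- 14; T <- 60
  a <- matrix(rnorm(n * T), n)
  b <- matrix(rnorm(n * T), n)
  cl0 <- cluster_permutation_test_1d(a, b, n_perm = 300, seed = 1)
  expect_true(nrow(cl0) == 0 || all(cl0$p > 0.05))

  eff <- matrix(0, n, T); eff[, 21:35] <- 1.8
  cl1 <- cluster_permutation_test_1d(a + eff, b, n_perm = 300, seed = 1)
  expect_gt(nrow(cl1), 0)
  sig <- cl1[cl1$p < 0.05, , drop = FALSE]
  expect_equal(nrow(sig), 1)
  overlap <- length(intersect(seq(sig$start, sig$end), 21:35))
  expect_gte(overlap / 15, 0.8)

  cl2 <- cluster_permutation_test_1d(a + eff, b, n_perm = 300, seed = 1)
  expect_identical(cl1$p, cl2$p)
})
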