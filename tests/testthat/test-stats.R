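test_that("Kruskal-Wallis matches hand-ranked arithmetic", {
  ident <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  # ranks 1..9, rank sums 6/15/24: H = 12/(9*10) * sum(R^2/3) - 3*10 = 7.2
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 non-empty")
})

test_that("the null distribution is invariant under label permutation", {
  set.seed(123)
  pooled <- rnorm(36)
  labs <- rep(1:3, each = 12)
  h_obs <- kruskal_wallis(pooled, labs)$statistic
  h_perm <- replicate(1000, kruskal_wallis(pooled, sample(labs))$statistic)
  # observed statistic from arbitrary labels is a typical draw of the
  # permutation null
  p_perm <- mean(h_perm >= h_obs)
  expect_gt(p_perm, 0.01)
  expect_lt(abs(mean(h_perm) - 2), 0.5) # E[H] = k - 1 under the null
})

test_that("Benjamini-Hochberg step-up matches the hand computation", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(1)
  g <- rep(c("a", "b"), each = 10)
  v <- c(rnorm(10), rnorm(10))
  pw <- pairwise_wilcoxon_bh(v, g)
  expect_true(all(pw$pairs$p.adjusted >= pw$pairs$p.value - 1e-12))
  expect_true(isSymmetric(pw$p_matrix))
})

test_that("identical groups share a letter; separated groups do not", {
  set.seed(7)
  same <- pairwise_wilcoxon_bh(rnorm(40), rep(c("a", "b"), each = 20))
  expect_gt(same$pairs$p.adjusted, 0.05)
  expect_equal(unname(same$letters["a"]), unname(same$letters["b"]))

  v <- c(rnorm(15, 0), rnorm(15, 10), rnorm(15, 20))
  g <- rep(c("g1", "g2", "g3"), each = 15)
  sep <- pairwise_wilcoxon_bh(v, g)
  expect_equal(length(unique(sep$letters)), 3)

  tiny <- pairwise_wilcoxon_bh(c(1, 5, 6, 7), c("a", "b", "b", "b"))
  expect_true(is.na(tiny$pairs$p.value)) # group of size < 2
})

test_that("paired Wilcoxon matches exhaustive sign-flip enumeration", {
  before <- c(1, 2, 3, 4, 5, 6)
  after <- c(2, 4, 6, 8, 10, 12)
  res <- wilcoxon_paired(before, after)
  # enumerate all 2^6 sign assignments of ranks 1..6
  d <- abs(after - before)
  r <- rank(d)
  v_obs <- sum(r[after > before])
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  v_all <- as.matrix(signs) %*% r
  mu <- sum(r) / 2
  p_exact <- mean(abs(v_all - mu) >= abs(v_obs - mu))
  expect_equal(res$p.value, p_exact) # 2/64
  expect_equal(p_exact, 2 / 64)
  expect_true(res$exact)

  # the same check across random small samples without ties
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:10, 1)
    b <- rnorm(n)
    a <- b + rnorm(n, 0.5)
    if (any(a == b)) next
    d <- abs(a - b); r <- rank(d)
    v_obs <- sum(r[a > b])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    mu <- sum(r) / 2
    p_exact <- mean(abs(v_all - mu) >= abs(v_obs - mu))
    expect_equal(wilcoxon_paired(b, a)$p.value, p_exact)
  }
})

test_that("paired Wilcoxon is shift invariant and rejects degenerate input", {
  set.seed(3)
  b <- rnorm(12)
  a <- b + rnorm(12, 0.3)
  r1 <- wilcoxon_paired(b, a)
  r2 <- wilcoxon_paired(b + 100, a + 100)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p.value, r2$p.value)
  expect_error(wilcoxon_paired(b, b), "degenerate")
})

test_that("KW gatekeeping keeps the family-wise type-I error near alpha", {
  set.seed(2026)
  rejections <- 0
  for (i in 1:2000) {
    v <- rnorm(72)
    g <- rep(1:4, each = 18)
    kw <- suppressWarnings(stats::kruskal.test(v, g))
    if (kw$p.value < 0.05) {
      pw <- pairwise_wilcoxon_bh(v, g)
      if (any(pw$pairs$p.adjusted < 0.05, na.rm = TRUE)) {
        rejections <- rejections + 1
      }
    }
  }
  expect_lte(rejections / 2000, 0.07)
})

test_that("compare_orc_groups assembles the full comparison report", {
  set.seed(15)
  d <- tibble::tibble(
    orc = rep(1:4, each = 18),
    gsi = c(rnorm(18, 12, 2), rnorm(18, 7, 2), rnorm(18, 3.5, 1), rnorm(18, 1.5, 0.5))
  )
  cmp <- compare_orc_groups(d, "gsi")
  expect_lt(cmp$kruskal$p.value, 0.001)
  expect_false(is.null(cmp$pairwise))
  expect_equal(nrow(tidy(cmp)), 6)
  expect_equal(glance(cmp)$df, 3)
  expect_equal(nrow(cmp$group_summary), 4)
  # ORC 1 and ORC 4 must not share a letter
  l <- cmp$pairwise$letters
  shared <- intersect(strsplit(l[["1"]], "")[[1]], strsplit(l[["4"]], "")[[1]])
  expect_length(shared, 0)
})
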