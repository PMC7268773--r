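test_that("make_clusters groups positions by gap within chromosomes", {
  expect_equal(make_clusters(rep("chr1", 4), c(1L, 50L, 140L, 400L), 100L),
               c(1L, 1L, 1L, 2L))
  expect_equal(make_clusters("chr1", 7L), 1L)
  # identical coordinates on two chromosomes never share a cluster
  cl <- make_clusters(rep(c("chr1", "chr2"), each = 3),
                      rep(c(10L, 20L, 30L), 2), 100L)
  expect_equal(cl, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_error(make_clusters(rep("chr1", 3), c(10L, 5L, 20L)), "sorted")
})

test_that("make_clusters matches a pairwise-scan oracle on random inputs", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    chrom <- sort(sample(c("chr1", "chr2"), n, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n), chrom), function(idx) {
      sort(sample(1:2000, length(idx)))
    }), use.names = FALSE)
    maxgap <- sample(c(10L, 100L, 500L), 1)
    expect_equal(make_clusters(chrom, pos, maxgap),
                 bf_clusters(chrom, pos, maxgap))
  }
})

region_stats <- function(beta, cluster, pos = NULL) {
  if (is.null(pos)) pos <- seq_along(beta) * 10L
  data.frame(chrom = "chr1", pos = pos, cluster = cluster,
             beta_smooth = beta)
}

test_that("find_regions extracts sign-consistent runs above the threshold", {
  # quantile 0.4 of |beta| = (0.1, 0.1, 1, 2, 2, 2) pins the threshold at 1
  st <- region_stats(c(2, 2, -0.1, 2, 1, 0.1),
                     c(1L, 1L, 1L, 1L, 2L, 2L))
  reg <- find_regions(st, K_quantile = 0.4)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$area, c(4, 2))
  expect_equal(reg$n_positions, c(2L, 1L))
  expect_equal(reg$direction, c("gain", "gain"))
  # runs must share a sign: alternating values give single-position regions
  st2 <- region_stats(c(2, -2, 2, 1, 0.5, 0.5),
                      c(1L, 1L, 1L, 2L, 2L, 2L))
  reg2 <- find_regions(st2, K_quantile = 0.4)
  expect_equal(nrow(reg2), 3L)
  expect_equal(reg2$direction, c("gain", "loss", "gain"))
  expect_equal(reg2$n_positions, rep(1L, 3))
  # nothing exceeds the threshold strictly when all values are identical
  st3 <- region_stats(rep(1.5, 5), rep(1L, 5))
  expect_equal(nrow(find_regions(st3, K_quantile = 0.7)), 0L)
})

test_that("find_regions matches an exhaustive run scan on random inputs", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    cluster <- sort(sample(1:4, n, replace = TRUE))
    beta <- round(rnorm(n), 2)
    K <- runif(1, 0.2, 0.9)
    st <- region_stats(beta, cluster)
    reg <- find_regions(st, K_quantile = K)
    thr <- quantile(abs(beta), K, names = FALSE)
    oracle <- bf_find_regions(beta, cluster, thr)
    expect_equal(nrow(reg), nrow(oracle))
    if (nrow(reg)) {
      expect_equal(reg$area, oracle$area)
      expect_equal(reg$start, st$pos[oracle$from])
      expect_equal(reg$end, st$pos[oracle$to])
    }
  }
})

test_that("bh_adjust matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bf_bh(p))
  }
})

test_that("simes_pvalues combines cluster p-values correctly", {
  st <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 200L),
                   cluster = c(1L, 1L, 1L, 2L),
                   p = c(0.01, 0.04, 0.03, 0.2),
                   beta_smooth = c(0.5, 0.4, 0.6, -0.3))
  out <- simes_pvalues(st)
  expect_equal(out$p[out$cluster == 1], 0.03)   # min(3*.01/1, 3*.03/2, 3*.04/3)
  expect_equal(out$p[out$cluster == 2], 0.2)    # single position passes through
  expect_equal(out$direction, c("gain", "loss")[order(order(out$cluster))],
               ignore_attr = TRUE)
  expect_equal(out$start[out$cluster == 1], 10L)
  expect_equal(out$end[out$cluster == 1], 30L)
  # equal p-values: the minimum is attained at i = n
  st_eq <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L), cluster = 1L,
                      p = rep(0.07, 3), beta_smooth = 1)
  expect_equal(simes_pvalues(st_eq)$p, 0.07)
})

test_that("Simes cluster p respects its combination bounds", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(1:20, 1)
    p <- runif(n)
    st <- data.frame(chrom = "chr1", pos = seq_len(n) * 5L, cluster = 1L,
                     p = p, beta_smooth = rnorm(n))
    pc <- simes_pvalues(st)$p
    expect_equal(pc, bf_simes(p))
    expect_gte(pc, min(p))
    expect_lte(pc, n * min(p) + 1e-12)
  }
})

test_that("permutation enumeration and p-value estimator behave as stated", {
  set.seed(55)
  sim <- simulate_score_matrix(sim_config(n_clusters = 30, seed = 55))
  se <- filter_positions(sim$se)
  X <- two_group_design(3)
  res <- permutation_pvalues(se, X, c(0, 1), K_quantile = 0.5)
  # 3 vs 3: C(6,3)/2 - 1 = 9 non-redundant label reassignments
  expect_equal(attr(res, "n_permutations"), 9L)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$adj_p >= res$p - 1e-12))
  expect_identical(res$method[1], "permutation")

  # 2 vs 2 leaves only 2 permutations: advise the Simes route
  sub <- se[, c(1, 2, 4, 5)]
  expect_error(permutation_pvalues(sub, two_group_design(2), c(0, 1)),
               "Simes")
  # a single group cannot be permuted
  expect_error(permutation_pvalues(se, cbind(1, rep(0, 6)), c(0, 1)),
               "two levels")
})

test_that("swapping group labels mirrors directions and keeps p-values", {
  set.seed(60)
  sim <- simulate_score_matrix(sim_config(n_clusters = 30, seed = 60))
  se <- filter_positions(sim$se)
  X1 <- cbind(1, rep(0:1, each = 3))
  X2 <- cbind(1, rep(1:0, each = 3))
  r1 <- permutation_pvalues(se, X1, c(0, 1), K_quantile = 0.5)
  r2 <- permutation_pvalues(se, X2, c(0, 1), K_quantile = 0.5)
  key1 <- paste(r1$chrom, r1$start, r1$end)
  r2 <- r2[match(key1, paste(r2$chrom, r2$start, r2$end)), ]
  expect_equal(r1$p, r2$p)
  expect_equal(r1$area, r2$area)
  expect_true(all(r1$direction != r2$direction))

  s1 <- simes_pvalues(site_stats(se, X1, c(0, 1)))
  s2 <- simes_pvalues(site_stats(se, X2, c(0, 1)))
  expect_equal(s1$p, s2$p)
  expect_true(all(s1$direction != s2$direction))
})

test_that("the add-one estimator keeps permutation p-values away from zero", {
  set.seed(70)
  sim <- simulate_score_matrix(sim_config(n_clusters = 30, seed = 70))
  se <- filter_positions(sim$se)
  res <- permutation_pvalues(se, two_group_design(3), c(0, 1),
                             K_quantile = 0.5)
  n_null <- attr(res, "n_null_areas")
  expect_gt(n_null, 0L)
  # a region beating every pooled null area still gets (0 + 1)/(N + 1)
  expect_gte(min(res$p), 1 / (n_null + 1) - 1e-12)
})
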