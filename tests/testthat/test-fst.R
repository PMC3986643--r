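test_that("snp_fst_pair reproduces hand arithmetic and handles monomorphic pairs", {
  expect_equal(snp_fst_pair(0.3, 0.3), 0)
  expect_equal(snp_fst_pair(0, 1), 1)
  expect_equal(snp_fst_pair(0.2, 0.8), 0.36)  # pbar 0.5, num 0.09, den 0.25
  expect_true(is.na(snp_fst_pair(0, 0)))
  expect_true(is.na(snp_fst_pair(1, 1)))
})

test_that("snp_fst_pair invariances and algebraic identity", {
  set.seed(31)
  p1 <- runif(200); p2 <- runif(200)
  f <- snp_fst_pair(p1, p2)
  expect_equal(f, snp_fst_pair(p2, p1))                      # symmetry
  expect_equal(f, snp_fst_pair(1 - p1, 1 - p2))              # allele relabelling
  pbar <- (p1 + p2) / 2
  expect_equal(f, (p1 - p2)^2 / (4 * pbar * (1 - pbar)))     # identity
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
})

test_that("Weir & Cockerham theta matches one-way ANOVA variance components", {
  # independent oracle: method-of-moments from anova() on raw allele indicators
  n1 <- 40; n2 <- 60
  p1 <- c(0.2, 0.5, 0.9, 0.05, 0.5)
  p2 <- c(0.8, 0.5, 0.1, 0.30, 0.55)
  c1 <- round(p1 * n1); c2 <- round(p2 * n2)
  pop <- factor(rep(c("a", "b"), c(n1, n2)))
  nc <- (100 - (n1^2 + n2^2) / 100) / 1
  theta_aov <- vapply(seq_along(c1), function(j) {
    y <- c(rep(1, c1[j]), rep(0, n1 - c1[j]), rep(1, c2[j]), rep(0, n2 - c2[j]))
    ms <- anova(lm(y ~ pop))[["Mean Sq"]]
    sa <- (ms[1] - ms[2]) / nc
    sa / (sa + ms[2])
  }, numeric(1))
  expect_equal(wc_fst_pair(c1 / n1, c2 / n2, n1, n2), theta_aov)
})

test_that("W&C theta approaches 2x the Eq.-1 estimator in the balanced weak-divergence limit", {
  # the two estimators are NOT asymptotically equal: for r = 2 populations
  # theta -> s^2/(pq + s^2/2) with s^2 = (p1-p2)^2 / (r-1), i.e. a factor
  # r/(r-1) = 2 above Eq. 1 as p1 -> p2 (see the methods vignette)
  ratio <- wc_fst_pair(0.3, 0.31, 1e7, 1e7) / snp_fst_pair(0.3, 0.31)
  expect_lt(abs(ratio - 2), 0.02)
})

test_that("fst_window_scan averages per-SNP values over polymorphic SNPs only", {
  # construct two panels with exact frequencies; windows of 2 SNPs each
  freqs <- rbind(c(0.5, 0.5), c(0.25, 0.75),  # window 1: fst 0, fst 1/3
                 c(0.0, 0.0), c(1.0, 1.0))    # window 2: both monomorphic
  nh <- 8
  col <- function(p) c(rep(1L, round(p * nh)), rep(0L, nh - round(p * nh)))
  H1 <- sapply(freqs[, 1], col); H2 <- sapply(freqs[, 2], col)
  pos <- c(100, 200, 1100, 1200)
  pa <- make_panel(H1, pos, len = 2000, population = "a")
  pb <- make_panel(H2, pos, len = 2000, population = "b")
  grid <- build_grid(c(chr1 = 2000), width = 1000, step = 1000)
  sc <- fst_window_scan(pa, pb, grid)
  f1 <- snp_fst_pair(0.5, 0.5); f2 <- snp_fst_pair(0.25, 0.75)
  expect_equal(sc$raw[1], mean(c(f1, f2)))
  expect_true(is.na(sc$raw[2]))
  expect_equal(sc$n_snps, c(2L, 0L))
  expect_lt(abs(mean(sc$std, na.rm = TRUE) - 1), 1e-12)
})

test_that("8 populations give 28 pairwise comparisons and scale-invariant standardization", {
  set.seed(32)
  panels <- setNames(lapply(1:8, function(i) rand_panel(6, 40, spacing = 100)),
                     paste0("p", 1:8))
  grid <- build_grid(c(chr1 = 4000), width = 2000, step = 1000)
  ps <- fst_pair_scan(panels, grid,
                      groups = setNames(c("dairy", "dairy", rep("beef", 6)),
                                        paste0("p", 1:8)))
  expect_equal(ncol(ps$std), choose(8, 2))
  expect_equal(ncol(ps$std), 28L)
  expect_equal(sum(ps$pairs$cross), 2 * 6)
  expect_equal(sum(!ps$pairs$cross), 1 + choose(6, 2))
  for (k in seq_len(ncol(ps$std)))
    if (any(is.finite(ps$std[, k])))
      expect_lt(abs(mean(ps$std[, k], na.rm = TRUE) - 1), 1e-12)
})

test_that("mann_whitney_u matches exact enumeration and handles degenerate ties", {
  set.seed(33)
  x <- rnorm(3); y <- rnorm(4)
  got <- mann_whitney_u(x, y)
  # exhaustive U distribution over all assignments of ranks to the x-sample
  all_u <- apply(combn(7, 3), 2, function(idx) sum(rank(c(x, y))[idx]) - 6)
  expect_equal(got$p, mean(all_u >= got$U))
  expect_true(got$exact)

  # 12 cross vs 16 within, all cross strictly greater: U maximal, minimal p
  x <- 100 + seq_len(12); y <- seq_len(16)
  got <- mann_whitney_u(x, y)
  expect_equal(got$U, 12 * 16)
  expect_equal(got$U, 192)
  expect_equal(got$p, 1 / choose(28, 12))

  # identical constant values: U at its null mean, p = 0.5
  got <- mann_whitney_u(rep(1, 5), rep(1, 7))
  expect_equal(got$U, 5 * 7 / 2)
  expect_equal(got$p, 0.5)
})

test_that("group_contrast_test compares cross-group to within-group pairs per window", {
  pairs <- data.frame(pop1 = c("d1", "d1", "d2", "b1"),
                      pop2 = c("b1", "b2", "b1", "b2"),
                      group1 = c("dairy", "dairy", "dairy", "beef"),
                      group2 = c("beef", "beef", "beef", "beef"))
  pairs$cross <- pairs$group1 != pairs$group2
  std <- rbind(c(5, 6, 7, 1),      # cross pairs all greater
               c(1, 2, 3, 10),     # within pair greater
               c(NA, NA, NA, 1))   # no cross values -> missing
  ct <- group_contrast_test(list(std = std, pairs = pairs))
  expect_equal(ct$U[1], 3)         # maximal: 3 cross x 1 within
  expect_equal(ct$p[1], 1 / choose(4, 3))
  expect_gt(ct$p[2], 0.5)
  expect_true(is.na(ct$p[3]))
  expect_equal(ct$n_cross[1], 3L)
  expect_error(group_contrast_test(list(std = std, pairs = pairs[, 1:2])),
               "group labels")
})
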