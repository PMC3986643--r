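test_that("call_ancestral takes the outgroup majority and leaves ties missing", {
  og <- rbind(c(0L, 1L, 2L, NA),
              c(0L, 1L, 2L, NA),
              c(0L, 0L, 2L, NA))   # dosage of allele 1
  # site 1: 6 calls of 0 -> ancestral 0; site 2: 2 vs 4 -> allele 1 minority? counts0=2? dose 1 each of first two rows
  anc <- call_ancestral(og)
  expect_identical(anc[1], 0L)           # {0:6, 1:0}
  expect_identical(anc[2], 0L)           # {0:4, 1:2}
  expect_identical(anc[3], 1L)           # {0:0, 1:6}
  expect_true(is.na(anc[4]))             # zero calls
  expect_true(is.na(call_ancestral(matrix(c(1L, 1L, 0L, 2L), 4, 1))[1]))  # 4 vs 4 tie
  cnt <- attr(anc, "counts")
  expect_equal(unname(cnt[, 1]), c(6, 0))
})

test_that("ehh_curve matches combinatorial hand counts", {
  # 6 haplotypes; allele 1 carriers: rows 1-4
  H <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 1), c(1, 1, 0), c(0, 0, 0), c(0, 1, 0))
  panel <- make_panel(H, c(0, 100, 200), len = 1000)
  cv <- ehh_curve(panel, core = 1, allele = 1, threshold = 0)
  expect_equal(cv$n_carriers, 4L)
  # first right flank: carriers split 2/2 -> EHH = (1 + 1) / C(4,2) = 1/3
  expect_equal(cv$right$ehh[1], 1 / 3)
  # second flank: groups {1,2}, {3}, {4} -> 1/6
  expect_equal(cv$right$ehh[2], 1 / 6)
  expect_equal(nrow(cv$left), 0L)  # core at chromosome start

  # all carriers identical over the region -> EHH stays 1
  H2 <- rbind(matrix(1L, 4, 4), matrix(0L, 2, 4))
  H2[5, 4] <- 1L
  p2 <- make_panel(H2, c(0, 10, 20, 30), len = 100)
  cv2 <- ehh_curve(p2, core = 2, allele = 1, threshold = 0.5)
  expect_true(all(c(cv2$left$ehh, cv2$right$ehh) == 1))
  expect_true(cv2$truncated_left && cv2$truncated_right)

  # fewer than 2 carriers: undefined (row 6 is the lone ancestral carrier at SNP 4)
  expect_null(ehh_curve(p2, core = 4, allele = 0, threshold = 0.5))
})

test_that("EHH is monotone non-increasing away from the core", {
  set.seed(21)
  for (i in 1:10) {
    panel <- rand_panel(12, 15)
    core <- sample(3:13, 1)
    for (al in 0:1) {
      cv <- ehh_curve(panel, core, al, threshold = 0)
      if (is.null(cv)) next
      expect_true(all(diff(c(1, cv$right$ehh)) <= 1e-12))
      expect_true(all(diff(c(1, cv$left$ehh)) <= 1e-12))
    }
  }
})

test_that("iehh integrates to the threshold crossing (rectangle and Riemann oracles)", {
  # plateau of EHH = 1 out to ~10 kb each side, then an immediate crash
  mk_curve <- function() list(
    left = data.frame(dist = c(10000, 10001), ehh = c(1, 0)),
    right = data.frame(dist = c(10000, 10001), ehh = c(1, 0)))
  a <- iehh(mk_curve(), threshold = 0.5)
  expect_lt(abs(a - 20000) / 20000, 0.001)

  # threshold 1: EHH < 1 at the first flank truncates immediately -> area 0
  cv <- list(left = data.frame(dist = 500, ehh = 0.9),
             right = data.frame(dist = 700, ehh = 0.8))
  expect_equal(as.numeric(iehh(cv, threshold = 1)), 0)

  # piecewise-linear toy curves vs dense Riemann sums, within 0.1%
  set.seed(22)
  for (i in 1:8) {
    d <- sort(sample(1:20000, 12))
    e <- sort(runif(12, 0, 0.99), decreasing = TRUE)
    cv <- list(left = data.frame(dist = d, ehh = e),
               right = data.frame(dist = d * 1.3, ehh = e^1.1))
    for (thr in c(0.5, 0.2)) {
      got <- as.numeric(iehh(cv, threshold = thr))
      want <- riemann_iehh_side(cv$left$dist, cv$left$ehh, thr) +
              riemann_iehh_side(cv$right$dist, cv$right$ehh, thr)
      expect_lt(abs(got - want) / want, 0.001)
    }
  }
})

test_that("raw_ihs forms the derived/ancestral ratio and propagates missingness", {
  r <- raw_ihs(c(2, 20, NA, 0), c(2, 2, 1, 1))
  expect_equal(r$log10_ratio[1], 0)
  expect_equal(r$log10_ratio[2], 1)
  expect_true(is.na(r$x[3]) && is.na(r$x[4]))
})

test_that("SNPs at or below the MAF floor are excluded from the scan", {
  set.seed(23)
  nh <- 2000
  H <- matrix(rbinom(nh * 8, 1, 0.4), nh, 8)
  H[, 4] <- 0L; H[1, 4] <- 1L     # MAF 0.0005 <= 0.001 -> excluded
  H[, 5] <- 0L; H[1:40, 5] <- 1L  # MAF 0.02 -> kept
  panel <- make_panel(H, seq(0, by = 2000, length.out = 8))
  rec <- ihs_scan(panel, anc = rep(0L, 8), discard_truncated = FALSE)
  expect_true(is.na(rec$freq_anc[4]) || is.na(rec$ihs[4]))
  expect_true(is.na(rec$x[4]))
  expect_false(is.na(rec$x[5]))
})

test_that("binned standardization yields mean 0 and SD 1 in every populated bin", {
  set.seed(24)
  x <- rnorm(600, sd = 0.4)
  f <- runif(600)
  std <- standardize_ihs(x, f)
  for (b in unique(std$bin)) {
    v <- std$ihs[std$bin == b]
    v <- v[!is.na(v)]
    if (!length(v)) next
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sd(v) - 1), 1e-10)
  }
  # single record in a bin -> missing; record at its bin mean -> 0
  s2 <- standardize_ihs(c(1, 1, 3), c(0.01, 0.5, 0.52))
  expect_true(is.na(s2$ihs[1]))
  expect_equal(s2$ihs[2], -s2$ihs[3])
  s3 <- standardize_ihs(c(1, 2, 3), c(0.5, 0.51, 0.52))
  expect_equal(s3$ihs[2], 0)
})

test_that("compiled scan equals the pure-R EHH/iEHH reference", {
  set.seed(25)
  for (i in 1:6) {
    panel <- rand_panel(14, 12, spacing = 500)
    anc <- sample(c(0L, 1L), 12, replace = TRUE)
    rec <- ihs_scan(panel, anc = anc, threshold = 0.5, maf_min = 0,
                    discard_truncated = FALSE)
    for (j in seq_len(12)) {
      for (which_allele in c("anc", "der")) {
        al <- if (which_allele == "anc") anc[j] else 1L - anc[j]
        cv <- ehh_curve(panel, j, al, threshold = 0.5)
        want <- if (is.null(cv)) NA_real_ else as.numeric(iehh(cv, threshold = 0.5))
        got <- if (which_allele == "anc") rec$iehh_anc[j] else rec$iehh_der[j]
        if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
      }
    }
  }
})

test_that("iEHH matches exhaustive identical-pair enumeration on a tiny fixture", {
  set.seed(26)
  nh <- 10; m <- 12
  H <- matrix(rbinom(nh * m, 1, 0.5), nh, m)
  pos <- sort(sample(0:20000, m))
  panel <- make_panel(H, pos, len = 30000)
  thr <- 0.3
  oracle_iehh <- function(core, allele) {
    carriers <- which(H[, core] == allele)
    nA <- length(carriers)
    if (nA < 2) return(NA_real_)
    side <- function(step) {
      js <- if (step > 0) seq(core + 1, m) else rev(seq(1, core - 1))
      if (core + step < 1 || core + step > m) return(c(0, TRUE))
      dist <- c(); ehh <- c()
      for (j in js) {
        lo <- min(core, j); hi <- max(core, j)
        same <- 0
        for (a in seq_len(nA - 1)) for (b in (a + 1):nA)
          if (all(H[carriers[a], lo:hi] == H[carriers[b], lo:hi])) same <- same + 1
        dist <- c(dist, abs(pos[j] - pos[core]))
        ehh <- c(ehh, same / choose(nA, 2))
        if (ehh[length(ehh)] < thr) break
      }
      c(riemann_iehh_side(dist, ehh, thr), ehh[length(ehh)] >= thr)
    }
    L <- side(-1); R <- side(+1)
    c(L[1] + R[1])
  }
  anc <- rep(0L, m)
  rec <- ihs_scan(panel, anc = anc, threshold = thr, maf_min = 0,
                  discard_truncated = FALSE)
  for (j in 2:(m - 1)) {
    want_a <- oracle_iehh(j, 0L)
    want_d <- oracle_iehh(j, 1L)
    if (is.na(want_a)) expect_true(is.na(rec$iehh_anc[j]))
    else expect_lt(abs(rec$iehh_anc[j] - want_a) / max(want_a, 1), 0.001)
    if (is.na(want_d)) expect_true(is.na(rec$iehh_der[j]))
    else expect_lt(abs(rec$iehh_der[j] - want_d) / max(want_d, 1), 0.001)
  }
})

test_that("swapping the ancestral call at a SNP flips the sign of log10 x", {
  set.seed(27)
  panel <- rand_panel(16, 10, spacing = 800)
  anc0 <- rep(0L, 10)
  anc1 <- anc0; anc1[5] <- 1L
  r0 <- ihs_scan(panel, anc = anc0, maf_min = 0, discard_truncated = FALSE)
  r1 <- ihs_scan(panel, anc = anc1, maf_min = 0, discard_truncated = FALSE)
  if (!is.na(r0$log10_ratio[5]))
    expect_equal(r1$log10_ratio[5], -r0$log10_ratio[5])
  expect_equal(r1$log10_ratio[-5], r0$log10_ratio[-5])
})

test_that("window_abs_ihs takes the maximum |iHS| per window", {
  grid <- build_grid(c(chr1 = 250000), width = 250000, step = 50000)
  rec <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000, 200000),
                    abs_ihs = c(0.5, 2.3, 1.1, NA))
  w <- window_abs_ihs(rec, grid)
  expect_equal(w$max_abs_ihs[1], 2.3)
  rec$abs_ihs <- NA_real_
  w2 <- window_abs_ihs(rec, grid)
  expect_true(is.na(w2$max_abs_ihs[1]))
})
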