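test_that("sim_config validates its invariants", {
  expect_error(sim_config(mutation_rate = -1), ">= 0")
  expect_error(sim_config(trait = list(h2 = 1)), "h2")
  expect_error(sim_config(trait = list(truncation_fraction = 0)), "truncation")
  expect_error(sim_config(breeds = data.frame(name = "x", ne = 1L,
                                              generations = 5L, group = "dairy")),
               "Ne must be >= 2")
  expect_error(sim_config(sweeps = data.frame(chrom = "chr1", pos = 2e7, s = 0.1,
                                              breeds = "DairyA")),
               "within the chromosome")
  expect_error(sim_config(sweeps = data.frame(chrom = "chr1", pos = 100, s = -1,
                                              breeds = "DairyA")),
               ">= 0")
})

test_that("zero mutation rate cannot produce segregating sites", {
  cfg <- tiny_sim_config(mutation_rate = 0)
  set.seed(1)
  expect_error(simulate_neutral_panel(cfg), "no segregating sites")
})

test_that("the neutral panel is strictly binary, segregating, sorted and reproducible", {
  cfg <- tiny_sim_config(seed = 5)
  set.seed(5); p1 <- simulate_neutral_panel(cfg)
  set.seed(5); p2 <- simulate_neutral_panel(cfg)
  expect_identical(p1$hap, p2$hap)
  expect_identical(p1$map$pos, p2$map$pos)
  expect_true(all(p1$hap %in% c(0L, 1L)))
  f <- allele_freq(p1)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(p1$map$pos) > 0))
  expect_equal(nrow(p1$hap), 2 * cfg$base_ne)
})

test_that("no recombination means no four-gamete violations", {
  set.seed(6)
  cfg <- tiny_sim_config(recombination_rate = 0)
  panel <- simulate_neutral_panel(cfg)
  m <- ncol(panel$hap)
  pairs <- cbind(sample(m, 200, replace = TRUE), sample(m, 200, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  four <- apply(pairs, 1, function(ij) {
    g <- unique(paste(panel$hap[, ij[1]], panel$hap[, ij[2]]))
    length(g) == 4
  })
  expect_false(any(four))
})

test_that("the neutral site-frequency spectrum matches the 1/i expectation", {
  # tiny-n oracle world; across-replicate SE because linked sites are correlated
  set.seed(7)
  ne <- 25L; reps <- 20
  grp <- list(1, 2:3, 4:7, 8:15, 16:(2 * ne - 1))
  exp_p <- (1 / seq_len(2 * ne - 1)) / sum(1 / seq_len(2 * ne - 1))
  expd <- vapply(grp, function(i) sum(exp_p[i]), numeric(1))
  obs <- matrix(NA_real_, reps, length(grp))
  cfg <- sim_config(seed = 7, chrom_length = 5e5, base_ne = ne,
                    mutation_rate = 4e-7, recombination_rate = 1e-7,
                    trait = list(n_qtl = 5L))
  for (r in seq_len(reps)) {
    panel <- simulate_neutral_panel(cfg)
    dc <- colSums(panel$hap)
    tab <- tabulate(dc, nbins = 2 * ne - 1)
    obs[r, ] <- vapply(grp, function(i) sum(tab[i]) / sum(tab), numeric(1))
  }
  se <- apply(obs, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(obs) - expd) < 4 * se + 0.02))
})

test_that("breeds drift apart as an independent single-locus oracle predicts", {
  set.seed(8)
  cfg <- sim_config(seed = 8, chrom_length = 5e6, base_ne = 100L,
                    breeds = data.frame(name = c("A", "B"), ne = 50L,
                                        generations = 30L,
                                        group = c("dairy", "beef")),
                    trait = list(n_qtl = 10L))
  base <- simulate_neutral_panel(cfg)
  p0 <- allele_freq(base)
  eng <- replicate(8, {
    sp <- split_breeds(base, cfg)
    mean(snp_fst_pair(allele_freq(sp$panels$A), allele_freq(sp$panels$B)), na.rm = TRUE)
  })
  # oracle: founder sampling + binomial drift per locus, same estimator
  m <- length(p0)
  ora <- replicate(30, {
    k1 <- rhyper(m, round(p0 * 200), 200 - round(p0 * 200), 100) / 100
    k2 <- rhyper(m, round(p0 * 200), 200 - round(p0 * 200), 100) / 100
    for (t in 1:30) {
      k1 <- rbinom(m, 100, k1) / 100
      k2 <- rbinom(m, 100, k2) / 100
    }
    mean(snp_fst_pair(k1, k2), na.rm = TRUE)
  })
  tol <- 4 * sqrt(var(eng) / length(eng) + var(ora) / length(ora))
  expect_lt(abs(mean(eng) - mean(ora)), tol)
})

test_that("split with zero generations leaves breeds essentially undifferentiated", {
  set.seed(9)
  cfg <- tiny_sim_config()
  cfg$breeds$generations <- 0L
  base <- simulate_neutral_panel(cfg)
  sp <- split_breeds(base, cfg)
  fst <- mean(snp_fst_pair(allele_freq(sp$panels$A), allele_freq(sp$panels$B)),
              na.rm = TRUE)
  expect_lt(fst, 0.03)   # founder-sampling noise only (Ne 30 from base 40)
  # shared map: same columns in every breed, all polymorphic somewhere
  expect_identical(sp$panels$A$map$pos, sp$panels$B$map$pos)
  pooled <- colSums(sp$panels$A$hap) + colSums(sp$panels$B$hap)
  n_tot <- 2 * sum(cfg$breeds$ne)
  expect_true(all(pooled > 0 & pooled < n_tot))
})

test_that("a selection coefficient of zero reproduces pure drift (KS test)", {
  set.seed(10)
  nh <- 100L
  H0 <- matrix(0L, nh, 3)
  H0[1:(nh / 2), 2] <- 1L            # tracked site at frequency 0.5
  H0[1:30, 1] <- 1L; H0[61:90, 3] <- 1L
  pos <- c(100L, 5000L, 9000L)
  run_final <- function(sweep_pos) {
    r <- sweepscan:::wf_run_cpp(H0, pos, 1e4, 15L, 0, 1e-7, sweep_pos, 0, 2, FALSE)
    mean(r$hap[, match(5000L, r$pos)])
  }
  with_sel_machinery <- replicate(40, run_final(5000))
  neutral <- replicate(40, run_final(-1))
  ks <- suppressWarnings(ks.test(with_sel_machinery, neutral))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strong sweep fixes the allele and drives HAPH toward zero locally", {
  set.seed(11)
  cfg <- sim_config(seed = 11, chrom_length = 2e6,
                    breeds = data.frame(name = c("A", "B"), ne = 60L,
                                        generations = 20L,
                                        group = c("dairy", "beef")),
                    trait = list(n_qtl = 10L))
  base <- simulate_neutral_panel(cfg)
  sp <- split_breeds(base, cfg)
  sw <- impose_sweep(sp$panels,
                     list(chrom = "chr1", pos = 1e6, s = 1, breeds = "A",
                          generations = 300L, stop_freq = 1.0),
                     cfg)
  tr <- sw$truth
  expect_equal(tr$final_freq[tr$breed == "A"], 1)
  expect_equal(tr$final_freq[tr$breed == "B"], 0)   # non-target untouched
  expect_true(all(sw$map$pos[sw$map$chrom == "chr1"] == sort(sw$map$pos[sw$map$chrom == "chr1"])))
  # the fixed region scores (near) zero HAPH: fixed segments have one haplotype
  part <- segment_partition(sw$panels$A$map)
  segval <- vapply(seq_len(nrow(part)), function(s) {
    sp2 <- haplotype_spectrum(sw$panels$A$hap[, part$first[s]:part$last[s]])
    haph_raw(sp2$p)
  }, numeric(1))
  at <- which.min(abs(part$midpoint - 1e6))
  expect_lt(segval[at], mean(segval))
  expect_lt(segval[at], 0.05)
})

test_that("a lost sweep allele is retried and the retry limit errors out", {
  set.seed(12)
  cfg <- tiny_sim_config()
  cfg$sweep_retry <- 1L
  base <- simulate_neutral_panel(cfg)
  sp <- split_breeds(base, cfg)
  # s = 0 from a single copy in a population of 60: loss is near-certain,
  # so one retry must exhaust quickly
  expect_error(
    impose_sweep(sp$panels,
                 list(chrom = "chr1", pos = 123457, s = 0, breeds = "A",
                      generations = 400L, stop_freq = 1.0), cfg),
    "lost")
})

test_that("mid-sweep |iHS| beats the genome median (scaled-down module oracle)", {
  # 10 replicates instead of the module example's 20, to stay in the test budget
  set.seed(13)
  hits <- 0L
  for (r in 1:10) {
    cfg <- sim_config(seed = 1300 + r,
                      sweeps = data.frame(chrom = "chr1", pos = 5e6, s = 2,
                                          breeds = "DairyA", generations = 400,
                                          stop_freq = 0.7),
                      breeds = data.frame(name = c("DairyA", "BeefA"), ne = 100L,
                                          generations = 50L,
                                          group = c("dairy", "beef")),
                      trait = list(n_qtl = 20L, truncation_fraction = 1,
                                   generations = 0L))
    ds <- simulate_dataset(cfg)
    grid <- build_grid(ds$map)
    anc <- call_ancestral(ds$outgroup)
    iw <- window_abs_ihs(ihs_scan(ds$panels$DairyA, anc = anc), grid)
    swi <- which(grid$start <= 5e6 & grid$end > 5e6)
    if (max(iw$max_abs_ihs[swi], na.rm = TRUE) >
        median(iw$max_abs_ihs, na.rm = TRUE)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("simulate_trait hits the target heritability and responds to selection", {
  set.seed(14)
  cfg <- tiny_sim_config()
  cfg$trait <- utils::modifyList(cfg$trait,
                                 list(n_qtl = 15L, h2 = 0.99, effect_sd = 1,
                                      min_maf = 0.05))
  base <- simulate_neutral_panel(cfg)
  sp <- split_breeds(base, cfg)
  tr <- simulate_trait(sp$panels, cfg)
  # h2 = 0.99 without selection: y ~ g with slope ~ 1, R^2 ~ 0.99
  fit <- lm(tr$phenotypes$y ~ tr$truth$genetic_values)
  expect_lt(abs(coef(fit)[2] - 1), 0.05)
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_lt(abs(tr$truth$realized_h2 - 0.99), 1e-10)   # exact by construction

  # truncation_fraction = 1 leaves the panels untouched
  cfg$trait$truncation_fraction <- 1; cfg$trait$generations <- 5L
  tr2 <- simulate_trait(sp$panels, cfg)
  expect_identical(tr2$panels$A$hap, sp$panels$A$hap)

  # truncation selection produces a positive response in nearly all replicates
  up <- 0L
  for (r in 1:10) {
    cfg2 <- tiny_sim_config(seed = 1400 + r)
    cfg2$trait <- utils::modifyList(cfg2$trait,
      list(n_qtl = 15L, h2 = 0.4, truncation_fraction = 0.3, generations = 6L))
    set.seed(1400 + r)
    trr <- simulate_trait(split_breeds(simulate_neutral_panel(cfg2), cfg2)$panels, cfg2)
    mp <- trr$truth$mean_phenotype
    if (mean(mp[nrow(mp), ]) > mean(mp[1, ])) up <- up + 1L
  }
  expect_gte(up, 9L)
})

test_that("simulate_trait errors when the trait has no genetic variance", {
  panel <- make_panel(matrix(0L, 10, 40), seq(0, by = 100, length.out = 40))
  cfg <- tiny_sim_config()
  cfg$trait$n_qtl <- 5L
  expect_error(simulate_trait(list(A = panel), cfg), "zero genetic variance|no usable")
})

test_that("outgroup genotypes recover ancestral states as designed", {
  map <- make_map(seq(0, by = 100, length.out = 5000))
  set.seed(15)
  og0 <- derive_outgroup(map, error_rate = 0)
  expect_true(all(call_ancestral(og0) == 0L))   # 100% recovery

  # one individual, error 0.5: among called (non-tie) sites, recovery ~ 50%
  og1 <- derive_outgroup(map, n_individuals = 1L, error_rate = 0.5)
  anc <- call_ancestral(og1)
  expect_lt(abs(mean(anc[!is.na(anc)] == 0L) - 0.5), 0.05)

  # defaults: ~85% of sites show a single allele across the outgroup (+-3%)
  og <- derive_outgroup(map)
  single <- mean(apply(og, 2, function(d) sum(d) == 0 || sum(d) == 2 * nrow(og)))
  expect_lt(abs(single - 0.85), 0.03)
  expect_lt(abs(attr(og, "expected_single_allele") - 0.85), 1e-12)
})

test_that("simulate_dataset is bit-reproducible from its seed", {
  cfg <- tiny_sim_config(seed = 16)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$panels$A$hap, d2$panels$A$hap)
  expect_identical(d1$map$pos, d2$map$pos)
  expect_identical(d1$phenotypes$y, d2$phenotypes$y)
  expect_identical(d1$outgroup, d2$outgroup)
})
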