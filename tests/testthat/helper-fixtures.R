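# Shared fixture builders. All fixtures are generated in code; tests that use
# randomness set their own seed.

make_map <- function(pos, chrom = "chr1", len = NULL) {
  if (is.null(len)) len <- max(pos) + 1000
  genome_map(rep(chrom, length(pos)), pos, setNames(len, chrom))
}

make_panel <- function(hap, pos, chrom = "chr1", len = NULL, population = "test") {
  haplotype_panel(hap, make_map(pos, chrom, len), population)
}

# random binary panel, columns iid Bernoulli(p)
rand_panel <- function(nh, m, p = 0.5, spacing = 1000, population = "test") {
  hap <- matrix(rbinom(nh * m, 1L, p), nh, m)
  make_panel(hap, seq(0L, by = spacing, length.out = m), population = population)
}

# small two-breed simulation used by several IO / pipeline tests
tiny_sim_config <- function(seed = 1, ...) {
  sim_config(seed = seed, chrom_length = 1e6, base_ne = 40L, burn_in = 300L,
             breeds = data.frame(name = c("A", "B"), ne = 30L,
                                 generations = 10L,
                                 group = c("dairy", "beef"),
                                 stringsAsFactors = FALSE),
             trait = list(n_qtl = 15L, truncation_fraction = 1,
                          generations = 0L),
             ...)
}

# independent brute-force HAPH: identify distinct rows by pairwise comparison,
# then population variance of their frequencies
brute_haph <- function(H) {
  n <- nrow(H)
  cls <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (cls[i] > 0L) next
    k <- k + 1L
    cls[i] <- k
    if (i < n) for (j in (i + 1L):n) {
      if (cls[j] == 0L && all(H[i, ] == H[j, ])) cls[j] <- k
    }
  }
  p <- as.numeric(table(cls)) / n
  mean((p - mean(p))^2)
}

# independent trapezoid-with-interpolated-crossing integral of an EHH curve
# side, evaluated by dense Riemann sum on the linear interpolant
riemann_iehh_side <- function(dist, ehh, threshold, n_grid = 2e5) {
  d <- c(0, dist); e <- c(1, ehh)
  cross <- which(e < threshold)[1]
  if (is.na(cross)) {
    upper <- max(d)
  } else {
    i <- cross
    upper <- d[i - 1] + (d[i] - d[i - 1]) * (e[i - 1] - threshold) / (e[i - 1] - e[i])
  }
  if (upper <= 0) return(0)
  x <- seq(0, upper, length.out = n_grid)
  y <- approx(d, e, xout = x, rule = 2)$y
  sum((y[-1] + y[-n_grid]) / 2) * (upper / (n_grid - 1))
}
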