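#' Per-SNP pairwise F_ST (printed-symbols estimator)
#'
#' Default estimator for two populations with allele frequencies `p1`, `p2`:
#' `F_ST = [(p1 - pbar)^2 + (p2 - pbar)^2] / 2 / [pbar (1 - pbar)]` with
#' `pbar = (p1 + p2)/2`; algebraically `(p1 - p2)^2 / (4 pbar (1 - pbar))`.
#' No sample-size correction. SNPs monomorphic across the pair
#' (`pbar` 0 or 1) are undefined (`NA`) and excluded from window averages.
#'
#' @param p1,p2 allele frequencies in each population (vectorized).
#' @return F_ST values in `[0, 1]`, `NA` where the pair is monomorphic.
#' @seealso [wc_fst_pair] for the Weir & Cockerham (1984) theta with
#'   sample-size correction.
#' @export
snp_fst_pair <- function(p1, p2) {
  stopifnot(all(p1 >= 0 & p1 <= 1, na.rm = TRUE), all(p2 >= 0 & p2 <= 1, na.rm = TRUE))
  pbar <- (p1 + p2) / 2
  den <- pbar * (1 - pbar)
  num <- ((p1 - pbar)^2 + (p2 - pbar)^2) / 2
  ifelse(den == 0, NA_real_, num / den)
}

#' Weir & Cockerham (1984) theta for two populations (allele-count version)
#'
#' Moment estimator with sample-size correction, on allele counts (appropriate
#' for phased haplotype data; no heterozygosity term).
#'
#' @param p1,p2 allele frequencies.
#' @param n1,n2 haplotype (allele) sample sizes.
#' @return theta per SNP; `NA` where undefined.
#' @export
wc_fst_pair <- function(p1, p2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / ((n1 - 1) + (n2 - 1))
  den <- msp + (nc - 1) * msg
  ifelse(den == 0, NA_real_, (msp - msg) / den)
}

#' Windowed pairwise F_ST for one pair of populations
#'
#' Per-SNP F_ST averaged (unweighted mean of ratios) over the polymorphic SNPs
#' assigned to each window, then standardized by the mean over windows for the
#' pair (mean 1).
#'
#' @param panel1,panel2 [haplotype_panel]s on the same map.
#' @param grid a `window_grid`.
#' @param estimator `"eq1"` (default, [snp_fst_pair]) or `"wc84"`
#'   ([wc_fst_pair]).
#' @return Data frame per window: `chrom`, `start`, `end`, `n_snps`, `raw`,
#'   `std`.
#' @export
fst_window_scan <- function(panel1, panel2, grid, estimator = c("eq1", "wc84")) {
  estimator <- match.arg(estimator)
  stopifnot(identical(panel1$map$pos, panel2$map$pos))
  p1 <- allele_freq(panel1)
  p2 <- allele_freq(panel2)
  fst <- if (estimator == "eq1") snp_fst_pair(p1, p2)
         else wc_fst_pair(p1, p2, n_haplotypes(panel1), n_haplotypes(panel2))
  map <- panel1$map
  asg <- assign_points(grid, map$chrom, map$pos)
  raw <- vapply(asg, function(idx) {
    v <- fst[idx]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
             n_snps = vapply(asg, function(idx) sum(!is.na(fst[idx])), integer(1)),
             raw = raw, std = standardize_windows(raw), stringsAsFactors = FALSE)
}

#' All pairwise windowed F_ST scans
#'
#' Runs [fst_window_scan] for every unordered pair of populations (8 breeds =
#' 28 comparisons) and records each pair's group labels (e.g. dairy/beef).
#'
#' @param panels named list of [haplotype_panel]s on a shared map.
#' @param grid a `window_grid`.
#' @param groups named character vector mapping population name to group
#'   (`"dairy"`/`"beef"`); needed for [group_contrast_test].
#' @param estimator see [fst_window_scan].
#' @return List with `std` and `raw` (windows x pairs matrices) and `pairs`
#'   (data frame: `pop1`, `pop2`, `group1`, `group2`, `cross` - TRUE for
#'   between-group pairs).
#' @export
fst_pair_scan <- function(panels, grid, groups = NULL, estimator = "eq1") {
  nm <- names(panels)
  if (is.null(nm)) stop("panels must be a named list")
  cmb <- utils::combn(nm, 2)
  n_pairs <- ncol(cmb)
  std <- raw <- matrix(NA_real_, nrow(grid), n_pairs)
  lab <- character(n_pairs)
  for (k in seq_len(n_pairs)) {
    sc <- fst_window_scan(panels[[cmb[1, k]]], panels[[cmb[2, k]]], grid,
                          estimator = estimator)
    raw[, k] <- sc$raw
    std[, k] <- sc$std
    lab[k] <- paste(cmb[1, k], cmb[2, k], sep = ":")
  }
  colnames(std) <- colnames(raw) <- lab
  pairs <- data.frame(pop1 = cmb[1, ], pop2 = cmb[2, ], stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    pairs$group1 <- unname(groups[pairs$pop1])
    pairs$group2 <- unname(groups[pairs$pop2])
    pairs$cross <- pairs$group1 != pairs$group2
  }
  list(std = std, raw = raw, pairs = pairs)
}

#' Mann-Whitney U test (one-sided, greater)
#'
#' U counts the (x, y) pairs with x > y (ties count 1/2). Exact p-value by U
#' enumeration when there are no ties and `n1 * n2 <= exact_max`; otherwise
#' mid-rank normal approximation with tie correction and continuity
#' correction. With all values tied the variance is zero and p = 0.5 (U is at
#' its null mean).
#'
#' @param x,y numeric samples; alternative is x stochastically greater than y.
#' @param exact_max largest `n1 * n2` for the exact path (default 400).
#' @return List with `U`, `p`, `exact`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 400) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(list(U = NA_real_, p = NA_real_, exact = NA))
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 * n2 <= exact_max) {
    p <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    return(list(U = U, p = p, exact = TRUE))
  }
  n <- n1 + n2
  tt <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
  if (sig2 <= 0) return(list(U = U, p = 0.5, exact = FALSE))
  z <- (U - n1 * n2 / 2 - 0.5) / sqrt(sig2)
  list(U = U, p = pnorm(z, lower.tail = FALSE), exact = FALSE)
}

#' Dairy-versus-beef window contrast
#'
#' Per window, compares the standardized F_ST of cross-group pairs (one dairy,
#' one beef population) against within-group pairs (both dairy or both beef)
#' with a one-sided Mann-Whitney U test (alternative: cross-group values
#' stochastically greater). Windows where either group has no finite value are
#' missing.
#'
#' @param pair_scan result of [fst_pair_scan] (must carry group labels).
#' @return Data frame per window: `U`, `p`, `n_cross`, `n_within`.
#' @export
group_contrast_test <- function(pair_scan) {
  if (is.null(pair_scan$pairs$cross))
    stop("pair scan carries no group labels; rerun fst_pair_scan with groups=")
  cross <- pair_scan$pairs$cross
  std <- pair_scan$std
  out <- data.frame(U = rep(NA_real_, nrow(std)), p = NA_real_,
                    n_cross = 0L, n_within = 0L)
  for (w in seq_len(nrow(std))) {
    x <- std[w, cross]; x <- x[is.finite(x)]
    y <- std[w, !cross]; y <- y[is.finite(y)]
    out$n_cross[w] <- length(x)
    out$n_within[w] <- length(y)
    if (!length(x) || !length(y)) next
    mw <- mann_whitney_u(x, y)
    out$U[w] <- mw$U
    out$p[w] <- mw$p
  }
  out
}
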