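#' Call ancestral alleles from outgroup genotypes
#'
#' The ancestral allele at each SNP is the majority allele over all outgroup
#' allele calls. An exact tie, or zero calls, leaves the SNP uncalled (`NA`),
#' which excludes it from the iHS scan.
#'
#' @param outgroup integer matrix of outgroup genotypes, individuals x SNPs,
#'   coded as the dosage of allele 1 (0/1/2, `NA` = missing call).
#' @return Integer vector of ancestral alleles (0/1/`NA`), one per SNP, with
#'   attribute `counts` (2-row matrix of allele-0 and allele-1 call counts).
#' @export
call_ancestral <- function(outgroup) {
  outgroup <- as.matrix(outgroup)
  n1 <- colSums(outgroup, na.rm = TRUE)
  ncall <- 2L * colSums(!is.na(outgroup))
  n0 <- ncall - n1
  anc <- ifelse(ncall == 0L, NA_integer_,
                ifelse(n0 > n1, 0L, ifelse(n1 > n0, 1L, NA_integer_)))
  structure(as.integer(anc), counts = rbind(allele0 = n0, allele1 = n1))
}

#' Extended haplotype homozygosity curve at a core SNP
#'
#' For the carriers of `allele` at the core SNP, EHH at a flanking SNP is the
#' probability that two random distinct carrier haplotypes are identical at
#' every SNP from the core through that position:
#' `EHH = sum_h C(n_h, 2) / C(n_A, 2)` over identity groups `h`. The curve
#' starts at 1 at the core, is non-increasing outward, and is followed in each
#' direction until it drops below `threshold` or the chromosome ends.
#'
#' Pure-R reference implementation; the genome scan ([ihs_scan]) uses a
#' compiled path with identical semantics.
#'
#' @param panel a [haplotype_panel].
#' @param core SNP column index of the core.
#' @param allele core allele (0 or 1).
#' @param threshold decay threshold at which extension stops (default 0.5).
#' @return List with `left`/`right` data frames (`dist` bp from core, `ehh`),
#'   `n_carriers`, and `truncated_left`/`truncated_right` flags set when the
#'   chromosome end was reached with EHH still at or above the threshold;
#'   `NULL` when fewer than 2 haplotypes carry the allele (iHS undefined).
#' @export
ehh_curve <- function(panel, core, allele, threshold = 0.5) {
  H <- panel$hap
  map <- panel$map
  ch <- map$chrom[core]
  on_chr <- which(map$chrom == ch)
  carriers <- which(H[, core] == allele)
  if (length(carriers) < 2L) return(NULL)
  one_side <- function(step) {
    ids <- rep(1L, length(carriers))
    nA <- length(carriers)
    pairsA <- choose(nA, 2)
    dist <- numeric(0); ehh <- numeric(0)
    truncated <- TRUE
    j <- core + step
    while (j %in% on_chr) {
      ids <- match(paste(ids, H[carriers, j]), unique(paste(ids, H[carriers, j])))
      e <- sum(choose(tabulate(ids), 2)) / pairsA
      dist <- c(dist, abs(map$pos[j] - map$pos[core]))
      ehh <- c(ehh, e)
      if (e < threshold) { truncated <- FALSE; break }
      j <- j + step
    }
    list(df = data.frame(dist = dist, ehh = ehh), truncated = truncated)
  }
  L <- one_side(-1L); R <- one_side(+1L)
  list(core = core, allele = allele, n_carriers = length(carriers),
       left = L$df, right = R$df,
       truncated_left = L$truncated, truncated_right = R$truncated)
}

#' Integrated EHH (iEHH) of a curve
#'
#' Trapezoidal integral of the EHH decay curve over physical distance (bp),
#' summed over the two directions. Each direction starts at (0 bp, EHH = 1)
#' and is truncated at the linearly interpolated point where EHH crosses
#' `threshold`; if the chromosome ends first the integral stops at the last
#' SNP and the result is marked truncated.
#'
#' @param curve result of [ehh_curve].
#' @param threshold decay threshold (default 0.5). Must match the threshold
#'   the curve was computed with (a curve followed further is also fine).
#' @return Numeric area (bp x EHH units) with attribute `truncated`.
#' @export
iehh <- function(curve, threshold = 0.5) {
  if (is.null(curve)) return(NA_real_)
  one <- function(df) {
    d_prev <- 0; e_prev <- 1; area <- 0
    stopifnot(e_prev >= threshold)  # EHH(0) = 1 by construction
    for (i in seq_len(nrow(df))) {
      d <- df$dist[i]; e <- df$ehh[i]
      if (e < threshold) {
        dcross <- if (e_prev > e) d_prev + (d - d_prev) * (e_prev - threshold) / (e_prev - e) else d
        return(list(area = area + 0.5 * (e_prev + threshold) * (dcross - d_prev),
                    truncated = FALSE))
      }
      area <- area + 0.5 * (e_prev + e) * (d - d_prev)
      d_prev <- d; e_prev <- e
    }
    list(area = area, truncated = TRUE)  # ran out of SNPs above threshold
  }
  L <- one(curve$left); R <- one(curve$right)
  structure(L$area + R$area, truncated = L$truncated || R$truncated)
}

#' Raw (unstandardized) iHS ratio
#'
#' `x = iEHH_derived / iEHH_ancestral` and its log10. Undefined (NA) when
#' either integral is missing or zero.
#'
#' @param iehh_der,iehh_anc integrated EHH for the derived and ancestral
#'   allele (vectorized).
#' @return Data frame with columns `x` and `log10_ratio`.
#' @export
raw_ihs <- function(iehh_der, iehh_anc) {
  x <- ifelse(is.na(iehh_der) | is.na(iehh_anc) | iehh_anc <= 0 | iehh_der <= 0,
              NA_real_, iehh_der / iehh_anc)
  data.frame(x = x, log10_ratio = log10(x))
}

#' Bin-wise standardization of iHS
#'
#' Standardizes the log10 iEHH ratios to mean 0 and SD 1 within each of
#' `n_bins` equal-width bins of ancestral-allele frequency on (0, 1), using
#' the bin's sample mean and sample (n-1) SD. Records in bins with fewer than
#' 2 usable records, or zero SD, become missing.
#'
#' @param log10_ratio raw log10 iEHH ratios (NA allowed).
#' @param freq_anc ancestral-allele frequency per record.
#' @param n_bins number of frequency bins (default 20).
#' @return Data frame with columns `bin` (integer bin index) and `ihs`
#'   (standardized score; `abs(ihs)` is the |iHS| the window scan uses).
#' @export
standardize_ihs <- function(log10_ratio, freq_anc, n_bins = 20L) {
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- findInterval(freq_anc, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  bin[is.na(freq_anc)] <- NA_integer_
  ihs <- rep(NA_real_, length(log10_ratio))
  for (b in unique(bin[!is.na(bin)])) {
    idx <- which(bin == b & !is.na(log10_ratio))
    if (length(idx) < 2L) next
    mu <- mean(log10_ratio[idx])
    sig <- sd(log10_ratio[idx])
    if (sig == 0) next
    ihs[idx] <- (log10_ratio[idx] - mu) / sig
  }
  data.frame(bin = bin, ihs = ihs)
}

#' Genome-wide iHS scan for one population
#'
#' Computes per-SNP iEHH for the ancestral and derived allele (compiled EHH
#' path, decay threshold `threshold`), filters to minor allele frequency
#' `> maf_min`, forms the raw log10 ratio and standardizes it in `n_bins`
#' ancestral-frequency bins ([standardize_ihs]).
#'
#' @param panel a [haplotype_panel].
#' @param anc ancestral-allele calls (0/1/NA per SNP), e.g. from
#'   [call_ancestral]; defaults to the `anc` column of the panel's map.
#' @param threshold EHH decay threshold (default 0.5).
#' @param maf_min minor-allele-frequency floor; SNPs must exceed it (default
#'   0.001).
#' @param n_bins frequency bins for standardization (default 20).
#' @param discard_truncated drop SNPs whose EHH curve reached a chromosome end
#'   while still at or above the threshold (default TRUE, the behaviour of the
#'   standard EHH tooling; such integrals are right-censored and otherwise
#'   inject extreme ratios near chromosome borders).
#' @return Data frame, one row per SNP: `chrom`, `pos`, `anc`, `freq_anc`,
#'   `iehh_anc`, `iehh_der`, `x`, `log10_ratio`, `bin`, `ihs`, `abs_ihs`,
#'   `truncated`.
#' @export
ihs_scan <- function(panel, anc = NULL, threshold = 0.5, maf_min = 0.001,
                     n_bins = 20L, discard_truncated = TRUE) {
  map <- panel$map
  if (is.null(anc)) {
    if (is.null(map$anc)) stop("no ancestral calls: pass anc= or use a map with an anc column")
    anc <- map$anc
  }
  anc <- as.integer(anc)
  stopifnot(length(anc) == nrow(map))
  f1 <- allele_freq(panel)                       # derived (allele 1) frequency
  maf <- pmin(f1, 1 - f1)
  use <- !is.na(anc) & maf > maf_min
  anc_used <- ifelse(use, anc, NA_integer_)

  ia <- rep(NA_real_, nrow(map)); idv <- rep(NA_real_, nrow(map))
  trunc <- rep(FALSE, nrow(map))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    res <- ehh_scan_cpp(panel$hap[, idx, drop = FALSE], map$pos[idx],
                        anc_used[idx], threshold)
    ia[idx] <- res$iehh_anc
    idv[idx] <- res$iehh_der
    trunc[idx] <- res$truncated
  }
  freq_anc <- ifelse(is.na(anc), NA_real_, ifelse(anc == 1L, f1, 1 - f1))
  if (discard_truncated) {
    ia[trunc] <- NA_real_
    idv[trunc] <- NA_real_
  }
  rr <- raw_ihs(idv, ia)
  std <- standardize_ihs(rr$log10_ratio, freq_anc, n_bins = n_bins)
  data.frame(chrom = map$chrom, pos = map$pos, anc = anc,
             freq_anc = freq_anc, iehh_anc = ia, iehh_der = idv,
             x = rr$x, log10_ratio = rr$log10_ratio,
             bin = std$bin, ihs = std$ihs, abs_ihs = abs(std$ihs),
             truncated = trunc, stringsAsFactors = FALSE)
}

#' Window maximum of |iHS|
#'
#' Assigns SNPs to windows and takes the maximum |iHS| per window. No further
#' standardization: iHS is already in SD units from the binned
#' standardization.
#'
#' @param records per-SNP table from [ihs_scan].
#' @param grid a `window_grid`.
#' @param top_q flagged fraction (default 0.05).
#' @return Data frame, one row per window: `chrom`, `start`, `end`, `n_snps`,
#'   `max_abs_ihs`, `flag`.
#' @export
window_abs_ihs <- function(records, grid, top_q = 0.05) {
  asg <- assign_points(grid, records$chrom, records$pos)
  mx <- vapply(asg, function(idx) {
    v <- records$abs_ihs[idx]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else max(v)
  }, numeric(1))
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    n_snps = vapply(asg, length, integer(1)),
                    max_abs_ihs = mx, stringsAsFactors = FALSE)
  out$flag <- flag_top_fraction(out$max_abs_ihs, q = top_q)
  out
}
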