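#' Partition a SNP map into 30/31-SNP segments
#'
#' Splits each chromosome's SNPs, left to right, into non-overlapping,
#' contiguous segments of 30 or 31 SNPs. The remainder `r = n mod 30` is
#' absorbed by widening the first `r` segments to 31 SNPs, so every segment
#' has 30 or 31 SNPs and all SNPs are covered. When `n` cannot be tiled by
#' 30/31-SNP segments at all (fewer than 930 SNPs and `r` exceeding the
#' segment count) every segment is widened to 31 and the terminal remainder
#' (< 30 SNPs) is left uncovered. Chromosomes with fewer than `segment_size`
#' SNPs are skipped with a warning. The segment midpoint is the
#' mean bp of its first and last SNP; it decides window membership in
#' [haph_scan].
#'
#' @param map a [genome_map].
#' @param segment_size base segment length in SNPs (default 30).
#' @return Data frame with one row per segment: `chrom`, `first` and `last`
#'   (SNP indices into the map), `n_snp`, `midpoint` (bp).
#' @export
segment_partition <- function(map, segment_size = 30L) {
  pieces <- lapply(unique(map$chrom), function(ch) {
    idx <- which(map$chrom == ch)
    n <- length(idx)
    nseg <- n %/% segment_size
    if (nseg == 0L) {
      warning("chromosome ", ch, " has only ", n, " SNPs (< ", segment_size,
              "); no segments built")
      return(NULL)
    }
    r <- n %% segment_size
    sizes <- rep(segment_size, nseg)
    if (r > 0L && r <= nseg) {
      sizes[seq_len(r)] <- segment_size + 1L
    } else if (r > nseg) {
      # n cannot be tiled by {30, 31} segments; leave the terminal remainder
      # (< 30 SNPs after widening every segment) uncovered
      extra <- r - nseg
      sizes <- sizes + 1L
      message("chromosome ", ch, ": terminal remainder of ", extra,
              " SNP(s) not covered by any segment")
    }
    last <- cumsum(sizes)
    first <- last - sizes + 1L
    data.frame(chrom = ch, first = idx[first], last = idx[last], n_snp = sizes,
               midpoint = (map$pos[idx[first]] + map$pos[idx[last]]) / 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(chrom = character(), first = integer(), last = integer(),
                      n_snp = integer(), midpoint = numeric())
  rownames(out) <- NULL
  out
}

#' Haplotype spectrum of a segment
#'
#' Tabulates the distinct haplotype strings over a block of SNP columns and
#' their within-population frequencies. Haplotypes with any missing call in
#' the block are excluded; if fewer than `min_usable` of the haplotypes remain
#' the spectrum is unusable (`NULL`).
#'
#' @param H haplotype matrix block (haplotypes x SNPs, 0/1, NA allowed).
#' @param min_usable minimum usable fraction of haplotypes (default 0.5).
#' @return List with `p` (frequencies of the distinct haplotypes, summing to
#'   1), `n_distinct`, `n_used`; or `NULL` if unusable.
#' @export
haplotype_spectrum <- function(H, min_usable = 0.5) {
  H <- as.matrix(H)
  ok <- !apply(is.na(H), 1L, any)
  if (sum(ok) < min_usable * nrow(H) || sum(ok) == 0L) return(NULL)
  keys <- do.call(paste0, as.data.frame(H[ok, , drop = FALSE]))
  tab <- table(keys)
  p <- as.numeric(tab) / sum(tab)
  list(p = p, n_distinct = length(p), n_used = sum(ok))
}

#' Raw HAPH statistic
#'
#' The variance of the distinct-haplotype frequencies at a segment:
#' `HAPH = (1/N) * sum_i (p_i - 1/N)^2` over the `N` distinct haplotypes with
#' frequencies `p_i`. High when one or a few haplotypes dominate a spectrum of
#' many rare ones; 0 when all distinct haplotypes are equally frequent - in
#' particular 0 at a fixed segment (N = 1), which is why swept-to-fixation
#' regions score near zero.
#'
#' @param p frequencies of the distinct haplotypes (must sum to 1).
#' @param denom `"N"` (population variance, default) or `"N-1"` (sample
#'   variance).
#' @return Non-negative scalar in `[0, 1)`.
#' @export
haph_raw <- function(p, denom = c("N", "N-1")) {
  denom <- match.arg(denom)
  if (any(p <= 0)) stop("haplotype frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  N <- length(p)
  v <- sum((p - 1 / N)^2) / N
  if (denom == "N-1") {
    if (N == 1L) return(0)
    v <- v * N / (N - 1L)
  }
  v
}

#' HAPH window scan for one population
#'
#' Computes the raw HAPH for every 30/31-SNP segment, averages segments into
#' the 250 kb windows their midpoints fall in, standardizes by the mean over
#' windows (mean 1) and flags the top fraction.
#'
#' @param panel a [haplotype_panel].
#' @param grid a `window_grid` from [build_grid].
#' @param partition segment table from [segment_partition]; built from the
#'   panel's map when omitted.
#' @param top_q flagged fraction (default 0.05).
#' @param denom HAPH variance denominator, see [haph_raw].
#' @param min_usable see [haplotype_spectrum].
#' @return Data frame with one row per window: `chrom`, `start`, `end`,
#'   `n_segments`, `raw`, `std`, `flag`; attribute `segments` holds the
#'   per-segment values.
#' @export
haph_scan <- function(panel, grid, partition = NULL, top_q = 0.05,
                      denom = "N", min_usable = 0.5) {
  if (is.null(partition)) partition <- segment_partition(panel$map)
  seg_val <- vapply(seq_len(nrow(partition)), function(s) {
    sp <- haplotype_spectrum(
      panel$hap[, partition$first[s]:partition$last[s], drop = FALSE],
      min_usable = min_usable)
    if (is.null(sp)) NA_real_ else haph_raw(sp$p, denom = denom)
  }, numeric(1))
  asg <- assign_points(grid, partition$chrom, partition$midpoint)
  raw <- vapply(asg, function(idx) {
    v <- seg_val[idx]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  out <- data.frame(chrom = grid$chrom, start = grid$start, end = grid$end,
                    n_segments = vapply(asg, length, integer(1)),
                    raw = raw, std = standardize_windows(raw),
                    stringsAsFactors = FALSE)
  out$flag <- flag_top_fraction(out$std, q = top_q)
  attr(out, "segments") <- cbind(partition, haph = seg_val)
  out
}

#' Merge flagged windows into sweep regions
#'
#' Flagged (top-fraction) windows on the same chromosome whose intervals are
#' separated by less than `gap` bp merge into one region spanning from the
#' smallest start to the largest end; overlapping windows always merge.
#' Regions longer than 2 Mb and 5 Mb are reported separately, the long-sweep
#' shortlists.
#'
#' @param grid a `window_grid`.
#' @param flags logical per-window flags (e.g. the `flag` column of
#'   [haph_scan]); `NA` is treated as unflagged.
#' @param gap maximum separation in bp for merging (default 1 Mb).
#' @return List with data frames `regions` (all merged regions: `chrom`,
#'   `start`, `end`, `length`, `n_windows`), `over_2mb` and `over_5mb`.
#' @export
merge_sweep_regions <- function(grid, flags, gap = 1e6) {
  sel <- which(!is.na(flags) & flags)
  cols <- c("chrom", "start", "end", "length", "n_windows")
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      length = numeric(), n_windows = integer())
  if (!length(sel)) return(list(regions = empty, over_2mb = empty, over_5mb = empty))
  w <- grid[sel, c("chrom", "start", "end")]
  w <- w[order(w$chrom, w$start), ]
  regions <- list()
  cur <- w[1, ]
  nw <- 1L
  for (i in seq_len(nrow(w))[-1]) {
    if (w$chrom[i] == cur$chrom && (w$start[i] - cur$end) < gap) {
      cur$end <- max(cur$end, w$end[i])
      nw <- nw + 1L
    } else {
      regions[[length(regions) + 1L]] <- cbind(cur, n_windows = nw)
      cur <- w[i, ]
      nw <- 1L
    }
  }
  regions[[length(regions) + 1L]] <- cbind(cur, n_windows = nw)
  reg <- do.call(rbind, regions)
  reg$length <- reg$end - reg$start
  reg <- reg[, cols]
  rownames(reg) <- NULL
  list(regions = reg,
       over_2mb = reg[reg$length > 2e6, , drop = FALSE],
       over_5mb = reg[reg$length > 5e6, , drop = FALSE])
}
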