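#' SNP map for a set of chromosomes
#'
#' An ordered table of biallelic SNPs: chromosome, 0-based bp position and,
#' optionally, an ancestral-allele call per SNP. Chromosome lengths travel with
#' the map because window grids are anchored at bp 0 and extend to the
#' chromosome end, not to the last SNP.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based bp positions, strictly increasing
#'   within each chromosome.
#' @param chrom_len named numeric vector of chromosome lengths in bp; must
#'   cover every chromosome present.
#' @param anc optional integer vector of ancestral alleles (0/1, `NA` =
#'   uncalled), one per SNP.
#' @return A `genome_map`: a data frame with columns `chrom`, `pos` (and `anc`
#'   when given) and a `chrom_len` attribute.
#' @export
genome_map <- function(chrom, pos, chrom_len, anc = NULL) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  stopifnot(length(chrom) == length(pos))
  if (is.null(names(chrom_len)) || !all(unique(chrom) %in% names(chrom_len)))
    stop("chrom_len must be a named vector covering every chromosome in the map")
  ord <- order(match(chrom, names(chrom_len)), pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (anyDuplicated(p)) stop("duplicate positions on chromosome ", ch)
    if (any(p < 0) || any(p >= chrom_len[[ch]]))
      stop("positions outside [0, chrom_len) on chromosome ", ch)
  }
  map <- data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  if (!is.null(anc)) {
    stopifnot(length(anc) == length(pos))
    map$anc <- as.integer(anc)[ord]
    bad <- !is.na(map$anc) & !(map$anc %in% c(0L, 1L))
    if (any(bad)) stop("ancestral alleles must be 0, 1 or NA")
  }
  attr(map, "chrom_len") <- chrom_len
  class(map) <- c("genome_map", "data.frame")
  map
}

#' @export
`[.genome_map` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "chrom_len") <- attr(x, "chrom_len")
    class(out) <- c("genome_map", "data.frame")
  }
  out
}

chrom_lengths <- function(map) attr(map, "chrom_len")

#' Phased haplotype panel for one population
#'
#' A strictly binary matrix of phased haplotypes (rows) by SNPs (columns),
#' tied to a [genome_map]. Individual `i` owns rows `2*i - 1` and `2*i`.
#' Allele 1 is the derived allele under the package's simulator convention;
#' the statistics themselves only require a consistent binary coding.
#'
#' @param hap integer matrix of 0/1 (NA allowed for missing calls),
#'   `2 * n_individuals` rows and `nrow(map)` columns.
#' @param map a [genome_map].
#' @param population population (breed) label.
#' @return A `haplotype_panel` (list with elements `hap`, `map`, `population`).
#' @export
haplotype_panel <- function(hap, map, population = "pop") {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (!inherits(map, "genome_map")) stop("map must be a genome_map")
  if (ncol(hap) != nrow(map))
    stop("panel has ", ncol(hap), " SNP columns but the map has ", nrow(map), " SNPs")
  if (nrow(hap) %% 2L != 0L) stop("haplotype count must be even (phased diploids)")
  v <- hap[!is.na(hap)]
  if (length(v) && !all(v %in% c(0L, 1L))) stop("haplotypes must be strictly binary")
  structure(list(hap = hap, map = map, population = as.character(population)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel '%s': %d haplotypes (%d diploids) x %d SNPs on %d chromosome(s)\n",
              x$population, nrow(x$hap), nrow(x$hap) / 2L, ncol(x$hap),
              length(unique(x$map$chrom))))
  invisible(x)
}

n_haplotypes <- function(panel) nrow(panel$hap)

#' Genotype dosage matrix of a panel
#'
#' Collapses phased haplotypes to per-individual derived-allele dosages in
#' \{0, 1, 2\} (individuals x SNPs), the genotype coding the GEBV stage uses.
#'
#' @param panel a [haplotype_panel].
#' @return Integer matrix, `n_individuals` x `n_snps`.
#' @export
dosage_matrix <- function(panel) {
  H <- panel$hap
  n <- nrow(H) / 2L
  H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
}

#' Derived-allele frequencies of a panel
#'
#' @param panel a [haplotype_panel].
#' @return Numeric vector of derived (allele 1) frequencies, one per SNP,
#'   computed over non-missing calls.
#' @export
allele_freq <- function(panel) colMeans(panel$hap, na.rm = TRUE)
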