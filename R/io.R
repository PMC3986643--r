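#' Write breed panels as a phased VCF
#'
#' One multi-sample VCF with GT-only records, phased with `|`. Positions are
#' 1-based in the file (internal coordinates are 0-based). By the simulator's
#' convention REF is the ancestral allele (written `A`) and ALT the derived
#' allele (written `G`); the convention is recorded in the header. A
#' two-column sample-to-population table is written next to the VCF
#' (`<path>.samples.tsv`) unless `samples_path = NA`.
#'
#' @param panels named list of [haplotype_panel]s on a shared map.
#' @param path output VCF path.
#' @param samples_path path for the sample table (default `<path>.samples.tsv`;
#'   `NA` skips it).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panels, path, samples_path = NULL) {
  map <- panels[[1]]$map
  lens <- chrom_lengths(map)
  samples <- character(0); pops <- character(0)
  gt_cols <- list()
  for (nm in names(panels)) {
    H <- panels[[nm]]$hap
    n <- nrow(H) / 2L
    ids <- paste0(nm, "_", seq_len(n))
    samples <- c(samples, ids)
    pops <- c(pops, rep(nm, n))
    h1 <- H[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- H[seq(2L, 2L * n, 2L), , drop = FALSE]
    g <- matrix(paste0(h1, "|", h2), nrow = n)
    g[is.na(h1) | is.na(h2)] <- ".|."
    gt_cols[[nm]] <- g
  }
  gt <- do.call(rbind, gt_cols)  # samples x snps
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    "##convention=REF is the ancestral allele; ALT the derived allele; positions 1-based",
    paste0("##contig=<ID=", names(lens), ",length=", format(lens, scientific = FALSE, trim = TRUE), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- cbind(map$chrom, map$pos + 1L, paste0("snp", seq_len(nrow(map))),
                "A", "G", ".", ".", ".", "GT", t(gt))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(body, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (is.null(samples_path)) samples_path <- paste0(path, ".samples.tsv")
  if (!is.na(samples_path))
    write.table(data.frame(sample = samples, population = pops),
                samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phased VCF into per-population haplotype panels
#'
#' Uses `VariantAnnotation::readVcf` when available (a plain-text fallback
#' parser handles the GT-only VCFs this package writes). Only biallelic SNP
#' records with fully phased GT (`|` separator) are kept; multi-allelic or
#' unphased records are dropped with a message. Allele 1 in the returned
#' panels is the ALT allele; under this package's convention that is the
#' derived allele.
#'
#' @param path VCF path.
#' @param sample_populations data frame (`sample`, `population`) or path to
#'   such a TSV; defaults to `<path>.samples.tsv`.
#' @param method `"auto"` (VariantAnnotation when installed), or force
#'   `"variantannotation"` / `"text"`.
#' @return List with `panels` (named list of [haplotype_panel]s) and `map`.
#' @export
read_phased_vcf <- function(path, sample_populations = NULL,
                            method = c("auto", "variantannotation", "text")) {
  method <- match.arg(method)
  if (is.null(sample_populations)) sample_populations <- paste0(path, ".samples.tsv")
  if (is.character(sample_populations))
    sample_populations <- read.delim(sample_populations, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "population") %in% names(sample_populations)))
  use_va <- switch(method,
                   auto = requireNamespace("VariantAnnotation", quietly = TRUE),
                   variantannotation = TRUE, text = FALSE)

  if (use_va) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    gt <- VariantAnnotation::geno(vcf)$GT
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- BiocGenerics::start(rr) - 1L
    alt_n <- S4Vectors::elementNROWS(rr$ALT)
    lens <- GenomeInfoDb::seqlengths(rr)
    if (any(is.na(lens))) lens[is.na(lens)] <- NA
  } else {
    raw <- readLines(path)
    hdr <- raw[startsWith(raw, "##")]
    cn <- strsplit(sub("^#", "", raw[startsWith(raw, "#CHROM")]), "\t")[[1]]
    body <- read.delim(text = raw[!startsWith(raw, "#")], header = FALSE,
                       col.names = cn, check.names = FALSE,
                       stringsAsFactors = FALSE)
    chrom <- as.character(body$CHROM)
    pos <- body$POS - 1L
    alt_n <- lengths(strsplit(as.character(body$ALT), ","))
    gt <- as.matrix(body[, setdiff(cn, c("CHROM", "POS", "ID", "REF", "ALT",
                                         "QUAL", "FILTER", "INFO", "FORMAT")),
                         drop = FALSE])
    ctg <- hdr[startsWith(hdr, "##contig=")]
    lens <- setNames(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)),
                     sub(".*ID=([^,>]+).*", "\\1", ctg))
  }
  gt1 <- gt
  gt1[] <- sub(":.*", "", gt)  # GT is the first FORMAT field
  ok_gt <- matrix(grepl("^[01.]\\|[01.]$", gt1), nrow = nrow(gt1))
  phased <- rowSums(!ok_gt) == 0L
  biallelic <- alt_n == 1L
  keep <- phased & biallelic
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message("dropped ", sum(!biallelic), " multi-allelic and ",
            sum(biallelic & !phased), " unphased/invalid record(s)")
  if (!any(keep)) stop("no phased biallelic records in ", path)
  gt1 <- gt1[keep, , drop = FALSE]
  chrom <- chrom[keep]; pos <- pos[keep]
  if (any(is.na(lens)) || !length(lens))
    lens <- tapply(pos, chrom, function(x) max(x) + 1)[unique(chrom)]
  map <- genome_map(chrom, pos, lens[unique(chrom)])

  samp <- colnames(gt1)
  miss <- setdiff(samp, sample_populations$sample)
  if (length(miss)) stop("samples missing from the population table: ",
                         paste(miss, collapse = ", "))
  pops <- setNames(sample_populations$population, sample_populations$sample)[samp]
  panels <- list()
  a1 <- substr(gt1, 1L, 1L)
  a2 <- substr(gt1, 3L, 3L)
  to_int <- function(x) { x[x == "."] <- NA; matrix(as.integer(x), nrow(gt1)) }
  a1 <- to_int(a1); a2 <- to_int(a2)
  for (pp in unique(pops)) {
    cols <- which(pops == pp)
    H <- matrix(NA_integer_, 2L * length(cols), nrow(gt1))
    H[seq(1L, 2L * length(cols), 2L), ] <- t(a1[, cols, drop = FALSE])
    H[seq(2L, 2L * length(cols), 2L), ] <- t(a2[, cols, drop = FALSE])
    panels[[pp]] <- haplotype_panel(H, map, population = pp)
  }
  list(panels = panels, map = map)
}

#' Write a per-window statistics table as TSV
#'
#' Adds a header comment recording the coordinate convention. A path ending in
#' `.gz` is written gzip-compressed.
#'
#' @param df per-window data frame (`chrom`, `start`, `end`, value columns).
#' @param path output path (plain or `.gz`).
#' @return `path`, invisibly.
#' @export
write_window_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("# window coordinates are 0-based, half-open [start, end)", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sweep regions as BED (0-based, half-open)
#'
#' @param regions data frame with `chrom`, `start`, `end` (e.g. the `regions`
#'   element of [merge_sweep_regions]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = format(regions$start, scientific = FALSE, trim = TRUE),
                    end = format(regions$end, scientific = FALSE, trim = TRUE))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read the phenotype table
#'
#' Plain TSV with columns `animal_id`, `breed` and one column per trait.
#'
#' @param phenotypes data frame.
#' @param path file path.
#' @return `path` / the data frame.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write / read outgroup genotypes (TSV, individuals x SNPs dosages)
#'
#' @param outgroup integer matrix from [derive_outgroup].
#' @param path file path.
#' @return `path` / the matrix.
#' @export
write_outgroup_tsv <- function(outgroup, path) {
  write.table(outgroup, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_outgroup_tsv
#' @export
read_outgroup_tsv <- function(path)
  as.matrix(read.delim(path, header = FALSE))

#' Write simulation truth as JSON
#'
#' @param truth the `truth` element of [simulate_dataset].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}
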