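Package: sweepscan
Title: Selection-Signature Scans and QTL Overlap in Multi-Breed Haplotype Panels
Version: 0.1.0
Authors@R:
    person("Pkg", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Window-based selection-signature analysis for phased, multi-population
    haplotype panels: haplotype-homozygosity (HAPH) over 30/31-SNP segments with
    sweep-region calling, the integrated haplotype score (|iHS|) with outgroup-based
    ancestral-allele polarization, pairwise windowed F_ST with a dairy-versus-beef
    Mann-Whitney contrast, local genomic-breeding-value (GEBV) window variance for
    putative QTL discovery (SNP-BLUP ridge or a BayesR-style mixture Gibbs sampler),
    and a sliding-window-corrected chi-squared enrichment test between selection
    signatures and QTL windows. Includes a forward Wright-Fisher simulator
    (recombination, infinite-sites mutation, hard sweeps, truncation selection on a
    polygenic trait) that generates the multi-breed panels, outgroup genotypes and
    phenotypes the analysis consumes, plus phased-VCF/TSV/BED/JSON interfaces and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
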