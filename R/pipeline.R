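#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Defaults are the analysis
#' constants: 250 kb windows stepped by 50 kb, 30/31-SNP segments, top 5%
#' flags, EHH decay threshold 0.5, MAF floor 0.001, 20 iHS frequency bins,
#' overlap factor 5 (= width/step). `sim` configures the bundled generator;
#' set it to `NULL` and pass `vcf`/`phenotypes`/`outgroup` paths to analyse
#' external data.
#'
#' @param width,step window geometry in bp.
#' @param segment_size HAPH segment length in SNPs.
#' @param top_q flagged fraction of windows.
#' @param ehh_threshold EHH decay threshold.
#' @param maf_min minor-allele-frequency floor for iHS.
#' @param ihs_bins iHS standardization bins.
#' @param fst_estimator `"eq1"` or `"wc84"`.
#' @param effect_model `"ridge"` or `"bayesr"`.
#' @param gebv_h2 heritability passed to the effect model.
#' @param bayesr list of [fit_bayesr] controls (used when
#'   `effect_model = "bayesr"`).
#' @param sweep_gap merge gap for sweep regions (bp).
#' @param overlap_factor cell divisor of the enrichment test (default
#'   `width/step`).
#' @param bonferroni_m Bonferroni divisor; `NULL` = number of tests run.
#' @param seed master seed; also seeds the simulator unless `sim` carries its
#'   own.
#' @param outdir output directory.
#' @param sim a [sim_config] (default: desk-scale scenario with this `seed`),
#'   or `NULL` to read inputs from files.
#' @param vcf,sample_populations,phenotypes,outgroup input paths when
#'   `sim = NULL`.
#' @param groups named population-to-group vector when reading external data.
#' @return List of class `run_config`.
#' @export
run_config <- function(width = 250000L, step = 50000L, segment_size = 30L,
                       top_q = 0.05, ehh_threshold = 0.5, maf_min = 0.001,
                       ihs_bins = 20L, fst_estimator = "eq1",
                       effect_model = c("ridge", "bayesr"), gebv_h2 = NULL,
                       bayesr = list(), sweep_gap = 1e6,
                       overlap_factor = NULL, bonferroni_m = NULL,
                       seed = 1L, outdir = tempfile("sweepscan_run_"),
                       sim = sim_config(seed = seed), vcf = NULL,
                       sample_populations = NULL, phenotypes = NULL,
                       outgroup = NULL, groups = NULL) {
  effect_model <- match.arg(effect_model)
  if (is.null(overlap_factor)) overlap_factor <- width / step
  structure(list(width = width, step = step, segment_size = segment_size,
                 top_q = top_q, ehh_threshold = ehh_threshold,
                 maf_min = maf_min, ihs_bins = ihs_bins,
                 fst_estimator = fst_estimator, effect_model = effect_model,
                 gebv_h2 = gebv_h2, bayesr = bayesr, sweep_gap = sweep_gap,
                 overlap_factor = overlap_factor, bonferroni_m = bonferroni_m,
                 seed = as.integer(seed), outdir = outdir, sim = sim,
                 vcf = vcf, sample_populations = sample_populations,
                 phenotypes = phenotypes, outgroup = outgroup, groups = groups),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> window grid -> per-breed HAPH (with
#' sweep-region calling) -> ancestral calls -> per-breed |iHS| -> pairwise
#' F_ST with the dairy-beef contrast -> local-GEBV window variance for the
#' dairy breeds -> overlap enrichment, writing TSV/BED/JSON artifacts and a
#' manifest (config hash, seed, versions, file checksums) to `config$outdir`.
#' Identical config and seed give identical outputs.
#'
#' Enrichment rows follow the headline analysis: each dairy breed's HAPH and
#' |iHS| top windows are tested against that breed's QTL windows, and the
#' dairy-beef F_ST contrast's top windows against windows in the QTL top
#' fraction of either dairy breed.
#'
#' @param config a [run_config].
#' @return Invisibly, a list with all in-memory results (`dataset`, `grid`,
#'   `haph`, `sweep_regions`, `ihs`, `fst`, `contrast`, `gebv`, `enrichment`,
#'   `manifest`, `outdir`).
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)

  dataset <- run_stage("simulate/load", {
    if (!is.null(config$sim)) {
      ds <- simulate_dataset(config$sim)
      write_phased_vcf(ds$panels, out("panels.vcf"))
      write_phenotypes_tsv(ds$phenotypes, out("phenotypes.tsv"))
      write_outgroup_tsv(ds$outgroup, out("outgroup.tsv"))
      write_truth_json(ds$truth, out("truth.json"))
      ds
    } else {
      vc <- read_phased_vcf(config$vcf, config$sample_populations)
      list(panels = vc$panels, map = vc$map, groups = config$groups,
           outgroup = if (!is.null(config$outgroup)) read_outgroup_tsv(config$outgroup),
           phenotypes = if (!is.null(config$phenotypes)) read_phenotypes_tsv(config$phenotypes),
           truth = NULL)
    }
  })
  set.seed(config$seed + 1L)  # analysis-stage substream (Mann-Whitney has none, but keep the contract)

  grid <- run_stage("windows", build_grid(dataset$map, config$width, config$step))

  haph <- list(); sweep_regions <- list()
  run_stage("haph", {
    part <- segment_partition(dataset$map, config$segment_size)
    for (br in names(dataset$panels)) {
      sc <- haph_scan(dataset$panels[[br]], grid, partition = part,
                      top_q = config$top_q)
      haph[[br]] <- sc
      sweep_regions[[br]] <- merge_sweep_regions(grid, sc$flag, gap = config$sweep_gap)
      write_window_tsv(sc, out(paste0("haph_", br, ".tsv")))
      write_bed(sweep_regions[[br]]$regions, out(paste0("sweep_regions_", br, ".bed")))
    }
  })

  ihs <- list(); ihs_windows <- list()
  run_stage("ihs", {
    anc <- call_ancestral(dataset$outgroup)
    for (br in names(dataset$panels)) {
      rec <- ihs_scan(dataset$panels[[br]], anc = anc,
                      threshold = config$ehh_threshold,
                      maf_min = config$maf_min, n_bins = config$ihs_bins)
      ihs[[br]] <- rec
      ihs_windows[[br]] <- window_abs_ihs(rec, grid, top_q = config$top_q)
      write.table(rec, out(paste0("ihs_", br, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_window_tsv(ihs_windows[[br]], out(paste0("ihs_windows_", br, ".tsv")))
    }
  })

  fst <- run_stage("fst", {
    ps <- fst_pair_scan(dataset$panels, grid, groups = dataset$groups,
                        estimator = config$fst_estimator)
    wide <- cbind(grid[, c("chrom", "start", "end")], ps$std)
    write_window_tsv(wide, out("fst_windows.tsv"))
    ps
  })
  contrast <- run_stage("fst-contrast", {
    ct <- group_contrast_test(fst)
    ct$flag <- flag_top_fraction(ct$U, q = config$top_q)
    write_window_tsv(cbind(grid[, c("chrom", "start", "end")], ct),
                     out("fst_contrast.tsv"))
    ct
  })

  gebv <- list()
  if (!is.null(dataset$phenotypes)) run_stage("local-gebv", {
    h2 <- if (!is.null(config$gebv_h2)) config$gebv_h2
          else if (!is.null(config$sim)) config$sim$trait$h2 else 0.3
    dairy <- names(dataset$groups)[dataset$groups == "dairy"]
    for (br in intersect(dairy, names(dataset$panels))) {
      X <- dosage_matrix(dataset$panels[[br]])
      y <- dataset$phenotypes$y[dataset$phenotypes$breed == br]
      eff <- if (config$effect_model == "ridge") fit_ridge(X, y, h2)
             else do.call(fit_bayesr, c(list(X = X, y = y, h2 = h2), config$bayesr))
      gv <- window_gebv_variance(X, eff, dataset$map, grid, top_q = config$top_q)
      gebv[[br]] <- gv
      write.table(data.frame(snp = seq_along(eff$effect), effect = eff$effect),
                  out(paste0("snp_effects_", br, ".tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_window_tsv(gv, out(paste0("gebv_var_", br, ".tsv")))
    }
  })

  enrichment <- if (!length(gebv)) NULL else run_stage("enrichment", {
    rows <- NULL
    either_qtl <- Reduce(function(a, b) {
      r <- a | b; r[is.na(a) & is.na(b)] <- NA; r[is.na(a)] <- b[is.na(a)]
      r[is.na(b)] <- a[is.na(b)]; r
    }, lapply(gebv, `[[`, "flag"))
    for (br in names(gebv)) {
      rows <- rbind(rows,
        cbind(statistic = "HAPH", key = br, trait = "y",
              overlap_chi2(haph[[br]]$flag, gebv[[br]]$flag, config$overlap_factor)),
        cbind(statistic = "absIHS", key = br, trait = "y",
              overlap_chi2(ihs_windows[[br]]$flag, gebv[[br]]$flag, config$overlap_factor)))
    }
    rows <- rbind(rows,
      cbind(statistic = "FST_dairy_beef", key = "contrast", trait = "y",
            overlap_chi2(contrast$flag, either_qtl, config$overlap_factor)))
    enrichment_report(rows, m = config$bonferroni_m, path = out("enrichment.tsv"))
  })

  manifest <- run_stage("manifest", {
    files <- setdiff(list.files(config$outdir), "manifest.json")
    mf <- list(package = "sweepscan",
               version = as.character(packageVersion("sweepscan")),
               r_version = as.character(getRversion()),
               seed = config$seed,
               config_hash = config_hash(config),
               files = as.list(setNames(
                 unname(tools::md5sum(file.path(config$outdir, files))), files)))
    jsonlite::write_json(mf, out("manifest.json"), auto_unbox = TRUE)
    mf
  })

  invisible(list(dataset = dataset, grid = grid, haph = haph,
                 sweep_regions = sweep_regions, ihs = ihs,
                 ihs_windows = ihs_windows, fst = fst, contrast = contrast,
                 gebv = gebv, enrichment = enrichment, manifest = manifest,
                 outdir = config$outdir))
}

# stable hash of the configuration (outdir excluded: it does not affect results)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$outdir <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  # small polynomial rolling hash so we need no extra dependency
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
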