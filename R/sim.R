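#' Simulation configuration
#'
#' The desk-scale world: one 10 Mb chromosome (~196 windows, ~5,000 SNPs)
#' simulated forward under Wright-Fisher dynamics with recombination and
#' infinite-sites mutation; a base population of `base_ne` diploids burnt in
#' for `10 * base_ne` generations; six breeds (2 dairy, 4 beef, Ne 100)
#' drifting independently for 50 generations after the split; an optional set
#' of hard sweeps; a polygenic trait (100 QTL, h2 0.3) under mild truncation
#' selection (top 50%, 3 generations); and a 17-animal outgroup whose per-call
#' error rate is calibrated so ~85% of sites show a single allele across the
#' outgroup.
#'
#' The default rates define a time-rescaled population (rescaling factor
#' ~10): per-bp recombination and mutation are inflated so that a small-Ne
#' panel reproduces the haplotype-diversity regime (`rho` per 30-SNP segment
#' > 1, many distinct haplotypes per segment, between-breed F_ST ~ 0.1) that
#' the window statistics assume. Selection coefficients are on the same
#' rescaled clock: a simulated `s` of 1 corresponds to a real-time `s` of
#' ~0.1. See the methods vignette.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param mutation_rate per-bp per-generation mutation rate (the default gives
#'   roughly 5,000 segregating SNPs in the base panel).
#' @param recombination_rate Morgan per bp (default 1e-7; the rescaled
#'   equivalent of 1 cM/Mb, see above).
#' @param base_ne diploid size of the base population.
#' @param burn_in burn-in generations (default `10 * base_ne`).
#' @param breeds data frame with columns `name`, `ne`, `generations`
#'   (since split), `group` (`"dairy"`/`"beef"`).
#' @param sweeps `NULL`, or a data frame with columns `chrom`, `pos` (bp),
#'   `s` (selection coefficient, >= 0), `breeds` (comma-separated target
#'   breed names), and optionally `generations` (default 200) and `stop_freq`
#'   (stop once the derived allele reaches this frequency; default 1).
#' @param trait list: `n_qtl`, `h2` in (0,1), `truncation_fraction` in (0,1],
#'   `generations` of truncation selection, `effect_sd`, `min_maf` (pooled
#'   minor-allele-frequency floor for QTL sites, default 0.05), optional
#'   `qtl_positions` (data frame `chrom`,`pos` to pin QTL to the nearest
#'   usable site).
#' @param outgroup list: `n_individuals`, `error_rate` (`NULL` = calibrate to
#'   `target_single_allele`), `target_single_allele`.
#' @param sweep_retry retry limit when a sweep allele is lost (default 100).
#' @param seed integer seed driving every stage of [simulate_dataset].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 1L,
                       chrom_length = 1e7,
                       mutation_rate = 2.2e-7,
                       recombination_rate = 1e-7,
                       base_ne = 100L,
                       burn_in = NULL,
                       breeds = NULL,
                       sweeps = NULL,
                       trait = list(),
                       outgroup = list(),
                       sweep_retry = 100L,
                       seed = 1L) {
  if (is.null(burn_in)) burn_in <- 10L * base_ne
  if (is.null(breeds))
    breeds <- data.frame(
      name = c("DairyA", "DairyB", "BeefA", "BeefB", "BeefC", "BeefD"),
      ne = 100L, generations = 50L,
      group = c("dairy", "dairy", "beef", "beef", "beef", "beef"),
      stringsAsFactors = FALSE)
  trait <- utils::modifyList(
    list(n_qtl = 100L, h2 = 0.3, truncation_fraction = 0.5,
         generations = 3L, effect_sd = 1, min_maf = 0.05,
         qtl_positions = NULL), trait)
  outgroup <- utils::modifyList(
    list(n_individuals = 17L, error_rate = NULL, target_single_allele = 0.85),
    outgroup)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, mutation_rate = mutation_rate,
              recombination_rate = recombination_rate,
              base_ne = as.integer(base_ne), burn_in = as.integer(burn_in),
              breeds = breeds, sweeps = sweeps, trait = trait,
              outgroup = outgroup, sweep_retry = as.integer(sweep_retry),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_chromosomes < 1L) stop("need at least one chromosome")
    if (chrom_length <= 0) stop("chrom_length must be positive")
    if (mutation_rate < 0 || recombination_rate < 0) stop("rates must be >= 0")
    if (base_ne < 2L) stop("base_ne must be >= 2")
    if (any(breeds$ne < 2)) stop("breed Ne must be >= 2")
    if (any(breeds$generations < 0)) stop("generations_since_split must be >= 0")
    if (anyDuplicated(breeds$name)) stop("breed names must be unique")
    if (trait$h2 <= 0 || trait$h2 >= 1) stop("h2 must be in (0, 1)")
    if (trait$truncation_fraction <= 0 || trait$truncation_fraction > 1)
      stop("truncation_fraction must be in (0, 1]")
    if (!is.null(sweeps)) {
      if (any(sweeps$s < 0)) stop("selection coefficients must be >= 0")
      if (any(sweeps$pos < 0 | sweeps$pos >= chrom_length))
        stop("sweep positions must lie within the chromosome")
    }
  })
  invisible(cfg)
}

chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chromosomes))

#' Simulate the neutral base panel
#'
#' Forward Wright-Fisher simulation of `base_ne` diploids per chromosome with
#' recombination and infinite-sites mutation, run for `burn_in` generations
#' (default `10 * base_ne`). Returns the whole population as a phased panel of
#' `2 * base_ne` haplotypes; every SNP is segregating (derived-allele
#' frequency strictly in (0, 1)), positions strictly increasing per
#' chromosome, derived allele coded 1. Chromosomes evolve independently.
#'
#' Uses the current RNG state (seed upstream via `set.seed` or use
#' [simulate_dataset] which seeds every stage from `config$seed`).
#'
#' @param config a [sim_config].
#' @return A [haplotype_panel] named `"base"`.
#' @export
simulate_neutral_panel <- function(config) {
  nh <- 2L * config$base_ne
  haps <- list(); chs <- character(0); poss <- integer(0)
  for (ci in seq_len(config$n_chromosomes)) {
    res <- wf_run_cpp(matrix(0L, nh, 0L), integer(0), config$chrom_length,
                      config$burn_in, config$mutation_rate,
                      config$recombination_rate, -1, 0, 2, TRUE)
    haps[[ci]] <- res$hap
    chs <- c(chs, rep(chrom_names(config)[ci], length(res$pos)))
    poss <- c(poss, res$pos)
  }
  hap <- do.call(cbind, haps)
  if (ncol(hap) == 0L)
    stop("no segregating sites after burn-in; increase mutation_rate or burn_in")
  lens <- setNames(rep(config$chrom_length, config$n_chromosomes), chrom_names(config))
  haplotype_panel(hap, genome_map(chs, poss, lens), population = "base")
}

# run the WF engine over each chromosome of a panel, keeping the map aligned
evolve_panel <- function(panel, generations, rec, chrom_len, mu = 0,
                         sweep = NULL, purge = FALSE) {
  map <- panel$map
  hap <- panel$hap
  info <- list(freq = NA_real_, lost = FALSE, max_freq = NA_real_,
               generations = generations)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    spos <- -1; ss <- 0; sf <- 2
    if (!is.null(sweep) && sweep$chrom == ch) {
      spos <- sweep$pos; ss <- sweep$s; sf <- sweep$stop_freq
    }
    res <- wf_run_cpp(hap[, idx, drop = FALSE], map$pos[idx], chrom_len,
                      generations, mu, rec, spos, ss, sf, purge)
    if (purge) stop("evolve_panel keeps the map; purging not supported here")
    stopifnot(identical(res$pos, map$pos[idx]))
    hap[, idx] <- res$hap
    if (spos >= 0) {
      info$freq <- res$sweep_freq
      info$lost <- res$sweep_lost
      info$max_freq <- res$sweep_max_freq
      info$generations <- res$generations
    }
  }
  list(panel = haplotype_panel(hap, map, panel$population), info = info)
}

#' Split the base population into drifting breeds
#'
#' Each breed is founded by `ne` diploids sampled from the base population
#' (without replacement when possible) and then drifts independently for its
#' stated number of generations at constant `ne`, with recombination but no
#' new mutation, so all breeds keep the one shared SNP map. Sites left with no
#' variation anywhere (same allele in every breed) are dropped from the shared
#' map and all panels.
#'
#' @param base the base [haplotype_panel] from [simulate_neutral_panel].
#' @param config a [sim_config] (uses `breeds`, `recombination_rate`,
#'   `chrom_length`).
#' @return List with `panels` (named list of [haplotype_panel]s) and `map`
#'   (the pruned shared [genome_map]).
#' @export
split_breeds <- function(base, config) {
  breeds <- config$breeds
  if (any(breeds$ne < 2)) stop("breed Ne must be >= 2")
  n_base <- nrow(base$hap) / 2L
  panels <- list()
  for (i in seq_len(nrow(breeds))) {
    ne <- breeds$ne[i]
    founders <- if (ne <= n_base) sample.int(n_base, ne)
                else sample.int(n_base, ne, replace = TRUE)
    rows <- as.vector(rbind(2L * founders - 1L, 2L * founders))
    pan <- haplotype_panel(base$hap[rows, , drop = FALSE], base$map,
                           population = breeds$name[i])
    if (breeds$generations[i] > 0L)
      pan <- evolve_panel(pan, breeds$generations[i], config$recombination_rate,
                          config$chrom_length, mu = 0)$panel
    panels[[breeds$name[i]]] <- pan
  }
  # drop sites with no variation across the pooled breeds
  pooled_alt <- Reduce(`+`, lapply(panels, function(p) colSums(p$hap)))
  pooled_n <- sum(vapply(panels, n_haplotypes, numeric(1)))
  keep <- which(pooled_alt > 0 & pooled_alt < pooled_n)
  map <- base$map[keep, ]
  panels <- lapply(panels, function(p)
    haplotype_panel(p$hap[, keep, drop = FALSE], map, p$population))
  list(panels = panels, map = map)
}

#' Impose a hard sweep on target breeds
#'
#' Introduces (or reuses) a derived allele at the sweep position and drives it
#' with genic selection (fitness `(1+s)^g`) in each target breed until
#' `generations` have passed or the allele frequency reaches `stop_freq`. If
#' the position is not already a SNP, a new site is inserted: all-ancestral in
#' every breed, with one random origin haplotype set to derived in each target
#' breed. A sweep allele lost along the way is restarted from a fresh origin
#' haplotype, up to `config$sweep_retry` times. Non-target breeds are
#' untouched.
#'
#' @param panels named list of breed [haplotype_panel]s on a shared map.
#' @param sweep one row of the `sweeps` table (see [sim_config]): `chrom`,
#'   `pos`, `s`, `breeds` (comma-separated names), optional `generations`,
#'   `stop_freq`.
#' @param config a [sim_config].
#' @return List with `panels`, `map` (possibly extended by the new site), and
#'   `truth`: data frame of final derived-allele frequency per breed plus the
#'   generations each target breed ran.
#' @export
impose_sweep <- function(panels, sweep, config) {
  sweep <- as.list(sweep)
  if (is.null(sweep$generations) || is.na(sweep$generations)) sweep$generations <- 200L
  if (is.null(sweep$stop_freq) || is.na(sweep$stop_freq)) sweep$stop_freq <- 1.0
  targets <- trimws(strsplit(sweep$breeds, ",")[[1]])
  if (!all(targets %in% names(panels)))
    stop("unknown target breed(s): ", paste(setdiff(targets, names(panels)), collapse = ", "))
  map <- panels[[1]]$map
  if (!any(map$chrom == sweep$chrom)) stop("unknown chromosome: ", sweep$chrom)
  at <- which(map$chrom == sweep$chrom & map$pos == sweep$pos)
  if (!length(at)) {
    # insert a new all-ancestral site at the sweep position in every breed;
    # map rows are sorted by chromosome (map order) then position
    chr_rows <- which(map$chrom == sweep$chrom)
    at <- min(chr_rows) + sum(map$pos[chr_rows] < sweep$pos)
    m <- nrow(map)
    left <- seq_len(at - 1L)
    right <- if (at <= m) at:m else integer(0)
    map2 <- genome_map(c(map$chrom[left], sweep$chrom, map$chrom[right]),
                       c(map$pos[left], as.integer(sweep$pos), map$pos[right]),
                       chrom_lengths(map))
    panels <- lapply(panels, function(p) {
      H <- cbind(p$hap[, left, drop = FALSE], 0L, p$hap[, right, drop = FALSE])
      haplotype_panel(H, map2, p$population)
    })
    map <- map2
  }
  freqs <- setNames(vapply(panels, function(p) mean(p$hap[, at]), numeric(1)),
                    names(panels))
  gens <- setNames(rep(NA_integer_, length(panels)), names(panels))
  for (br in targets) {
    pan0 <- panels[[br]]
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      pan <- pan0
      if (mean(pan$hap[, at]) == 0) {
        origin <- sample.int(nrow(pan$hap), 1L)
        pan$hap[origin, at] <- 1L
      }
      ev <- evolve_panel(pan, as.integer(sweep$generations),
                         config$recombination_rate, config$chrom_length,
                         mu = 0,
                         sweep = list(chrom = sweep$chrom, pos = sweep$pos,
                                      s = sweep$s, stop_freq = sweep$stop_freq))
      if (!ev$info$lost) {
        panels[[br]] <- ev$panel
        freqs[br] <- ev$info$freq
        gens[br] <- ev$info$generations
        break
      }
      if (attempt >= config$sweep_retry)
        stop("sweep allele lost ", attempt, " times in breed ", br,
             "; increase s or the retry limit")
    }
  }
  truth <- data.frame(breed = names(panels), chrom = sweep$chrom,
                      pos = sweep$pos, s = sweep$s,
                      target = names(panels) %in% targets,
                      final_freq = unname(freqs), generations = unname(gens),
                      stringsAsFactors = FALSE)
  list(panels = panels, map = map, truth = truth)
}

#' Simulate a polygenic trait, optionally under truncation selection
#'
#' Samples `n_qtl` QTL among the segregating SNPs (or pins them to
#' `qtl_positions`), draws additive effects `N(0, effect_sd^2)`, and sets the
#' environmental variance so the realized heritability equals `h2`
#' (environmental deviations are orthogonalized against the genetic values and
#' rescaled, so realized h2 matches exactly). With
#' `truncation_fraction < 1` and `generations > 0`, each breed undergoes
#' truncation selection: every generation the top fraction of phenotypes
#' become parents (equal weights), with one genome-wide parent vector shared
#' across chromosomes, recombination, and constant breed size.
#'
#' @param panels named list of breed [haplotype_panel]s on a shared map.
#' @param config a [sim_config] (uses `trait`, `recombination_rate`,
#'   `chrom_length`).
#' @return List with `panels` (post-selection), `phenotypes` (data frame
#'   `animal_id`, `breed`, `y`), and `truth` (list: `qtl` data frame with
#'   `chrom`, `pos`, `idx`, `effect`; `realized_h2`; `var_g`; `var_e`;
#'   `genetic_values`; per-generation `mean_phenotype` by breed).
#' @export
simulate_trait <- function(panels, config) {
  tr <- config$trait
  if (is.null(tr$min_maf)) tr$min_maf <- 0.05
  map <- panels[[1]]$map
  m <- nrow(map)
  if (tr$n_qtl > m) stop("n_qtl exceeds the number of segregating SNPs")
  # candidate QTL must carry variance: pooled MAF over all breeds >= min_maf
  pooled <- Reduce(`+`, lapply(panels, function(p) colSums(p$hap))) /
    sum(vapply(panels, n_haplotypes, numeric(1)))
  usable <- which(pmin(pooled, 1 - pooled) >= tr$min_maf)
  if (!length(usable)) usable <- seq_len(m)
  if (is.null(tr$qtl_positions)) {
    qtl <- sort(sample(usable, min(tr$n_qtl, length(usable))))
  } else {
    qtl <- vapply(seq_len(nrow(tr$qtl_positions)), function(i) {
      on_ch <- intersect(usable, which(map$chrom == tr$qtl_positions$chrom[i]))
      if (!length(on_ch)) stop("no usable SNPs on chromosome ", tr$qtl_positions$chrom[i])
      on_ch[which.min(abs(map$pos[on_ch] - tr$qtl_positions$pos[i]))]
    }, integer(1))
  }
  eff <- rnorm(length(qtl), sd = tr$effect_sd)

  genetic_values <- function(pans)
    lapply(pans, function(p) drop(dosage_matrix(p)[, qtl, drop = FALSE] %*% eff))

  g <- genetic_values(panels)
  var_g <- var(unlist(g))
  if (!is.finite(var_g) || var_g == 0)
    stop("h2 unreachable: zero genetic variance at the sampled QTL")
  var_e <- var_g * (1 - tr$h2) / tr$h2

  mean_y <- list()
  if (tr$truncation_fraction < 1 && tr$generations > 0L) {
    for (gen in seq_len(tr$generations)) {
      g <- genetic_values(panels)
      ym <- numeric(0)
      for (br in names(panels)) {
        pan <- panels[[br]]
        n <- nrow(pan$hap) / 2L
        y <- g[[br]] + rnorm(n, sd = sqrt(var_e))
        ym[br] <- mean(y)
        n_sel <- max(2L, ceiling(tr$truncation_fraction * n))
        sel <- order(y, decreasing = TRUE)[seq_len(n_sel)]
        parents <- sample(sel, 2L * n, replace = TRUE)
        hap <- pan$hap
        for (ch in unique(pan$map$chrom)) {
          idx <- which(pan$map$chrom == ch)
          hap[, idx] <- make_gametes_cpp(pan$hap[, idx, drop = FALSE],
                                         pan$map$pos[idx], config$chrom_length,
                                         config$recombination_rate, parents)
        }
        panels[[br]] <- haplotype_panel(hap, pan$map, pan$population)
      }
      mean_y[[gen]] <- ym
    }
    g <- genetic_values(panels)
    var_g <- var(unlist(g))
    if (!is.finite(var_g) || var_g == 0)
      stop("h2 unreachable: genetic variance exhausted by selection")
    var_e <- var_g * (1 - tr$h2) / tr$h2
  }

  # final phenotypes: noise orthogonal to g, scaled so realized h2 == h2
  gall <- unlist(g)
  e <- rnorm(length(gall))
  e <- e - mean(e)
  gc <- gall - mean(gall)
  e <- e - gc * sum(e * gc) / sum(gc^2)
  e <- e * sqrt(var_e / var(e))
  y <- gall + e
  breed_of <- rep(names(panels), vapply(g, length, integer(1)))
  pheno <- data.frame(
    animal_id = paste0(breed_of, "_", unlist(lapply(g, seq_along))),
    breed = breed_of, y = y, stringsAsFactors = FALSE)
  realized_h2 <- var(gall) / var(y)
  list(panels = panels, phenotypes = pheno,
       truth = list(qtl = data.frame(chrom = map$chrom[qtl], pos = map$pos[qtl],
                                     idx = qtl, effect = eff,
                                     stringsAsFactors = FALSE),
                    realized_h2 = realized_h2, var_g = var(gall), var_e = var_e,
                    genetic_values = gall,
                    mean_phenotype = if (length(mean_y)) do.call(rbind, mean_y) else NULL))
}

#' Sample a genotyped cohort from a breed panel
#'
#' Produces `n` diploid offspring by one round of random mating within the
#' panel (one genome-wide parent pair per offspring, recombination per
#' chromosome). In livestock the genotyped cohort is usually much larger than
#' the effective population size; this is the generator's analogue. The panel
#' itself (the breeding population) is left untouched.
#'
#' @param panel a [haplotype_panel].
#' @param n cohort size in diploid individuals.
#' @param recombination_rate Morgan per bp.
#' @param chrom_length chromosome length in bp.
#' @return A [haplotype_panel] of `2 * n` haplotypes on the same map.
#' @export
sample_cohort <- function(panel, n, recombination_rate, chrom_length) {
  n_par <- nrow(panel$hap) / 2L
  parents <- sample.int(n_par, 2L * n, replace = TRUE)
  map <- panel$map
  hap <- matrix(0L, 2L * n, ncol(panel$hap))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    hap[, idx] <- make_gametes_cpp(panel$hap[, idx, drop = FALSE], map$pos[idx],
                                   chrom_length, recombination_rate, parents)
  }
  haplotype_panel(hap, map, panel$population)
}

#' Simulate outgroup genotypes carrying the ancestral allele
#'
#' Every outgroup allele call is the true ancestral allele (0), flipped to
#' derived with probability `error_rate`. The default error rate is calibrated
#' so that the expected fraction of sites showing a single allele across all
#' `2 * n_individuals` outgroup calls equals `target_single_allele`:
#' `(1 - e)^K + e^K = target` with `K = 2 * n_individuals`.
#'
#' @param map a [genome_map].
#' @param n_individuals outgroup animals (default 17).
#' @param error_rate per-call flip probability; `NULL` (default) calibrates to
#'   `target_single_allele`.
#' @param target_single_allele calibration target (default 0.85).
#' @return Integer matrix `n_individuals` x `n_snps` of derived-allele dosages
#'   (0/1/2) with attributes `error_rate` and `expected_single_allele`.
#' @export
derive_outgroup <- function(map, n_individuals = 17L, error_rate = NULL,
                            target_single_allele = 0.85) {
  K <- 2L * n_individuals
  if (is.null(error_rate)) error_rate <- 1 - target_single_allele^(1 / K)
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  m <- nrow(map)
  og <- matrix(rbinom(n_individuals * m, 2L, error_rate), n_individuals, m)
  structure(og, error_rate = error_rate,
            expected_single_allele = (1 - error_rate)^K + error_rate^K)
}

#' Simulate the full multi-breed dataset
#'
#' Seeds the RNG from `config$seed` and runs base panel -> breed split ->
#' sweeps -> trait -> outgroup, returning everything the analysis pipeline
#' consumes plus the ground truth for parameter-recovery tests.
#'
#' @param config a [sim_config].
#' @return List: `panels` (named list of breed panels), `map` (shared
#'   [genome_map]), `groups` (named breed-to-group vector), `outgroup`,
#'   `phenotypes`, `truth` (list with `sweeps`, `qtl`, `realized_h2`, ...),
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  base <- simulate_neutral_panel(config)
  sp <- split_breeds(base, config)
  panels <- sp$panels
  map <- sp$map
  sweep_truth <- NULL
  if (!is.null(config$sweeps) && nrow(config$sweeps) > 0) {
    for (i in seq_len(nrow(config$sweeps))) {
      sw <- impose_sweep(panels, config$sweeps[i, ], config)
      panels <- sw$panels
      map <- sw$map
      sweep_truth <- rbind(sweep_truth, cbind(sweep = i, sw$truth))
    }
  }
  trt <- simulate_trait(panels, config)
  panels <- trt$panels
  og <- derive_outgroup(map, n_individuals = config$outgroup$n_individuals,
                        error_rate = config$outgroup$error_rate,
                        target_single_allele = config$outgroup$target_single_allele)
  groups <- setNames(config$breeds$group, config$breeds$name)
  list(panels = panels, map = map, groups = groups, outgroup = og,
       phenotypes = trt$phenotypes,
       truth = c(list(sweeps = sweep_truth), trt$truth["qtl"],
                 trt$truth["realized_h2"], trt$truth["var_g"],
                 trt$truth["var_e"]),
       config = config)
}
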