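---
title: "Window-based selection scans and QTL overlap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-based selection scans and QTL overlap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The problem

Strong artificial selection leaves footprints in livestock genomes: a favoured
mutation drags one long haplotype to high frequency (a hard sweep), reducing
local haplotype diversity within the selected breed and shifting allele
frequencies between breeds. `sweepscan` implements a window-based scan for
such footprints in phased multi-breed SNP panels and tests whether the
selected regions coincide with the regions that carry trait variance
(putative QTL). Four per-window quantities are computed on a common sliding
grid:

* **HAPH** — the variance of distinct-haplotype frequencies in 30/31-SNP
  segments, a within-breed haplotype-homozygosity statistic;
* **|iHS|** — the magnitude of the integrated haplotype score, contrasting
  haplotype homozygosity around the derived versus the ancestral allele of
  each SNP;
* **pairwise F\_ST** — allele-frequency differentiation between every pair of
  breeds, with a one-sided Mann–Whitney contrast of dairy-versus-beef pairs
  against within-group pairs;
* **local GEBV variance** — the variance across animals of the window's
  genomic value `sum_j X_aj * beta_j`, which measures the window's
  contribution to genetic variance for a trait.

Windows in the top 5% of a selection statistic and in the top 5% of local
GEBV variance are cross-tabulated and tested for over-representation with a
chi-squared test corrected for the 5-fold overlap of the sliding grid.

# Window machinery

Windows are 250 kb wide and start every 50 kb, anchored at bp 0 of each
chromosome (the anchor is a convention; the source analyses do not state
one). Coordinates are 0-based and half-open internally, 1-based in exported
VCF; every exported window table records the convention in a header comment.
Raw per-window values are standardized by dividing by the mean over windows
with data, so standardized values average exactly 1; windows without data
(no SNPs or no segment midpoints) are missing and excluded from both the mean
and the top-fraction denominator. The flagged top fraction is
`ceiling(q * n_finite)` windows with ties broken by genomic order, so the
count is deterministic. Because the width is five steps, the grid decomposes
into five interleaved non-overlapping tilings (`nonoverlapping_subsets()`),
which is what the enrichment correction and the local-GEBV conservation
property rely on.

The window width has a coalescent rationale: a segment of `c` Morgans has an
approximate age of `1/c` generations, so 250 kb at 1 cM/Mb is about 400
generations — old enough to predate breed formation
(`window_age_generations()`).

# HAPH

Each chromosome is cut, left to right, into non-overlapping segments of 30
SNPs, with the remainder `r = n mod 30` absorbed by widening the first `r`
segments to 31 SNPs. (If `n` cannot be tiled by 30/31 at all — possible only
below 930 SNPs — all segments widen to 31 and a terminal remainder of fewer
than 30 SNPs stays uncovered.) For the distinct haplotypes of a segment with
within-breed frequencies `p_1..p_N`,

```
HAPH = (1/N) * sum_i (p_i - 1/N)^2 .
```

This is the population variance of the distinct-haplotype frequencies. The
denominator is the number of **distinct** haplotypes: at a fixed segment
(N = 1) HAPH is exactly 0, matching the known blind spot of the statistic in
regions swept to fixation. The alternative reading (N = haplotype copies)
would give a value near 1 at fixation and is rejected; a `denom = "N-1"`
switch provides the sample-variance variant. Haplotypes with any missing call
in a segment are dropped; a segment is unusable when fewer than half its
haplotypes (configurable) survive.

Segments are averaged into the windows **their midpoints fall in** (midpoint
= mean bp of the first and last SNP), standardized per breed, and the top 5%
flagged. Flagged windows on one chromosome separated by less than 1 Mb merge
into sweep regions; regions longer than 2 Mb and 5 Mb are reported as the
long-sweep shortlists.

A consequence of the `1/N` denominator worth knowing: HAPH is maximized by
*near-complete* sweeps (one haplotype near frequency 1 plus a few escapees,
N small), not by mid-frequency sweeps, whose "one common + many rare"
spectrum carries a large N in the denominator. The parameter-recovery suite
therefore demonstrates HAPH on a sweep driven to ~0.98.

# |iHS|

The ancestral allele of each SNP is the majority allele over all outgroup
allele calls; an exact tie or zero calls leaves the SNP unpolarized and out
of the scan. For a core SNP and one of its alleles, the extended haplotype
homozygosity at flanking SNP `t` is

```
EHH(t) = sum_h C(n_h, 2) / C(n_A, 2)
```

over groups `h` of carrier haplotypes identical at every SNP from the core
through `t`; the curve starts at 1 and is non-increasing outward. iEHH is the
trapezoidal integral of EHH over physical distance (no genetic map is
assumed), summed over the two directions, truncated at the linearly
interpolated point where EHH crosses the decay threshold. The threshold
default is 0.5 (the value used by the source analysis; the conventional 0.05
is available). SNPs whose curve reaches a chromosome end at or above the
threshold are discarded by default (`discard_truncated = TRUE`): their
integrals are right-censored, and keeping them floods the window maxima with
border artifacts — this matches the default of the standard EHH tooling the
source analysis used, and deviates deliberately from a pure
"truncate-and-keep" rule.

The raw score of a SNP is `log10(iEHH_derived / iEHH_ancestral)`, defined
when both integrals are positive and the minor allele frequency exceeds 0.001
(the source panel's floor; note that at desk-scale sample sizes this floor is
far less selective than in a panel of ten thousand animals). Scores are
standardized to mean 0, SD 1 (sample SD) within 20 equal-width bins of
ancestral-allele frequency on (0,1) — equal-width rather than quantile bins,
with a documented switch point in `standardize_ihs()`; bins with fewer than
two records or zero SD yield missing scores. The per-window statistic is the
maximum |iHS| over assigned SNPs, with no further standardization since iHS
is already in SD units.

# Pairwise F\_ST

The default per-SNP estimator for a pair of breeds with allele frequencies
`p1, p2` is exactly the printed-symbols form

```
F_ST = [ (p1 - pbar)^2 + (p2 - pbar)^2 ] / 2 / [ pbar (1 - pbar) ],
pbar = (p1 + p2) / 2,
```

algebraically `(p1 - p2)^2 / (4 pbar qbar)`, with no sample-size correction.
SNPs monomorphic across the pair are excluded (not scored 0/0). The window
value is the unweighted mean over assigned polymorphic SNPs (mean of ratios),
then standardized per pair. The Weir & Cockerham (1984) allele-count theta is
available (`estimator = "wc84"`); note the two estimators are **not**
asymptotically equal — for two balanced populations theta tends to
`s^2 / (pbar qbar + s^2/2)` with `s^2 = (p1 - p2)^2`, a factor 2 above the
default in the weak-differentiation limit. The package's tests assert this
true limiting relationship.

The dairy-versus-beef contrast compares, window by window, the standardized
F\_ST of cross-group pairs against within-group pairs with a one-sided
Mann–Whitney U test (alternative: cross-group stochastically greater). U is
exact (enumeration via the null U distribution) when there are no ties and
`n1 * n2 <= 400`; otherwise mid-ranks with tie-corrected variance, normal
approximation and continuity correction. With all values tied the variance is
zero and p = 0.5 (U at its null mean).

# Local GEBV variance

SNP effects are estimated either by SNP-BLUP ridge regression — shrinkage
`lambda = m (1 - h2) / h2`, solved in the animal dimension when `m > n`,
deterministic — or by a BayesR-style Gibbs sampler: a 4-component normal
mixture prior on effects with variances `(0, 1e-4, 1e-3, 1e-2) * sigma2_g`
(`sigma2_g = h2 * var(y)`), Dirichlet(1,...,1) mixture proportions, and a
scaled-inverse-chi-squared residual variance; the estimate is the posterior
mean averaged over chains. Desk-scale defaults are 5,000 iterations / 2,000
burn-in / 3 chains; the reference analysis scale (50,000 / 30,000 / 5) is a
matter of arguments. The pedigree polygenic term of the original BayesR is
deliberately omitted — the synthetic data carry no pedigree.

One identifiability note: under a null trait the posterior mixture
proportions stay near the uniform prior, because the zero-variance component
and the `1e-4 * sigma2_g` component are likelihood-equivalent per SNP at
desk-scale `n`. The model still attributes essentially no genetic variance
(the fitted `var(X beta)` is below 1% of `var(y)` in the tests); assertions
about "mass in the null component" are therefore made on fitted variance, not
on `pi_1`.

The local GEBV of animal `a` in window `w` is `sum_{j in w} X_aj beta_j` over
the window's assigned SNPs; the window value is its variance across animals
(n-1 denominator) and the top 5% are the putative QTL windows. All SNPs of a
window contribute, not only those with nonzero posterior-mean effects. Over
any non-overlapping window tiling, each animal's local GEBVs sum exactly to
the total GEBV of the covered SNPs — an identity the tests assert to
1e-12 relative tolerance.

# Overlap enrichment

Two flag vectors are cross-tabulated over windows where both are defined. All
four cells are divided by the overlap factor (5 = width/step), so the
corrected table is the average of the five non-overlapping window sets, and a
Pearson chi-squared test with 1 df is computed on the corrected counts —
algebraically, exactly the raw-count statistic divided by 5. No Yates
correction is applied (a switch exists). Fold enrichment is
`a * total / ((a + b)(a + c))`, invariant to the correction; the expected
overlap is reported on the same corrected scale as the observed count.
An exact alternative (`method = "subsets"`) computes the raw-count test on
each truly non-overlapping subset and averages. Bonferroni significance is
`p <= 0.05 / m` with `m` defaulting to the number of tests in the run. The
flagged fraction is a parameter of the whole pipeline, so the top-20%
sensitivity variant is one argument away.

# The synthetic-data generator

`simulate_dataset()` produces everything the pipeline consumes: phased breed
panels on a shared SNP map, outgroup genotypes, phenotypes, and the ground
truth (sweep frequencies, QTL effects, realized heritability).

**Engine.** A forward Wright–Fisher simulation (compiled): constant-size
monoecious diploid populations, multinomial parent sampling, Poisson
crossovers, infinite-sites mutation on integer bp. The base population burns
in for `10 * Ne` generations from a mutation-free start; every returned SNP
segregates, the derived allele is coded 1. Chromosomes evolve independently
(no cross-chromosome pedigree correlation) except during truncation
selection, where one genome-wide parent vector is shared across chromosomes
because selection there is genome-wide.

**Breed split.** Each breed is founded from the base population and drifts
independently with recombination but **no new mutation**, so all breeds keep
one shared map — which the cross-breed statistics assume. Sites with no
variation left anywhere are dropped; a site alternately fixed between breeds
is kept (it is exactly the F\_ST signal).

**Sweeps.** Genic selection with fitness `(1+s)^g` via fitness-weighted
parent sampling: the expected next-generation frequency is the deterministic
genic-selection update and the multinomial sampling supplies the binomial
noise, while hitchhiking arises naturally. A lost sweep allele restarts from
a fresh origin haplotype, up to 100 times. Sweeps stop at a target frequency
(`stop_freq`) or after a generation budget; non-target breeds are untouched.

**Trait.** QTL are sampled among sites with pooled MAF >= 0.05 (a QTL fixed
everywhere carries no variance), effects are normal, and the environmental
deviations are orthogonalized against the genetic values and rescaled so the
realized heritability equals the target exactly. Truncation selection takes
the top fraction of phenotypes as parents each generation.
`sample_cohort()` draws a genotyped cohort larger than Ne by one round of
random mating — in cattle the genotyped panel is routinely an order of
magnitude larger than the effective population size.

**Outgroup.** Each outgroup allele call is the true ancestral allele flipped
with a small error rate, calibrated by default so ~85% of sites show a single
allele across the 17-animal outgroup: `(1-e)^34 + e^34 = 0.85`.

## The time-rescaled default world

The defaults (one 10 Mb chromosome, ~5,000 SNPs, six breeds of Ne 100, 50
generations since the split) use a per-bp recombination rate of 1e-7 Morgan —
ten times the cattle genome average — and correspondingly inflated mutation.
This is the standard rescaling of forward simulation: dividing Ne by a factor
`lambda` while multiplying `mu`, `r` and `s` by `lambda` preserves the
population-scaled parameters `theta = 4 Ne mu L`, `rho = 4 Ne r L` and
`Ne*s` that the statistics actually respond to. Without the rescaling a
desk-sized panel is degenerate for every haplotype statistic: `rho` per
30-SNP segment falls below 1, neutral segments collapse to two or three
haplotypes, whole 250 kb blocks drift to fixation within a breed
(indistinguishable from sweeps by HAPH — and not something HAPH should be
asked to distinguish), and EHH stays above 0.5 across megabases so a large
share of SNPs is border-censored. In the rescaled world a neutral segment
holds ~12 distinct haplotypes, ~4% of SNPs are border-censored and
between-breed F\_ST is ~0.10 — the regime multi-breed cattle panels actually
occupy. Simulated selection coefficients are on the rescaled clock: `s = 1`
corresponds to a real-time `s` of roughly 0.1.

## What the generator does not emulate

Realistic cattle demography and LD (two-epoch history, bottlenecks),
site-frequency distortions from real ascertainment (SNP-chip sites), a
pedigree (hence no polygenic term in BayesR), genotyping or phasing error in
the panels themselves (only the outgroup flip error), sex chromosomes, and
gene conversion. A green parameter-recovery test therefore establishes that
the statistics behave as designed *in the diversity regime they assume*, not
that they would detect any particular locus in a real 23,000-animal panel.

## The recovery demonstration world

The parameter-recovery suite uses two 10 Mb chromosomes and breeds of
Ne 200, so the within-breed coalescent scale (2Ne = 400 generations) exceeds
both the split depth and the window design horizon — drift alone then rarely
fixes whole 250 kb blocks, and sweeps are the dominant source of long
homozygous haplotypes, which is the premise of the scan. Selection
coefficients sit on the rescaled clock: the simulated `s = 2` of both sweeps
is a real-time `s` of about 0.2. The HAPH target is a sweep driven to ~0.98
(HAPH's maximum lies near completion, see above); the |iHS| target is a
mid-sweep locus stopped near 0.7; the QTL targets are three
well-separated windows, each holding ten equal-effect QTL at polymorphic
sites, analysed in 300-400-animal cohorts with the ridge model at h2 = 0.5.
Equal (rather than zero-mean random) cluster effects are used because a
cluster's variance contribution under random signs is itself a random
variable that can vanish, leaving the "truth window" undefined.

One recovery criterion is expected to fail and is left failing: requiring a
mid-sweep locus to reach the top 5% of per-window max|iHS| in >= 80% of
replicates. At a few thousand SNPs the null tail of per-window maxima lies at
2.7-3.5 SD while the achievable mid-sweep score is capped near 3-3.5: a
chromosome-length swept haplotype is border-censored and discarded, and the
within-bin SD (~0.6-0.7) is coalescent noise, not estimation error, so no
affordable increase in sample size or genome length closes the gap. The
weaker property that the sweep window's max|iHS| exceeds the genome median is
comfortably satisfied and is asserted in the unit suite.

# Numerical choices and degenerate inputs

* Standardization errors out when the finite mean is 0 (an all-zero scan);
  the local-GEBV path catches this and reports missing standardized values.
* Top-fraction flags use `ceiling` and genomic-order tie-breaks; flags are
  `NA` for windows without data.
* EHH needs >= 2 carriers; iHS needs both iEHH values positive; bins need
  >= 2 records and positive SD.
* Mann–Whitney: exact only without ties and `n1 n2 <= 400`; all-tied input
  returns p = 0.5.
* The enrichment table is missing (with a warning) when any corrected margin
  is 0.
* All randomness flows from a single seed (`sim_config(seed = )`,
  `run_config(seed = )`); every run is bit-reproducible, and the pipeline
  manifest records seed, config hash and file checksums.

# Known limitations

HAPH's null distribution is not calibrated (the original haplotype-count test
it descends from has a coalescent null; the top-5% rule used here is an
outlier criterion, not a test). The enrichment null ignores LD block
structure — a permutation test respecting blocks would be stricter than the
divide-by-5 correction, which the tests show to be conservative. The |iHS|
window maximum is noisy at desk scale, as quantified above. The Eq.-1 F\_ST
estimator has no sample-size correction; for very unequal or small breed
samples the W&C84 option is preferable.
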