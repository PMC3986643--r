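// Forward Wright-Fisher engine and haplotype-statistic inner loops.
//
// Conventions shared with the R level:
//  * a haplotype panel is an integer matrix, rows = haplotypes (individual i
//    owns rows 2i and 2i+1, 0-based), columns = SNPs, 0 = ancestral allele,
//    1 = derived allele;
//  * bp positions are 0-based integers in [0, chrom_len);
//  * all randomness comes from R's RNG so set.seed() controls everything.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef std::vector<unsigned char> Hap;

static int sample_cumulative(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// One gamete from diploid parent p (rows 2p, 2p+1 of H). Crossover count is
// Poisson(rec * L) with breakpoints uniform on (0, L); source haplotype
// switches at each breakpoint, starting from a fair coin.
static void make_gamete(const std::vector<Hap>& H, const std::vector<int>& pos,
                        double rec, double L, int p, Hap& out) {
  const Hap& a = H[2 * p];
  const Hap& b = H[2 * p + 1];
  size_t S = pos.size();
  int start = (unif_rand() < 0.5) ? 0 : 1;
  int k = (rec > 0.0 && L > 0.0) ? (int)R::rpois(rec * L) : 0;
  out.resize(S);
  if (k == 0) {
    out = (start == 0) ? a : b;
    return;
  }
  std::vector<double> bp((size_t)k);
  for (int i = 0; i < k; i++) bp[(size_t)i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  for (size_t j = 0; j < S; j++) {
    int cnt = (int)(std::upper_bound(bp.begin(), bp.end(), (double)pos[j]) - bp.begin());
    out[j] = ((start + cnt) & 1) == 0 ? a[j] : b[j];
  }
}

static IntegerMatrix pack_sorted(const std::vector<Hap>& H, std::vector<int>& pos) {
  int nh = (int)H.size();
  int S = (int)pos.size();
  std::vector<int> ord((size_t)S);
  for (int j = 0; j < S; j++) ord[(size_t)j] = j;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return pos[(size_t)a] < pos[(size_t)b]; });
  IntegerMatrix out(nh, S);
  for (int j = 0; j < S; j++) {
    int src = ord[(size_t)j];
    for (int r = 0; r < nh; r++) out(r, j) = H[(size_t)r][(size_t)src];
  }
  std::vector<int> ps((size_t)S);
  for (int j = 0; j < S; j++) ps[(size_t)j] = pos[(size_t)ord[(size_t)j]];
  pos = ps;
  return out;
}

// Evolve a constant-size population of nh/2 diploids for up to n_gen
// generations on one chromosome.
//
// mu      : per-bp per-generation mutation rate (infinite sites on integer bp;
//           0 disables mutation).
// rec     : Morgan per bp.
// sweep_pos : bp of a site under genic selection (-1 = neutral run). Fitness of
//           an individual with g copies of the derived allele is (1+s)^g, so
//           the expected post-selection frequency is the deterministic genic
//           update and multinomial parent sampling supplies the binomial noise.
// stop_freq : stop early once the sweep allele frequency reaches this value
//           (use 2 to never stop early; 1 stops at fixation).
// purge   : drop sites that are lost or fixed (the sweep site is never purged
//           while fixed, only when lost). Must be FALSE whenever the SNP map
//           has to stay aligned with other populations.
// [[Rcpp::export]]
List wf_run_cpp(IntegerMatrix hap, IntegerVector pos_in, double chrom_len,
                int n_gen, double mu, double rec,
                double sweep_pos, double sweep_s, double stop_freq,
                bool purge) {
  int nh = hap.nrow();
  int N = nh / 2;
  if (N < 1) stop("population must contain at least one diploid individual");
  int isweep = (sweep_pos >= 0) ? (int)sweep_pos : -1;

  std::vector<Hap> H((size_t)nh), H2((size_t)nh);
  std::vector<int> pos(pos_in.begin(), pos_in.end());
  for (int r = 0; r < nh; r++) {
    H[(size_t)r].resize(pos.size());
    for (size_t j = 0; j < pos.size(); j++) H[(size_t)r][j] = (unsigned char)hap(r, (int)j);
  }
  std::unordered_set<int> posset(pos.begin(), pos.end());

  bool lost = false;
  double freq = 0.0, max_freq = 0.0;
  int gens_run = 0;

  // initial sweep frequency (if the site is present)
  if (isweep >= 0) {
    for (size_t j = 0; j < pos.size(); j++) {
      if (pos[j] == isweep) {
        int c = 0;
        for (int r = 0; r < nh; r++) c += H[(size_t)r][j];
        freq = (double)c / nh;
        max_freq = freq;
      }
    }
  }

  std::vector<double> cum((size_t)N);
  for (int gen = 0; gen < n_gen; gen++) {
    // fitness-weighted parent sampling
    int sc = -1;
    if (isweep >= 0) {
      for (size_t j = 0; j < pos.size(); j++)
        if (pos[j] == isweep) { sc = (int)j; break; }
    }
    double acc = 0.0;
    for (int i = 0; i < N; i++) {
      double w = 1.0;
      if (sc >= 0 && sweep_s != 0.0) {
        int g = H[(size_t)(2 * i)][(size_t)sc] + H[(size_t)(2 * i + 1)][(size_t)sc];
        w = std::pow(1.0 + sweep_s, (double)g);
      }
      acc += w;
      cum[(size_t)i] = acc;
    }
    for (int i = 0; i < N; i++) {
      int p1 = sample_cumulative(cum);
      int p2 = sample_cumulative(cum);
      make_gamete(H, pos, rec, chrom_len, p1, H2[(size_t)(2 * i)]);
      make_gamete(H, pos, rec, chrom_len, p2, H2[(size_t)(2 * i + 1)]);
    }
    std::swap(H, H2);

    // infinite-sites mutation (columns appended in one block per generation)
    if (mu > 0.0) {
      int nm = (int)R::rpois((double)nh * mu * chrom_len);
      std::vector<std::pair<int, int> > muts;  // (row, new column offset)
      for (int t = 0; t < nm; t++) {
        int bp = (int)(unif_rand() * chrom_len);
        if (bp >= (int)chrom_len) bp = (int)chrom_len - 1;
        if (posset.count(bp)) continue;  // occupied site: skip (infinite-sites approx.)
        posset.insert(bp);
        int row = (int)(unif_rand() * nh);
        if (row >= nh) row = nh - 1;
        muts.push_back(std::make_pair(row, (int)pos.size()));
        pos.push_back(bp);
      }
      if (!muts.empty()) {
        for (int r = 0; r < nh; r++) H[(size_t)r].resize(pos.size(), 0);
        for (size_t t = 0; t < muts.size(); t++)
          H[(size_t)muts[t].first][(size_t)muts[t].second] = 1;
      }
    }

    gens_run = gen + 1;

    // track the sweep allele every generation (one-column count)
    if (isweep >= 0) {
      int sc2 = -1;
      for (size_t j = 0; j < pos.size(); j++)
        if (pos[j] == isweep) { sc2 = (int)j; break; }
      if (sc2 >= 0) {
        int c = 0;
        for (int r = 0; r < nh; r++) c += H[(size_t)r][(size_t)sc2];
        freq = (double)c / nh;
        if (freq > max_freq) max_freq = freq;
      } else {
        freq = 0.0;
      }
    }

    // full allele counts + purge of lost/fixed sites only every few
    // generations (bookkeeping only: dead columns do not affect dynamics);
    // the sweep site survives fixation.
    bool last_gen = (gen == n_gen - 1) ||
                    (isweep >= 0 && ((freq == 0.0 && max_freq > 0.0) ||
                                     (stop_freq <= 1.0 && freq >= stop_freq)));
    if (purge && (last_gen || (gen % 5) == 4)) {
      size_t S = pos.size();
      std::vector<int> cnt(S, 0);
      for (int r = 0; r < nh; r++) {
        const Hap& h = H[(size_t)r];
        for (size_t j = 0; j < S; j++) cnt[j] += h[j];
      }
      std::vector<size_t> keep;
      keep.reserve(S);
      for (size_t j = 0; j < S; j++) {
        bool is_sweep = (isweep >= 0 && pos[j] == isweep);
        if (cnt[j] == 0 || (cnt[j] == nh && !is_sweep)) {
          posset.erase(pos[j]);
        } else {
          keep.push_back(j);
        }
      }
      if (keep.size() != S) {
        for (int r = 0; r < nh; r++) {
          Hap& h = H[(size_t)r];
          for (size_t k = 0; k < keep.size(); k++) h[k] = h[keep[k]];
          h.resize(keep.size());
        }
        std::vector<int> ps(keep.size());
        for (size_t k = 0; k < keep.size(); k++) ps[k] = pos[keep[k]];
        pos = ps;
      }
    }

    if (isweep >= 0 && freq == 0.0 && max_freq > 0.0) { lost = true; break; }
    if (isweep >= 0 && stop_freq <= 1.0 && freq >= stop_freq) break;
    if ((gen & 63) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix out = pack_sorted(H, pos);
  return List::create(_["hap"] = out, _["pos"] = wrap(pos),
                      _["generations"] = gens_run, _["sweep_freq"] = freq,
                      _["sweep_max_freq"] = max_freq, _["sweep_lost"] = lost);
}

// One round of reproduction with a caller-supplied parent for every offspring
// haplotype (1-based diploid parent indices). Used by the truncation-selection
// trait stage, where one genome-wide parent vector must be shared across
// chromosomes. No mutation, no purging: the SNP map is left untouched.
// [[Rcpp::export]]
IntegerMatrix make_gametes_cpp(IntegerMatrix hap, IntegerVector pos_in,
                               double chrom_len, double rec,
                               IntegerVector parent_of_gamete) {
  int nh = hap.nrow();
  int S = hap.ncol();
  int n_out = parent_of_gamete.size();
  std::vector<Hap> H((size_t)nh);
  std::vector<int> pos(pos_in.begin(), pos_in.end());
  for (int r = 0; r < nh; r++) {
    H[(size_t)r].resize((size_t)S);
    for (int j = 0; j < S; j++) H[(size_t)r][(size_t)j] = (unsigned char)hap(r, j);
  }
  IntegerMatrix out(n_out, S);
  Hap g;
  for (int i = 0; i < n_out; i++) {
    int p = parent_of_gamete[i] - 1;
    if (p < 0 || 2 * p + 1 >= nh) stop("parent index out of range");
    make_gamete(H, pos, rec, chrom_len, p, g);
    for (int j = 0; j < S; j++) out(i, j) = g[(size_t)j];
  }
  return out;
}

// ---------------------------------------------------------------------------
// EHH / iEHH genome scan.
//
// For a core SNP and one of its alleles, EHH at flanking SNP t is
//   sum_h C(n_h, 2) / C(n_A, 2)
// over groups h of carrier haplotypes identical from the core through t.
// The curve is followed outward until EHH < threshold (or the chromosome
// end); iEHH is the trapezoidal integral over bp distance, truncated at the
// linearly interpolated threshold crossing, with the two directions summed.
// ---------------------------------------------------------------------------

// Integrate one direction. Returns area; sets truncated=true when the
// chromosome end was reached with EHH still >= threshold.
static double iehh_direction(const IntegerMatrix& hap, const IntegerVector& pos,
                             const std::vector<int>& carriers, int core,
                             int step, double threshold, bool& truncated) {
  int nA = (int)carriers.size();
  double pairsA = 0.5 * nA * (nA - 1);
  int S = hap.ncol();
  std::vector<int> id((size_t)nA, 0);
  std::vector<int> newid((size_t)nA);
  std::vector<int> remap;  // key -> compact id, keys touched this step
  double area = 0.0, ehh_prev = 1.0, d_prev = 0.0;
  int n_groups = 1;
  truncated = false;
  for (int j = core + step;; j += step) {
    if (j < 0 || j >= S) { truncated = true; break; }
    // refine identity groups by the allele at SNP j
    remap.assign((size_t)(2 * n_groups), -1);
    int next = 0;
    for (int c = 0; c < nA; c++) {
      int key = 2 * id[(size_t)c] + hap(carriers[(size_t)c], j);
      if (remap[(size_t)key] < 0) remap[(size_t)key] = next++;
      newid[(size_t)c] = remap[(size_t)key];
    }
    n_groups = next;
    id = newid;
    std::vector<int> gsz((size_t)n_groups, 0);
    for (int c = 0; c < nA; c++) gsz[(size_t)id[(size_t)c]]++;
    double pairs = 0.0;
    for (int g = 0; g < n_groups; g++) pairs += 0.5 * gsz[(size_t)g] * (gsz[(size_t)g] - 1);
    double ehh = pairs / pairsA;
    double d = std::abs((double)pos[j] - (double)pos[core]);
    if (ehh < threshold) {
      // interpolate the crossing and close the integral there
      double dcross = (ehh_prev > ehh)
                          ? d_prev + (d - d_prev) * (ehh_prev - threshold) / (ehh_prev - ehh)
                          : d;
      area += 0.5 * (ehh_prev + threshold) * (dcross - d_prev);
      break;
    }
    area += 0.5 * (ehh_prev + ehh) * (d - d_prev);
    ehh_prev = ehh;
    d_prev = d;
    if (ehh == 0.0) break;  // cannot recover; threshold <= 0 edge case
  }
  return area;
}

// Per-SNP iEHH for the ancestral and derived allele over one chromosome.
// anc[j] in {0,1} gives the ancestral allele; NA_INTEGER skips the SNP.
// Returns iehh_anc / iehh_der (NA when < 2 carriers) and truncation flags.
// [[Rcpp::export]]
List ehh_scan_cpp(IntegerMatrix hap, IntegerVector pos, IntegerVector anc,
                  double threshold) {
  int S = hap.ncol();
  int nh = hap.nrow();
  NumericVector ia(S, NA_REAL), id(S, NA_REAL);
  LogicalVector trunc_any(S, false);
  std::vector<int> carriers;
  carriers.reserve((size_t)nh);
  for (int j = 0; j < S; j++) {
    if (anc[j] == NA_INTEGER) continue;
    for (int which = 0; which < 2; which++) {
      int allele = which == 0 ? anc[j] : 1 - anc[j];
      carriers.clear();
      for (int r = 0; r < nh; r++)
        if (hap(r, j) == allele) carriers.push_back(r);
      if ((int)carriers.size() < 2) continue;
      bool tl = false, tr = false;
      double a = iehh_direction(hap, pos, carriers, j, -1, threshold, tl) +
                 iehh_direction(hap, pos, carriers, j, +1, threshold, tr);
      if (which == 0) ia[j] = a; else id[j] = a;
      if (tl || tr) trunc_any[j] = true;
    }
    if ((j & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["iehh_anc"] = ia, _["iehh_der"] = id,
                      _["truncated"] = trunc_any);
}

// ---------------------------------------------------------------------------
// BayesR-style Gibbs sampler: 4-component normal mixture prior on SNP effects
// (component variances supplied, first one 0), Dirichlet(1,...,1) prior on the
// mixture proportions, scaled-inverse-chi-squared residual variance. X and y
// must be centered. No polygenic/pedigree term.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List bayesr_gibbs_cpp(NumericMatrix X, NumericVector y, NumericVector comp_var,
                      int n_iter, int burn_in) {
  int n = X.nrow(), m = X.ncol(), K = comp_var.size();
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter");
  std::vector<double> xtx((size_t)m);
  for (int j = 0; j < m; j++) {
    double s = 0.0;
    for (int i = 0; i < n; i++) s += X(i, j) * X(i, j);
    xtx[(size_t)j] = s;
  }
  double vary = 0.0;
  for (int i = 0; i < n; i++) vary += y[i] * y[i];
  vary /= std::max(1, n - 1);

  std::vector<double> b((size_t)m, 0.0), r(y.begin(), y.end());
  std::vector<double> pi((size_t)K, 1.0 / K), ll((size_t)K), pr((size_t)K);
  std::vector<int> cnt((size_t)K);
  double var_e = 0.5 * vary;
  const double nu0 = 4.0, S0 = 0.5 * vary;  // weak residual-variance prior

  std::vector<double> b_sum((size_t)m, 0.0), pi_sum((size_t)K, 0.0),
      pip_sum((size_t)m, 0.0);
  int kept = 0;

  for (int it = 0; it < n_iter; it++) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int j = 0; j < m; j++) {
      double bj = b[(size_t)j];
      double rhs = 0.0;
      if (bj != 0.0) {
        for (int i = 0; i < n; i++) {
          r[(size_t)i] += X(i, j) * bj;
          rhs += X(i, j) * r[(size_t)i];
        }
      } else {
        for (int i = 0; i < n; i++) rhs += X(i, j) * r[(size_t)i];
      }
      double sx = xtx[(size_t)j];
      if (sx <= 0.0) { b[(size_t)j] = 0.0; cnt[0]++; continue; }
      double lmax = -1e300;
      for (int k = 0; k < K; k++) {
        double V = sx * var_e + sx * sx * comp_var[k];
        ll[(size_t)k] = std::log(pi[(size_t)k]) - 0.5 * std::log(V) - 0.5 * rhs * rhs / V;
        if (ll[(size_t)k] > lmax) lmax = ll[(size_t)k];
      }
      double tot = 0.0;
      for (int k = 0; k < K; k++) { pr[(size_t)k] = std::exp(ll[(size_t)k] - lmax); tot += pr[(size_t)k]; }
      double u = unif_rand() * tot;
      int comp = K - 1;
      double acc2 = 0.0;
      for (int k = 0; k < K; k++) { acc2 += pr[(size_t)k]; if (u <= acc2) { comp = k; break; } }
      cnt[(size_t)comp]++;
      if (comp_var[comp] <= 0.0) {
        b[(size_t)j] = 0.0;
      } else {
        double C = sx + var_e / comp_var[comp];
        double mean = rhs / C, sd = std::sqrt(var_e / C);
        double bnew = mean + sd * norm_rand();
        b[(size_t)j] = bnew;
        for (int i = 0; i < n; i++) r[(size_t)i] -= X(i, j) * bnew;
      }
    }
    // mixture proportions | counts
    double gtot = 0.0;
    for (int k = 0; k < K; k++) { pr[(size_t)k] = R::rgamma(1.0 + cnt[(size_t)k], 1.0); gtot += pr[(size_t)k]; }
    for (int k = 0; k < K; k++) pi[(size_t)k] = pr[(size_t)k] / gtot;
    // residual variance
    double rss = 0.0;
    for (int i = 0; i < n; i++) rss += r[(size_t)i] * r[(size_t)i];
    var_e = (rss + nu0 * S0) / R::rchisq((double)n + nu0);
    if (it >= burn_in) {
      kept++;
      for (int j = 0; j < m; j++) {
        b_sum[(size_t)j] += b[(size_t)j];
        if (b[(size_t)j] != 0.0) pip_sum[(size_t)j] += 1.0;
      }
      for (int k = 0; k < K; k++) pi_sum[(size_t)k] += pi[(size_t)k];
    }
    if ((it & 127) == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector bm(m), pip(m), pim(K);
  for (int j = 0; j < m; j++) { bm[j] = b_sum[(size_t)j] / kept; pip[j] = pip_sum[(size_t)j] / kept; }
  for (int k = 0; k < K; k++) pim[k] = pi_sum[(size_t)k] / kept;
  return List::create(_["beta"] = bm, _["pip"] = pip, _["pi"] = pim,
                      _["var_e"] = var_e);
}
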