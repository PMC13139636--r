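#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Moran-type neutral dynamics: serial death-replacement on a vector of
// individuals (0-based taxon index per individual). Each event kills one
// random individual; with probability m the replacement is drawn from the
// metacommunity (cumulative probabilities meta_cum), otherwise it copies a
// random surviving local individual. Uses R's RNG, so set.seed() applies.
// [[Rcpp::export]]
IntegerVector cpp_moran(IntegerVector comm, NumericVector meta_cum, double m,
                        double n_events) {
  IntegerVector out = clone(comm);
  const int n = out.size();
  const int S = meta_cum.size();
  const double *cum = meta_cum.begin();
  for (double e = 0; e < n_events; e += 1.0) {
    int di = (int)(unif_rand() * n);
    if (di >= n) di = n - 1;
    int taxon;
    if (unif_rand() < m) {
      double u = unif_rand();
      taxon = (int)(std::lower_bound(cum, cum + S, u) - cum);
      if (taxon >= S) taxon = S - 1;
    } else {
      int ci = (int)(unif_rand() * n);
      if (ci >= n) ci = n - 1;
      taxon = out[ci];
    }
    out[di] = taxon;
  }
  return out;
}

// Abundance-weighted beta-mean-nearest-taxon-distance for all sample pairs,
// plus a tip-shuffle null. D: S x S patristic distances; F: S x n relative
// abundances within each sample (zero where absent). Returns observed betaMNTD
// and, when n_null > 0, the null mean/sd and the standardized effect (betaNTI).
// The null permutes taxon labels across the distance matrix (tips), keeping
// the abundance structure fixed.
// [[Rcpp::export]]
List cpp_bmntd_nti(NumericMatrix D, NumericMatrix F, int n_null) {
  const int S = D.nrow(), n = F.ncol();
  std::vector<std::vector<int> > pres(n);
  for (int s = 0; s < n; ++s)
    for (int i = 0; i < S; ++i)
      if (F(i, s) > 0) pres[s].push_back(i);

  std::vector<int> perm(S);
  std::vector<double> tipmin(S);
  NumericMatrix M(S, n);

  NumericMatrix obs(n, n), nmean(n, n), nsd(n, n), bnti(n, n);
  std::vector<double> sum1(n * n, 0.0), sum2(n * n, 0.0);

  for (int rep = 0; rep <= n_null; ++rep) {
    if (rep == 0) {
      for (int i = 0; i < S; ++i) perm[i] = i;
    } else {
      // Fisher-Yates with R's RNG
      for (int i = 0; i < S; ++i) perm[i] = i;
      for (int i = S - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
    }
    // M(i, s) = min over taxa j present in s of D(perm[i], perm[j]).
    // First compute the minima in tip space (sequential scans over D's
    // columns), then gather through the permutation once per sample.
    for (int s = 0; s < n; ++s) {
      std::fill(tipmin.begin(), tipmin.end(), R_PosInf);
      for (size_t jj = 0; jj < pres[s].size(); ++jj) {
        const double *dcol = &D(0, perm[pres[s][jj]]);
        for (int t = 0; t < S; ++t)
          if (dcol[t] < tipmin[t]) tipmin[t] = dcol[t];
      }
      double *mcol = &M(0, s);
      for (int i = 0; i < S; ++i) mcol[i] = tipmin[perm[i]];
    }
    // pair values: 0.5 * (sum_i F(i,a) M(i,b) + sum_j F(j,b) M(j,a))
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b < n; ++b) {
        double va = 0.0, vb = 0.0;
        for (size_t ii = 0; ii < pres[a].size(); ++ii) {
          int i = pres[a][ii];
          va += F(i, a) * M(i, b);
        }
        for (size_t jj = 0; jj < pres[b].size(); ++jj) {
          int j = pres[b][jj];
          vb += F(j, b) * M(j, a);
        }
        double v = 0.5 * (va + vb);
        if (rep == 0) {
          obs(a, b) = obs(b, a) = v;
        } else {
          sum1[a * n + b] += v;
          sum2[a * n + b] += v * v;
        }
      }
    }
  }
  if (n_null > 0) {
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b) {
        double mu = sum1[a * n + b] / n_null;
        double var = (sum2[a * n + b] - n_null * mu * mu) / (n_null - 1);
        double sd = var > 0 ? std::sqrt(var) : 0.0;
        nmean(a, b) = nmean(b, a) = mu;
        nsd(a, b) = nsd(b, a) = sd;
        bnti(a, b) = bnti(b, a) =
            sd > 0 ? (obs(a, b) - mu) / sd : NA_REAL;
      }
  }
  return List::create(_["obs"] = obs, _["null_mean"] = nmean,
                      _["null_sd"] = nsd, _["bnti"] = bnti);
}

static double bray_curtis_sparse(const std::vector<int> &ta,
                                 const std::vector<int> &tb,
                                 const std::vector<double> &na,
                                 const std::vector<double> &nb,
                                 std::vector<char> &mark) {
  double sumabs = 0.0, tot = 0.0;
  for (size_t k = 0; k < ta.size(); ++k) mark[ta[k]] = 1;
  for (size_t k = 0; k < tb.size(); ++k) {
    int i = tb[k];
    if (mark[i]) {
      sumabs += std::fabs(na[i] - nb[i]);
      mark[i] = 2;
    } else {
      sumabs += nb[i];
    }
    tot += nb[i];
  }
  for (size_t k = 0; k < ta.size(); ++k) {
    int i = ta[k];
    if (mark[i] == 1) sumabs += na[i];
    tot += na[i];
    mark[i] = 0;
  }
  for (size_t k = 0; k < tb.size(); ++k) mark[tb[k]] = 0;
  return tot > 0 ? sumabs / tot : 0.0;
}

// One null community: draw `richness` distinct taxa with probability
// proportional to occ_w (Efraimidis-Spirakis keys), then allocate `total`
// individuals among them proportionally to meta_p (conditional binomials).
static void null_community(int richness, double total,
                           const NumericVector &occ_w,
                           const NumericVector &meta_p,
                           std::vector<std::pair<double, int> > &keys,
                           std::vector<int> &taxa, std::vector<double> &abund) {
  const int S = occ_w.size();
  keys.clear();
  for (int i = 0; i < S; ++i) {
    if (occ_w[i] > 0)
      keys.push_back(std::make_pair(-std::log(unif_rand()) / occ_w[i], i));
  }
  int r = richness < (int)keys.size() ? richness : (int)keys.size();
  std::partial_sort(keys.begin(), keys.begin() + r, keys.end());
  taxa.clear();
  double psum = 0.0;
  for (int k = 0; k < r; ++k) {
    taxa.push_back(keys[k].second);
    psum += meta_p[keys[k].second];
  }
  // each drawn taxon receives one individual (richness preserved), the
  // rest are allocated proportionally to the metacommunity abundances
  double remaining = total - r;
  if (remaining < 0) remaining = 0;
  for (int k = 0; k < r; ++k) {
    int i = taxa[k];
    double x;
    if (k == r - 1 || psum <= 0) {
      x = remaining;
    } else {
      double p = meta_p[i] / psum;
      if (p > 1) p = 1;
      x = R::rbinom(remaining, p);
    }
    abund[i] = 1.0 + x;
    remaining -= x;
    psum -= meta_p[i];
    if (remaining < 0) remaining = 0;
  }
}

// Raup-Crick (Bray-Curtis) for the given 0-based sample pairs. counts: n x S.
// occ_w: per-taxon occurrence frequency (null probability of being drawn);
// meta_p: per-taxon metacommunity relative abundance (null allocation weight).
// Each null replicate draws ONE null community per sample and evaluates every
// pair on that draw (the same sharing the tip-shuffle null uses); marginally
// each pair still sees n_null independent null dissimilarities.
// [[Rcpp::export]]
NumericVector cpp_rc_bray(NumericMatrix counts, IntegerMatrix pairs,
                          int n_null, NumericVector occ_w,
                          NumericVector meta_p) {
  const int n = counts.nrow(), S = counts.ncol(), P = pairs.nrow();
  NumericVector rc(P);
  std::vector<char> mark(S, 0);
  std::vector<std::pair<double, int> > keys;
  keys.reserve(S);

  // which samples participate in any pair
  std::vector<char> needed(n, 0);
  for (int p = 0; p < P; ++p) {
    needed[pairs(p, 0)] = 1;
    needed[pairs(p, 1)] = 1;
  }

  // observed sparse communities and dissimilarities
  std::vector<std::vector<int> > obs_taxa(n);
  std::vector<std::vector<double> > dense(n);
  std::vector<int> rich(n, 0);
  std::vector<double> tot(n, 0.0);
  for (int s = 0; s < n; ++s) {
    if (!needed[s]) continue;
    dense[s].assign(S, 0.0);
    for (int i = 0; i < S; ++i) {
      double x = counts(s, i);
      if (x > 0) {
        ++rich[s]; tot[s] += x;
        dense[s][i] = x;
        obs_taxa[s].push_back(i);
      }
    }
  }
  std::vector<double> obs(P);
  for (int p = 0; p < P; ++p) {
    int a = pairs(p, 0), b = pairs(p, 1);
    obs[p] = bray_curtis_sparse(obs_taxa[a], obs_taxa[b],
                                dense[a], dense[b], mark);
  }

  // clear the observed abundances before the null draws reuse the buffers
  for (int s = 0; s < n; ++s)
    for (size_t k = 0; k < obs_taxa[s].size(); ++k)
      dense[s][obs_taxa[s][k]] = 0.0;

  std::vector<std::vector<int> > null_taxa(n);
  std::vector<double> below(P, 0.0), equal(P, 0.0);
  for (int rep = 0; rep < n_null; ++rep) {
    for (int s = 0; s < n; ++s) {
      if (!needed[s]) continue;
      for (size_t k = 0; k < null_taxa[s].size(); ++k)
        dense[s][null_taxa[s][k]] = 0.0;
      null_community(rich[s], tot[s], occ_w, meta_p, keys, null_taxa[s],
                     dense[s]);
    }
    for (int p = 0; p < P; ++p) {
      int a = pairs(p, 0), b = pairs(p, 1);
      double d = bray_curtis_sparse(null_taxa[a], null_taxa[b],
                                    dense[a], dense[b], mark);
      if (d < obs[p] - 1e-10) below[p] += 1.0;
      else if (d <= obs[p] + 1e-10) equal[p] += 1.0;
    }
  }
  for (int p = 0; p < P; ++p)
    rc[p] = 2.0 * (below[p] + 0.5 * equal[p]) / n_null - 1.0;
  return rc;
}
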