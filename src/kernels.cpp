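#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fisher-Yates shuffle of 0..(n-1) using R's RNG so set.seed() governs
// every draw.
static void rperm(std::vector<int> &p) {
  const int n = static_cast<int>(p.size());
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
}

static double pearson(const std::vector<double> &x,
                      const std::vector<double> &y) {
  const int n = static_cast<int>(x.size());
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
  mx /= n; my /= n;
  double sxy = 0.0, sxx = 0.0, syy = 0.0;
  for (int i = 0; i < n; ++i) {
    const double dx = x[i] - mx, dy = y[i] - my;
    sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
  }
  if (sxx <= 0.0 || syy <= 0.0) return NA_REAL;
  return sxy / std::sqrt(sxx * syy);
}

// Average ranks (midranks for ties).
static void midranks(const std::vector<double> &x, std::vector<double> &r) {
  const int n = static_cast<int>(x.size());
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&x](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[idx[j + 1]] == x[idx[i]]) ++j;
    const double rank = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) r[idx[k]] = rank;
    i = j + 1;
  }
}

static double spearman(const std::vector<double> &x,
                       const std::vector<double> &y,
                       std::vector<double> &rx, std::vector<double> &ry) {
  midranks(x, rx);
  midranks(y, ry);
  return pearson(rx, ry);
}

// Bray-Curtis similarity 1 - sum|x-y| / sum(x+y).
static double bc_sim(const std::vector<double> &x,
                     const std::vector<double> &y) {
  double num = 0.0, den = 0.0;
  for (size_t i = 0; i < x.size(); ++i) {
    num += std::fabs(x[i] - y[i]);
    den += x[i] + y[i];
  }
  if (den <= 0.0) return NA_REAL;
  return 1.0 - num / den;
}

// Renormalized-permutation ("ReBoot"-style) null for one feature pair.
// X is features x samples with every sample column summing to 1.  Each
// iteration permutes the two features' values across samples
// independently, renormalizes every sample column total (only the two
// permuted rows change, so the new totals are computed incrementally),
// and recomputes Pearson, Spearman and Bray-Curtis similarity on the
// renormalized pair.  Returns an n_iter x 3 matrix of null scores.
// [[Rcpp::export]]
NumericMatrix cpp_reboot_null(const NumericMatrix &X, const int fi,
                              const int fj, const int n_iter) {
  const int n = X.ncol();
  std::vector<double> colsum(n, 0.0);
  for (int s = 0; s < n; ++s) {
    double tot = 0.0;
    for (int f = 0; f < X.nrow(); ++f) tot += X(f, s);
    colsum[s] = tot;
  }
  std::vector<int> pa(n), pb(n);
  std::vector<double> xa(n), xb(n), ya(n), yb(n), rx(n), ry(n);
  NumericMatrix out(n_iter, 3);
  for (int it = 0; it < n_iter; ++it) {
    rperm(pa);
    rperm(pb);
    for (int s = 0; s < n; ++s) {
      xa[s] = X(fi, pa[s]);
      xb[s] = X(fj, pb[s]);
      const double denom = colsum[s] - X(fi, s) - X(fj, s) + xa[s] + xb[s];
      if (denom > 0.0) {
        ya[s] = xa[s] / denom;
        yb[s] = xb[s] / denom;
      } else {
        ya[s] = 0.0;
        yb[s] = 0.0;
      }
    }
    out(it, 0) = pearson(ya, yb);
    out(it, 1) = spearman(ya, yb, rx, ry);
    out(it, 2) = bc_sim(ya, yb);
  }
  return out;
}

// Abundance-weighted betaMNTD for one community pair given a tip
// distance matrix D and 0-based tip indices of the taxa present in each
// community, with within-community relative abundances wi / wj.
static double bmntd_pair(const NumericMatrix &D, const std::vector<int> &ii,
                         const std::vector<int> &jj,
                         const std::vector<double> &wi,
                         const std::vector<double> &wj) {
  double a = 0.0;
  for (size_t k = 0; k < ii.size(); ++k) {
    double mn = R_PosInf;
    for (size_t l = 0; l < jj.size(); ++l) {
      const double d = D(ii[k], jj[l]);
      if (d < mn) mn = d;
    }
    a += wi[k] * mn;
  }
  double b = 0.0;
  for (size_t l = 0; l < jj.size(); ++l) {
    double mn = R_PosInf;
    for (size_t k = 0; k < ii.size(); ++k) {
      const double d = D(ii[k], jj[l]);
      if (d < mn) mn = d;
    }
    b += wj[l] * mn;
  }
  return 0.5 * (a + b);
}

// [[Rcpp::export]]
double cpp_bmntd(const NumericMatrix &D, const IntegerVector &idx_i,
                 const IntegerVector &idx_j, const NumericVector &wi,
                 const NumericVector &wj) {
  std::vector<int> ii(idx_i.begin(), idx_i.end());
  std::vector<int> jj(idx_j.begin(), idx_j.end());
  std::vector<double> a(wi.begin(), wi.end());
  std::vector<double> b(wj.begin(), wj.end());
  return bmntd_pair(D, ii, jj, a, b);
}

// Sampled tip-shuffle null: each draw relabels taxa by a uniform random
// permutation of ALL tree tips (equivalently permutes rows/columns of D)
// and recomputes betaMNTD for the pair.
// [[Rcpp::export]]
NumericVector cpp_bmntd_null(const NumericMatrix &D,
                             const IntegerVector &idx_i,
                             const IntegerVector &idx_j,
                             const NumericVector &wi, const NumericVector &wj,
                             const int n_null) {
  const int ntip = D.nrow();
  std::vector<int> perm(ntip);
  std::vector<int> ii(idx_i.size()), jj(idx_j.size());
  std::vector<double> a(wi.begin(), wi.end());
  std::vector<double> b(wj.begin(), wj.end());
  NumericVector out(n_null);
  for (int t = 0; t < n_null; ++t) {
    rperm(perm);
    for (size_t k = 0; k < ii.size(); ++k) ii[k] = perm[idx_i[k]];
    for (size_t l = 0; l < jj.size(); ++l) jj[l] = perm[idx_j[l]];
    out[t] = bmntd_pair(D, ii, jj, a, b);
  }
  return out;
}

// Exhaustive null: evaluates betaMNTD under every supplied permutation
// (rows of `perms`, 0-based over all tips).
// [[Rcpp::export]]
NumericVector cpp_bmntd_perms(const NumericMatrix &D,
                              const IntegerMatrix &perms,
                              const IntegerVector &idx_i,
                              const IntegerVector &idx_j,
                              const NumericVector &wi,
                              const NumericVector &wj) {
  std::vector<int> ii(idx_i.size()), jj(idx_j.size());
  std::vector<double> a(wi.begin(), wi.end());
  std::vector<double> b(wj.begin(), wj.end());
  NumericVector out(perms.nrow());
  for (int t = 0; t < perms.nrow(); ++t) {
    for (size_t k = 0; k < ii.size(); ++k) ii[k] = perms(t, idx_i[k]);
    for (size_t l = 0; l < jj.size(); ++l) jj[l] = perms(t, idx_j[l]);
    out[t] = bmntd_pair(D, ii, jj, a, b);
  }
  return out;
}
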