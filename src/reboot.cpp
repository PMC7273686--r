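#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::pair<double, int> ValIdx;

// Average ranks (midranks for ties) via sorting (value, index) pairs.
static void average_ranks(const std::vector<double>& v,
                          std::vector<ValIdx>& buf,
                          std::vector<double>& out) {
  const int n = static_cast<int>(v.size());
  for (int i = 0; i < n; ++i) buf[i] = ValIdx(v[i], i);
  std::sort(buf.begin(), buf.end());
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && buf[j + 1].first == buf[i].first) ++j;
    const double r = 0.5 * (i + j) + 1.0;
    for (int k = i; k <= j; ++k) out[buf[k].second] = r;
    i = j + 1;
  }
}

static double pearson_of(const std::vector<double>& a,
                         const std::vector<double>& b) {
  const int n = static_cast<int>(a.size());
  double ma = 0.0, mb = 0.0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double saa = 0.0, sbb = 0.0, sab = 0.0;
  for (int i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    saa += da * da; sbb += db * db; sab += da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

static double spearman_of(const std::vector<double>& a,
                          const std::vector<double>& b,
                          std::vector<ValIdx>& buf,
                          std::vector<double>& ra,
                          std::vector<double>& rb) {
  average_ranks(a, buf, ra);
  average_ranks(b, buf, rb);
  return pearson_of(ra, rb);
}

// Bray-Curtis similarity 1 - sum|x-y| / sum(x+y); NA if both all-zero.
static double bray_sim_of(const std::vector<double>& a,
                          const std::vector<double>& b) {
  const int n = static_cast<int>(a.size());
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n; ++i) {
    num += std::fabs(a[i] - b[i]);
    den += a[i] + b[i];
  }
  if (den <= 0.0) return NA_REAL;
  return 1.0 - num / den;
}

// In-place Fisher-Yates shuffle using R's RNG.
static void shuffle_idx(std::vector<int>& idx) {
  const int n = static_cast<int>(idx.size());
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

static bool is_constant(const std::vector<double>& v) {
  for (size_t i = 1; i < v.size(); ++i)
    if (v[i] != v[0]) return false;
  return true;
}

// Sorted order plus tie-group boundaries of a fixed profile; lets
// bootstrap iterations rank a resample in O(n) from its multiplicities.
struct SortedProfile {
  std::vector<int> ord;        // sample indices sorted by value
  std::vector<int> group_end;  // exclusive end position of each tie group
  void build(const std::vector<double>& v, std::vector<ValIdx>& buf) {
    const int n = static_cast<int>(v.size());
    for (int i = 0; i < n; ++i) buf[i] = ValIdx(v[i], i);
    std::sort(buf.begin(), buf.end());
    ord.resize(n);
    group_end.clear();
    for (int i = 0; i < n; ++i) ord[i] = buf[i].second;
    int i = 0;
    while (i < n) {
      int j = i;
      while (j + 1 < n && buf[j + 1].first == buf[i].first) ++j;
      group_end.push_back(j + 1);
      i = j + 1;
    }
  }
  // Weighted midranks of a resample with per-sample multiplicities m
  // (summing to n_tot). Writes the rank of each original sample into
  // rank_of (samples with m == 0 get an arbitrary value, unused).
  // Returns the largest tie-group weight (== n_tot iff constant).
  int midranks(const std::vector<int>& m, std::vector<double>& rank_of) const {
    double cum = 0.0;
    int max_group = 0, start = 0;
    for (size_t g = 0; g < group_end.size(); ++g) {
      const int end = group_end[g];
      int w = 0;
      for (int k = start; k < end; ++k) w += m[ord[k]];
      if (w > 0) {
        const double r = cum + 0.5 * (w + 1);
        for (int k = start; k < end; ++k) rank_of[ord[k]] = r;
        cum += w;
        if (w > max_group) max_group = w;
      }
      start = end;
    }
    return max_group;
  }
};

// Weighted Pearson of per-sample ranks with multiplicities m (sum n_tot).
static double weighted_pearson(const std::vector<int>& m,
                               const std::vector<double>& ra,
                               const std::vector<double>& rb,
                               int n_tot) {
  double sa = 0.0, sb = 0.0;
  const int n = static_cast<int>(m.size());
  for (int j = 0; j < n; ++j) if (m[j] > 0) {
    sa += m[j] * ra[j];
    sb += m[j] * rb[j];
  }
  const double ma = sa / n_tot, mb = sb / n_tot;
  double saa = 0.0, sbb = 0.0, sab = 0.0;
  for (int j = 0; j < n; ++j) if (m[j] > 0) {
    const double da = ra[j] - ma, db = rb[j] - mb;
    saa += m[j] * da * da;
    sbb += m[j] * db * db;
    sab += m[j] * da * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Weighted Bray-Curtis over multiplicities.
static double weighted_bray(const std::vector<int>& m,
                            const std::vector<double>& x,
                            const std::vector<double>& y) {
  double num = 0.0, den = 0.0;
  const int n = static_cast<int>(m.size());
  for (int j = 0; j < n; ++j) if (m[j] > 0) {
    num += m[j] * std::fabs(x[j] - y[j]);
    den += m[j] * (x[j] + y[j]);
  }
  if (den <= 0.0) return NA_REAL;
  return 1.0 - num / den;
}

// Draw a bootstrap resample of n indices; returns number of distinct ones.
static int draw_resample(std::vector<int>& m, int n) {
  std::fill(m.begin(), m.end(), 0);
  int distinct = 0;
  for (int i = 0; i < n; ++i) {
    int j = static_cast<int>(unif_rand() * n);
    if (j >= n) j = n - 1;
    if (m[j] == 0) ++distinct;
    ++m[j];
  }
  return distinct;
}

// Permutation null scores for one taxon pair. `x`/`y` are counts when
// `renormalize` is TRUE (Spearman on renormalized relative abundances,
// `rest_total` = per-sample totals minus the pair's counts); otherwise they
// are relative-abundance profiles shuffled as-is.
// measure: 0 = spearman, 1 = bray-curtis similarity.
// [[Rcpp::export]]
NumericVector perm_scores_cpp(NumericVector x, NumericVector y,
                              NumericVector rest_total,
                              int n_iter, int measure, bool renormalize) {
  const int n = x.size();
  NumericVector out(n_iter);
  std::vector<int> px(n), py(n);
  std::iota(px.begin(), px.end(), 0);
  std::iota(py.begin(), py.end(), 0);
  std::vector<double> xv(n), yv(n), ra(n), rb(n);
  std::vector<ValIdx> buf(n);
  for (int b = 0; b < n_iter; ++b) {
    shuffle_idx(px);
    shuffle_idx(py);
    if (renormalize) {
      for (int i = 0; i < n; ++i) {
        const double xp = x[px[i]], yp = y[py[i]];
        const double tot = rest_total[i] + xp + yp;
        if (tot > 0.0) { xv[i] = xp / tot; yv[i] = yp / tot; }
        else           { xv[i] = 0.0;      yv[i] = 0.0; }
      }
    } else {
      for (int i = 0; i < n; ++i) { xv[i] = x[px[i]]; yv[i] = y[py[i]]; }
    }
    out[b] = (measure == 0) ? spearman_of(xv, yv, buf, ra, rb)
                            : bray_sim_of(xv, yv);
  }
  return out;
}

// Bootstrap scores for one pair of relative-abundance profiles: resample
// sample columns with replacement. Iterations whose resample has fewer than
// 3 distinct samples, or leaves either profile constant (Spearman only),
// are redrawn up to `max_retry` times, then scored NA.
// [[Rcpp::export]]
NumericVector boot_scores_cpp(NumericVector xr, NumericVector yr,
                              int n_iter, int measure, int max_retry) {
  const int n = xr.size();
  NumericVector out(n_iter);
  std::vector<double> x0(xr.begin(), xr.end()), y0(yr.begin(), yr.end());
  std::vector<ValIdx> buf(n);
  SortedProfile spx, spy;
  spx.build(x0, buf);
  spy.build(y0, buf);
  std::vector<int> m(n);
  std::vector<double> ra(n), rb(n);
  for (int b = 0; b < n_iter; ++b) {
    double score = NA_REAL;
    for (int attempt = 0; attempt <= max_retry; ++attempt) {
      const int distinct = draw_resample(m, n);
      if (distinct < 3) continue;
      if (measure == 0) {
        if (spx.midranks(m, ra) == n) continue;
        if (spy.midranks(m, rb) == n) continue;
        score = weighted_pearson(m, ra, rb, n);
      } else {
        score = weighted_bray(m, x0, y0);
      }
      break;
    }
    out[b] = score;
  }
  return out;
}

static double mean_narm(const std::vector<double>& v) {
  double s = 0.0; int k = 0;
  for (double x : v) if (!ISNAN(x)) { s += x; ++k; }
  return k > 0 ? s / k : NA_REAL;
}

static double sd_narm(const std::vector<double>& v, double m) {
  if (ISNAN(m)) return NA_REAL;
  double s = 0.0; int k = 0;
  for (double x : v) if (!ISNAN(x)) { s += (x - m) * (x - m); ++k; }
  return k > 1 ? std::sqrt(s / (k - 1)) : NA_REAL;
}

// Lower order-statistic quantile (type 1) of non-NA values.
static double quantile_narm(std::vector<double> v, double q) {
  v.erase(std::remove_if(v.begin(), v.end(),
                         [](double x) { return ISNAN(x) != 0; }),
          v.end());
  if (v.empty()) return NA_REAL;
  std::sort(v.begin(), v.end());
  int k = static_cast<int>(std::ceil(q * v.size())) - 1;
  if (k < 0) k = 0;
  if (k >= static_cast<int>(v.size())) k = static_cast<int>(v.size()) - 1;
  return v[k];
}

// Bulk ReBoot summaries for all candidate pairs of one environment table.
// counts: taxa x samples counts; relab: matching relative abundances;
// totals: per-sample count sums; pairs: 0-based two-column index matrix.
// Returns one row per pair:
//   [0] mean null rho   [1] mean boot rho  [2] sd boot rho
//   [3] mean null bc    [4] mean boot bc   [5] sd boot bc
//   [6] null bc q(lo)   [7] null bc q(hi)
// Permutation shuffles are shared between the two measures within an
// iteration; bootstrap resamples likewise. Uses R's RNG (seed via set.seed).
// [[Rcpp::export]]
NumericMatrix reboot_summaries_cpp(NumericMatrix counts, NumericMatrix relab,
                                   NumericVector totals, IntegerMatrix pairs,
                                   int n_iter, double bc_quantile,
                                   int max_retry) {
  const int n = counts.ncol();
  const int np = pairs.nrow();
  NumericMatrix out(np, 8);
  std::vector<int> px(n), py(n), m(n);
  std::vector<double> x(n), y(n), xr0(n), yr0(n), rest(n);
  std::vector<double> xv(n), yv(n), ra(n), rb(n);
  std::vector<double> null_rho(n_iter), null_bc(n_iter);
  std::vector<double> boot_rho(n_iter), boot_bc(n_iter);
  std::vector<ValIdx> buf(n);
  SortedProfile spx, spy;

  for (int p = 0; p < np; ++p) {
    const int a = pairs(p, 0), b = pairs(p, 1);
    for (int i = 0; i < n; ++i) {
      x[i] = counts(a, i); y[i] = counts(b, i);
      xr0[i] = relab(a, i); yr0[i] = relab(b, i);
      rest[i] = totals[i] - x[i] - y[i];
    }
    std::iota(px.begin(), px.end(), 0);
    std::iota(py.begin(), py.end(), 0);

    // permutation null: renormalized Spearman, plain-shuffle Bray-Curtis
    for (int it = 0; it < n_iter; ++it) {
      shuffle_idx(px);
      shuffle_idx(py);
      for (int i = 0; i < n; ++i) {
        const double xp = x[px[i]], yp = y[py[i]];
        const double tot = rest[i] + xp + yp;
        if (tot > 0.0) { xv[i] = xp / tot; yv[i] = yp / tot; }
        else           { xv[i] = 0.0;      yv[i] = 0.0; }
      }
      null_rho[it] = spearman_of(xv, yv, buf, ra, rb);
      for (int i = 0; i < n; ++i) { xv[i] = xr0[px[i]]; yv[i] = yr0[py[i]]; }
      null_bc[it] = bray_sim_of(xv, yv);
    }

    // bootstrap: joint column resample, both measures per iteration
    spx.build(xr0, buf);
    spy.build(yr0, buf);
    for (int it = 0; it < n_iter; ++it) {
      double s_rho = NA_REAL, s_bc = NA_REAL;
      for (int attempt = 0; attempt <= max_retry; ++attempt) {
        const int distinct = draw_resample(m, n);
        if (distinct < 3) continue;
        if (spx.midranks(m, ra) == n) continue;
        if (spy.midranks(m, rb) == n) continue;
        s_rho = weighted_pearson(m, ra, rb, n);
        s_bc = weighted_bray(m, xr0, yr0);
        break;
      }
      boot_rho[it] = s_rho;
      boot_bc[it] = s_bc;
    }

    const double m_nr = mean_narm(null_rho);
    const double m_br = mean_narm(boot_rho);
    const double m_nb = mean_narm(null_bc);
    const double m_bb = mean_narm(boot_bc);
    out(p, 0) = m_nr;
    out(p, 1) = m_br;
    out(p, 2) = sd_narm(boot_rho, m_br);
    out(p, 3) = m_nb;
    out(p, 4) = m_bb;
    out(p, 5) = sd_narm(boot_bc, m_bb);
    out(p, 6) = quantile_narm(null_bc, bc_quantile);
    out(p, 7) = quantile_narm(null_bc, 1.0 - bc_quantile);
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Row-wise midranks of a taxa x samples matrix (for fast pairwise Spearman
// via Pearson correlation of ranks).
// [[Rcpp::export]]
NumericMatrix row_ranks_cpp(NumericMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> v(nc), r(nc);
  std::vector<ValIdx> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) v[j] = m(i, j);
    average_ranks(v, buf, r);
    for (int j = 0; j < nc; ++j) out(i, j) = r[j];
  }
  return out;
}
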