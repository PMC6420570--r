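#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Induced-subgraph code -> standard 16-type triad index, order
// 003 012 102 021D 021U 021C 111D 111U 030T 030C 201 120D 120U 120C 210 300.
// Bits of the code for a triple (u,v,w):
//   1: u->v, 2: v->u, 4: u->w, 8: w->u, 16: v->w, 32: w->v
static const int TRI_TYPE[64] = {
  0,1,1,2,1,3,5,7,1,5,4,6,2,7,6,10,
  1,5,3,7,4,8,8,12,5,9,8,13,6,13,11,14,
  1,4,5,6,5,8,9,13,3,8,8,11,7,12,13,14,
  2,6,7,10,6,11,13,14,7,13,12,14,10,14,14,15
};

// ---------------------------------------------------------------------------
// Triad census (Batagelj-Mrvar edge-scan algorithm), O(m * mean degree).
// Nodes are 0-based; no self-loops allowed (checked upstream).
// ---------------------------------------------------------------------------

static void census16_core(int n,
                          const std::vector<int>& from,
                          const std::vector<int>& to,
                          double* cnt) {
  for (int i = 0; i < 16; ++i) cnt[i] = 0.0;
  if (n < 3) return;

  std::vector<uint8_t> adj((size_t)n * n, 0);
  std::vector<std::vector<int>> nbr(n);
  for (size_t k = 0; k < from.size(); ++k) {
    int a = from[k], b = to[k];
    adj[(size_t)a * n + b] = 1;
    nbr[a].push_back(b);
    nbr[b].push_back(a);
  }
  for (int v = 0; v < n; ++v) {
    std::sort(nbr[v].begin(), nbr[v].end());
    nbr[v].erase(std::unique(nbr[v].begin(), nbr[v].end()), nbr[v].end());
  }

  std::vector<char> mark(n, 0);
  std::vector<int> uni;
  uni.reserve(n);

  for (int u = 0; u < n; ++u) {
    for (int v : nbr[u]) {
      if (v <= u) continue;
      uni.clear();
      for (int w : nbr[u]) if (w != v && !mark[w]) { mark[w] = 1; uni.push_back(w); }
      for (int w : nbr[v]) if (w != u && !mark[w]) { mark[w] = 1; uni.push_back(w); }
      int S = (int)uni.size();
      bool mut = adj[(size_t)u * n + v] && adj[(size_t)v * n + u];
      cnt[mut ? 2 : 1] += (double)(n - S - 2);
      for (int w : uni) {
        mark[w] = 0;
        if (v < w || (u < w && w < v &&
                      !(adj[(size_t)u * n + w] || adj[(size_t)w * n + u]))) {
          int code = (adj[(size_t)u * n + v] ? 1 : 0) |
                     (adj[(size_t)v * n + u] ? 2 : 0) |
                     (adj[(size_t)u * n + w] ? 4 : 0) |
                     (adj[(size_t)w * n + u] ? 8 : 0) |
                     (adj[(size_t)v * n + w] ? 16 : 0) |
                     (adj[(size_t)w * n + v] ? 32 : 0);
          cnt[TRI_TYPE[code]] += 1.0;
        }
      }
    }
  }
  double total = (double)n * (n - 1) * (n - 2) / 6.0;
  double s = 0;
  for (int i = 1; i < 16; ++i) s += cnt[i];
  cnt[0] = total - s;
}

// [[Rcpp::export]]
NumericVector triad_census16_cpp(IntegerVector from, IntegerVector to, int n) {
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  for (size_t k = 0; k < f.size(); ++k) {
    if (f[k] < 0 || f[k] >= n || t[k] < 0 || t[k] >= n)
      stop("edge endpoint out of range");
    if (f[k] == t[k]) stop("self-loops are not allowed");
  }
  NumericVector out(16);
  census16_core(n, f, t, REAL(out));
  return out;
}

// ---------------------------------------------------------------------------
// Curveball randomisation. Rows are consumers holding sorted resource sets;
// one trade exchanges a random subset of two rows' exclusive elements.
// Elements equal to the other row's owner are never traded (keeps the web
// free of self-loops while preserving all margins).
// ---------------------------------------------------------------------------

typedef std::vector<std::vector<int>> Rows;

static void one_trade(Rows& rows, const std::vector<int>& owners) {
  int R = (int)rows.size();
  if (R < 2) return;
  int a = (int)(unif_rand() * R); if (a >= R) a = R - 1;
  int b = (int)(unif_rand() * (R - 1)); if (b >= R - 1) b = R - 2;
  if (b >= a) ++b;

  const std::vector<int>& ra = rows[a];
  const std::vector<int>& rb = rows[b];
  std::vector<int> shared, fixed_a, fixed_b, sa, sb;
  size_t i = 0, j = 0;
  while (i < ra.size() && j < rb.size()) {
    if (ra[i] == rb[j]) { shared.push_back(ra[i]); ++i; ++j; }
    else if (ra[i] < rb[j]) {
      (ra[i] == owners[b] ? fixed_a : sa).push_back(ra[i]); ++i;
    } else {
      (rb[j] == owners[a] ? fixed_b : sb).push_back(rb[j]); ++j;
    }
  }
  for (; i < ra.size(); ++i) (ra[i] == owners[b] ? fixed_a : sa).push_back(ra[i]);
  for (; j < rb.size(); ++j) (rb[j] == owners[a] ? fixed_b : sb).push_back(rb[j]);

  if (sa.empty() || sb.empty()) return;
  size_t na = sa.size();
  std::vector<int> pool(sa);
  pool.insert(pool.end(), sb.begin(), sb.end());
  for (size_t k = pool.size() - 1; k > 0; --k) {
    size_t r = (size_t)(unif_rand() * (k + 1)); if (r > k) r = k;
    std::swap(pool[k], pool[r]);
  }
  std::vector<int> new_a(shared), new_b(shared);
  new_a.insert(new_a.end(), fixed_a.begin(), fixed_a.end());
  new_b.insert(new_b.end(), fixed_b.begin(), fixed_b.end());
  new_a.insert(new_a.end(), pool.begin(), pool.begin() + na);
  new_b.insert(new_b.end(), pool.begin() + na, pool.end());
  std::sort(new_a.begin(), new_a.end());
  std::sort(new_b.begin(), new_b.end());
  rows[a] = new_a;
  rows[b] = new_b;
}

static void edges_to_rows(const std::vector<int>& from, const std::vector<int>& to,
                          int n, Rows& rows, std::vector<int>& owners) {
  std::vector<std::vector<int>> res(n);
  for (size_t k = 0; k < from.size(); ++k) res[to[k]].push_back(from[k]);
  rows.clear(); owners.clear();
  for (int v = 0; v < n; ++v) {
    if (!res[v].empty()) {
      std::sort(res[v].begin(), res[v].end());
      rows.push_back(res[v]);
      owners.push_back(v);
    }
  }
}

static void rows_to_edges(const Rows& rows, const std::vector<int>& owners,
                          std::vector<int>& from, std::vector<int>& to) {
  from.clear(); to.clear();
  for (size_t r = 0; r < rows.size(); ++r)
    for (int s : rows[r]) { from.push_back(s); to.push_back(owners[r]); }
}

// [[Rcpp::export]]
List curveball_rewire_cpp(IntegerVector from, IntegerVector to, int n,
                          int n_trades) {
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  Rows rows; std::vector<int> owners;
  edges_to_rows(f, t, n, rows, owners);
  for (int k = 0; k < n_trades; ++k) one_trade(rows, owners);
  std::vector<int> nf, nt;
  rows_to_edges(rows, owners, nf, nt);
  return List::create(_["from"] = wrap(nf), _["to"] = wrap(nt));
}

// [[Rcpp::export]]
NumericMatrix ensemble_census_cpp(IntegerVector from, IntegerVector to, int n,
                                  int R, int n_trades) {
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  Rows rows0; std::vector<int> owners;
  edges_to_rows(f, t, n, rows0, owners);
  NumericMatrix out(R, 16);
  std::vector<int> nf, nt;
  double cnt[16];
  for (int r = 0; r < R; ++r) {
    Rows rows(rows0);
    for (int k = 0; k < n_trades; ++k) one_trade(rows, owners);
    rows_to_edges(rows, owners, nf, nt);
    census16_core(n, nf, nt, cnt);
    for (int i = 0; i < 16; ++i) out(r, i) = cnt[i];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused per-web profile: for each sampling iteration draw a binary web from
// the probability matrix support, census it (full web and consumer sub-web),
// and census an independent Curveball ensemble for each scope. Isolated
// nodes need no explicit pruning here: they carry no edges, cannot receive
// any under margin-preserving rewiring, and do not contribute to connected
// triads.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List web_profile_cpp(IntegerVector from, IntegerVector to, NumericVector prob,
                     int n, LogicalVector basal, int iterations, int R,
                     int trades_factor) {
  size_t m = from.size();
  NumericMatrix obs_full(iterations, 16), obs_sub(iterations, 16);
  NumericMatrix mu_full(iterations, 16), sd_full(iterations, 16);
  NumericMatrix mu_sub(iterations, 16), sd_sub(iterations, 16);
  IntegerVector n_edges_full(iterations), n_edges_sub(iterations);

  std::vector<int> kf, kt, sf, st, nf, nt;
  double cnt[16];

  for (int it = 0; it < iterations; ++it) {
    kf.clear(); kt.clear();
    for (size_t k = 0; k < m; ++k)
      if (unif_rand() < prob[k]) { kf.push_back(from[k]); kt.push_back(to[k]); }
    sf.clear(); st.clear();
    for (size_t k = 0; k < kf.size(); ++k)
      if (!basal[kf[k]] && !basal[kt[k]]) { sf.push_back(kf[k]); st.push_back(kt[k]); }
    n_edges_full[it] = (int)kf.size();
    n_edges_sub[it] = (int)sf.size();

    for (int scope = 0; scope < 2; ++scope) {
      const std::vector<int>& ef = scope == 0 ? kf : sf;
      const std::vector<int>& et = scope == 0 ? kt : st;
      NumericMatrix& obs = scope == 0 ? obs_full : obs_sub;
      NumericMatrix& mu = scope == 0 ? mu_full : mu_sub;
      NumericMatrix& sd = scope == 0 ? sd_full : sd_sub;

      census16_core(n, ef, et, cnt);
      for (int i = 0; i < 16; ++i) obs(it, i) = cnt[i];

      Rows rows0; std::vector<int> owners;
      edges_to_rows(ef, et, n, rows0, owners);
      int n_trades = trades_factor * (int)rows0.size();
      double s1[16] = {0}, s2[16] = {0};
      for (int r = 0; r < R; ++r) {
        Rows rows(rows0);
        for (int k = 0; k < n_trades; ++k) one_trade(rows, owners);
        rows_to_edges(rows, owners, nf, nt);
        census16_core(n, nf, nt, cnt);
        for (int i = 0; i < 16; ++i) { s1[i] += cnt[i]; s2[i] += cnt[i] * cnt[i]; }
      }
      for (int i = 0; i < 16; ++i) {
        double mean = s1[i] / R;
        double var = R > 1 ? (s2[i] - R * mean * mean) / (R - 1) : 0.0;
        if (var < 0) var = 0;
        mu(it, i) = mean;
        sd(it, i) = std::sqrt(var);
      }
    }
  }
  return List::create(
    _["obs_full"] = obs_full, _["obs_sub"] = obs_sub,
    _["mu_full"] = mu_full, _["sd_full"] = sd_full,
    _["mu_sub"] = mu_sub, _["sd_sub"] = sd_sub,
    _["n_edges_full"] = n_edges_full, _["n_edges_sub"] = n_edges_sub);
}
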