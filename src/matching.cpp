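// Maximum-weight matching in a general graph (Blossom algorithm).
//
// Primal-dual O(n^3) implementation over a dense edge table with integer
// weights (callers scale real scores to integers; integrality keeps every
// dual adjustment exact, so no floating-point tolerances are needed).
// Vertices may stay unmatched: the search stops as soon as the smallest
// dual of an outer vertex would drop below zero, which yields a maximum
// *weight* (not maximum cardinality, not perfect) matching. Edges with
// non-positive weight are treated as absent.
//
// Validated in the test suite against exhaustive enumeration on small
// graphs and against brute-force structure enumeration in the decoder.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cstring>

typedef long long ll;
static const ll LL_INF = (ll)1e18;

namespace {

struct Edge {
  int u, v;
  ll w;
};

class Blossom {
public:
  int n;                 // original vertices 1..n
  int n_x;               // including active blossom ids (n+1 ..)
  int N;                 // array capacity
  std::vector<std::vector<Edge> > g;
  std::vector<ll> lab;
  std::vector<int> match_, slack_, st, pa, S, vis;
  std::vector<std::vector<int> > flower, flower_from;
  std::deque<int> q;
  int vis_t;

  explicit Blossom(int n_) : n(n_) {
    N = 2 * n + 2;
    g.assign(N, std::vector<Edge>(N));
    for (int u = 0; u < N; ++u)
      for (int v = 0; v < N; ++v)
        g[u][v] = (Edge){u, v, 0};
    lab.assign(N, 0);
    match_.assign(N, 0);
    slack_.assign(N, 0);
    st.assign(N, 0);
    pa.assign(N, 0);
    S.assign(N, -1);
    vis.assign(N, 0);
    flower.assign(N, std::vector<int>());
    flower_from.assign(N, std::vector<int>(N, 0));
    n_x = n;
    vis_t = 0;
  }

  ll e_delta(const Edge &e) const {
    return lab[e.u] + lab[e.v] - g[e.u][e.v].w * 2;
  }

  void update_slack(int u, int x) {
    if (!slack_[x] || e_delta(g[u][x]) < e_delta(g[slack_[x]][x]))
      slack_[x] = u;
  }

  void set_slack(int x) {
    slack_[x] = 0;
    for (int u = 1; u <= n; ++u)
      if (g[u][x].w > 0 && st[u] != x && S[st[u]] == 0)
        update_slack(u, x);
  }

  void q_push(int x) {
    if (x <= n) {
      q.push_back(x);
    } else {
      for (size_t i = 0; i < flower[x].size(); ++i) q_push(flower[x][i]);
    }
  }

  void set_st(int x, int b) {
    st[x] = b;
    if (x > n)
      for (size_t i = 0; i < flower[x].size(); ++i) set_st(flower[x][i], b);
  }

  int get_pr(int b, int xr) {
    int pr = (int)(std::find(flower[b].begin(), flower[b].end(), xr) -
                   flower[b].begin());
    if (pr % 2 == 1) {  // path of odd parity: flip traversal direction
      std::reverse(flower[b].begin() + 1, flower[b].end());
      return (int)flower[b].size() - pr;
    }
    return pr;
  }

  void set_match(int u, int v) {
    match_[u] = g[u][v].v;
    if (u > n) {
      Edge &e = g[u][v];
      int xr = flower_from[u][e.u];
      int pr = get_pr(u, xr);
      for (int i = 0; i < pr; ++i)
        set_match(flower[u][i], flower[u][i ^ 1]);
      set_match(xr, v);
      std::rotate(flower[u].begin(), flower[u].begin() + pr, flower[u].end());
    }
  }

  void augment(int u, int v) {
    for (;;) {
      int xnv = st[match_[u]];
      set_match(u, v);
      if (!xnv) return;
      set_match(xnv, st[pa[xnv]]);
      u = st[pa[xnv]];
      v = xnv;
    }
  }

  int get_lca(int u, int v) {
    for (++vis_t; u || v; std::swap(u, v)) {
      if (!u) continue;
      if (vis[u] == vis_t) return u;
      vis[u] = vis_t;
      u = st[match_[u]];
      if (u) u = st[pa[u]];
    }
    return 0;
  }

  void add_blossom(int u, int lca, int v) {
    int b = n + 1;
    while (b <= n_x && st[b]) ++b;
    if (b > n_x) ++n_x;
    lab[b] = 0;
    S[b] = 0;
    match_[b] = match_[lca];
    flower[b].clear();
    flower[b].push_back(lca);
    for (int x = u, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match_[x]]);
      q_push(y);
    }
    std::reverse(flower[b].begin() + 1, flower[b].end());
    for (int x = v, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match_[x]]);
      q_push(y);
    }
    set_st(b, b);
    for (int x = 1; x <= n_x; ++x) g[b][x].w = g[x][b].w = 0;
    for (int x = 1; x <= n; ++x) flower_from[b][x] = 0;
    for (size_t i = 0; i < flower[b].size(); ++i) {
      int xs = flower[b][i];
      for (int x = 1; x <= n_x; ++x)
        if (g[xs][x].w > 0 &&
            (g[b][x].w == 0 || e_delta(g[xs][x]) < e_delta(g[b][x]))) {
          g[b][x] = g[xs][x];
          g[x][b] = g[x][xs];
        }
      for (int x = 1; x <= n; ++x)
        if (flower_from[xs][x]) flower_from[b][x] = xs;
    }
    set_slack(b);
  }

  void expand_blossom(int b) {  // S[b] == 1, lab[b] == 0
    for (size_t i = 0; i < flower[b].size(); ++i)
      set_st(flower[b][i], flower[b][i]);
    int xr = flower_from[b][g[b][pa[b]].u];
    int pr = get_pr(b, xr);
    for (int i = 0; i < pr; i += 2) {
      int xs = flower[b][i], xns = flower[b][i + 1];
      pa[xs] = g[xns][xs].u;
      S[xs] = 1;
      S[xns] = 0;
      slack_[xs] = 0;
      set_slack(xns);
      q_push(xns);
    }
    S[xr] = 1;
    pa[xr] = pa[b];
    for (size_t i = pr + 1; i < flower[b].size(); ++i) {
      S[flower[b][i]] = -1;
      set_slack(flower[b][i]);
    }
    st[b] = 0;
  }

  bool on_found_edge(const Edge &e) {
    int u = st[e.u], v = st[e.v];
    if (S[v] == -1) {
      pa[v] = e.u;
      S[v] = 1;
      int nu = st[match_[v]];
      slack_[v] = slack_[nu] = 0;
      S[nu] = 0;
      q_push(nu);
    } else if (S[v] == 0) {
      int lca = get_lca(u, v);
      if (!lca) {
        augment(u, v);
        augment(v, u);
        return true;
      }
      add_blossom(u, lca, v);
    }
    return false;
  }

  bool matching() {
    std::fill(S.begin() + 1, S.begin() + n_x + 1, -1);
    std::fill(slack_.begin() + 1, slack_.begin() + n_x + 1, 0);
    q.clear();
    for (int x = 1; x <= n_x; ++x)
      if (st[x] == x && !match_[x]) {
        pa[x] = 0;
        S[x] = 0;
        q_push(x);
      }
    if (q.empty()) return false;
    for (;;) {
      while (!q.empty()) {
        int u = q.front();
        q.pop_front();
        if (S[st[u]] == 1) continue;
        for (int v = 1; v <= n; ++v)
          if (g[u][v].w > 0 && st[u] != st[v]) {
            if (e_delta(g[u][v]) == 0) {
              if (on_found_edge(g[u][v])) return true;
            } else {
              update_slack(u, st[v]);
            }
          }
      }
      ll d = LL_INF;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1) d = std::min(d, lab[b] / 2);
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack_[x]) {
          if (S[x] == -1)
            d = std::min(d, e_delta(g[slack_[x]][x]));
          else if (S[x] == 0)
            d = std::min(d, e_delta(g[slack_[x]][x]) / 2);
        }
      for (int u = 1; u <= n; ++u) {
        if (S[st[u]] == 0) {
          if (lab[u] <= d) return false;  // an outer dual would hit zero
          lab[u] -= d;
        } else if (S[st[u]] == 1) {
          lab[u] += d;
        }
      }
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b) {
          if (S[b] == 0)
            lab[b] += d * 2;
          else if (S[b] == 1)
            lab[b] -= d * 2;
        }
      q.clear();
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack_[x] && st[slack_[x]] != x &&
            e_delta(g[slack_[x]][x]) == 0)
          if (on_found_edge(g[slack_[x]][x])) return true;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1 && lab[b] == 0) expand_blossom(b);
    }
    return false;
  }

  void add_edge(int u, int v, ll w) {
    if (w > g[u][v].w) g[u][v].w = g[v][u].w = w;
  }

  void solve() {
    ll w_max = 0;
    for (int u = 1; u <= n; ++u) {
      st[u] = u;
      flower_from[u][u] = u;
      for (int v = 1; v <= n; ++v) w_max = std::max(w_max, g[u][v].w);
    }
    for (int u = 1; u <= n; ++u) lab[u] = w_max;
    while (matching()) {
    }
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_max_weight_matching(int n,
                                            Rcpp::IntegerVector edge_u,
                                            Rcpp::IntegerVector edge_v,
                                            Rcpp::NumericVector edge_w) {
  if (n < 1) Rcpp::stop("n must be >= 1");
  if (edge_u.size() != edge_v.size() || edge_u.size() != edge_w.size())
    Rcpp::stop("edge vectors must have equal length");
  Blossom bl(n);
  for (R_xlen_t k = 0; k < edge_u.size(); ++k) {
    int u = edge_u[k], v = edge_v[k];
    if (u < 1 || u > n || v < 1 || v > n)
      Rcpp::stop("edge endpoint out of range");
    if (u == v) Rcpp::stop("self-loops are not supported");
    ll w = (ll)std::llround(edge_w[k]);
    if (w > 0) bl.add_edge(u, v, w);
  }
  bl.solve();
  Rcpp::IntegerVector match(n);
  for (int u = 1; u <= n; ++u) {
    int m = bl.match_[u];
    // report a partner only if the matched edge carries positive weight
    match[u - 1] = (m > 0 && bl.g[u][m].w > 0) ? m : 0;
  }
  return match;
}
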