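// Stochastic core: rigid-body diffusion, contact-gated fusion and
// volume-conditioned fission of indivisible particles on a periodic 2D box.
// All randomness comes from R's RNG so set.seed() fully determines a run.
#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
#include <climits>
#include <algorithm>
using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent, rnk;
  explicit UnionFind(int n) : parent(n), rnk(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (rnk[a] < rnk[b]) std::swap(a, b);
    parent[b] = a;
    if (rnk[a] == rnk[b]) rnk[a]++;
  }
};

// minimum-image signed separation on a periodic axis of length L
inline double mimg(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

inline double wrapc(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;   // guard against floating-point roundup
  if (x < 0.0) x = 0.0;
  return x;
}

inline double step_prob(double rate, double dt, bool exact) {
  double p = exact ? 1.0 - std::exp(-rate * dt) : rate * dt;
  return p > 1.0 ? 1.0 : p;
}

// uniform integer in [0, k)
inline int runif_int(int k) {
  int i = static_cast<int>(unif_rand() * k);
  return i >= k ? k - 1 : i;
}

const int EV_FISSION = 1;
const int EV_FUSION  = 2;

const int BIAS_RANDOM   = 0;
const int BIAS_BOUNDARY = 1;
const int BIAS_ADJACENT = 2;

struct Sim {
  int n;
  std::vector<double> px, py;
  std::vector<char> marked;
  std::vector<std::array<int, 2>> edges;   // 0-based particle ids
  double L, rp, uv, dt, d_floor;
  double bias_fraction;
  int bias_mode;
  bool exact_prob;
  bool record_events;
  // laws[cond][kind][coef]; cond: 0 component without mark, 1 with mark;
  // kind: 0 fission, 1 fusion, 2 diffusion; coef: 0 slope, 1 intercept
  double laws[2][3][2];
  double tnow;

  std::vector<double> ev;    // rows of 8
  std::vector<double> snap;  // rows of 6

  // scratch per step
  std::vector<int> root;
  std::vector<int> sz;        // indexed by root id
  std::vector<char> hasmark;  // indexed by root id

  void comps() {
    UnionFind uf(n);
    for (const auto& e : edges) uf.unite(e[0], e[1]);
    root.assign(n, 0);
    sz.assign(n, 0);
    hasmark.assign(n, 0);
    for (int i = 0; i < n; ++i) root[i] = uf.find(i);
    for (int i = 0; i < n; ++i) {
      sz[root[i]]++;
      if (marked[i]) hasmark[root[i]] = 1;
    }
  }

  // clamped linear law at the 3D-equivalent volume of an n-particle network
  double rate_of(int cond, int kind, int nodes) const {
    double v = nodes * uv;
    double r = laws[cond][kind][0] * v + laws[cond][kind][1];
    return r > 0.0 ? r : 0.0;
  }

  void push_event(int type, int a, int b, double before,
                  double after_a, double after_b, double has_dump) {
    ev.push_back(tnow); ev.push_back(type);
    ev.push_back(a + 1); ev.push_back(b + 1);
    ev.push_back(before); ev.push_back(after_a); ev.push_back(after_b);
    ev.push_back(has_dump);
  }

  void diffuse() {
    comps();
    std::vector<double> mx(n, 0.0), my(n, 0.0);
    std::vector<char> drawn(n, 0);
    for (int i = 0; i < n; ++i) {
      int r = root[i];
      if (!drawn[r]) {
        double D = laws[hasmark[r]][2][0] * (sz[r] * uv) + laws[hasmark[r]][2][1];
        if (D < d_floor) D = d_floor;
        double step = std::sqrt(4.0 * D * dt);
        double th = unif_rand() * 2.0 * M_PI;
        mx[r] = step * std::cos(th);
        my[r] = step * std::sin(th);
        drawn[r] = 1;
      }
    }
    for (int i = 0; i < n; ++i) {
      px[i] = wrapc(px[i] + mx[root[i]], L);
      py[i] = wrapc(py[i] + my[root[i]], L);
    }
  }

  // force_p < 0 means use the rate laws
  void fusions(double force_p) {
    comps();
    const double reach = 2.0 * rp;
    const double reach2 = reach * reach;
    // closest particle pair per pair of distinct components in contact
    std::map<std::pair<int, int>, std::array<double, 3>> best;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (root[i] == root[j]) continue;
        double dx = mimg(px[i] - px[j], L);
        if (std::fabs(dx) > reach) continue;
        double dy = mimg(py[i] - py[j], L);
        if (std::fabs(dy) > reach) continue;
        double d2 = dx * dx + dy * dy;
        if (d2 > reach2) continue;
        std::pair<int, int> key = std::minmax(root[i], root[j]);
        auto it = best.find(key);
        if (it == best.end() || d2 < it->second[0])
          best[key] = {d2, static_cast<double>(i), static_cast<double>(j)};
      }
    }
    if (best.empty()) return;
    std::vector<std::array<double, 3>> cand;
    cand.reserve(best.size());
    for (const auto& kv : best) cand.push_back(kv.second);
    for (int k = static_cast<int>(cand.size()) - 1; k > 0; --k)
      std::swap(cand[k], cand[runif_int(k + 1)]);

    UnionFind uf(n);
    for (const auto& e : edges) uf.unite(e[0], e[1]);
    std::vector<int> s2(n, 0);
    std::vector<char> m2(n, 0);
    for (int i = 0; i < n; ++i) {
      s2[uf.find(i)]++;
      if (marked[i]) m2[uf.find(i)] = 1;
    }
    for (const auto& c : cand) {
      int a = static_cast<int>(c[1]), b = static_cast<int>(c[2]);
      int ra = uf.find(a), rb = uf.find(b);
      if (ra == rb) continue;  // merged earlier this step
      double p;
      if (force_p >= 0.0) {
        p = force_p;
      } else {
        // symmetric pair rate: mean of each partner's own fusion law
        double rA = rate_of(m2[ra], 1, s2[ra]);
        double rB = rate_of(m2[rb], 1, s2[rb]);
        p = step_prob(0.5 * (rA + rB), dt, exact_prob);
      }
      if (unif_rand() < p) {
        int merged = s2[ra] + s2[rb];
        char mk = m2[ra] | m2[rb];
        edges.push_back({a, b});
        uf.unite(a, b);
        int rn = uf.find(a);
        s2[rn] = merged;
        m2[rn] = mk;
        if (record_events)
          push_event(EV_FUSION, a, b, NA_REAL, merged, merged, mk ? 1.0 : 0.0);
      }
    }
  }

  void fissions(double force_p) {
    comps();
    std::vector<int> todo;
    for (int i = 0; i < n; ++i)
      if (root[i] == i && sz[i] > 1) todo.push_back(i);
    if (todo.empty()) return;
    std::vector<int> memb = root;  // membership before any split this step

    for (int r : todo) {
      double p = (force_p >= 0.0)
        ? force_p
        : step_prob(rate_of(hasmark[r], 0, sz[r]), dt, exact_prob);
      if (unif_rand() >= p) continue;

      std::vector<int> eidx;
      for (int k = 0; k < static_cast<int>(edges.size()); ++k)
        if (memb[edges[k][0]] == r) eidx.push_back(k);
      if (eidx.empty()) continue;

      int chosen = -1;
      bool biased_draw = bias_mode != BIAS_RANDOM && unif_rand() < bias_fraction;
      if (biased_draw) {
        std::vector<int> elig;
        if (bias_mode == BIAS_BOUNDARY) {
          for (int k : eidx)
            if (marked[edges[k][0]] != marked[edges[k][1]]) elig.push_back(k);
        } else {  // one hop outside the marked set
          std::vector<std::vector<int>> adj(n);
          for (int k : eidx) {
            adj[edges[k][0]].push_back(edges[k][1]);
            adj[edges[k][1]].push_back(edges[k][0]);
          }
          std::vector<int> dist(n, INT_MAX);
          std::vector<int> q;
          for (int i = 0; i < n; ++i)
            if (memb[i] == r && marked[i]) { dist[i] = 0; q.push_back(i); }
          for (size_t h = 0; h < q.size(); ++h) {
            int u = q[h];
            for (int v : adj[u])
              if (dist[v] == INT_MAX) { dist[v] = dist[u] + 1; q.push_back(v); }
          }
          for (int k : eidx) {
            int da = dist[edges[k][0]], db = dist[edges[k][1]];
            if ((da == 1 && db == 2) || (da == 2 && db == 1)) elig.push_back(k);
          }
        }
        if (!elig.empty()) {
          chosen = elig[runif_int(static_cast<int>(elig.size()))];
        } else if (!hasmark[r]) {
          // bias is undefined away from marks: unmarked networks split anywhere
          chosen = eidx[runif_int(static_cast<int>(eidx.size()))];
        } else {
          continue;  // marked network with no eligible boundary: no fission
        }
      } else {
        chosen = eidx[runif_int(static_cast<int>(eidx.size()))];
      }

      int a = edges[chosen][0], b = edges[chosen][1];
      int before = sz[r];
      char had = hasmark[r];
      edges[chosen] = edges.back();
      edges.pop_back();

      // fragment containing a, over the remaining edges of this component
      std::vector<std::vector<int>> adj(n);
      for (const auto& e : edges)
        if (memb[e[0]] == r) {
          adj[e[0]].push_back(e[1]);
          adj[e[1]].push_back(e[0]);
        }
      std::vector<char> seen(n, 0);
      std::vector<int> q{a};
      seen[a] = 1;
      int szA = 0;
      for (size_t h = 0; h < q.size(); ++h) {
        int u = q[h];
        szA++;
        for (int v : adj[u]) if (!seen[v]) { seen[v] = 1; q.push_back(v); }
      }
      if (record_events)
        push_event(EV_FISSION, a, b, before, szA, before - szA, had ? 1.0 : 0.0);
    }
  }

  void snapshot() {
    comps();
    std::vector<int> lab(n, INT_MAX);
    for (int i = 0; i < n; ++i) lab[root[i]] = std::min(lab[root[i]], i);
    for (int i = 0; i < n; ++i) {
      snap.push_back(tnow);
      snap.push_back(i + 1);
      snap.push_back(px[i]);
      snap.push_back(py[i]);
      snap.push_back(marked[i] ? 1.0 : 0.0);
      snap.push_back(lab[root[i]] + 1);
    }
  }
};

Sim make_sim(NumericMatrix pos, IntegerMatrix edges, IntegerVector marked,
             double L, double r_particle, double unit_vol, double dt,
             NumericMatrix laws_unmarked, NumericMatrix laws_marked,
             double bias_fraction, int bias_mode, bool exact_prob,
             bool record_events, double t0, double d_floor) {
  Sim s;
  s.n = pos.nrow();
  s.px.resize(s.n); s.py.resize(s.n); s.marked.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.px[i] = pos(i, 0);
    s.py[i] = pos(i, 1);
    s.marked[i] = marked[i] ? 1 : 0;
  }
  s.edges.reserve(edges.nrow() + s.n);
  for (int k = 0; k < edges.nrow(); ++k)
    s.edges.push_back({edges(k, 0) - 1, edges(k, 1) - 1});
  s.L = L; s.rp = r_particle; s.uv = unit_vol; s.dt = dt;
  s.d_floor = d_floor;
  s.bias_fraction = bias_fraction;
  s.bias_mode = bias_mode;
  s.exact_prob = exact_prob;
  s.record_events = record_events;
  for (int k = 0; k < 3; ++k) {
    s.laws[0][k][0] = laws_unmarked(k, 0);
    s.laws[0][k][1] = laws_unmarked(k, 1);
    s.laws[1][k][0] = laws_marked(k, 0);
    s.laws[1][k][1] = laws_marked(k, 1);
  }
  s.tnow = t0;
  return s;
}

NumericMatrix pos_out(const Sim& s) {
  NumericMatrix out(s.n, 2);
  for (int i = 0; i < s.n; ++i) { out(i, 0) = s.px[i]; out(i, 1) = s.py[i]; }
  return out;
}

IntegerMatrix edges_out(const Sim& s) {
  IntegerMatrix out(static_cast<int>(s.edges.size()), 2);
  for (int k = 0; k < static_cast<int>(s.edges.size()); ++k) {
    out(k, 0) = s.edges[k][0] + 1;
    out(k, 1) = s.edges[k][1] + 1;
  }
  return out;
}

NumericMatrix rows_out(const std::vector<double>& v, int ncol,
                       CharacterVector names) {
  int nr = static_cast<int>(v.size()) / ncol;
  NumericMatrix out(nr, ncol);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < ncol; ++c)
      out(r, c) = v[r * ncol + c];
  colnames(out) = names;
  return out;
}

CharacterVector event_cols() {
  return CharacterVector::create("time_s", "event_type", "particle_a",
    "particle_b", "comp_size_before", "comp_size_after_a",
    "comp_size_after_b", "comp_has_dump");
}

CharacterVector snap_cols() {
  return CharacterVector::create("time_s", "particle_id", "x_um", "y_um",
    "dump_marked", "component_id");
}

}  // namespace

// [[Rcpp::export]]
List cpp_run(NumericMatrix pos, IntegerMatrix edges, IntegerVector marked,
             double L, double r_particle, double unit_vol, double dt,
             int n_steps, NumericMatrix laws_unmarked, NumericMatrix laws_marked,
             double bias_fraction, int bias_mode, bool exact_prob,
             int snap_every, bool record_events, bool snap_on_event,
             double t0, double d_floor) {
  Sim s = make_sim(pos, edges, marked, L, r_particle, unit_vol, dt,
                   laws_unmarked, laws_marked, bias_fraction, bias_mode,
                   exact_prob, record_events, t0, d_floor);
  if (snap_every > 0) s.snapshot();
  for (int step = 1; step <= n_steps; ++step) {
    s.tnow = t0 + step * dt;
    size_t ev0 = s.ev.size();
    s.diffuse();
    s.fusions(-1.0);
    s.fissions(-1.0);
    if (snap_every > 0) {
      if (step % snap_every == 0) s.snapshot();
      else if (snap_on_event && s.ev.size() > ev0) s.snapshot();
    }
  }
  return List::create(
    _["pos"] = pos_out(s),
    _["edges"] = edges_out(s),
    _["events"] = rows_out(s.ev, 8, event_cols()),
    _["snapshots"] = rows_out(s.snap, 6, snap_cols()),
    _["time"] = s.tnow);
}

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix pos, IntegerMatrix edges,
                          IntegerVector marked, double L, double unit_vol,
                          double dt, NumericMatrix laws_unmarked,
                          NumericMatrix laws_marked, double d_floor) {
  Sim s = make_sim(pos, edges, marked, L, 0.0, unit_vol, dt,
                   laws_unmarked, laws_marked, 0.0, BIAS_RANDOM, false,
                   false, 0.0, d_floor);
  s.diffuse();
  return pos_out(s);
}

// [[Rcpp::export]]
List cpp_fusions(NumericMatrix pos, IntegerMatrix edges, IntegerVector marked,
                 double L, double r_particle, double unit_vol, double dt,
                 NumericMatrix laws_unmarked, NumericMatrix laws_marked,
                 bool exact_prob, double force_p, double t0) {
  Sim s = make_sim(pos, edges, marked, L, r_particle, unit_vol, dt,
                   laws_unmarked, laws_marked, 0.0, BIAS_RANDOM, exact_prob,
                   true, t0, 1e-12);
  s.fusions(force_p);
  return List::create(_["edges"] = edges_out(s),
                      _["events"] = rows_out(s.ev, 8, event_cols()));
}

// [[Rcpp::export]]
List cpp_fissions(NumericMatrix pos, IntegerMatrix edges, IntegerVector marked,
                  double unit_vol, double dt, NumericMatrix laws_unmarked,
                  NumericMatrix laws_marked, double bias_fraction,
                  int bias_mode, bool exact_prob, double force_p, double t0) {
  Sim s = make_sim(pos, edges, marked, 1.0, 0.0, unit_vol, dt,
                   laws_unmarked, laws_marked, bias_fraction, bias_mode,
                   exact_prob, true, t0, 1e-12);
  s.fissions(force_p);
  return List::create(_["edges"] = edges_out(s),
                      _["events"] = rows_out(s.ev, 8, event_cols()));
}
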