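#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

double greedy_peak_q(const int* adj, int n, std::vector<int>* part);

// Degree-preserving randomization of a simple undirected graph given as a
// symmetric 0/1 adjacency matrix.  A "checkerboard" move picks two edges
// (a,b), (c,d) and rewires them to (a,c), (b,d) (orientation randomized),
// which on the symmetric adjacency is a 2x2 swap mirrored across the
// diagonal: row and column sums (= degrees) are invariant.  Moves creating
// self-loops or multi-edges are rejected, so the chain walks the set of
// simple graphs with the given degree sequence; the proposal is symmetric,
// hence the stationary distribution is uniform on that set.
// All randomness comes from R's RNG (set.seed() controls everything).

namespace {

inline int ri(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

struct EdgeGraph {
  int n;
  std::vector<int> ea, eb;          // edge endpoints
  std::vector<char> A;              // n*n adjacency

  char at(int i, int j) const { return A[(size_t)i * n + j]; }
  void set(int i, int j, char v) {
    A[(size_t)i * n + j] = v; A[(size_t)j * n + i] = v;
  }

  void from_matrix(const int* adj, int nn) {
    n = nn;
    A.assign((size_t)n * n, 0);
    ea.clear(); eb.clear();
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < j; ++i)
        if (adj[(size_t)j * n + i] != 0) {
          set(i, j, 1);
          ea.push_back(i);
          eb.push_back(j);
        }
  }

  bool try_swap() {
    const int ne = (int)ea.size();
    if (ne < 2) return false;
    int e1 = ri(ne), e2 = ri(ne);
    if (e1 == e2) return false;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposed new edges: (a,c) and (b,d)
    if (a == c || b == d) return false;           // loop
    if (at(a, c) || at(b, d)) return false;       // multi-edge
    set(a, b, 0); set(c, d, 0);
    set(a, c, 1); set(b, d, 1);
    ea[e1] = a; eb[e1] = c;
    ea[e2] = b; eb[e2] = d;
    return true;
  }

  // run a chain: tswap counts trials, swap counts applied moves
  double chain(double nsteps, bool count_trials) {
    double applied = 0.0, trials = 0.0;
    const double cap = count_trials ? nsteps
                                    : std::max(1000.0 * nsteps, 1000.0);
    while (trials < cap) {
      trials += 1.0;
      if (try_swap()) applied += 1.0;
      if (!count_trials && applied >= nsteps) break;
    }
    return applied;
  }

  IntegerMatrix as_matrix() const {
    IntegerMatrix out(n, n);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        out(i, j) = at(i, j);
    return out;
  }
};

// quasiswap-style independent draw: stub matching (configuration model)
// with the exact degree sequence, repaired into a simple graph by pair
// exchanges that strictly reduce the number of offending pairs (loops and
// duplicate edges), then mixed with `nmix` trial checkerboard moves.  The
// draw depends on the input only through its degree sequence.
struct QuasiDraw {
  int n;
  std::vector<int> pa, pb;
  std::vector<int> M;               // multiplicity, diag = loop count
  long violations;

  int mult(int a, int b) const { return M[(size_t)a * n + b]; }
  void madd(int a, int b, int v) {
    M[(size_t)a * n + b] += v;
    if (a != b) M[(size_t)b * n + a] += v;
  }
  // number of bad pairs sitting on cell (a,b) under current multiplicities
  long cell_bad(int a, int b) const {
    int m = mult(a, b);
    if (a == b) return m;                  // every loop is bad
    return m > 1 ? m : 0;                  // all copies of a duplicate edge
  }

  bool build(const std::vector<int>& deg) {
    std::vector<int> stubs;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < deg[i]; ++k) stubs.push_back(i);
    for (int i = (int)stubs.size() - 1; i > 0; --i)
      std::swap(stubs[i], stubs[ri(i + 1)]);
    const int np = (int)stubs.size() / 2;
    pa.assign(np, 0); pb.assign(np, 0);
    M.assign((size_t)n * n, 0);
    for (int k = 0; k < np; ++k) {
      pa[k] = stubs[2 * k]; pb[k] = stubs[2 * k + 1];
      madd(pa[k], pb[k], 1);
    }
    violations = 0;
    for (int a = 0; a < n; ++a) {
      violations += mult(a, a);
      for (int b = a + 1; b < n; ++b)
        if (mult(a, b) > 1) violations += mult(a, b);
    }
    // exchange partners with random pairs while the exchange strictly
    // reduces the number of offending pairs
    long stuck = 0;
    const int npairs = np;
    while (violations > 0 && stuck < 500000) {
      int k = ri(npairs);
      if (cell_bad(pa[k], pb[k]) == 0) { ++stuck; continue; }
      int l = ri(npairs);
      if (l == k) { ++stuck; continue; }
      int a = pa[k], b = pb[k], c = pa[l], d = pb[l];
      if (unif_rand() < 0.5) std::swap(c, d);
      // exchange (a,b),(c,d) -> (a,d),(c,b); recount only affected cells
      int cells[4][2] = {{a, b}, {c, d}, {a, d}, {c, b}};
      auto count_cells = [&]() {
        long tot = 0;
        for (int u = 0; u < 4; ++u) {
          bool dup = false;
          for (int v = 0; v < u; ++v) {
            bool same = (cells[u][0] == cells[v][0] &&
                         cells[u][1] == cells[v][1]) ||
                        (cells[u][0] == cells[v][1] &&
                         cells[u][1] == cells[v][0]);
            if (same) { dup = true; break; }
          }
          if (!dup) tot += cell_bad(cells[u][0], cells[u][1]);
        }
        return tot;
      };
      long before = count_cells();
      madd(a, b, -1); madd(c, d, -1);
      madd(a, d, +1); madd(c, b, +1);
      long after = count_cells();
      if (after < before) {
        pa[k] = a; pb[k] = d;
        pa[l] = c; pb[l] = b;
        violations += after - before;
        stuck = 0;
      } else {
        madd(a, d, -1); madd(c, b, -1);
        madd(a, b, +1); madd(c, d, +1);
        ++stuck;
      }
    }
    return violations == 0;
  }
};

// fill an EdgeGraph with an independent exact-degree draw; falls back to the
// observed graph when the repair stalls (flagged via the return value)
bool quasi_into(EdgeGraph& g, const int* adj, int n, double nmix) {
  std::vector<int> deg(n, 0);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (adj[(size_t)j * n + i] != 0) deg[j]++;
  QuasiDraw q;
  q.n = n;
  bool ok = false;
  for (int attempt = 0; attempt < 25 && !ok; ++attempt)
    ok = q.build(deg);
  if (ok) {
    g.n = n;
    g.A.assign((size_t)n * n, 0);
    g.ea.clear(); g.eb.clear();
    for (size_t k = 0; k < q.pa.size(); ++k) {
      int a = std::min(q.pa[k], q.pb[k]), b = std::max(q.pa[k], q.pb[k]);
      g.set(a, b, 1);
      g.ea.push_back(a);
      g.eb.push_back(b);
    }
  } else {
    g.from_matrix(adj, n);
  }
  g.chain(nmix, true);
  return ok;
}

} // namespace

// swap: run until `nsteps` successful moves (classic sequential swap);
// tswap: run exactly `nsteps` trial moves, applied or not.  `swaps` in the
// result reports moves applied (a graph with no swappable checkerboard
// comes back unchanged with swaps = 0).
// [[Rcpp::export(name = ".cppSwapChain")]]
List cppSwapChain(IntegerMatrix adj, double nsteps, bool count_trials) {
  EdgeGraph g;
  g.from_matrix(adj.begin(), adj.nrow());
  double applied = g.chain(nsteps, count_trials);
  return List::create(_["adjacency"] = g.as_matrix(),
                      _["swaps"] = applied);
}

// [[Rcpp::export(name = ".cppQuasiswap")]]
List cppQuasiswap(IntegerMatrix adj, double nmix) {
  EdgeGraph g;
  bool ok = quasi_into(g, adj.begin(), adj.nrow(), nmix);
  return List::create(_["adjacency"] = g.as_matrix(),
                      _["fallback"] = !ok);
}

// full modularity null ensemble in one call: nPerm randomizations
// (method 0 = swap, 1 = tswap, 2 = quasiswap) with the peak greedy Q of
// each draw.  swap/tswap run one chain (burnIn then thin steps per sample);
// quasiswap draws are independent, each mixed with `thin` trials.
// [[Rcpp::export(name = ".cppModularityNull")]]
NumericVector cppModularityNull(IntegerMatrix adj, int nPerm, int method,
                                double burnIn, double thin) {
  const int n = adj.nrow();
  NumericVector out(nPerm);
  std::vector<int> buf((size_t)n * n);
  EdgeGraph g;
  if (method != 2) {
    g.from_matrix(adj.begin(), n);
    g.chain(burnIn, method == 1);
  }
  for (int s = 0; s < nPerm; ++s) {
    if (method == 2) quasi_into(g, adj.begin(), n, thin);
    else g.chain(thin, method == 1);
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        buf[(size_t)j * n + i] = g.at(i, j);
    out[s] = greedy_peak_q(buf.data(), n, nullptr);
  }
  return out;
}
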