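#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Fast-greedy agglomerative modularity maximisation (Clauset-Newman-Moore
// scheme).  Starts from singleton communities and at each step merges the
// connected community pair with the largest modularity gain
//   dQ = e_ab / m - 2 * (d_a / 2m) * (d_b / 2m),
// returning the vertex->community map at the Q peak.  Ties are broken by the
// lexicographically smallest community-index pair (community index = the
// smallest original vertex it contains), so the procedure is deterministic
// and needs no RNG.  Community-pair edge counts live in a flat dense array;
// candidate pairs are scanned through per-community neighbour lists, which
// keeps the scan proportional to the number of connected community pairs.

namespace {

struct Greedy {
  int n;
  double m2;                       // 2m
  std::vector<double> E;           // n*n community-pair edge counts
  std::vector<double> dsum;        // community degree sums
  std::vector<bool> alive;
  std::vector< std::vector<int> > nb;   // community neighbour lists
  std::vector<int> comm;

  double eat(int a, int b) const { return E[(size_t)a * n + b]; }
  void eset(int a, int b, double v) {
    E[(size_t)a * n + b] = v; E[(size_t)b * n + a] = v;
  }

  // run on a 0/1 adjacency given as raw int pointer (column-major nxn)
  void init(const int* adj, int nn) {
    n = nn;
    E.assign((size_t)n * n, 0.0);
    dsum.assign(n, 0.0);
    alive.assign(n, true);
    nb.assign(n, std::vector<int>());
    comm.resize(n);
    m2 = 0.0;
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i)
        if (adj[(size_t)j * n + i] != 0) {
          dsum[i] += 1.0; m2 += 1.0;
          if (i < j) {
            eset(i, j, 1.0);
            nb[i].push_back(j);
            nb[j].push_back(i);
          }
        }
    for (int i = 0; i < n; ++i) comm[i] = i;
  }

  // returns peak Q; bestComm (if non-null) receives the peak partition
  double run(std::vector<int>* bestCommOut) {
    const double m = m2 / 2.0;
    double Q = 0.0;
    for (int i = 0; i < n; ++i) Q -= (dsum[i] / m2) * (dsum[i] / m2);
    double bestQ = Q;
    std::vector<int> bestComm;
    if (bestCommOut) bestComm = comm;

    for (;;) {
      double bestDQ = 0.0;
      int ba = -1, bb = -1;
      bool found = false;
      for (int a = 0; a < n; ++a) {
        if (!alive[a]) continue;
        for (int b : nb[a]) {
          if (b <= a || !alive[b] || eat(a, b) <= 0.0) continue;
          double dq = eat(a, b) / m - 2.0 * (dsum[a] / m2) * (dsum[b] / m2);
          if (!found || dq > bestDQ + 1e-12) {
            bestDQ = dq; ba = a; bb = b; found = true;
          }
        }
      }
      if (!found) break;

      // merge bb into ba (ba < bb: community index = smallest member)
      for (int c : nb[bb]) {
        if (!alive[c] || c == ba) continue;
        double ebc = eat(bb, c);
        if (ebc <= 0.0) continue;
        if (eat(ba, c) <= 0.0) nb[ba].push_back(c), nb[c].push_back(ba);
        eset(ba, c, eat(ba, c) + ebc);
        eset(bb, c, 0.0);
      }
      eset(ba, bb, 0.0);
      dsum[ba] += dsum[bb];
      alive[bb] = false;
      nb[bb].clear();
      for (int v = 0; v < n; ++v) if (comm[v] == bb) comm[v] = ba;

      Q += bestDQ;
      if (Q > bestQ + 1e-12) {
        bestQ = Q;
        if (bestCommOut) bestComm = comm;
      }
    }
    if (bestCommOut) *bestCommOut = bestComm;
    return bestQ;
  }
};

} // namespace

double greedy_peak_q(const int* adj, int n, std::vector<int>* part) {
  Greedy g;
  g.init(adj, n);
  if (g.m2 <= 0) stop("network has no edges");
  return g.run(part);
}

// [[Rcpp::export(name = ".cppGreedyModules")]]
List cppGreedyModules(IntegerMatrix adj) {
  const int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency must be square");
  std::vector<int> part;
  double q = greedy_peak_q(adj.begin(), n, &part);
  return List::create(_["membership"] = IntegerVector(part.begin(), part.end()),
                      _["Q"] = q);
}
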