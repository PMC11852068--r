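// Greedy community searches for binary graphs: hypergeometric Surprise
// maximization and Newman modularity maximization, plus the batched
// threshold-sweep driver. Written in C++ because the 100-tier sweep scores
// hundreds of thousands of 16-node graphs per band.

#include <Rcpp.h>
#include <Rmath.h>
#include <random>
#include <vector>
#include <functional>
#include <cmath>

using namespace Rcpp;

// log upper tail P(X >= mint) of Hypergeometric(M pairs, Mint intra, m drawn)
static double logTail(int M, int Mint, int m, int mint) {
  if (mint <= 0) return 0.0;
  if (Mint <= 0) return R_NegInf;
  return R::phyper(mint - 1.0, (double)Mint, (double)(M - Mint), (double)m,
                   /*lower_tail=*/0, /*log_p=*/1);
}

// memoized S = -log10 P(X >= mint); keys are (mint, Mint), M and m fixed
struct SurpriseMemo {
  int M;
  std::vector<double> tab;
  explicit SurpriseMemo(int M_) : M(M_), tab((size_t)(M_ + 1) * (M_ + 1), -1.0) {}
  double S(int Mint, int m, int mint) {
    if (m == 0) return 0.0;
    if (mint < 0) mint = 0;
    size_t key = (size_t)mint * (M + 1) + Mint;
    double v = tab[key];
    if (v >= 0) return v;
    double s = -logTail(M, Mint, m, mint) / M_LN10;
    if (s < 0 || !std::isfinite(s)) s = (s > 0) ? s : 0;
    tab[key] = s;
    return s;
  }
};

struct Graph {
  int n, m, M;
  std::vector<int> adj;   // n*n, 0/1
  std::vector<int> deg;
  int at(int i, int j) const { return adj[(size_t)i * n + j]; }
};

static Graph buildGraph(const IntegerMatrix &A) {
  Graph g;
  g.n = A.nrow();
  g.adj.assign((size_t)g.n * g.n, 0);
  g.deg.assign(g.n, 0);
  g.m = 0;
  for (int i = 0; i < g.n; ++i)
    for (int j = 0; j < g.n; ++j)
      if (i != j && A(i, j) != 0) g.adj[(size_t)i * g.n + j] = 1;
  for (int i = 0; i < g.n; ++i) {
    for (int j = 0; j < g.n; ++j) g.deg[i] += g.at(i, j);
    g.m += g.deg[i];
  }
  g.m /= 2;
  g.M = g.n * (g.n - 1) / 2;
  return g;
}

// community bookkeeping: labels, sizes, degree sums, inter-community edge
// counts (diagonal = intra), intra-pair and intra-edge totals
struct State {
  const Graph *g;
  std::vector<int> label, csize, cdeg;
  std::vector<int> ecnt;
  int mint, Mint;
  explicit State(const Graph &gr) : g(&gr) {
    int n = gr.n;
    label.resize(n); csize.assign(n, 1); cdeg = gr.deg;
    ecnt.assign((size_t)n * n, 0);
    for (int i = 0; i < n; ++i) label[i] = i;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (gr.at(i, j)) { ecnt[(size_t)i * n + j]++; ecnt[(size_t)j * n + i]++; }
    mint = 0; Mint = 0;
  }
  int &e(int a, int b) { return ecnt[(size_t)a * g->n + b]; }
  int econst(int a, int b) const { return ecnt[(size_t)a * g->n + b]; }
  // edges from node v into community c (excluding v itself)
  int edgesTo(int v, int c) const {
    int n = g->n, cnt = 0;
    for (int u = 0; u < n; ++u)
      if (u != v && label[u] == c && g->at(v, u)) ++cnt;
    return cnt;
  }
  int emptySlot() const {
    for (int c = 0; c < g->n; ++c) if (csize[c] == 0) return c;
    return -1;
  }
  void applyMerge(int a, int b) {
    int n = g->n;
    mint += e(a, b);
    Mint += csize[a] * csize[b];
    for (int v = 0; v < n; ++v) if (label[v] == b) label[v] = a;
    for (int c = 0; c < n; ++c) {
      if (c == a || c == b) continue;
      e(a, c) += e(b, c); e(c, a) = e(a, c);
      e(b, c) = 0; e(c, b) = 0;
    }
    e(a, a) += e(b, b) + e(a, b);
    e(a, b) = 0; e(b, a) = 0; e(b, b) = 0;
    csize[a] += csize[b]; csize[b] = 0;
    cdeg[a] += cdeg[b]; cdeg[b] = 0;
  }
  void applyRelabel(int v, int c) {
    int a = label[v], n = g->n;
    int eva = edgesTo(v, a), evc = edgesTo(v, c);
    mint += evc - eva;
    Mint += csize[c] - (csize[a] - 1);
    e(a, a) -= eva; e(c, c) += evc;
    for (int d = 0; d < n; ++d) {
      if (d == a || d == c) continue;
      int evd = edgesTo(v, d);
      if (evd == 0) continue;
      e(a, d) -= evd; e(d, a) = e(a, d);
      e(c, d) += evd; e(d, c) = e(c, d);
    }
    // v's edges into a become a-c edges; its edges into c stop being a-c edges
    e(a, c) += eva - evc; e(c, a) = e(a, c);
    csize[a]--; csize[c]++;
    cdeg[a] -= g->deg[v]; cdeg[c] += g->deg[v];
    label[v] = c;
  }
};

static double modularityOf(const State &s) {
  int n = s.g->n;
  double m = s.g->m, twoM = 2.0 * s.g->m, q = 0;
  for (int c = 0; c < n; ++c) {
    if (s.csize[c] == 0) continue;
    q += s.econst(c, c) / m - (s.cdeg[c] / twoM) * (s.cdeg[c] / twoM);
  }
  return q;
}

// Best-single-move greedy: start from singletons, repeatedly apply the merge
// or single-node relabel (including detaching a node into a fresh community)
// that most increases the objective; stop when no move improves. Ties between
// equal-gain moves are broken by the seeded RNG.
// objective: 0 = Surprise (log10 units), 1 = modularity.
static std::vector<int> greedySearch(const Graph &g, int objective,
                                     std::mt19937 &rng, double *finalValue) {
  State st(g);
  SurpriseMemo memo(g.M);
  int n = g.n;
  double m = g.m, twoM = 2.0 * g.m;

  if (g.m == 0) {
    if (finalValue) *finalValue = 0.0;
    return st.label;
  }
  double cur = (objective == 0) ? memo.S(st.Mint, g.m, st.mint) : modularityOf(st);

  const double eps = 1e-12;
  struct Move { int kind, x, y; };
  for (int iter = 0; iter < 40 * n; ++iter) {
    double bestDelta = 0.0;
    std::vector<Move> best;
    auto consider = [&](double delta, int kind, int x, int y) {
      if (delta <= eps) return;
      if (best.empty() || delta > bestDelta + eps) {
        bestDelta = delta;
        best.clear();
        best.push_back({kind, x, y});
      } else if (delta >= bestDelta - eps) {
        best.push_back({kind, x, y});
      }
    };
    // merges
    for (int a = 0; a < n; ++a) {
      if (st.csize[a] == 0) continue;
      for (int b = a + 1; b < n; ++b) {
        if (st.csize[b] == 0) continue;
        double delta;
        if (objective == 0) {
          delta = memo.S(st.Mint + st.csize[a] * st.csize[b], g.m,
                         st.mint + st.e(a, b)) - cur;
        } else {
          delta = st.e(a, b) / m -
                  2.0 * st.cdeg[a] * st.cdeg[b] / (twoM * twoM);
        }
        consider(delta, 0, a, b);
      }
    }
    // single-node relabels
    int slot = st.emptySlot();
    for (int v = 0; v < n; ++v) {
      int a = st.label[v];
      int eva = st.edgesTo(v, a);
      for (int c = 0; c < n; ++c) {
        if (c == a) continue;
        bool detach = (st.csize[c] == 0);
        if (detach && (c != slot || st.csize[a] <= 1)) continue;
        int evc = detach ? 0 : st.edgesTo(v, c);
        double delta;
        if (objective == 0) {
          delta = memo.S(st.Mint + st.csize[c] - (st.csize[a] - 1), g.m,
                         st.mint + evc - eva) - cur;
        } else {
          double da = st.cdeg[a], dc = st.cdeg[c], dv = g.deg[v];
          delta = (evc - eva) / m -
                  ((dc + dv) * (dc + dv) - dc * dc +
                   (da - dv) * (da - dv) - da * da) / (twoM * twoM);
        }
        consider(delta, 1, v, c);
      }
    }
    if (best.empty()) break;
    const Move &mv = best.size() == 1 ? best[0]
                                      : best[(size_t)(rng() % best.size())];
    if (mv.kind == 0) st.applyMerge(mv.x, mv.y);
    else st.applyRelabel(mv.x, mv.y);
    cur = (objective == 0) ? memo.S(st.Mint, g.m, st.mint) : modularityOf(st);
  }
  if (objective == 1 && cur < 0) {
    // the all-in-one partition (Q = 0) dominates; fall back to it
    std::fill(st.label.begin(), st.label.end(), 0);
    cur = 0;
  }
  if (finalValue) *finalValue = cur;
  return st.label;
}

static IntegerVector contiguous(const std::vector<int> &label) {
  int n = (int)label.size();
  std::vector<int> map(n, -1);
  IntegerVector out(n);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (map[label[i]] < 0) map[label[i]] = next++;
    out[i] = map[label[i]];
  }
  return out;
}

// [[Rcpp::export(name = ".cppDetectSurprise")]]
IntegerVector cppDetectSurprise(IntegerMatrix adjacency, int seed) {
  Graph g = buildGraph(adjacency);
  std::mt19937 rng((unsigned)seed);
  double val;
  return contiguous(greedySearch(g, 0, rng, &val));
}

// [[Rcpp::export(name = ".cppDetectModularity")]]
IntegerVector cppDetectModularity(IntegerMatrix adjacency, int seed) {
  Graph g = buildGraph(adjacency);
  std::mt19937 rng((unsigned)seed);
  double val;
  return contiguous(greedySearch(g, 1, rng, &val));
}

// union-find largest-component fraction
static double lccFrac(const Graph &g) {
  int n = g.n;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (g.at(i, j)) { int a = find(i), b = find(j); if (a != b) parent[a] = b; }
  std::vector<int> cnt(n, 0);
  int best = 1;
  for (int i = 0; i < n; ++i) {
    int c = ++cnt[find(i)];
    if (c > best) best = c;
  }
  return (double)best / n;
}

// Threshold sweep over a stack of weighted matrices (n x n x nmat, column
// major). For each threshold: binarize (strict >), run the Surprise greedy,
// record S and the largest-component fraction; return per-threshold means.
// For one matrix the edge set is a monotone function of the threshold, so
// graphs are deduplicated across thresholds via the retained-edge count.
// [[Rcpp::export(name = ".cppSweepSurprise")]]
List cppSweepSurprise(NumericVector mats, IntegerVector dims,
                      NumericVector taus, int seed) {
  int n = dims[0], nmat = dims[2], ntau = taus.size();
  std::vector<double> sumS(ntau, 0.0), sumLcc(ntau, 0.0);
  IntegerMatrix A(n, n);
  for (int mi = 0; mi < nmat; ++mi) {
    // fresh tie-break stream per matrix: results do not depend on the order
    // in which trials/subjects are stacked
    std::mt19937 rng((unsigned)seed);
    const double *w = &mats[(size_t)mi * n * n];
    double lastS = 0, lastLcc = 0;
    int lastCount = -1;
    for (int ti = 0; ti < ntau; ++ti) {
      double tau = taus[ti];
      int count = 0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          if (w[(size_t)j * n + i] > tau) ++count;
      if (count != lastCount) {
        for (int i = 0; i < n; ++i)
          for (int j = 0; j < n; ++j)
            A(i, j) = (i != j && w[(size_t)j * n + i] > tau) ? 1 : 0;
        Graph g = buildGraph(A);
        double val = 0;
        if (g.m == 0) {
          val = 0; lastLcc = 1.0 / n;
        } else {
          greedySearch(g, 0, rng, &val);
          lastLcc = lccFrac(g);
        }
        lastS = val;
        lastCount = count;
      }
      sumS[ti] += lastS;
      sumLcc[ti] += lastLcc;
    }
  }
  NumericVector meanS(ntau), meanLcc(ntau);
  for (int ti = 0; ti < ntau; ++ti) {
    meanS[ti] = sumS[ti] / nmat;
    meanLcc[ti] = sumLcc[ti] / nmat;
  }
  return List::create(_["meanSurprise"] = meanS, _["lccFraction"] = meanLcc);
}

// Per-window network features at a fixed threshold: average node degree and
// the modularity of the greedy-maximal partition for every matrix.
// [[Rcpp::export(name = ".cppFeaturesBatch")]]
List cppFeaturesBatch(NumericVector mats, IntegerVector dims, double tau,
                      int seed) {
  int n = dims[0], nmat = dims[2];
  NumericVector kbar(nmat), Q(nmat);
  IntegerVector zeroEdge(nmat);
  IntegerMatrix A(n, n);
  for (int mi = 0; mi < nmat; ++mi) {
    std::mt19937 rng((unsigned)seed);  // per-matrix stream, order-invariant
    const double *w = &mats[(size_t)mi * n * n];
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        A(i, j) = (i != j && w[(size_t)j * n + i] > tau) ? 1 : 0;
    Graph g = buildGraph(A);
    kbar[mi] = 2.0 * g.m / n;
    if (g.m == 0) {
      Q[mi] = 0.0; zeroEdge[mi] = 1;
    } else {
      double val = 0;
      greedySearch(g, 1, rng, &val);
      Q[mi] = val;
      zeroEdge[mi] = 0;
    }
  }
  return List::create(_["kbar"] = kbar, _["Q"] = Q, _["zeroEdge"] = zeroEdge);
}
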