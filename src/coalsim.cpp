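// Censored multispecies coalescent simulator.
//
// A species tree is passed down as flat arrays (0-based node ids; tips are
// 0..S-1). Each internal node owns the population on the branch *above* it,
// whose duration is that branch's length in coalescent units; the root
// population has infinite duration. One lineage enters per sampled species,
// so terminal branches can host no coalescence and carry no information.
//
// Randomness never touches R's RNG: each gene g draws from its own SplitMix64
// stream keyed by (seed, offset + g), so per-gene simulation is
// order-independent and reproducible across entry points.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

struct SplitMix {
  uint64_t state;
  explicit SplitMix(uint64_t s) : state(s) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double unif_pos() {
    double u;
    do { u = unif(); } while (u <= 0.0);
    return u;
  }
  double rexp(double rate) { return -std::log(unif_pos()) / rate; }
  int rint(int n) { return (int)(next() % (uint64_t)n); }
};

static uint64_t gene_stream(double seed, double offset, int i) {
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t g = (uint64_t)(int64_t)offset + (uint64_t)i;
  SplitMix mix(s ^ (g * 0xD1B54A32D192ED03ULL));
  return mix.next();
}

// Gene tree under construction: parallel arrays over nodes, leaves first.
struct Gene {
  std::vector<int> par;      // parent node id, -1 at root
  std::vector<double> tm;    // coalescent-unit height
  std::vector<int> lab;      // species tip id at leaves, -1 internally
};

// Run the coalescent among `lin` for at most `dur` units starting at absolute
// height `bottom`; merged pairs are chosen uniformly.
static void coalesce(std::vector<int>& lin, double bottom, double dur,
                     Gene& g, SplitMix& rng) {
  double elapsed = 0.0;
  while ((int)lin.size() >= 2) {
    int k = (int)lin.size();
    double w = rng.rexp(0.5 * k * (k - 1));
    if (elapsed + w > dur) break;
    elapsed += w;
    int i = rng.rint(k);
    int j = rng.rint(k - 1);
    if (j >= i) ++j;
    int nd = (int)g.par.size();
    g.par.push_back(-1);
    g.tm.push_back(bottom + elapsed);
    g.lab.push_back(-1);
    g.par[lin[i]] = nd;
    g.par[lin[j]] = nd;
    int a = std::min(i, j), b = std::max(i, j);
    lin[a] = nd;
    lin.erase(lin.begin() + b);
  }
}

static Gene sim_gene(const IntegerMatrix& child, const NumericVector& dur,
                     const NumericVector& height, const IntegerVector& postorder,
                     const std::vector<int>& present, SplitMix& rng,
                     std::vector<int>& leaf_of) {
  Gene g;
  int nn = dur.size();
  std::vector<std::vector<int> > pool(nn);
  std::fill(leaf_of.begin(), leaf_of.end(), -1);
  for (size_t t = 0; t < present.size(); ++t) {
    int tip = present[t];
    int nd = (int)g.par.size();
    g.par.push_back(-1);
    g.tm.push_back(0.0);
    g.lab.push_back(tip);
    leaf_of[tip] = nd;
    pool[tip].push_back(nd);
  }
  for (int idx = 0; idx < postorder.size(); ++idx) {
    int x = postorder[idx];
    std::vector<int>& lin = pool[x];
    for (int c = 0; c < 2; ++c) {
      int ch = child(x, c);
      if (ch >= 0) lin.insert(lin.end(), pool[ch].begin(), pool[ch].end());
    }
    coalesce(lin, height[x], dur[x], g, rng);
  }
  return g;
}

static double pair_time(const Gene& g, int u, int v, std::vector<int>& anc) {
  anc.clear();
  int x = u;
  while (x != -1) { anc.push_back(x); x = g.par[x]; }
  x = v;
  while (std::find(anc.begin(), anc.end(), x) == anc.end()) x = g.par[x];
  return g.tm[x];
}

// Aggregated rooted-triple counts over simulated genes. `triples` holds
// 0-based tip ids (a,b,c); output column 0/1/2 counts ab|c, ac|b, bc|a.
// [[Rcpp::export]]
IntegerMatrix sim_triple_counts_cpp(int S, IntegerMatrix child, NumericVector dur,
                                    NumericVector height, IntegerVector postorder,
                                    List occupancy, IntegerMatrix triples,
                                    double seed, double offset) {
  int ntr = triples.nrow();
  IntegerMatrix out(ntr, 3);
  std::vector<int> leaf_of(S);
  std::vector<int> anc;
  int ng = occupancy.size();
  for (int i = 0; i < ng; ++i) {
    IntegerVector occ = occupancy[i];
    std::vector<int> present(occ.begin(), occ.end());
    SplitMix rng(gene_stream(seed, offset, i));
    Gene g = sim_gene(child, dur, height, postorder, present, rng, leaf_of);
    for (int r = 0; r < ntr; ++r) {
      int la = leaf_of[triples(r, 0)];
      int lb = leaf_of[triples(r, 1)];
      int lc = leaf_of[triples(r, 2)];
      if (la < 0 || lb < 0 || lc < 0) continue;
      double tab = pair_time(g, la, lb, anc);
      double tac = pair_time(g, la, lc, anc);
      double tbc = pair_time(g, lb, lc, anc);
      int col = (tab < tac && tab < tbc) ? 0 : (tac < tbc ? 1 : 2);
      out(r, col) += 1;
    }
  }
  return out;
}

// Full gene trees as "phylo" building blocks (edge matrix in preorder,
// 1-based ids with tips 1..k, root k+1).
// [[Rcpp::export]]
List sim_gene_trees_cpp(int S, IntegerMatrix child, NumericVector dur,
                        NumericVector height, IntegerVector postorder,
                        List occupancy, double seed, double offset) {
  int ng = occupancy.size();
  List out(ng);
  std::vector<int> leaf_of(S);
  for (int i = 0; i < ng; ++i) {
    IntegerVector occ = occupancy[i];
    std::vector<int> present(occ.begin(), occ.end());
    int k = (int)present.size();
    SplitMix rng(gene_stream(seed, offset, i));
    Gene g = sim_gene(child, dur, height, postorder, present, rng, leaf_of);

    if (k == 1) {
      IntegerMatrix edge(1, 2);
      edge(0, 0) = 2; edge(0, 1) = 1;
      out[i] = List::create(_["edge"] = edge,
                            _["edge.length"] = NumericVector::create(0.0),
                            _["Nnode"] = 1,
                            _["tip"] = IntegerVector(present.begin(), present.end()));
      continue;
    }

    int total = (int)g.par.size();
    int root = -1;
    for (int v = 0; v < total; ++v) if (g.par[v] == -1) root = v;
    std::vector<std::vector<int> > ch(total);
    for (int v = 0; v < total; ++v) if (g.par[v] >= 0) ch[g.par[v]].push_back(v);

    std::vector<int> id(total, 0);
    for (int v = 0; v < k; ++v) id[v] = v + 1;
    int nxt = k + 1;
    std::vector<int> stack, order;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (g.lab[v] >= 0) continue;
      id[v] = nxt++;
      order.push_back(v);
      for (size_t c = 0; c < ch[v].size(); ++c) stack.push_back(ch[v][c]);
    }

    IntegerMatrix edge(total - 1, 2);
    NumericVector elen(total - 1);
    int e = 0;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int v = order[oi];
      for (size_t c = 0; c < ch[v].size(); ++c) {
        int w = ch[v][c];
        edge(e, 0) = id[v];
        edge(e, 1) = id[w];
        elen[e] = g.tm[v] - g.tm[w];
        ++e;
      }
    }
    out[i] = List::create(_["edge"] = edge,
                          _["edge.length"] = elen,
                          _["Nnode"] = k - 1,
                          _["tip"] = IntegerVector(present.begin(), present.end()));
  }
  return out;
}

// Root (TMRCA) heights of simulated genes; used for calibration checks.
// [[Rcpp::export]]
NumericVector sim_root_times_cpp(int S, IntegerMatrix child, NumericVector dur,
                                 NumericVector height, IntegerVector postorder,
                                 List occupancy, double seed, double offset) {
  int ng = occupancy.size();
  NumericVector out(ng);
  std::vector<int> leaf_of(S);
  for (int i = 0; i < ng; ++i) {
    IntegerVector occ = occupancy[i];
    std::vector<int> present(occ.begin(), occ.end());
    SplitMix rng(gene_stream(seed, offset, i));
    Gene g = sim_gene(child, dur, height, postorder, present, rng, leaf_of);
    double mx = 0.0;
    for (size_t v = 0; v < g.tm.size(); ++v) mx = std::max(mx, g.tm[v]);
    out[i] = mx;
  }
  return out;
}
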