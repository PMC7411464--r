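#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge swaps on one edge-type class.
//
// edges: m x 2 integer matrix of 0-based node indices. For a bipartite
// class (ceRNA: lncRNA-TF) column 1 must hold the lncRNA side and
// column 2 the TF side; swaps then exchange TF endpoints only, which
// preserves both the degree sequence and bipartiteness. For a
// unipartite class (PPI: TF-TF) a random orientation is chosen per
// attempt so both pairings are proposed. Swaps creating self-loops or
// duplicate edges within the class are rejected. Uses R's RNG, so
// results are reproducible under set.seed().
//
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, bool bipartite,
                               int n_attempts) {
  const int m = edges.nrow();
  std::vector<int> a(m), b(m);
  for (int i = 0; i < m; ++i) { a[i] = edges(i, 0); b[i] = edges(i, 1); }

  const long long K = 4000000LL;
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  auto key = [&](int u, int v) {
    if (!bipartite && u > v) std::swap(u, v);
    return (long long)u * K + v;
  };
  for (int i = 0; i < m; ++i) present.insert(key(a[i], b[i]));

  int successes = 0;
  if (m >= 2) {
    for (int t = 0; t < n_attempts; ++t) {
      int e = (int)(unif_rand() * m); if (e >= m) e = m - 1;
      int f = (int)(unif_rand() * m); if (f >= m) f = m - 1;
      if (e == f) continue;
      int ae = a[e], be = b[e], af = a[f], bf = b[f];
      if (!bipartite && unif_rand() < 0.5) std::swap(af, bf);
      // proposal: (ae, bf) and (af, be)
      if (ae == af || be == bf) continue;              // no-op swap
      if (!bipartite && (ae == bf || af == be)) continue; // self-loop
      long long k1 = key(ae, bf), k2 = key(af, be);
      if (present.count(k1) || present.count(k2)) continue;
      present.erase(key(ae, be));
      present.erase(key(af, bf));
      present.insert(k1);
      present.insert(k2);
      a[e] = ae; b[e] = bf;
      a[f] = af; b[f] = be;
      ++successes;
    }
  }
  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) { out(i, 0) = a[i]; out(i, 1) = b[i]; }
  out.attr("n_success") = successes;
  return out;
}
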