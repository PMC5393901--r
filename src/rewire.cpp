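#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge swap on an integer edge list.
// Picks two random edges (a,b),(c,d) (with a random orientation of the
// second) and proposes (a,d),(c,b); the swap is skipped when the four
// endpoints are not distinct or when either proposed edge already exists,
// so the graph stays simple and every node keeps its degree. Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n_attempts) {
  const int m = edges.nrow();
  IntegerMatrix out = clone(edges);
  if (m < 2) return out;

  auto key = [](int a, int b) -> long long {
    long long lo = a < b ? a : b;
    long long hi = a < b ? b : a;
    return (lo << 32) | hi;
  };
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  for (int i = 0; i < m; ++i) present.insert(key(out(i, 0), out(i, 1)));

  for (int t = 0; t < n_attempts; ++t) {
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = out(i, 0), b = out(i, 1);
    int c = out(j, 0), d = out(j, 1);
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == b || c == d) continue;
    if (a == c || a == d || b == c || b == d) continue;
    long long k1 = key(a, d), k2 = key(c, b);
    if (present.count(k1) || present.count(k2)) continue;
    present.erase(key(a, b));
    present.erase(key(c, d));
    present.insert(k1);
    present.insert(k2);
    out(i, 0) = a; out(i, 1) = d;
    out(j, 0) = c; out(j, 1) = b;
  }
  return out;
}
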