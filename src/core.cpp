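#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <limits>

using namespace Rcpp;

// Pair key for a simple undirected graph on n vertices; a, b are 0-based.
static inline long long pair_key(int a, int b, int n) {
  if (a > b) std::swap(a, b);
  return (long long)a * n + b;
}

// Uniform integer on [0, n); uses R's RNG so results follow set.seed().
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Event-driven SIR on a contact sequence, one seed, n_runs independent runs.
//
// iv, jv: 0-based vertex indices, tv: integer times; contacts sorted
// non-decreasing in tv.  The seed becomes infective at the time of its own
// first contact (that contact can transmit).  A vertex infected at time t0
// is infective on [t0, t0 + delta).  Contacts sharing a timestep are
// processed in a fresh uniformly random order each run.
// Returns the outbreak size (number ever infected, seed included) per run.
// [[Rcpp::export]]
IntegerVector sir_sizes_cpp(IntegerVector iv, IntegerVector jv,
                            IntegerVector tv, int n_vertices, int seed_vertex,
                            double lambda, double delta, int n_runs) {
  const int L = iv.size();
  const double INF = std::numeric_limits<double>::infinity();

  // seed's first contact time
  double t0 = NA_REAL;
  for (int k = 0; k < L; ++k) {
    if (iv[k] == seed_vertex || jv[k] == seed_vertex) { t0 = tv[k]; break; }
  }
  if (!R_finite(t0)) stop("seed vertex has no contacts");

  // tie groups: runs of equal timestamps
  std::vector<int> grp_start;
  grp_start.push_back(0);
  for (int k = 1; k < L; ++k)
    if (tv[k] != tv[k - 1]) grp_start.push_back(k);
  grp_start.push_back(L);

  std::vector<int> ord(L);
  std::vector<double> inf_time(n_vertices, INF);
  std::vector<int> infected;
  infected.reserve(n_vertices);
  IntegerVector sizes(n_runs);

  for (int k = 0; k < L; ++k) ord[k] = k;

  for (int run = 0; run < n_runs; ++run) {
    for (size_t q = 0; q < infected.size(); ++q) inf_time[infected[q]] = INF;
    infected.clear();
    inf_time[seed_vertex] = t0;
    infected.push_back(seed_vertex);

    // shuffle within each tie group (Fisher-Yates)
    for (size_t g = 0; g + 1 < grp_start.size(); ++g) {
      int s = grp_start[g], e = grp_start[g + 1];
      for (int k = e - 1; k > s; --k) {
        int r = s + runif_int(k - s + 1);
        std::swap(ord[k], ord[r]);
      }
    }

    for (int k = 0; k < L; ++k) {
      int c = ord[k];
      int u = iv[c], v = jv[c];
      double t = tv[c];
      bool inf_u = inf_time[u] <= t && t < inf_time[u] + delta;
      bool inf_v = inf_time[v] <= t && t < inf_time[v] + delta;
      if (inf_u && !inf_v && inf_time[v] == INF) {
        if (lambda >= 1.0 || unif_rand() < lambda) {
          inf_time[v] = t;
          infected.push_back(v);
        }
      } else if (inf_v && !inf_u && inf_time[u] == INF) {
        if (lambda >= 1.0 || unif_rand() < lambda) {
          inf_time[u] = t;
          infected.push_back(u);
        }
      }
    }
    sizes[run] = (int)infected.size();
  }
  return sizes;
}

// Configuration-model stub matching with rejection of self- and multi-edges.
// degrees: requested stub counts.  Two stubs are drawn uniformly at random
// from the remaining pool; an invalid draw (same vertex, or edge already
// present) counts one failure.  After `give_up` consecutive failures the
// remaining stubs are deleted.  Returns 1-based edge endpoints and the
// number of deleted stubs.
// [[Rcpp::export]]
List config_model_cpp(IntegerVector degrees, int give_up) {
  const int n = degrees.size();
  std::vector<int> stubs;
  long long total = 0;
  for (int v = 0; v < n; ++v) total += degrees[v];
  stubs.reserve(total);
  for (int v = 0; v < n; ++v)
    for (int d = 0; d < degrees[v]; ++d) stubs.push_back(v);

  std::unordered_set<long long> seen;
  seen.reserve(total);
  std::vector<int> ei, ej;
  ei.reserve(total / 2);
  ej.reserve(total / 2);

  int m = (int)stubs.size();
  int fail = 0;
  while (m >= 2 && fail < give_up) {
    int p = runif_int(m);
    int q = runif_int(m - 1);
    if (q >= p) ++q;  // second stub distinct from the first
    int a = stubs[p], b = stubs[q];
    if (a == b) { ++fail; continue; }
    long long key = pair_key(a, b, n);
    if (seen.count(key)) { ++fail; continue; }
    seen.insert(key);
    ei.push_back(std::min(a, b) + 1);
    ej.push_back(std::max(a, b) + 1);
    // remove both stubs (higher index first so the swap stays valid)
    int hi = std::max(p, q), lo = std::min(p, q);
    stubs[hi] = stubs[m - 1];
    stubs[lo] = stubs[m - 2];
    m -= 2;
    fail = 0;
  }
  return List::create(_["i"] = wrap(ei), _["j"] = wrap(ej),
                      _["leftover_stubs"] = m);
}

// Degree-preserving rewiring: sequentially for each edge (i,j), pick a random
// partner edge (x,y) and with equal probability replace the two by
// (i,y),(x,j) or (i,x),(j,y); if the replacement would introduce a self- or
// multi-edge, redraw the partner.  After `give_up` consecutive failed
// redraws for one edge an error is thrown.  ei, ej are 1-based.
// [[Rcpp::export]]
List rewire_cpp(IntegerVector ei, IntegerVector ej, int n_vertices,
                int give_up) {
  const int M = ei.size();
  if (M < 2) stop("need at least two edges to rewire");
  std::vector<int> a(M), b(M);
  std::unordered_set<long long> seen;
  seen.reserve(2 * M);
  for (int e = 0; e < M; ++e) {
    a[e] = ei[e] - 1;
    b[e] = ej[e] - 1;
    seen.insert(pair_key(a[e], b[e], n_vertices));
  }

  for (int e = 0; e < M; ++e) {
    int fail = 0;
    for (;;) {
      if (fail >= give_up)
        stop("no admissible swap found after %d attempts", give_up);
      int f = runif_int(M - 1);
      if (f >= e) ++f;
      int i = a[e], j = b[e], x = a[f], y = b[f];
      int n1a, n1b, n2a, n2b;
      if (unif_rand() < 0.5) { n1a = i; n1b = y; n2a = x; n2b = j; }
      else                   { n1a = i; n1b = x; n2a = j; n2b = y; }
      if (n1a == n1b || n2a == n2b) { ++fail; continue; }
      long long k_old1 = pair_key(i, j, n_vertices);
      long long k_old2 = pair_key(x, y, n_vertices);
      long long k_new1 = pair_key(n1a, n1b, n_vertices);
      long long k_new2 = pair_key(n2a, n2b, n_vertices);
      if (k_new1 == k_new2) { ++fail; continue; }
      seen.erase(k_old1);
      seen.erase(k_old2);
      if (seen.count(k_new1) || seen.count(k_new2)) {
        seen.insert(k_old1);
        seen.insert(k_old2);
        ++fail;
        continue;
      }
      seen.insert(k_new1);
      seen.insert(k_new2);
      a[e] = std::min(n1a, n1b); b[e] = std::max(n1a, n1b);
      a[f] = std::min(n2a, n2b); b[f] = std::max(n2a, n2b);
      break;
    }
  }
  IntegerVector oi(M), oj(M);
  for (int e = 0; e < M; ++e) { oi[e] = a[e] + 1; oj[e] = b[e] + 1; }
  return List::create(_["i"] = oi, _["j"] = oj);
}
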