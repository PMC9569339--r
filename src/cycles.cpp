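#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Per-edge chordless-cycle census.
//
// For each edge (i, j) with neighborhoods N(i), N(j):
//   triangles  T  = |N(i) ∩ N(j)|
//   squares    S  = #{(a, b) : a in A, b in B, (a, b) in E}
//   pentagons  P  = #{(a, c, b) : a in A, b in B, (a, b) not in E,
//                     c in N(a) ∩ N(b), c not in {i, j} ∪ N(i) ∪ N(j)}
// where A = N(i) \ ({j} ∪ N(j)) and B = N(j) \ ({i} ∪ N(i)) are the
// non-common, non-endpoint neighbors of each end. The exclusions remove every
// possible chord, so S and P count chordless 4- and 5-cycles through the
// edge exactly once. s_i / s_j are the numbers of distinct members of A / B
// matched in at least one chordless square (they enter the pentagon
// normalization). `max_len` truncates the census (3 = triangles only,
// 4 = +squares) for callers that only need edge clustering.
// [[Rcpp::export]]
List edge_cycle_counts_cpp(int n, IntegerMatrix edges, int max_len = 5) {
  const int m = edges.nrow();
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < m; ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    adj[i].push_back(j);
    adj[j].push_back(i);
  }
  for (int v = 0; v < n; ++v) std::sort(adj[v].begin(), adj[v].end());

  IntegerVector tri(m), sq(m), pent(m), pent_pairs(m), si(m), sj(m),
      deg_i(m), deg_j(m);
  // scratch membership flags, cleared between edges
  std::vector<char> inNi(n, 0), inNj(n, 0), inA(n, 0), inB(n, 0);
  std::vector<char> amatch(n, 0), bmatch(n, 0), inNa(n, 0), pfound(n, 0);

  for (int e = 0; e < m; ++e) {
    const int i = edges(e, 0), j = edges(e, 1);
    const std::vector<int>& Ni = adj[i];
    const std::vector<int>& Nj = adj[j];
    deg_i[e] = Ni.size();
    deg_j[e] = Nj.size();
    for (size_t a = 0; a < Ni.size(); ++a) inNi[Ni[a]] = 1;
    for (size_t b = 0; b < Nj.size(); ++b) inNj[Nj[b]] = 1;

    int T = 0;
    for (size_t a = 0; a < Ni.size(); ++a) T += inNj[Ni[a]];
    tri[e] = T;

    if (max_len >= 4) {
      std::vector<int> A, B;
      for (size_t a = 0; a < Ni.size(); ++a) {
        int v = Ni[a];
        if (v != j && !inNj[v]) { A.push_back(v); inA[v] = 1; }
      }
      for (size_t b = 0; b < Nj.size(); ++b) {
        int v = Nj[b];
        if (v != i && !inNi[v]) { B.push_back(v); inB[v] = 1; }
      }

      int S = 0, nsi = 0, nsj = 0;
      for (size_t ai = 0; ai < A.size(); ++ai) {
        const int a = A[ai];
        const std::vector<int>& Na = adj[a];
        bool hit = false;
        for (size_t c = 0; c < Na.size(); ++c) {
          const int b = Na[c];
          if (inB[b]) {
            ++S;
            hit = true;
            if (!bmatch[b]) { bmatch[b] = 1; ++nsj; }
          }
        }
        if (hit) { amatch[a] = 1; ++nsi; }
      }
      sq[e] = S;
      si[e] = nsi;
      sj[e] = nsj;

      if (max_len >= 5) {
        // pfound marks the b's seen for the current a, so that the number of
        // distinct (a, b) end-neighbor pairs joined by a chordless 2-path is
        // counted alongside the raw pentagon count
        long long P = 0, Ppairs = 0;
        std::vector<int> seen;
        for (size_t ai = 0; ai < A.size(); ++ai) {
          const int a = A[ai];
          const std::vector<int>& Na = adj[a];
          for (size_t ci = 0; ci < Na.size(); ++ci) inNa[Na[ci]] = 1;
          seen.clear();
          for (size_t ci = 0; ci < Na.size(); ++ci) {
            const int c = Na[ci];
            if (c == i || c == j || inNi[c] || inNj[c]) continue;
            const std::vector<int>& Nc = adj[c];
            for (size_t bi = 0; bi < Nc.size(); ++bi) {
              const int b = Nc[bi];
              if (inB[b] && b != a && !inNa[b]) {
                ++P;
                if (!pfound[b]) { pfound[b] = 1; seen.push_back(b); }
              }
            }
          }
          Ppairs += seen.size();
          for (size_t s = 0; s < seen.size(); ++s) pfound[seen[s]] = 0;
          for (size_t ci = 0; ci < Na.size(); ++ci) inNa[Na[ci]] = 0;
        }
        pent[e] = (int)P;
        pent_pairs[e] = (int)Ppairs;
      }

      for (size_t ai = 0; ai < A.size(); ++ai) { inA[A[ai]] = 0; amatch[A[ai]] = 0; }
      for (size_t bi = 0; bi < B.size(); ++bi) { inB[B[bi]] = 0; bmatch[B[bi]] = 0; }
    }

    for (size_t a = 0; a < Ni.size(); ++a) inNi[Ni[a]] = 0;
    for (size_t b = 0; b < Nj.size(); ++b) inNj[Nj[b]] = 0;
  }

  return List::create(
    _["deg_i"] = deg_i, _["deg_j"] = deg_j, _["triangles"] = tri,
    _["squares"] = sq, _["pentagons"] = pent, _["pentagon_pairs"] = pent_pairs,
    _["s_i"] = si, _["s_j"] = sj);
}
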