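#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode A/C/G/T; -1 for N or anything else.
static inline int encode_base(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Best gap-free diagonal alignment between q and t (fixed orientation).
//
// Exact-match k-mer seeds anchor candidate diagonals (k-mers containing N
// are never seeded). Each candidate diagonal is scored by gap-free
// extension over the full overlap span of the two sequences along that
// diagonal; N matches nothing and counts against identity through the
// denominator. The diagonal with the most matching columns wins, which on
// substitution-divergent sequences reproduces the single best nucmer-style
// chain.
//
// Returns matches, span (aligned columns) and the number of seeded
// diagonals; span == 0 when no seed is found.
// [[Rcpp::export]]
List ani_diagonal_cpp(std::string q, std::string t, int k) {
  const int qlen = (int)q.size(), tlen = (int)t.size();
  List out = List::create(_["matches"] = 0, _["span"] = 0,
                          _["n_diagonals"] = 0);
  if (qlen < k || tlen < k) return out;

  // hash all valid k-mers of t -> positions
  std::unordered_map<uint64_t, std::vector<int>> index;
  index.reserve((size_t)tlen);
  {
    uint64_t kmer = 0; int valid = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int i = 0; i < tlen; ++i) {
      int code = encode_base(t[i]);
      if (code < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)code) & mask;
      if (++valid >= k) index[kmer].push_back(i - k + 1);
    }
  }

  // candidate diagonals (d = qpos - tpos) weighted by seed count
  std::unordered_map<int, int> diag_seeds;
  {
    uint64_t kmer = 0; int valid = 0;
    const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int i = 0; i < qlen; ++i) {
      int code = encode_base(q[i]);
      if (code < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)code) & mask;
      if (++valid >= k) {
        auto hit = index.find(kmer);
        if (hit != index.end()) {
          int qpos = i - k + 1;
          for (int tpos : hit->second) diag_seeds[qpos - tpos]++;
        }
      }
    }
  }
  if (diag_seeds.empty()) return out;

  // evaluate the best-supported diagonals by full gap-free extension
  std::vector<std::pair<int, int>> diags(diag_seeds.begin(), diag_seeds.end());
  std::sort(diags.begin(), diags.end(),
            [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
              return a.second > b.second;
            });
  const int max_eval = 64;  // spurious diagonals carry few seeds
  int best_matches = -1, best_span = 0;
  for (size_t di = 0; di < diags.size() && (int)di < max_eval; ++di) {
    int d = diags[di].first;
    int q0 = std::max(0, d), q1 = std::min(qlen, tlen + d);
    if (q1 <= q0) continue;
    int matches = 0;
    for (int qi = q0; qi < q1; ++qi) {
      char a = q[qi], b = t[qi - d];
      if (a == b && a != 'N') ++matches;
    }
    int span = q1 - q0;
    if (matches > best_matches ||
        (matches == best_matches && span < best_span)) {
      best_matches = matches;
      best_span = span;
    }
  }
  out["matches"] = best_matches < 0 ? 0 : best_matches;
  out["span"] = best_matches < 0 ? 0 : best_span;
  out["n_diagonals"] = (int)diags.size();
  return out;
}
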