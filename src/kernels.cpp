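#include <Rcpp.h>
using namespace Rcpp;

// Maximum count of aligned identical characters between a and c over all
// relative shifts. With c = reverse complement of b this is the largest
// number of Watson-Crick pairings when a anneals antiparallel to b.
// [[Rcpp::export]]
int pairing_max_cpp(std::string a, std::string c) {
  int la = a.size(), lc = c.size();
  int best = 0;
  for (int shift = -(lc - 1); shift <= la - 1; ++shift) {
    int count = 0;
    int i0 = std::max(0, shift);
    int i1 = std::min(la, lc + shift);
    for (int i = i0; i < i1; ++i) {
      if (a[i] == c[i - shift]) ++count;
    }
    if (count > best) best = count;
  }
  return best;
}

static inline bool wc_pair(char x, char y) {
  return (x == 'A' && y == 'T') || (x == 'T' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G');
}

// Minimum delta-G over all ungapped stem-loop foldings: stem of at least
// stem_min contiguous Watson-Crick pairs, loop length in [loop_min,
// loop_max], energy = loop_penalty + sum of pair energies (A.T at_e,
// G.C gc_e, both negative). Returns 0 when no folding is possible or none
// is negative.
// [[Rcpp::export]]
double hairpin_dg_cpp(std::string s, int stem_min = 3, int loop_min = 3,
                      int loop_max = 12, double at_e = -1.0,
                      double gc_e = -1.5, double loop_penalty = 3.5) {
  int n = s.size();
  double best = 0.0;
  for (int k = stem_min; 2 * k + loop_min <= n; ++k) {
    for (int loop = loop_min; loop <= loop_max; ++loop) {
      int span = 2 * k + loop;
      if (span > n) break;
      for (int i = 0; i + span <= n; ++i) {
        // stem1 s[i .. i+k-1], loop, stem2 s[i+k+loop .. i+span-1];
        // stem1 position j pairs antiparallel with s[i + span - 1 - j]
        double e = loop_penalty;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          char x = s[i + j], y = s[i + span - 1 - j];
          if (!wc_pair(x, y)) { ok = false; break; }
          e += (x == 'G' || x == 'C') ? gc_e : at_e;
        }
        if (ok && e < best) best = e;
      }
    }
  }
  return best;
}
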