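#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// End-anchored semi-global alignment landscapes.
//
// A match of a read r (length m) in a reference S is identified by the
// 0-based reference position i that the read's LAST base aligns to; the
// first and last read base must align to reference characters (no gap
// columns at either read end) and the alignment must lie fully inside S.
// delta[i] is the minimal distance over all such alignments ending at i;
// cstart[i] is the leftmost start position among minimal-distance
// alignments ending at i (the canonical start).
//
// Conventions shared with the R side:
//   * infeasible positions carry the sentinel m + 1 in delta and NA in cstart
//   * 'N' (or any non-ACGT character) mismatches everything, including 'N'

static inline int subst(char a, char b) {
  if (a != b) return 1;
  switch (a) { case 'A': case 'C': case 'G': case 'T': return 0; }
  return 1; // N/N and other ambiguity codes never match
}

// [[Rcpp::export(name = ".ls_hamming")]]
List ls_hamming(std::string read, std::string ref) {
  const int m = (int)read.size(), n = (int)ref.size();
  const int INF = m + 1;
  IntegerVector delta(n, INF), cstart(n, NA_INTEGER);
  for (int i = m - 1; i < n; ++i) {
    int d = 0;
    const int s = i - m + 1;
    for (int j = 0; j < m; ++j) d += subst(read[j], ref[s + j]);
    if (d <= m) { delta[i] = d; cstart[i] = s; }
  }
  return List::create(_["delta"] = delta, _["cstart"] = cstart);
}

// Column-wise DP. Rows j = 1..m-1 hold the cost of end-anchored alignments
// of read[0..j-1] whose first base sits on a reference character; the final
// read base is folded in as a forced diagonal, which pins the end position.
// Start positions of minimal-cost paths are propagated alongside the costs
// (every optimal path passes through optimally reached cells, so taking the
// minimum start over cost-achieving predecessors is exact).
// [[Rcpp::export(name = ".ls_edit")]]
List ls_edit(std::string read, std::string ref) {
  const int m = (int)read.size(), n = (int)ref.size();
  const int INF = m + 1, BIG = 4 * (m + 2);
  IntegerVector delta(n, INF), cstart(n, NA_INTEGER);
  if (m == 1) {
    for (int i = 0; i < n; ++i) { delta[i] = subst(read[0], ref[i]); cstart[i] = i; }
    return List::create(_["delta"] = delta, _["cstart"] = cstart);
  }
  std::vector<int> Dprev(m, BIG), Dcur(m, BIG), Sprev(m, -1), Scur(m, -1);
  for (int i = 0; i < n; ++i) {
    // row 1: read[0] forced onto a reference character (diagonal entry only)
    {
      int cd = subst(read[0], ref[i]);
      int ch = (i > 0) ? Dprev[1] + 1 : BIG;
      if (ch < cd)      { Dcur[1] = ch; Scur[1] = Sprev[1]; }
      else if (ch == cd){ Dcur[1] = cd; Scur[1] = std::min(i, Sprev[1]); }
      else              { Dcur[1] = cd; Scur[1] = i; }
    }
    for (int j = 2; j <= m - 1; ++j) {
      int cd = (i > 0) ? Dprev[j - 1] + subst(read[j - 1], ref[i]) : BIG;
      int cv = Dcur[j - 1] + 1;          // read base j inserted (interior only)
      int ch = (i > 0) ? Dprev[j] + 1 : BIG; // reference base i deleted
      int best = std::min(cd, std::min(cv, ch));
      int st = INT_MAX;
      if (cd == best && Sprev[j - 1] >= 0) st = std::min(st, Sprev[j - 1]);
      if (cv == best && Scur[j - 1] >= 0)  st = std::min(st, Scur[j - 1]);
      if (ch == best && Sprev[j] >= 0)     st = std::min(st, Sprev[j]);
      if (best > BIG) best = BIG;
      Dcur[j] = best; Scur[j] = (st == INT_MAX) ? -1 : st;
    }
    if (i > 0) {
      int d = Dprev[m - 1] + subst(read[m - 1], ref[i]);
      if (d <= m) { delta[i] = d; cstart[i] = Sprev[m - 1]; }
    }
    std::swap(Dprev, Dcur); std::swap(Sprev, Scur);
    std::fill(Dcur.begin(), Dcur.end(), BIG);
    std::fill(Scur.begin(), Scur.end(), -1);
  }
  return List::create(_["delta"] = delta, _["cstart"] = cstart);
}
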