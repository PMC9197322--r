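// Brute-force reference enumerator of maximal perfect tandem repeats.
//
// Deliberately naive: every (position, unit-length) pair is tested and
// extended unit by unit, independent of the vectorised scanner in R/mining.R.
// It exists so that the production miner can be property-tested against an
// implementation that shares none of its code path.

#include <Rcpp.h>
using namespace Rcpp;

static bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".ssr_oracle_scan")]]
DataFrame ssr_oracle_scan(std::string seq, IntegerVector min_repeats) {
  int n = (int) seq.size();
  std::vector<int> us, starts, ends, counts;
  std::vector<std::string> motifs;

  for (int i = 0; i < n; ++i) {
    for (int u = 1; u <= 6; ++u) {
      if (i + u > n) break;
      bool ok = true;
      for (int j = 0; j < u; ++j)
        if (!is_base(seq[i + j])) { ok = false; break; }
      if (!ok) continue;
      // left maximality: skip if a full identical unit precedes the start
      if (i >= u) {
        bool same = true;
        for (int j = 0; j < u; ++j)
          if (seq[i - u + j] != seq[i + j]) { same = false; break; }
        if (same) continue;
      }
      // extend right by whole units
      int k = 1;
      while (true) {
        int p = i + k * u;
        if (p + u > n) break;
        bool same = true;
        for (int j = 0; j < u; ++j)
          if (seq[p + j] != seq[i + j]) { same = false; break; }
        if (!same) break;
        ++k;
      }
      if (k < min_repeats[u - 1]) continue;
      // primitivity: motif must not repeat a shorter unit
      bool prim = true;
      for (int d = 1; d < u && prim; ++d) {
        if (u % d) continue;
        bool rep = true;
        for (int j = d; j < u; ++j)
          if (seq[i + j] != seq[i + (j % d)]) { rep = false; break; }
        if (rep) prim = false;
      }
      if (!prim) continue;
      us.push_back(u);
      starts.push_back(i + 1);
      ends.push_back(i + k * u);
      counts.push_back(k);
      motifs.push_back(seq.substr(i, u));
    }
  }

  // overlap resolution: longer tract first, then smaller unit, then leftmost
  int m = (int) us.size();
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    int la = ends[a] - starts[a] + 1, lb = ends[b] - starts[b] + 1;
    if (la != lb) return la > lb;
    if (us[a] != us[b]) return us[a] < us[b];
    return starts[a] < starts[b];
  });
  std::vector<bool> occupied(n + 2, false), kept(m, false);
  for (int t = 0; t < m; ++t) {
    int i = idx[t];
    bool clash = false;
    for (int p = starts[i]; p <= ends[i]; ++p)
      if (occupied[p]) { clash = true; break; }
    if (clash) continue;
    kept[i] = true;
    for (int p = starts[i]; p <= ends[i]; ++p) occupied[p] = true;
  }

  std::vector<int> ord;
  for (int i = 0; i < m; ++i) if (kept[i]) ord.push_back(i);
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return starts[a] < starts[b];
  });

  int nk = (int) ord.size();
  IntegerVector o_start(nk), o_end(nk), o_unit(nk), o_count(nk);
  CharacterVector o_motif(nk);
  for (int t = 0; t < nk; ++t) {
    int i = ord[t];
    o_start[t] = starts[i];
    o_end[t] = ends[i];
    o_unit[t] = us[i];
    o_count[t] = counts[i];
    o_motif[t] = motifs[i];
  }
  return DataFrame::create(_["start"] = o_start, _["end"] = o_end,
                           _["unit_length"] = o_unit,
                           _["repeat_count"] = o_count,
                           _["motif"] = o_motif,
                           _["stringsAsFactors"] = false);
}
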