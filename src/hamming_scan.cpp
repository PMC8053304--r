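#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Reverse complement of each DNA string (A/C/G/T plus N passthrough).
// [[Rcpp::export]]
CharacterVector revcomp_many(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) {
      switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default: break;
      }
    }
    out[i] = r;
  }
  return out;
}

// Minimum Hamming distance of each read against each template over all
// ungapped placements of the read inside the template. Reads longer than a
// template get INT_MAX for that template. Strand handling is done by the
// caller (pass reverse-complemented reads too and take the minimum).
// [[Rcpp::export]]
IntegerMatrix hamming_scan(CharacterVector reads, CharacterVector templates) {
  const int nr = reads.size(), nt = templates.size();
  IntegerMatrix out(nr, nt);
  std::vector<std::string> tpl(nt);
  for (int j = 0; j < nt; ++j) tpl[j] = as<std::string>(templates[j]);
  for (int i = 0; i < nr; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const int m = rd.size();
    for (int j = 0; j < nt; ++j) {
      const std::string& tp = tpl[j];
      const int L = tp.size();
      int best = INT_MAX;
      for (int off = 0; off + m <= L; ++off) {
        int mm = 0;
        for (int k = 0; k < m; ++k) {
          mm += (rd[k] != tp[off + k]);
          if (mm >= best) break;
        }
        if (mm < best) best = mm;
        if (best == 0) break;
      }
      out(i, j) = best;
    }
  }
  return out;
}
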