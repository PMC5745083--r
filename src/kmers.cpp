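#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int base_code(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N or anything else invalidates the window
  }
}

// Canonical integer codes (base-4, A=0 C=1 G=2 T=3) for every k-mer window
// of every read; windows containing non-ACGT characters are skipped. The
// canonical code is min(code, revcomp code), matching lexicographic-minimum
// canonicalization because the base order A<C<G<T is the alphabet order.
// Rolling computation keeps this O(total bases). k is capped at 15 so codes
// fit exactly in a double (4^15 < 2^53).
// [[Rcpp::export(name = ".cpp_canonical_codes")]]
NumericVector cpp_canonical_codes(const CharacterVector& reads, int k) {
  if (k < 1 || k > 15) stop("k must be between 1 and 15");
  std::vector<double> out;
  const double kmax = std::pow(4.0, k - 1); // place value of leading base
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int n = (int) LENGTH(STRING_ELT(reads, i));
    if (n < k) continue;
    double fwd = 0.0, rev = 0.0;
    int run = 0; // window length currently held (capped at k)
    for (int j = 0; j < n; ++j) {
      int b = base_code(s[j]);
      if (b < 0) { run = 0; fwd = 0.0; rev = 0.0; continue; }
      if (run < k) {
        // build up: fwd has the first base most significant,
        // rev = sum_i (3 - w_i) * 4^i is the reverse-complement code
        fwd = fwd * 4.0 + b;
        rev = rev + (3 - b) * std::pow(4.0, run);
        ++run;
      } else {
        // slide: drop the leading base, append the new one
        double lead = std::floor(fwd / kmax);
        fwd = (fwd - lead * kmax) * 4.0 + b;
        rev = (rev - (3.0 - lead)) / 4.0 + (3 - b) * kmax;
      }
      if (run == k) out.push_back(fwd < rev ? fwd : rev);
    }
  }
  return wrap(out);
}

// Count occurrences (both strands) of a fixed site within each read.
// [[Rcpp::export(name = ".cpp_contains_site")]]
LogicalVector cpp_contains_site(const CharacterVector& reads,
                                const std::string& site,
                                const std::string& site_rc) {
  R_xlen_t n = reads.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string r(CHAR(STRING_ELT(reads, i)));
    out[i] = (r.find(site) != std::string::npos) ||
             (r.find(site_rc) != std::string::npos);
  }
  return out;
}
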