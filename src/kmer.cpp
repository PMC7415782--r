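#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode; anything not ACGT (incl. N) breaks the current k-mer window.
static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Count canonical k-mers (lexicographic min of k-mer and reverse complement)
// over a set of reads. k <= 31 so a k-mer packs into 64 bits.
// [[Rcpp::export]]
List kmer_count_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift_rc = 2 * (k - 1);
  double n_instances = 0;
  double n_short = 0;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    int len = (int) LENGTH(STRING_ELT(reads, r));
    if (len < k) { n_short += 1; continue; }
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // number of consecutive valid bases ending here
    for (int i = 0; i < len; ++i) {
      int b = base2bit(s[i]);
      if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t) b) & mask;
      rev = (rev >> 2) | (((uint64_t) (3 - b)) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
        n_instances += 1;
      }
    }
  }
  // histogram: depth -> number of distinct k-mers
  std::unordered_map<uint32_t, double> hist;
  for (auto &kv : counts) hist[kv.second] += 1;
  std::vector<uint32_t> depths;
  depths.reserve(hist.size());
  for (auto &kv : hist) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  IntegerVector depth(depths.size());
  NumericVector distinct(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    depth[i] = (int) depths[i];
    distinct[i] = hist[depths[i]];
  }
  return List::create(_["depth"] = depth,
                      _["distinct_kmers"] = distinct,
                      _["n_instances"] = n_instances,
                      _["n_short_reads"] = n_short);
}
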