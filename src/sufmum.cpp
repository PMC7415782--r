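#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Maximal unique match (MUM) discovery between two genomes via a generalized
// suffix array over ref + qry + revcomp(qry), one unique sentinel code per
// sequence copy and per ambiguous base, so matches never cross sequence
// boundaries or touch N.

namespace {

struct CopyInfo {
  int start;   // global offset of first base
  int len;     // bases in this copy
  int src;     // 0 = ref, 1 = qry
  int seq;     // chromosome index within its genome (0-based)
  int strand;  // 0 = forward, 1 = revcomp copy (qry only)
};

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// suffix array by prefix doubling with counting sort: O(n log n), insensitive
// to long shared prefixes between near-identical genomes
void build_sa(const std::vector<int> &code, std::vector<int> &sa) {
  const int n = (int) code.size();
  sa.resize(n);
  std::vector<int> rnk(n), tmp(n), cnt;
  int maxc = 0;
  for (int c : code) maxc = std::max(maxc, c);
  cnt.assign(std::max(maxc + 1, n) + 1, 0);
  for (int i = 0; i < n; ++i) cnt[code[i]]++;
  for (size_t i = 1; i < cnt.size(); ++i) cnt[i] += cnt[i - 1];
  for (int i = n - 1; i >= 0; --i) sa[--cnt[code[i]]] = i;
  rnk[sa[0]] = 0;
  for (int i = 1; i < n; ++i)
    rnk[sa[i]] = rnk[sa[i - 1]] + (code[sa[i]] != code[sa[i - 1]] ? 1 : 0);
  int classes = rnk[sa[n - 1]] + 1;
  for (int k = 1; classes < n && k < n; k <<= 1) {
    // order by second key (rank at offset k)
    int p = 0;
    for (int i = n - k; i < n; ++i) tmp[p++] = i;
    for (int i = 0; i < n; ++i) if (sa[i] >= k) tmp[p++] = sa[i] - k;
    // stable counting sort by first key
    std::fill(cnt.begin(), cnt.begin() + classes + 1, 0);
    for (int i = 0; i < n; ++i) cnt[rnk[i] + 1]++;
    for (int i = 1; i <= classes; ++i) cnt[i] += cnt[i - 1];
    for (int i = 0; i < n; ++i) sa[cnt[rnk[tmp[i]]]++] = tmp[i];
    // new ranks
    std::vector<int> rnk2(n);
    rnk2[sa[0]] = 0;
    for (int i = 1; i < n; ++i) {
      int a = sa[i - 1], b = sa[i];
      int ra2 = (a + k < n) ? rnk[a + k] : -1;
      int rb2 = (b + k < n) ? rnk[b + k] : -1;
      rnk2[b] = rnk2[a] + ((rnk[a] != rnk[b] || ra2 != rb2) ? 1 : 0);
    }
    rnk.swap(rnk2);
    classes = rnk[sa[n - 1]] + 1;
  }
}

void build_lcp(const std::vector<int> &code, const std::vector<int> &sa,
               std::vector<int> &lcp) {
  const int n = (int) code.size();
  std::vector<int> rank_of(n);
  for (int i = 0; i < n; ++i) rank_of[sa[i]] = i;
  lcp.assign(n, 0); // lcp[i] = lcp(sa[i-1], sa[i]); lcp[0] unused
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_of[i] > 0) {
      int j = sa[rank_of[i] - 1];
      while (i + h < n && j + h < n && code[i + h] == code[j + h]) ++h;
      lcp[rank_of[i]] = h;
      if (h > 0) --h;
    } else h = 0;
  }
}

} // namespace

// [[Rcpp::export]]
DataFrame find_mums_cpp(CharacterVector ref_seqs, CharacterVector qry_seqs,
                        int min_len) {
  std::vector<CopyInfo> copies;
  std::vector<int> code;
  {
    size_t total = 0;
    for (R_xlen_t i = 0; i < ref_seqs.size(); ++i)
      total += LENGTH(STRING_ELT(ref_seqs, i)) + 1;
    for (R_xlen_t i = 0; i < qry_seqs.size(); ++i)
      total += 2 * (LENGTH(STRING_ELT(qry_seqs, i)) + 1);
    code.reserve(total);
  }
  int next_unique = 6; // 0..5 reserved (A,C,G,T use 2..5)
  auto push_seq = [&](const char *s, int len, int src, int seq, int strand,
                      bool rc) {
    CopyInfo ci;
    ci.start = (int) code.size();
    ci.len = len;
    ci.src = src;
    ci.seq = seq;
    ci.strand = strand;
    copies.push_back(ci);
    for (int i = 0; i < len; ++i) {
      char c = rc ? comp_base(s[len - 1 - i]) : s[i];
      int v;
      switch (c) {
      case 'A': v = 2; break;
      case 'C': v = 3; break;
      case 'G': v = 4; break;
      case 'T': v = 5; break;
      default:  v = next_unique++; break; // N and friends: never match
      }
      code.push_back(v);
    }
    code.push_back(next_unique++); // sentinel
  };
  for (R_xlen_t i = 0; i < ref_seqs.size(); ++i)
    push_seq(CHAR(STRING_ELT(ref_seqs, i)), LENGTH(STRING_ELT(ref_seqs, i)),
             0, (int) i, 0, false);
  for (R_xlen_t i = 0; i < qry_seqs.size(); ++i)
    push_seq(CHAR(STRING_ELT(qry_seqs, i)), LENGTH(STRING_ELT(qry_seqs, i)),
             1, (int) i, 0, false);
  for (R_xlen_t i = 0; i < qry_seqs.size(); ++i)
    push_seq(CHAR(STRING_ELT(qry_seqs, i)), LENGTH(STRING_ELT(qry_seqs, i)),
             1, (int) i, 1, true);

  const int n = (int) code.size();
  std::vector<int> sa, lcp;
  build_sa(code, sa);
  build_lcp(code, sa, lcp);

  // copy lookup by global position
  std::vector<int> copy_starts;
  copy_starts.reserve(copies.size());
  for (auto &c : copies) copy_starts.push_back(c.start);
  auto copy_of = [&](int pos) -> const CopyInfo & {
    int idx = (int) (std::upper_bound(copy_starts.begin(), copy_starts.end(),
                                      pos) - copy_starts.begin()) - 1;
    return copies[idx];
  };

  std::vector<int> o_rseq, o_rstart, o_qseq, o_qstart, o_len;
  std::vector<char> o_strand;
  for (int i = 1; i < n; ++i) {
    int L = lcp[i];
    if (L < min_len) continue;
    // unique: no neighbour shares a prefix this long
    if (i - 1 >= 1 && lcp[i - 1] >= L) continue;
    if (i + 1 <= n - 1 && lcp[i + 1] >= L) continue;
    int a = sa[i - 1], b = sa[i];
    const CopyInfo &ca = copy_of(a), &cb = copy_of(b);
    if (ca.src == cb.src) continue;
    // left-maximality (sentinel codes are unique, so boundaries always pass)
    if (a > 0 && b > 0 && code[a - 1] == code[b - 1]) continue;
    const CopyInfo &cr = (ca.src == 0) ? ca : cb;
    const CopyInfo &cq = (ca.src == 0) ? cb : ca;
    int pr = ((ca.src == 0) ? a : b) - cr.start;
    int pq = ((ca.src == 0) ? b : a) - cq.start;
    int qstart_fwd = (cq.strand == 0) ? pq : (cq.len - pq - L);
    o_rseq.push_back(cr.seq + 1);
    o_rstart.push_back(pr);
    o_qseq.push_back(cq.seq + 1);
    o_qstart.push_back(qstart_fwd);
    o_len.push_back(L);
    o_strand.push_back(cq.strand == 0 ? '+' : '-');
  }

  // sort by (ref seq, ref start, length)
  std::vector<int> ord(o_rseq.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int) i;
  std::sort(ord.begin(), ord.end(), [&](int x, int y) {
    if (o_rseq[x] != o_rseq[y]) return o_rseq[x] < o_rseq[y];
    if (o_rstart[x] != o_rstart[y]) return o_rstart[x] < o_rstart[y];
    if (o_qseq[x] != o_qseq[y]) return o_qseq[x] < o_qseq[y];
    return o_qstart[x] < o_qstart[y];
  });
  const int m = (int) ord.size();
  IntegerVector rseq(m), rstart(m), qseq(m), qstart(m), len(m);
  CharacterVector strand(m);
  for (int i = 0; i < m; ++i) {
    int j = ord[i];
    rseq[i] = o_rseq[j];
    rstart[i] = o_rstart[j];
    qseq[i] = o_qseq[j];
    qstart[i] = o_qstart[j];
    len[i] = o_len[j];
    strand[i] = std::string(1, o_strand[j]);
  }
  return DataFrame::create(_["ref_seq"] = rseq, _["ref_start"] = rstart,
                           _["qry_seq"] = qseq, _["qry_start"] = qstart,
                           _["length"] = len, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}
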