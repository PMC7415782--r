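#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Collinear chaining and gap-closing alignment for anchor-based whole-genome
// alignment. Query coordinates are expected in an orientation where both
// coordinates increase along a chain (reverse-strand anchors are mapped into
// revcomp space by the caller).

namespace {

struct Op { char op; int len; };

void push_op(std::vector<Op> &ops, char op, int len) {
  if (len <= 0) return;
  if (!ops.empty() && ops.back().op == op) ops.back().len += len;
  else ops.push_back({op, len});
}

// affine-gap global alignment, maximizing; exact DP over the full matrix.
// ops emitted over {=, X, I (qry-only), D (ref-only)}.
void nw_affine(const char *a, int n, const char *b, int m,
               int match, int mismatch, int gap_open, int gap_ext,
               std::vector<Op> &ops, long *score_out,
               long *nmatch_out, long *ncols_out) {
  const int NEG = INT_MIN / 4;
  const int W = m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG), Ix(M), Iy(M);
  // traceback: 2 bits per matrix cell state source
  std::vector<uint8_t> tbM((size_t)(n + 1) * W), tbX(tbM), tbY(tbM);
  M[0] = 0;
  for (int i = 1; i <= n; ++i) {
    Ix[(size_t)i * W] = -(gap_open + i * gap_ext);
    tbX[(size_t)i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -(gap_open + j * gap_ext);
    tbY[j] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t ro = (size_t)i * W, po = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : -mismatch;
      int d0 = M[po + j - 1], d1 = Ix[po + j - 1], d2 = Iy[po + j - 1];
      int best = d0; uint8_t tb = 0;
      if (d1 > best) { best = d1; tb = 1; }
      if (d2 > best) { best = d2; tb = 2; }
      if (best > NEG) { M[ro + j] = best + s; tbM[ro + j] = tb; }
      // Ix: gap in qry (consume ref, op D)
      int x0 = M[po + j] - gap_open - gap_ext, x1 = Ix[po + j] - gap_ext;
      if (x0 >= x1) { Ix[ro + j] = x0; tbX[ro + j] = 0; }
      else { Ix[ro + j] = x1; tbX[ro + j] = 1; }
      // Iy: gap in ref (consume qry, op I)
      int y0 = M[ro + j - 1] - gap_open - gap_ext, y1 = Iy[ro + j - 1] - gap_ext;
      if (y0 >= y1) { Iy[ro + j] = y0; tbY[ro + j] = 0; }
      else { Iy[ro + j] = y1; tbY[ro + j] = 1; }
    }
  }
  size_t end = (size_t)n * W + m;
  int state = 0, bestv = M[end];
  if (Ix[end] > bestv) { bestv = Ix[end]; state = 1; }
  if (Iy[end] > bestv) { bestv = Iy[end]; state = 2; }
  if (score_out) *score_out = bestv;
  std::vector<Op> rev;
  int i = n, j = m;
  long nmatch = 0, ncols = 0;
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      uint8_t tb = tbM[c];
      bool eq = (a[i - 1] == b[j - 1]);
      push_op(rev, eq ? '=' : 'X', 1);
      if (eq) ++nmatch;
      ++ncols; --i; --j; state = tb;
      if (i == 0 && j == 0) break;
      if (i == 0) state = 2;
      else if (j == 0) state = 1;
    } else if (state == 1) {
      uint8_t tb = tbX[c];
      push_op(rev, 'D', 1);
      ++ncols; --i; state = (tb == 1) ? 1 : 0;
      if (i == 0 && j > 0) state = 2;
    } else {
      uint8_t tb = tbY[c];
      push_op(rev, 'I', 1);
      ++ncols; --j; state = (tb == 1) ? 2 : 0;
      if (j == 0 && i > 0) state = 1;
    }
  }
  for (auto it = rev.rbegin(); it != rev.rend(); ++it)
    push_op(ops, it->op, it->len);
  if (nmatch_out) *nmatch_out = nmatch;
  if (ncols_out) *ncols_out = ncols;
}

std::string ops_to_string(const std::vector<Op> &ops) {
  std::string s;
  char buf[16];
  for (auto &o : ops) {
    snprintf(buf, sizeof(buf), "%d%c", o.len, o.op);
    s += buf;
  }
  return s;
}

} // namespace

// Single best maximum-weight collinear chain.
// Precedence: i before j iff all four coordinates strictly advance.
// Primary objective: total weight; secondary: minimal off-diagonal drift
// sum |ref_gap - qry_gap|; final tie: earlier predecessor index.
// [[Rcpp::export]]
List chain_best_cpp(IntegerVector rs, IntegerVector re,
                    IntegerVector qs, IntegerVector qe,
                    NumericVector w) {
  const int n = rs.size();
  if (n == 0) return List::create(_["weight"] = 0.0,
                                  _["idx"] = IntegerVector(0));
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (rs[a] != rs[b]) return rs[a] < rs[b];
    return qs[a] < qs[b];
  });
  std::vector<double> dpw(n), dpd(n);
  std::vector<int> prev(n, -1);
  double best = -1, best_d = 0; int besti = -1;
  for (int jj = 0; jj < n; ++jj) {
    int j = ord[jj];
    dpw[j] = w[j]; dpd[j] = 0;
    for (int ii = 0; ii < jj; ++ii) {
      int i = ord[ii];
      if (rs[i] < rs[j] && qs[i] < qs[j] && re[i] < re[j] && qe[i] < qe[j]) {
        double drift = std::abs((double)(rs[j] - re[i]) -
                                (double)(qs[j] - qe[i]));
        double cw = dpw[i] + w[j], cd = dpd[i] + drift;
        if (cw > dpw[j] + 1e-9 ||
            (cw > dpw[j] - 1e-9 && cd < dpd[j] - 1e-9)) {
          dpw[j] = cw; dpd[j] = cd; prev[j] = i;
        }
      }
    }
    if (dpw[j] > best + 1e-9 ||
        (dpw[j] > best - 1e-9 && dpd[j] < best_d - 1e-9)) {
      best = dpw[j]; best_d = dpd[j]; besti = j;
    }
  }
  std::vector<int> chain;
  for (int v = besti; v >= 0; v = prev[v]) chain.push_back(v + 1);
  std::reverse(chain.begin(), chain.end());
  return List::create(_["weight"] = best,
                      _["idx"] = IntegerVector(chain.begin(), chain.end()));
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = 1,
                  int gap_open = 4, int gap_ext = 1) {
  std::vector<Op> ops;
  long score = 0, nmatch = 0, ncols = 0;
  nw_affine(a.c_str(), (int) a.size(), b.c_str(), (int) b.size(),
            match, mismatch, gap_open, gap_ext, ops, &score, &nmatch, &ncols);
  return List::create(_["path"] = ops_to_string(ops),
                      _["score"] = (double) score,
                      _["n_match"] = (double) nmatch,
                      _["aligned_columns"] = (double) ncols);
}

// Assemble alignment blocks from one chain of anchors over one
// (ref chromosome, qry chromosome, strand) triple. Coordinates of anchors are
// in chain orientation (qry revcomp space for '-'); qry_seq must already be
// reverse-complemented for '-' chains. Splits at large or band-exceeding
// gaps; closes the rest with affine-gap DP.
// [[Rcpp::export]]
List build_blocks_cpp(std::string ref_seq, std::string qry_seq,
                      IntegerVector rs_in, IntegerVector qs_in,
                      IntegerVector len_in,
                      int max_gap, int band,
                      int match = 1, int mismatch = 1,
                      int gap_open = 4, int gap_ext = 1) {
  const int n = rs_in.size();
  // trim anchor overlaps against the previous kept anchor
  std::vector<int> rs, qs, ln;
  int prev_re = -1, prev_qe = -1;
  for (int i = 0; i < n; ++i) {
    int r = rs_in[i], q = qs_in[i], l = len_in[i];
    if (prev_re >= 0) {
      int d = std::max(0, std::max(prev_re - r, prev_qe - q));
      r += d; q += d; l -= d;
    }
    if (l <= 0) continue;
    rs.push_back(r); qs.push_back(q); ln.push_back(l);
    prev_re = r + l; prev_qe = q + l;
  }
  List out;
  if (rs.empty()) return out;
  // segment boundaries where gaps are unbridgeable
  std::vector<int> seg_start{0};
  std::vector<int> seg_end;
  for (size_t i = 1; i < rs.size(); ++i) {
    int rgap = rs[i] - (rs[i - 1] + ln[i - 1]);
    int qgap = qs[i] - (qs[i - 1] + ln[i - 1]);
    if (rgap > max_gap || qgap > max_gap ||
        std::abs(rgap - qgap) > band) {
      seg_end.push_back((int) i - 1);
      seg_start.push_back((int) i);
    }
  }
  seg_end.push_back((int) rs.size() - 1);
  for (size_t s = 0; s < seg_start.size(); ++s) {
    int a = seg_start[s], b = seg_end[s];
    std::vector<Op> ops;
    long nmatch = 0, ncols = 0;
    push_op(ops, '=', ln[a]);
    nmatch += ln[a]; ncols += ln[a];
    for (int i = a + 1; i <= b; ++i) {
      int rgap = rs[i] - (rs[i - 1] + ln[i - 1]);
      int qgap = qs[i] - (qs[i - 1] + ln[i - 1]);
      if (rgap > 0 && qgap == 0) { push_op(ops, 'D', rgap); ncols += rgap; }
      else if (rgap == 0 && qgap > 0) { push_op(ops, 'I', qgap); ncols += qgap; }
      else if (rgap > 0 && qgap > 0) {
        long nm = 0, nc = 0;
        nw_affine(ref_seq.c_str() + rs[i - 1] + ln[i - 1], rgap,
                  qry_seq.c_str() + qs[i - 1] + ln[i - 1], qgap,
                  match, mismatch, gap_open, gap_ext, ops,
                  nullptr, &nm, &nc);
        nmatch += nm; ncols += nc;
      }
      push_op(ops, '=', ln[i]);
      nmatch += ln[i]; ncols += ln[i];
    }
    out.push_back(List::create(
        _["ref_start"] = rs[a],
        _["ref_end"] = rs[b] + ln[b],
        _["qry_start"] = qs[a],
        _["qry_end"] = qs[b] + ln[b],
        _["n_match"] = (double) nmatch,
        _["aligned_columns"] = (double) ncols,
        _["edit_path"] = ops_to_string(ops)));
  }
  return out;
}
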