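#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---- base-level helpers ----------------------------------------------------

static inline char upbase(char c) {
  return (c >= 'a' && c <= 'z') ? (char)(c - 32) : c;
}

// Watson-Crick complementarity at the DNA level. IUPAC ambiguity codes
// (including N) never pair; wobble is excluded in the DNA search.
static inline bool wc_pair(char a, char b) {
  a = upbase(a); b = upbase(b);
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'C' && b == 'G') || (a == 'G' && b == 'C');
}

// Pairing rule for the fallback fold: optionally U-aware and wobble-aware.
static inline bool fold_pair(char a, char b, bool rna) {
  a = upbase(a); b = upbase(b);
  if (a == 'U') a = 'T';
  if (b == 'U') b = 'T';
  if (wc_pair(a, b)) return true;
  if (rna && ((a == 'G' && b == 'T') || (a == 'T' && b == 'G'))) return true;
  return false;
}

static inline char comp_base(char c) {
  switch (upbase(c)) {
  case 'A': return 'T';
  case 'T': return 'A';
  case 'C': return 'G';
  case 'G': return 'C';
  default:  return upbase(c); // ambiguity codes map to themselves: never pair
  }
}

static std::string comp_string(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) out[i] = comp_base(s[i]);
  return out;
}

// ---- minimum-penalty DP over two candidate arms ----------------------------
//
// M is stored row-major with (na+1) rows and (nb+1) cols; row r / col c are
// 0-based here and correspond to matrix coordinates (r+1, c+1) in the 1-based
// convention of the user-facing matrix. Header row/column hold cumulative gap
// penalties (coordinates 0,1,2,... when gap = 1).

struct Penalties { int match, mismatch, gap; };

static void dp_fill_core(const std::string &a, const std::string &b,
                         const Penalties &p, std::vector<int> &M) {
  const int na = (int)a.size(), nb = (int)b.size();
  M.assign((size_t)(na + 1) * (nb + 1), 0);
  for (int c = 0; c <= nb; ++c) M[c] = c * p.gap;
  for (int r = 1; r <= na; ++r) {
    int *row = &M[(size_t)r * (nb + 1)];
    const int *prev = &M[(size_t)(r - 1) * (nb + 1)];
    row[0] = r * p.gap;
    const char ca = a[r - 1];
    for (int c = 1; c <= nb; ++c) {
      int s = wc_pair(ca, b[c - 1]) ? p.match : p.mismatch;
      int best = prev[c - 1] + s;            // pair or mismatch
      int up   = prev[c] + p.gap;            // gap in arm B (consumes A)
      int left = row[c - 1] + p.gap;         // gap in arm A (consumes B)
      if (up < best) best = up;
      if (left < best) best = left;
      row[c] = best;
    }
  }
}

// Strand-equivariant content comparison used only to break residual ties.
// Compares the unordered pair {armA prefix, complement(armB) prefix} of the
// two candidate cells lexicographically; under reverse-complementation the
// two prefixes swap roles, so the comparison transposes with the matrix.
static int content_cmp(const std::string &a, const std::string &cb,
                       int r1, int c1, int r2, int c2) {
  std::string u1 = a.substr(0, r1), w1 = cb.substr(0, c1);
  std::string u2 = a.substr(0, r2), w2 = cb.substr(0, c2);
  if (w1 < u1) std::swap(u1, w1);
  if (w2 < u2) std::swap(u2, w2);
  if (u1 != u2) return u1 < u2 ? -1 : 1;
  if (w1 != w2) return w1 < w2 ? -1 : 1;
  return 0;
}

// Start-cell selection: maximise min(r,c) subject to M <= max_mismatch and
// min(r,c) >= min_stem; ties by lowest M, lowest max(r,c), then the
// strand-equivariant content comparison, finally lowest r.
static bool select_start_core(const std::vector<int> &M,
                              const std::string &a, const std::string &b,
                              int max_mismatch, int min_stem,
                              int &out_r, int &out_c) {
  const int na = (int)a.size(), nb = (int)b.size();
  std::string cb; // complement of b, built lazily for rare content ties
  bool have_cb = false;
  int br = -1, bc = -1;
  for (int r = 1; r <= na; ++r) {
    for (int c = 1; c <= nb; ++c) {
      int v = M[(size_t)r * (nb + 1) + c];
      if (v > max_mismatch) continue;
      int mn = std::min(r, c);
      if (mn < min_stem) continue;
      if (br < 0) { br = r; bc = c; continue; }
      int bmn = std::min(br, bc);
      if (mn != bmn) { if (mn > bmn) { br = r; bc = c; } continue; }
      int bv = M[(size_t)br * (nb + 1) + bc];
      if (v != bv) { if (v < bv) { br = r; bc = c; } continue; }
      int mx = std::max(r, c), bmx = std::max(br, bc);
      if (mx != bmx) { if (mx < bmx) { br = r; bc = c; } continue; }
      if (!have_cb) { cb = comp_string(b); have_cb = true; }
      int cc = content_cmp(a, cb, r, c, br, bc);
      if (cc != 0) { if (cc < 0) { br = r; bc = c; } continue; }
      if (r < br) { br = r; bc = c; }
    }
  }
  if (br < 0) return false;
  out_r = br; out_c = bc;
  return true;
}

// Traceback from (r0,c0) to (0,0), choosing at each step the predecessor
// consistent with the recurrence with minimal value; ties prefer the
// diagonal, then (between the two gap moves) the strand-equivariant content
// comparison of the remaining prefixes. Events, loop-outward order:
//   'P' complementary pair, 'M' mismatch,
//   'A' gap in arm A (consumes B), 'B' gap in arm B (consumes A).
// Returns false when the loop-closing rung is not a complementary pair.
static bool traceback_core(const std::vector<int> &M,
                           const std::string &a, const std::string &b,
                           const Penalties &p, int r0, int c0,
                           std::string &events_out) {
  const int nb = (int)b.size();
  std::string cb = comp_string(b);
  std::string ev;
  int r = r0, c = c0;
  while (r > 0 || c > 0) {
    const int here = M[(size_t)r * (nb + 1) + c];
    bool diag = false, up = false, left = false;
    int dv = 0, uv = 0, lv = 0;
    if (r > 0 && c > 0) {
      int s = wc_pair(a[r - 1], b[c - 1]) ? p.match : p.mismatch;
      dv = M[(size_t)(r - 1) * (nb + 1) + (c - 1)];
      diag = (here == dv + s);
    }
    if (r > 0) { uv = M[(size_t)(r - 1) * (nb + 1) + c]; up = (here == uv + p.gap); }
    if (c > 0) { lv = M[(size_t)r * (nb + 1) + (c - 1)]; left = (here == lv + p.gap); }
    if (!diag && !up && !left)
      stop("internal error: inconsistent alignment matrix during traceback");
    int best = INT_MAX;
    if (diag) best = std::min(best, dv);
    if (up)   best = std::min(best, uv);
    if (left) best = std::min(best, lv);
    char move;
    if (diag && dv == best) {
      move = wc_pair(a[r - 1], b[c - 1]) ? 'P' : 'M';
      --r; --c;
    } else if (up && uv == best && left && lv == best) {
      // strand-equivariant gap tie-break
      std::string u = a.substr(0, r), w = cb.substr(0, c);
      if (u <= w) { move = 'B'; --r; } else { move = 'A'; --c; }
    } else if (up && uv == best) {
      move = 'B'; --r;
    } else {
      move = 'A'; --c;
    }
    ev.push_back(move);
  }
  std::reverse(ev.begin(), ev.end());
  if (ev.empty() || ev[0] != 'P') return false;
  events_out = ev;
  return true;
}

// ---- exported wrappers -----------------------------------------------------

// [[Rcpp::export(name = ".dp_fill_cpp")]]
IntegerMatrix dp_fill_cpp(std::string arm_a, std::string arm_b,
                          int match, int mismatch, int gap) {
  Penalties p{match, mismatch, gap};
  std::vector<int> M;
  dp_fill_core(arm_a, arm_b, p, M);
  const int na = (int)arm_a.size(), nb = (int)arm_b.size();
  IntegerMatrix out(na + 1, nb + 1);
  for (int r = 0; r <= na; ++r)
    for (int c = 0; c <= nb; ++c)
      out(r, c) = M[(size_t)r * (nb + 1) + c];
  return out;
}

// [[Rcpp::export(name = ".select_start_cpp")]]
IntegerVector select_start_cpp(IntegerMatrix M, std::string arm_a,
                               std::string arm_b, int max_mismatch,
                               int min_stem) {
  const int na = (int)arm_a.size(), nb = (int)arm_b.size();
  std::vector<int> v((size_t)(na + 1) * (nb + 1));
  for (int r = 0; r <= na; ++r)
    for (int c = 0; c <= nb; ++c)
      v[(size_t)r * (nb + 1) + c] = M(r, c);
  int r, c;
  if (!select_start_core(v, arm_a, arm_b, max_mismatch, min_stem, r, c))
    return IntegerVector::create(0, 0);
  return IntegerVector::create(r + 1, c + 1); // 1-based matrix coordinates
}

// [[Rcpp::export(name = ".traceback_cpp")]]
SEXP traceback_cpp(IntegerMatrix M, std::string arm_a, std::string arm_b,
                   int i, int j, int match, int mismatch, int gap) {
  const int na = (int)arm_a.size(), nb = (int)arm_b.size();
  if (i < 2 || j < 2 || i > na + 1 || j > nb + 1)
    stop("start cell (%d, %d) is not an interior cell", i, j);
  std::vector<int> v((size_t)(na + 1) * (nb + 1));
  for (int r = 0; r <= na; ++r)
    for (int c = 0; c <= nb; ++c)
      v[(size_t)r * (nb + 1) + c] = M(r, c);
  Penalties p{match, mismatch, gap};
  std::string ev;
  if (!traceback_core(v, arm_a, arm_b, p, i - 1, j - 1, ev))
    return R_NilValue;
  return List::create(_["events"] = ev,
                      _["penalty"] = M(i - 1, j - 1),
                      _["len_a"] = i - 1,
                      _["len_b"] = j - 1);
}

// Scan one sequence: enumerate candidate loop spans, run the DP on the
// flanking arm windows, and collect accepted hits. Coordinates returned
// 1-based inclusive. Deduplication and sorting happen on the R side.
// [[Rcpp::export(name = ".scan_cpp")]]
DataFrame scan_cpp(std::string seq, int min_stem, int max_stem,
                   int min_loop, int max_loop, int max_mismatch,
                   int match, int mismatch, int gap) {
  const int L = (int)seq.size();
  Penalties p{match, mismatch, gap};
  std::vector<int> ls, le, los, loe, rs, re, pen, stem;
  std::vector<std::string> evs;
  std::vector<int> M;
  std::string armA, armB;
  for (int llen = min_loop; llen <= max_loop; ++llen) {
    for (int a = min_stem; a + llen + min_stem <= L; ++a) {
      const int b = a + llen; // loop occupies [a, b) 0-based
      const int ka = std::min(a, max_stem);
      const int kb = std::min(L - b, max_stem);
      armA.assign((size_t)ka, 'N');
      for (int t = 0; t < ka; ++t) armA[t] = upbase(seq[a - 1 - t]);
      armB.assign(seq, b, kb);
      for (int t = 0; t < kb; ++t) armB[t] = upbase(armB[t]);
      if (!wc_pair(armA[0], armB[0])) continue; // loop-closing rung must pair
      dp_fill_core(armA, armB, p, M);
      int r, c;
      if (!select_start_core(M, armA, armB, max_mismatch, min_stem, r, c))
        continue;
      std::string ev;
      if (!traceback_core(M, armA, armB, p, r, c, ev)) continue;
      const int lenA = r, lenB = c;
      ls.push_back(a - lenA + 1);
      le.push_back(a);
      los.push_back(a + 1);
      loe.push_back(b);
      rs.push_back(b + 1);
      re.push_back(b + lenB);
      pen.push_back(M[(size_t)r * (armB.size() + 1) + c]);
      stem.push_back(std::min(lenA, lenB));
      evs.push_back(ev);
    }
  }
  return DataFrame::create(
    _["left_start"] = ls, _["left_end"] = le,
    _["loop_start"] = los, _["loop_end"] = loe,
    _["right_start"] = rs, _["right_end"] = re,
    _["stem_len"] = stem, _["penalty"] = pen,
    _["events"] = evs, _["stringsAsFactors"] = false);
}

// ---- fallback fold: nested base-pair maximisation --------------------------
//
// Interval DP maximising the number of admissible pairs subject to hairpin
// loops of at least min_loop unpaired bases. Traceback prefers pairing the
// leftmost base (pairs closing earlier) with its nearest admissible partner
// (shorter spans), giving a deterministic structure.
// [[Rcpp::export(name = ".fold_cpp")]]
IntegerVector fold_cpp(std::string seq, int min_loop, bool rna) {
  const int n = (int)seq.size();
  if (n > 5000) stop("fallback fold supports sequences up to 5000 bases");
  IntegerVector pt(n, 0); // 1-based partner, 0 = unpaired
  if (n == 0) return pt;
  std::vector<int> N((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return N[(size_t)i * n + j]; };
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = at(i + 1, j); // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!fold_pair(seq[i], seq[k], rna)) continue;
        int v = 1 + (k - i >= 2 ? at(i + 1, k - 1) : 0) +
                (k + 1 <= j ? at(k + 1, j) : 0);
        if (v > best) best = v;
      }
      at(i, j) = best;
    }
  }
  // iterative traceback
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_loop + 1) continue;
    int target = at(i, j);
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!fold_pair(seq[i], seq[k], rna)) continue;
      int v = 1 + (k - i >= 2 ? at(i + 1, k - 1) : 0) +
              (k + 1 <= j ? at(k + 1, j) : 0);
      if (v == target) {
        pt[i] = k + 1;
        pt[k] = i + 1;
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return pt;
}
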