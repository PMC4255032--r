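#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap alignment kernels.
//
// cpp_xdrop_extend: banded seed-and-extend with x-drop termination, the
//   workhorse behind repeat annotation and copy-number scanning.
// cpp_align_full: plain full-matrix affine DP (global or local) with
//   traceback; used as an independent dynamic-programming reference in the
//   test suite and for small structural comparisons.
//
// Gap cost convention: a gap of length L costs gapOpen + gapExt * L
// (matching the Biostrings gapOpening/gapExtension convention).

static const int NEG_INF = -1000000000;

struct ExtRes {
  int ai;       // chars of a consumed
  int bj;       // chars of b consumed
  int score;
  int matches;
  int mismatches;
};

// Extend an alignment over prefixes of a and b, anchored at (0,0).
// Banded: |i - j| <= band. Terminates a row when its best cell drops more
// than xdrop below the best score seen so far.
static ExtRes extend_prefix(const std::string& a, const std::string& b,
                            int match, int mismatch,
                            int gapOpen, int gapExt,
                            int xdrop, int band) {
  ExtRes res = {0, 0, 0, 0, 0};
  int nA = (int)a.size(), nB = (int)b.size();
  // extension cannot usefully run past the band around the seed diagonal
  if (nA > nB + band) nA = nB + band;
  if (nB > nA + band) nB = nA + band;
  if (nA == 0 && nB == 0) return res;

  const int go = gapOpen + gapExt;  // cost of the first gap column
  const int W = 2 * band + 1;

  std::vector<int> Hprev(nB + 1, NEG_INF), Eprev(nB + 1, NEG_INF);
  std::vector<int> Hcur(nB + 1, NEG_INF), Ecur(nB + 1, NEG_INF),
      Fcur(nB + 1, NEG_INF);
  // traceback, band-compressed: tb[i*W + (j - (i - band))]
  // bits 0-1: H origin (0 = cell (0,0), 1 = diagonal, 2 = E/vertical,
  //           3 = F/horizontal); bit 2: E extends E; bit 3: F extends F
  std::vector<unsigned char> tb((size_t)(nA + 1) * W, 0);
  auto TB = [&](int i, int j) -> unsigned char& {
    return tb[(size_t)i * W + (j - (i - band))];
  };

  int best = 0, bi = 0, bj = 0;

  // row 0
  {
    int jhi = std::min(nB, band);
    Hcur[0] = 0;
    for (int j = 1; j <= jhi; ++j) {
      int fromH = Hcur[j - 1] - go;
      int fromF = Fcur[j - 1] - gapExt;
      if (fromF > fromH) { Fcur[j] = fromF; TB(0, j) |= 8; }
      else Fcur[j] = fromH;
      Hcur[j] = Fcur[j];
      TB(0, j) |= 3;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  for (int i = 1; i <= nA; ++i) {
    int jlo = std::max(0, i - band);
    int jhi = std::min(nB, i + band);
    if (jlo > jhi) break;
    std::fill(Hcur.begin(), Hcur.end(), NEG_INF);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    int rowmax = NEG_INF;
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char t = 0;
      // E: gap in b (consume a), from previous row
      int e = NEG_INF;
      {
        int fromH = (Hprev[j] > NEG_INF / 2) ? Hprev[j] - go : NEG_INF;
        int fromE = (Eprev[j] > NEG_INF / 2) ? Eprev[j] - gapExt : NEG_INF;
        if (fromE > fromH) { e = fromE; t |= 4; }
        else e = fromH;
      }
      Ecur[j] = e;
      // F: gap in a (consume b), from current row
      int f = NEG_INF;
      if (j > jlo) {
        int fromH = (Hcur[j - 1] > NEG_INF / 2) ? Hcur[j - 1] - go : NEG_INF;
        int fromF = (Fcur[j - 1] > NEG_INF / 2) ? Fcur[j - 1] - gapExt : NEG_INF;
        if (fromF > fromH) { f = fromF; t |= 8; }
        else f = fromH;
      }
      Fcur[j] = f;
      // H
      int h = NEG_INF;
      int dir = 0;
      if (j > 0 && Hprev[j - 1] > NEG_INF / 2) {
        int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
        h = Hprev[j - 1] + s;
        dir = 1;
      }
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      if (h < best - xdrop) {  // x-drop prune
        Hcur[j] = NEG_INF; Ecur[j] = NEG_INF; Fcur[j] = NEG_INF;
        continue;
      }
      t |= (unsigned char)dir;
      TB(i, j) = t;
      Hcur[j] = h;
      if (h > rowmax) rowmax = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    if (rowmax < best - xdrop) break;
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  // traceback from the best cell, counting matches / mismatches
  int i = bi, j = bj, m = 0, mm = 0;
  while (i > 0 || j > 0) {
    unsigned char t = TB(i, j);
    int dir = t & 3;
    if (dir == 1) {
      if (a[i - 1] == b[j - 1]) ++m; else ++mm;
      --i; --j;
    } else if (dir == 2) {
      // vertical run
      while (true) {
        bool ext = (TB(i, j) & 4) != 0;
        --i;
        if (!ext || i == 0) break;
      }
    } else if (dir == 3) {
      while (true) {
        bool ext = (TB(i, j) & 8) != 0;
        --j;
        if (!ext || j == 0) break;
      }
    } else {
      break;  // origin
    }
  }
  res.ai = bi; res.bj = bj; res.score = best;
  res.matches = m; res.mismatches = mm;
  return res;
}

// [[Rcpp::export]]
List cpp_xdrop_extend(std::string a, std::string b,
                      int aPos, int bPos, int k,
                      int match, int mismatch,
                      int gapOpen, int gapExt,
                      int xdrop, int band) {
  int nA = (int)a.size(), nB = (int)b.size();
  if (aPos < 1 || bPos < 1 || aPos + k - 1 > nA || bPos + k - 1 > nB)
    stop("anchor out of bounds");
  // left: reversed prefixes
  std::string aL(a.rbegin() + (nA - (aPos - 1)), a.rend());
  std::string bL(b.rbegin() + (nB - (bPos - 1)), b.rend());
  // right: suffixes after the seed
  std::string aR = a.substr(aPos + k - 1);
  std::string bR = b.substr(bPos + k - 1);

  ExtRes L = extend_prefix(aL, bL, match, mismatch, gapOpen, gapExt,
                           xdrop, band);
  ExtRes R = extend_prefix(aR, bR, match, mismatch, gapOpen, gapExt,
                           xdrop, band);

  int matches = k + L.matches + R.matches;
  int mismatches = L.mismatches + R.mismatches;
  int score = k * match + L.score + R.score;
  int aStart = aPos - L.ai, aEnd = aPos + k - 1 + R.ai;
  int bStart = bPos - L.bj, bEnd = bPos + k - 1 + R.bj;
  double identity = (matches + mismatches > 0)
      ? (double)matches / (double)(matches + mismatches) : 0.0;
  return List::create(
      _["a_start"] = aStart, _["a_end"] = aEnd,
      _["b_start"] = bStart, _["b_end"] = bEnd,
      _["score"] = score, _["matches"] = matches,
      _["mismatches"] = mismatches, _["identity"] = identity);
}

// [[Rcpp::export]]
List cpp_align_full(std::string a, std::string b,
                    int match, int mismatch,
                    int gapOpen, int gapExt,
                    bool local) {
  int n = (int)a.size(), m = (int)b.size();
  if ((double)(n + 1) * (double)(m + 1) > 1.2e8)
    stop("sequences too long for full DP");
  const int go = gapOpen + gapExt;
  size_t ncell = (size_t)(n + 1) * (m + 1);
  std::vector<int> H(ncell), E(ncell), F(ncell);
  std::vector<unsigned char> tb(ncell, 0);
  auto IX = [&](int i, int j) { return (size_t)i * (m + 1) + j; };

  H[IX(0, 0)] = 0; E[IX(0, 0)] = NEG_INF; F[IX(0, 0)] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    F[IX(0, j)] = (j == 1) ? -go : F[IX(0, j - 1)] - gapExt;
    if (j > 1) tb[IX(0, j)] |= 8;
    E[IX(0, j)] = NEG_INF;
    H[IX(0, j)] = local ? 0 : F[IX(0, j)];
    if (!local) tb[IX(0, j)] |= 3;
  }
  for (int i = 1; i <= n; ++i) {
    E[IX(i, 0)] = (i == 1) ? -go : E[IX(i - 1, 0)] - gapExt;
    if (i > 1) tb[IX(i, 0)] |= 4;
    F[IX(i, 0)] = NEG_INF;
    H[IX(i, 0)] = local ? 0 : E[IX(i, 0)];
    if (!local) tb[IX(i, 0)] |= 2;
  }

  int best = 0, bi = n, bj = m;
  if (local) { best = 0; bi = 0; bj = 0; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      unsigned char t = 0;
      int e, f, h, dir;
      {
        int fromH = H[IX(i - 1, j)] - go;
        int fromE = (E[IX(i - 1, j)] > NEG_INF / 2) ? E[IX(i - 1, j)] - gapExt
                                                    : NEG_INF;
        if (fromE > fromH) { e = fromE; t |= 4; } else e = fromH;
      }
      {
        int fromH = H[IX(i, j - 1)] - go;
        int fromF = (F[IX(i, j - 1)] > NEG_INF / 2) ? F[IX(i, j - 1)] - gapExt
                                                    : NEG_INF;
        if (fromF > fromH) { f = fromF; t |= 8; } else f = fromH;
      }
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      h = H[IX(i - 1, j - 1)] + s; dir = 1;
      if (e > h) { h = e; dir = 2; }
      if (f > h) { h = f; dir = 3; }
      if (local && h < 0) { h = 0; dir = 0; }
      t |= (unsigned char)dir;
      E[IX(i, j)] = e; F[IX(i, j)] = f; H[IX(i, j)] = h; tb[IX(i, j)] = t;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (!local) best = H[IX(n, m)];

  // traceback
  std::string alA, alB;
  int i = bi, j = bj, mcount = 0, mmcount = 0, gapcols = 0;
  while (i > 0 || j > 0) {
    unsigned char t = tb[IX(i, j)];
    int dir = t & 3;
    if (local && dir == 0) break;
    if (dir == 0) break;
    if (dir == 1) {
      alA.push_back(a[i - 1]); alB.push_back(b[j - 1]);
      if (a[i - 1] == b[j - 1]) ++mcount; else ++mmcount;
      --i; --j;
    } else if (dir == 2) {
      while (true) {
        bool ext = (tb[IX(i, j)] & 4) != 0;
        alA.push_back(a[i - 1]); alB.push_back('-'); ++gapcols;
        --i;
        if (!ext || i == 0) break;
      }
    } else {
      while (true) {
        bool ext = (tb[IX(i, j)] & 8) != 0;
        alA.push_back('-'); alB.push_back(b[j - 1]); ++gapcols;
        --j;
        if (!ext || j == 0) break;
      }
    }
  }
  int aStart = i + 1, bStart = j + 1;
  std::reverse(alA.begin(), alA.end());
  std::reverse(alB.begin(), alB.end());
  double identity = (mcount + mmcount > 0)
      ? (double)mcount / (double)(mcount + mmcount) : 0.0;
  return List::create(
      _["score"] = best,
      _["aligned_a"] = alA, _["aligned_b"] = alB,
      _["a_start"] = aStart, _["a_end"] = bi,
      _["b_start"] = bStart, _["b_end"] = bj,
      _["matches"] = mcount, _["mismatches"] = mmcount,
      _["gap_cols"] = gapcols, _["identity"] = identity);
}
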