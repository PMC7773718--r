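#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double NEG = -1e18;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// substitution score: identities of unambiguous bases score `match`;
// any comparison involving a non-ACGT code is treated as a mismatch
static inline double subst(char x, char y, double match, double mismatch) {
  if (x == y && is_acgt(x)) return match;
  return mismatch;
}

static inline char wc_complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Needleman-Wunsch / Gotoh global alignment with affine gaps.
// A gap of length L costs gap_open + gap_extend * L.
// States: M (diagonal), X (gap in b, consumes a), Y (gap in a, consumes b).
// Ties are broken deterministically: M preferred over X over Y, both when
// selecting a predecessor state and when selecting the final state.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const size_t n = a.size(), m = b.size();
  const double go = gap_open + gap_extend;  // cost of opening (first gapped base)
  const double ge = gap_extend;

  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<double> Mc(m + 1), Xc(m + 1), Yc(m + 1);
  // predecessor state per cell and state: 0 = M, 1 = X, 2 = Y
  std::vector<uint8_t> pM((n + 1) * (m + 1)), pX((n + 1) * (m + 1)), pY((n + 1) * (m + 1));
  const size_t W = m + 1;

  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (size_t j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = -(go + ge * (double)(j - 1));
    pY[j] = (j == 1) ? 0 : 2;
  }
  for (size_t i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = -(go + ge * (double)(i - 1));
    pX[i * W] = (i == 1) ? 0 : 1;
    for (size_t j = 1; j <= m; ++j) {
      // M: diagonal from best of M/X/Y at (i-1, j-1)
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double bm = Mp[j - 1]; uint8_t bs = 0;
      if (Xp[j - 1] > bm) { bm = Xp[j - 1]; bs = 1; }
      if (Yp[j - 1] > bm) { bm = Yp[j - 1]; bs = 2; }
      Mc[j] = bm + s; pM[i * W + j] = bs;
      // X: gap in b, from (i-1, j)
      double xm = Mp[j] - go; uint8_t xs = 0;
      if (Xp[j] - ge > xm) { xm = Xp[j] - ge; xs = 1; }
      if (Yp[j] - go > xm) { xm = Yp[j] - go; xs = 2; }
      Xc[j] = xm; pX[i * W + j] = xs;
      // Y: gap in a, from (i, j-1)
      double ym = Mc[j - 1] - go; uint8_t ys = 0;
      if (Xc[j - 1] - go > ym) { ym = Xc[j - 1] - go; ys = 1; }
      if (Yc[j - 1] - ge > ym) { ym = Yc[j - 1] - ge; ys = 2; }
      Yc[j] = ym; pY[i * W + j] = ys;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double best = Mp[m]; uint8_t state = 0;
  if (Xp[m] > best) { best = Xp[m]; state = 1; }
  if (Yp[m] > best) { best = Yp[m]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = pM[i * W + j]; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = pX[i * W + j]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = pY[i * W + j]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = best);
}

// Exhaustive enumeration of all global alignments (testing oracle).
// Independent of the dynamic-programming route above: walks every monotone
// path through the edit lattice, carrying the affine gap state.
static double bf_rec(const std::string& a, const std::string& b,
                     size_t i, size_t j, int last,
                     double acc, double match, double mismatch,
                     double go, double ge) {
  if (i == a.size() && j == b.size()) return acc;
  double best = NEG;
  if (i < a.size() && j < b.size()) {
    double v = bf_rec(a, b, i + 1, j + 1, 0,
                      acc + subst(a[i], b[j], match, mismatch),
                      match, mismatch, go, ge);
    best = std::max(best, v);
  }
  if (i < a.size()) {
    double cost = (last == 1) ? ge : go;
    best = std::max(best, bf_rec(a, b, i + 1, j, 1, acc - cost,
                                 match, mismatch, go, ge));
  }
  if (j < b.size()) {
    double cost = (last == 2) ? ge : go;
    best = std::max(best, bf_rec(a, b, i, j + 1, 2, acc - cost,
                                 match, mismatch, go, ge));
  }
  return best;
}

// [[Rcpp::export(name = ".brute_force_align_score")]]
double brute_force_align_score(std::string a, std::string b,
                               double match, double mismatch,
                               double gap_open, double gap_extend) {
  if (a.size() > 12 || b.size() > 12)
    stop("brute-force enumeration is limited to sequences of <= 12 nt");
  return bf_rec(a, b, 0, 0, -1, 0.0, match, mismatch,
                gap_open + gap_extend, gap_extend);
}

// Overlap-merge paired reads. Mate 2 is reverse-complemented internally so
// both mates are compared in plus orientation. Chooses the overlap
// maximizing the number of matching bases among overlaps with mismatch
// fraction <= max_mismatch_frac and length >= min_overlap; ties go to the
// longer overlap. Disagreements take the higher-quality base (mate 1 on
// quality ties).
// [[Rcpp::export(name = ".merge_read_pairs")]]
List merge_read_pairs(CharacterVector seq1, CharacterVector qual1,
                      CharacterVector seq2, CharacterVector qual2,
                      int min_overlap, double max_mismatch_frac) {
  const R_xlen_t nr = seq1.size();
  CharacterVector mseq(nr), mqual(nr);
  IntegerVector overlap(nr);
  LogicalVector ok(nr);
  for (R_xlen_t r = 0; r < nr; ++r) {
    std::string s1 = as<std::string>(seq1[r]);
    std::string q1 = as<std::string>(qual1[r]);
    std::string s2 = as<std::string>(seq2[r]);
    std::string q2 = as<std::string>(qual2[r]);
    std::reverse(s2.begin(), s2.end());
    for (size_t t = 0; t < s2.size(); ++t) s2[t] = wc_complement(s2[t]);
    std::reverse(q2.begin(), q2.end());
    const int l1 = (int)s1.size(), l2 = (int)s2.size();
    int bestL = -1, bestMatches = -1;
    const int maxL = std::min(l1, l2);
    for (int L = maxL; L >= min_overlap; --L) {
      int matches = 0;
      const int off = l1 - L;
      for (int k = 0; k < L; ++k) if (s1[off + k] == s2[k]) ++matches;
      double mmfrac = (double)(L - matches) / (double)L;
      if (mmfrac <= max_mismatch_frac && matches > bestMatches) {
        bestMatches = matches; bestL = L;
      }
    }
    if (bestL < 0) {
      mseq[r] = NA_STRING; mqual[r] = NA_STRING;
      overlap[r] = NA_INTEGER; ok[r] = false;
      continue;
    }
    const int off = l1 - bestL;
    std::string seq = s1.substr(0, off);
    std::string qual = q1.substr(0, off);
    for (int k = 0; k < bestL; ++k) {
      char c1 = s1[off + k], c2 = s2[k];
      char a1 = q1[off + k], a2 = q2[k];
      if (c1 == c2) { seq.push_back(c1); qual.push_back(std::max(a1, a2)); }
      else if (a2 > a1) { seq.push_back(c2); qual.push_back(a2); }
      else { seq.push_back(c1); qual.push_back(a1); }
    }
    seq += s2.substr(bestL);
    qual += q2.substr(bestL);
    mseq[r] = seq; mqual[r] = qual;
    overlap[r] = bestL; ok[r] = true;
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["overlap"] = overlap, _["ok"] = ok);
}

// All template positions (0-based) where `primer` matches with at most
// max_mismatch substitutions and an exact match over the 3 bases at the
// indicated end (the primer's 3' terminus): anchor_right for a primer given
// in plus orientation, anchor at the left end for a reverse-complemented
// footprint.
// [[Rcpp::export(name = ".scan_primer_sites")]]
List scan_primer_sites(std::string tmpl, std::string primer,
                       int max_mismatch, bool anchor_right) {
  const int n = (int)tmpl.size(), k = (int)primer.size();
  std::vector<int> starts, mms;
  if (k < 3 || n < k)
    return List::create(_["start"] = IntegerVector(0), _["mismatches"] = IntegerVector(0));
  for (int i = 0; i + k <= n; ++i) {
    bool anchored = true;
    if (anchor_right) {
      for (int t = k - 3; t < k; ++t) if (tmpl[i + t] != primer[t]) { anchored = false; break; }
    } else {
      for (int t = 0; t < 3; ++t) if (tmpl[i + t] != primer[t]) { anchored = false; break; }
    }
    if (!anchored) continue;
    int mm = 0;
    for (int t = 0; t < k; ++t) {
      if (tmpl[i + t] != primer[t] && ++mm > max_mismatch) break;
    }
    if (mm <= max_mismatch) { starts.push_back(i); mms.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}

// Hamming distance between equal-length string pairs (vectorized).
// [[Rcpp::export(name = ".hamming_vec")]]
IntegerVector hamming_vec(CharacterVector x, CharacterVector y) {
  const R_xlen_t nx = x.size();
  if (y.size() != nx) stop("x and y must have equal length");
  IntegerVector out(nx);
  for (R_xlen_t r = 0; r < nx; ++r) {
    std::string a = as<std::string>(x[r]);
    std::string b = as<std::string>(y[r]);
    if (a.size() != b.size()) { out[r] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t t = 0; t < a.size(); ++t) if (a[t] != b[t]) ++d;
    out[r] = d;
  }
  return out;
}

// Longest intramolecular stem: 5' arm s[i, i+k) paired antiparallel with
// 3' arm s[j, j+k) (s[i+t] complements s[j+k-1-t]) and loop j-(i+k).
// Reports the longest stem whose loop is >= min_loop.
// [[Rcpp::export(name = ".hairpin_scan")]]
List hairpin_scan(std::string s, int min_stem, int min_loop) {
  const int n = (int)s.size();
  int best = 0, bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // grow stem with outermost pair (i, j+k-1): pair s[i+t] with s[j+k-1-t]
      int kmax = std::min(j - i, n - j);
      for (int k = 1; k <= kmax; ++k) {
        int loop = j - (i + k);
        if (loop < min_loop) break;
        bool okp = true;
        for (int t = 0; t < k; ++t) {
          if (wc_complement(s[i + t]) != s[j + k - 1 - t]) { okp = false; break; }
        }
        if (okp && k > best) { best = k; bi = i; bj = j; }
      }
    }
  }
  return List::create(_["stem_len"] = best,
                      _["arm5_start"] = bi, _["arm3_start"] = bj,
                      _["loop_len"] = (best > 0) ? (bj - (bi + best)) : NA_INTEGER,
                      _["hairpin"] = (best >= min_stem));
}

// Longest ungapped complementary run between two primers in antiparallel
// orientation, over all relative offsets; also the longest runs anchored at
// either primer's 3' terminus.
// [[Rcpp::export(name = ".dimer_scan")]]
List dimer_scan(std::string a, std::string b) {
  std::string brc(b.rbegin(), b.rend());
  for (size_t t = 0; t < brc.size(); ++t) brc[t] = wc_complement(brc[t]);
  const int la = (int)a.size(), lb = (int)brc.size();
  int max_run = 0, max_a3 = 0, max_b3 = 0;
  // offset d: a[i] pairs brc[i - d]
  for (int d = -(lb - 1); d <= la - 1; ++d) {
    int run = 0;
    int lo = std::max(0, d), hi = std::min(la, lb + d);
    for (int i = lo; i < hi; ++i) {
      if (a[i] == brc[i - d]) {
        ++run;
        if (run > max_run) max_run = run;
        if (i == la - 1 && run > max_a3) max_a3 = run;       // touches a's 3' end
        if (i - d == 0 && run > max_b3) max_b3 = run;        // run starts at brc[0] = b's 3' end
      } else run = 0;
    }
    // b3: a run *covering* brc index 0 begins there; recompute forward runs from brc[0]
    if (d <= 0 && -d < la) {
      int run0 = 0, i = -d;
      while (i < hi && a[i] == brc[i - d]) { ++run0; ++i; }
      if (run0 > max_b3) max_b3 = run0;
    }
  }
  return List::create(_["max_run"] = max_run,
                      _["max_run_3prime_a"] = max_a3,
                      _["max_run_3prime_b"] = max_b3);
}
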