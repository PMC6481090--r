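#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'T': return 'A';
  case 'C': return 'G'; case 'G': return 'C';
  case 'a': return 't'; case 't': return 'a';
  case 'c': return 'g'; case 'g': return 'c';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (size_t i = 0; i < out.size(); ++i) out[i] = comp_base(out[i]);
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(as<std::string>(x[i]));
  }
  return out;
}

// Hamming distances between each string in x and each barcode.
// Unequal lengths give NA_INTEGER. 'N' counts as a mismatch to everything.
// [[Rcpp::export]]
IntegerMatrix hamming_matrix_cpp(CharacterVector x, CharacterVector barcodes) {
  R_xlen_t n = x.size(), k = barcodes.size();
  IntegerMatrix out(n, k);
  std::vector<std::string> bc(k);
  for (R_xlen_t j = 0; j < k; ++j) bc[j] = as<std::string>(barcodes[j]);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) {
      for (R_xlen_t j = 0; j < k; ++j) out(i, j) = NA_INTEGER;
      continue;
    }
    std::string s = as<std::string>(x[i]);
    for (R_xlen_t j = 0; j < k; ++j) {
      if (s.size() != bc[j].size()) { out(i, j) = NA_INTEGER; continue; }
      int d = 0;
      for (size_t p = 0; p < s.size(); ++p) if (s[p] != bc[j][p]) ++d;
      out(i, j) = d;
    }
  }
  return out;
}

// Best suffix(seq1)/prefix(seq2rc) overlap by minimal mismatch ratio;
// ties resolved toward the longer overlap. Returns c(overlap, mismatches),
// or c(-1, -1) when no overlap >= min_overlap satisfies max_ratio.
static void best_overlap_core(const std::string &s1, const std::string &s2rc,
                              int min_overlap, double max_ratio,
                              int &best_ov, int &best_mm) {
  int n1 = (int)s1.size(), n2 = (int)s2rc.size();
  int max_ov = std::min(n1, n2);
  best_ov = -1; best_mm = -1;
  double best_ratio = 2.0;
  for (int ov = min_overlap; ov <= max_ov; ++ov) {
    const char *a = s1.data() + (n1 - ov);
    const char *b = s2rc.data();
    int mm = 0;
    for (int p = 0; p < ov; ++p) if (a[p] != b[p]) ++mm;
    double ratio = (double)mm / (double)ov;
    if (ratio < best_ratio - 1e-12 ||
        (std::abs(ratio - best_ratio) <= 1e-12 && ov > best_ov)) {
      best_ratio = ratio; best_ov = ov; best_mm = mm;
    }
  }
  if (best_ov < 0 || best_ratio > max_ratio + 1e-12) { best_ov = -1; best_mm = -1; }
}

// [[Rcpp::export]]
IntegerVector best_overlap_cpp(std::string seq1, std::string seq2rc,
                               int min_overlap, double max_mismatch_ratio) {
  int ov, mm;
  best_overlap_core(seq1, seq2rc, min_overlap, max_mismatch_ratio, ov, mm);
  return IntegerVector::create(ov, mm);
}

// Vectorised merge of trimmed mate pairs. seq2/qual2 are given in raw
// (reverse-strand) orientation; they are reverse-complemented here.
// In the overlap the higher-quality base wins (ties keep mate1's base)
// and the consensus quality is the max of the two.
// [[Rcpp::export]]
List merge_pairs_cpp(CharacterVector seq1, CharacterVector qual1,
                     CharacterVector seq2, CharacterVector qual2,
                     int min_overlap, double max_mismatch_ratio) {
  R_xlen_t n = seq1.size();
  CharacterVector mseq(n), mqual(n);
  IntegerVector ovl(n), mism(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(seq1[i]);
    std::string q1 = as<std::string>(qual1[i]);
    std::string s2 = revcomp_str(as<std::string>(seq2[i]));
    std::string q2 = as<std::string>(qual2[i]);
    std::reverse(q2.begin(), q2.end());
    int ov, mm;
    best_overlap_core(s1, s2, min_overlap, max_mismatch_ratio, ov, mm);
    if (ov < 0) {
      mseq[i] = NA_STRING; mqual[i] = NA_STRING;
      ovl[i] = 0; mism[i] = NA_INTEGER;
      continue;
    }
    int n1 = (int)s1.size(), n2 = (int)s2.size();
    std::string seq = s1.substr(0, n1 - ov);
    std::string qual = q1.substr(0, n1 - ov);
    for (int p = 0; p < ov; ++p) {
      char b1 = s1[n1 - ov + p], b2 = s2[p];
      char c1 = q1[n1 - ov + p], c2 = q2[p];
      seq.push_back(c2 > c1 ? b2 : b1);
      qual.push_back(std::max(c1, c2));
    }
    seq += s2.substr(ov);
    qual += q2.substr(ov);
    mseq[i] = seq; mqual[i] = qual;
    ovl[i] = ov; mism[i] = mm;
  }
  return List::create(_["sequence"] = mseq, _["quality"] = mqual,
                      _["overlap"] = ovl, _["mismatches"] = mism);
}

// Semi-global affine-gap alignment: the query must be fully aligned,
// leading/trailing unaligned reference is free. Gap of length k costs
// gap_open + (k-1)*gap_extend (both negative). Traceback ties prefer
// diagonal, then deletion (gap in query), then insertion (gap in ref).
// Returns score, per-column op string over {M,I,D}, and the 0-based
// reference interval covered by the alignment.
// [[Rcpp::export]]
List align_semiglobal_cpp(std::string query, std::string ref,
                          double match, double mismatch,
                          double gap_open, double gap_extend) {
  int n = (int)query.size(), m = (int)ref.size();
  if (n == 0 || m == 0) stop("query and reference must be non-empty");
  const double NEG = -1e18;
  // state 0 = H (diag), 1 = E (insertion, consumes query), 2 = F (deletion, consumes ref)
  std::vector<double> H((n + 1) * (m + 1), NEG), E(H), F(H);
  // traceback: predecessor state for each cell/state; 3 = start
  std::vector<unsigned char> pH((n + 1) * (m + 1), 255), pE(pH), pF(pH);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  H[idx(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) { H[idx(0, j)] = 0.0; pH[idx(0, j)] = 3; } // free ref prefix
  pH[idx(0, 0)] = 3;
  for (int i = 1; i <= n; ++i) {
    E[idx(i, 0)] = gap_open + (i - 1) * gap_extend;
    pE[idx(i, 0)] = (i == 1) ? 3 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // H: diagonal from best of (i-1, j-1), tie order H > F > E
      double hh = H[idx(i - 1, j - 1)], ff = F[idx(i - 1, j - 1)], ee = E[idx(i - 1, j - 1)];
      double b = hh; unsigned char ps = 0;
      if (ff > b) { b = ff; ps = 2; }
      if (ee > b) { b = ee; ps = 1; }
      double s = (query[i - 1] == ref[j - 1] && query[i - 1] != 'N') ? match : mismatch;
      if (b > NEG / 2) { H[idx(i, j)] = b + s; pH[idx(i, j)] = ps; }
      // E: gap in ref (consume query base i)
      double eo = H[idx(i - 1, j)] + gap_open;
      double ef = F[idx(i - 1, j)] + gap_open;
      double ex = E[idx(i - 1, j)] + gap_extend;
      double eb = eo; unsigned char pe = 0;
      if (ef > eb) { eb = ef; pe = 2; }
      if (ex > eb) { eb = ex; pe = 1; }
      if (i == 1 && j >= 1) { // may also open from free start row
        double e0 = H[idx(0, j)] + gap_open;
        if (e0 > eb) { eb = e0; pe = 0; }
      }
      if (eb > NEG / 2) { E[idx(i, j)] = eb; pE[idx(i, j)] = pe; }
      // F: gap in query (consume ref base j)
      double fo = H[idx(i, j - 1)] + gap_open;
      double fe = E[idx(i, j - 1)] + gap_open;
      double fx = F[idx(i, j - 1)] + gap_extend;
      double fb = fo; unsigned char pf = 0;
      if (fx > fb) { fb = fx; pf = 2; }
      if (fe > fb) { fb = fe; pf = 1; }
      if (fb > NEG / 2) { F[idx(i, j)] = fb; pF[idx(i, j)] = pf; }
    }
  }
  // terminal: max over j of H/E at i = n (trailing ref is free); prefer
  // smaller j, and H over E, on ties
  double best = NEG; int bj = -1; int bs = 0;
  for (int j = 0; j <= m; ++j) {
    double vh = H[idx(n, j)], ve = E[idx(n, j)];
    if (vh > best + 1e-12) { best = vh; bj = j; bs = 0; }
    if (ve > best + 1e-12) { best = ve; bj = j; bs = 1; }
  }
  // traceback; '=' match, 'X' mismatch, 'I' insertion, 'D' deletion
  std::string ops;
  int i = n, j = bj, st = bs;
  int ref_end = bj;
  while (!(i == 0 && st == 0 && pH[idx(0, j)] == 3) ) {
    if (i == 0) break; // reached free start row
    unsigned char pr;
    if (st == 0) {
      pr = pH[idx(i, j)];
      bool eq = (query[i - 1] == ref[j - 1] && query[i - 1] != 'N');
      ops.push_back(eq ? '=' : 'X'); --i; --j;
    } else if (st == 1) {
      pr = pE[idx(i, j)];
      ops.push_back('I'); --i;
    } else {
      pr = pF[idx(i, j)];
      ops.push_back('D'); --j;
    }
    if (pr == 3) { st = 0; break; }
    st = pr;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best, _["ops"] = ops,
                      _["ref_start"] = j, _["ref_end"] = ref_end);
}
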