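#include <Rcpp.h>
using namespace Rcpp;

// 'N' (or any non-ACGT symbol) never matches, including against itself.
static inline bool base_match(char a, char b) {
  if (a != b) return false;
  return a == 'A' || a == 'C' || a == 'G' || a == 'T';
}

// Best ungapped placement of a probe on a subject strand: minimum Hamming
// distance over all offsets, first (smallest) offset on ties.
// [[Rcpp::export]]
List hamming_scan_cpp(std::string probe, std::string subject) {
  const int l = probe.size(), L = subject.size();
  if (l > L) stop("probe length (%d) exceeds subject length (%d)", l, L);
  int best_mm = l + 1, best_off = 0;
  for (int off = 0; off <= L - l; ++off) {
    int mm = 0;
    for (int i = 0; i < l && mm < best_mm; ++i) {
      if (!base_match(probe[i], subject[off + i])) ++mm;
    }
    if (mm < best_mm) { best_mm = mm; best_off = off; }
    if (best_mm == 0) break;
  }
  return List::create(_["mismatches"] = best_mm, _["offset"] = best_off);
}

// Smith-Waterman local alignment of probe (rows) vs subject (cols) with
// linear gap penalty. Identity is (aligned matches)/(probe length).
// Deterministic: the best-scoring cell is the first encountered scanning
// j (subject) outer, i (probe) inner; traceback prefers diagonal, then up
// (gap in subject), then left (gap in probe).
// [[Rcpp::export]]
List sw_align_cpp(std::string probe, std::string subject,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0) {
  const int n = probe.size(), m = subject.size();
  NumericMatrix H(n + 1, m + 1);
  double best = 0.0; int bi = 0, bj = 0;
  for (int j = 1; j <= m; ++j) {
    for (int i = 1; i <= n; ++i) {
      double diag = H(i - 1, j - 1) +
        (base_match(probe[i - 1], subject[j - 1]) ? match : mismatch);
      double up = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      double s = diag;
      if (up > s) s = up;
      if (left > s) s = left;
      if (s < 0.0) s = 0.0;
      H(i, j) = s;
      if (s > best) { best = s; bi = i; bj = j; }
    }
  }
  int matches = 0, i = bi, j = bj;
  int end_j = bj, start_j = bj;
  while (i > 0 && j > 0 && H(i, j) > 0.0) {
    double h = H(i, j);
    double sub = base_match(probe[i - 1], subject[j - 1]) ? match : mismatch;
    if (H(i - 1, j - 1) + sub == h) {
      if (base_match(probe[i - 1], subject[j - 1])) ++matches;
      --i; --j;
    } else if (H(i - 1, j) + gap == h) {
      --i;
    } else {
      --j;
    }
    start_j = j;
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["offset"] = start_j, _["end"] = end_j);
}

// Minimum Hamming distance of each probe against a subject and its
// reverse complement, batched so one call covers a whole probe table.
// [[Rcpp::export]]
IntegerVector multi_hamming_scan_cpp(CharacterVector probes,
                                     std::string subject,
                                     std::string subject_rc) {
  const int n = probes.size();
  const int L = subject.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    std::string p = as<std::string>(probes[k]);
    const int l = p.size();
    if (l > L) { out[k] = NA_INTEGER; continue; }
    int best = l + 1;
    for (int strand = 0; strand < 2 && best > 0; ++strand) {
      const std::string &s = strand == 0 ? subject : subject_rc;
      for (int off = 0; off <= L - l && best > 0; ++off) {
        int mm = 0;
        for (int i = 0; i < l && mm < best; ++i) {
          if (!base_match(p[i], s[off + i])) ++mm;
        }
        if (mm < best) best = mm;
      }
    }
    out[k] = best;
  }
  return out;
}
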