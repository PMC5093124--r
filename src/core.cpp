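#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment (Needleman-Wunsch, linear gap cost).
// free_end_gaps: terminal gaps in either sequence cost nothing, so the
// recursion starts from a zero first row/column and traceback begins at the
// best cell on the last row/column.
// [[Rcpp::export]]
CharacterVector nw_align_cpp(std::string a, std::string b,
                             double match, double mismatch, double gap,
                             bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 diag, 1 up (gap in b), 2 left (gap in a)
  for (int i = 1; i <= n; ++i) {
    S(i, 0) = free_end_gaps ? 0.0 : i * gap;
    P(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    S(0, j) = free_end_gaps ? 0.0 : j * gap;
    P(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sd = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double su = S(i - 1, j) + gap;
      double sl = S(i, j - 1) + gap;
      // prefer diagonal, then up, for a deterministic traceback
      double best = sd; int ptr = 0;
      if (su > best) { best = su; ptr = 1; }
      if (sl > best) { best = sl; ptr = 2; }
      S(i, j) = best;
      P(i, j) = ptr;
    }
  }
  int ti = n, tj = m;
  if (free_end_gaps) {
    double best = S(n, m);
    for (int i = 0; i <= n; ++i)
      if (S(i, m) > best) { best = S(i, m); ti = i; tj = m; }
    for (int j = 0; j <= m; ++j)
      if (S(n, j) > best) { best = S(n, j); ti = n; tj = j; }
  }
  std::string ga, gb;
  // trailing free gaps
  for (int i = n; i > ti; --i) { ga.push_back(a[i - 1]); gb.push_back('-'); }
  for (int j = m; j > tj; --j) { ga.push_back('-'); gb.push_back(b[j - 1]); }
  int i = ti, j = tj;
  while (i > 0 || j > 0) {
    int ptr = P(i, j);
    if (i > 0 && j > 0 && ptr == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && (ptr == 1 || j == 0)) {
      ga.push_back(a[i - 1]); gb.push_back('-'); --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return CharacterVector::create(ga, gb);
}

// Sliding IUPAC-aware mismatch scan. Inputs are bitmask encodings
// (A=1, C=2, G=4, T=8; IUPAC codes are unions; gap/invalid = 0).
// A primer base matches a template base iff the masks intersect.
// Returns an (n_offsets x 2) matrix: total mismatches and mismatches within
// the anchor_len positions at the primer's 3' end. anchor_at_end = TRUE when
// the primer's 3' terminus aligns with the window end (plus-strand scan of
// the primer itself); FALSE when the scanned sequence is the primer's reverse
// complement, whose first window positions carry the 3' terminus.
// max_mm: windows are abandoned once their mismatch count exceeds this
// cutoff and report the sentinel max_mm + 1 (callers filtering at <= max_mm
// see identical results to a full count). Pass k for exhaustive counts.
// [[Rcpp::export]]
IntegerMatrix scan_mm_cpp(IntegerVector primer, IntegerVector tmpl,
                          int anchor_len, bool anchor_at_end, int max_mm) {
  const int k = primer.size(), L = tmpl.size();
  const int noff = L - k + 1;
  if (noff <= 0) return IntegerMatrix(0, 2);
  IntegerMatrix out(noff, 2);
  for (int s = 0; s < noff; ++s) {
    int mm = 0, amm = 0;
    for (int p = 0; p < k; ++p) {
      if ((primer[p] & tmpl[s + p]) == 0) {
        ++mm;
        if (mm > max_mm) break;
        bool in_anchor = anchor_at_end ? (p >= k - anchor_len)
                                       : (p < anchor_len);
        if (in_anchor) ++amm;
      }
    }
    out(s, 0) = mm;
    out(s, 1) = amm;
  }
  return out;
}

// Best-window specificity scan with branch-and-bound: returns the minimum
// mismatch count over all windows (both semantics of the anchor handled by
// the caller) and the smallest anchor mismatch count among windows achieving
// that minimum. best_mm/best_amm seed the search with the best score found
// on previously scanned templates so hopeless windows abort early.
// [[Rcpp::export]]
IntegerVector scan_best_cpp(IntegerVector primer, IntegerVector tmpl,
                            int anchor_len, bool anchor_at_end,
                            int best_mm, int best_amm) {
  const int k = primer.size(), L = tmpl.size();
  const int noff = L - k + 1;
  for (int s = 0; s < noff; ++s) {
    int mm = 0, amm = 0;
    bool aborted = false;
    for (int p = 0; p < k; ++p) {
      if ((primer[p] & tmpl[s + p]) == 0) {
        ++mm;
        if (mm > best_mm) { aborted = true; break; }
        bool in_anchor = anchor_at_end ? (p >= k - anchor_len)
                                       : (p < anchor_len);
        if (in_anchor) ++amm;
      }
    }
    if (aborted) continue;
    if (mm < best_mm || (mm == best_mm && amm < best_amm)) {
      best_mm = mm;
      best_amm = amm;
    }
  }
  return IntegerVector::create(best_mm, best_amm);
}

// Batch specificity scoring: for every candidate (given with its reverse
// complement), the lexicographic minimum (mismatches, anchor mismatches)
// over every window of every template on both strands. One call replaces
// n_candidates x n_templates x 2 scan_best_cpp round-trips.
// [[Rcpp::export]]
IntegerMatrix score_candidates_cpp(List cands, List cands_rc, List templates,
                                   int anchor_len) {
  const int nc = cands.size();
  IntegerMatrix out(nc, 2);
  std::vector<IntegerVector> tmpls(templates.size());
  for (int t = 0; t < templates.size(); ++t) {
    tmpls[t] = as<IntegerVector>(templates[t]);
  }
  for (int c = 0; c < nc; ++c) {
    IntegerVector p = as<IntegerVector>(cands[c]);
    IntegerVector prc = as<IntegerVector>(cands_rc[c]);
    const int k = p.size();
    int best_mm = k + 1, best_amm = k + 1;
    for (size_t t = 0; t < tmpls.size(); ++t) {
      const IntegerVector& tm = tmpls[t];
      const int L = tm.size();
      if (L < k) continue;
      for (int pass = 0; pass < 2; ++pass) {
        const IntegerVector& pr = pass == 0 ? p : prc;
        const bool anchor_at_end = pass == 0;
        for (int s = 0; s <= L - k; ++s) {
          int mm = 0, amm = 0;
          bool aborted = false;
          for (int q = 0; q < k; ++q) {
            if ((pr[q] & tm[s + q]) == 0) {
              ++mm;
              if (mm > best_mm) { aborted = true; break; }
              bool in_anchor = anchor_at_end ? (q >= k - anchor_len)
                                             : (q < anchor_len);
              if (in_anchor) ++amm;
            }
          }
          if (aborted) continue;
          if (mm < best_mm || (mm == best_mm && amm < best_amm)) {
            best_mm = mm;
            best_amm = amm;
          }
        }
      }
    }
    out(c, 0) = best_mm;
    out(c, 1) = best_amm;
  }
  return out;
}

// Longest contiguous run of identical masks between a and b over all ungapped
// offsets, plus the longest such run ending at a's final position. Used for
// Watson-Crick complementarity screens after b has been reverse-complemented
// at the R level.
// [[Rcpp::export]]
IntegerVector max_common_run_cpp(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  int best = 0, best_end = 0;
  for (int d = -(m - 1); d <= n - 1; ++d) {
    int run = 0;
    int lo = std::max(0, d), hi = std::min(n, m + d);
    for (int i = lo; i < hi; ++i) {
      if (a[i] == b[i - d] && a[i] != 0) {
        ++run;
        if (run > best) best = run;
        if (i == n - 1 && run > best_end) best_end = run;
      } else {
        run = 0;
      }
    }
  }
  return IntegerVector::create(best, best_end);
}
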