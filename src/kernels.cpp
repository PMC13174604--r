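#include <Rcpp.h>
using namespace Rcpp;

// Ungapped overlap merge of mate pairs. r2rc must already be the reverse
// complement of mate 2. An overlap of length o aligns the last o bases of r1
// with the first o bases of r2rc; the consensus keeps r1's base at every
// overlap position (mate 1 covers the 5' end of the insert, where the
// cap-class adapter lives). Among overlaps with mismatch fraction <=
// max_mm_rate and length >= min_overlap the one maximising matches minus
// mismatches wins; ties go to the longer overlap.
// [[Rcpp::export]]
CharacterVector cpp_merge_pairs(CharacterVector r1, CharacterVector r2rc,
                                int min_overlap, double max_mm_rate) {
  R_xlen_t n = r1.size();
  if (r2rc.size() != n) stop("mate vectors differ in length");
  CharacterVector out(n, NA_STRING);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (r1[i] == NA_STRING || r2rc[i] == NA_STRING) continue;
    const char *a = CHAR(STRING_ELT(r1, i));
    const char *b = CHAR(STRING_ELT(r2rc, i));
    int la = LENGTH(STRING_ELT(r1, i));
    int lb = LENGTH(STRING_ELT(r2rc, i));
    int omax = la < lb ? la : lb;
    int best_o = -1, best_score = INT_MIN;
    for (int o = omax; o >= min_overlap; --o) {
      int allowed = (int)std::floor(max_mm_rate * o);
      int mm = 0;
      const char *a0 = a + (la - o);
      for (int k = 0; k < o; ++k) {
        if (a0[k] != b[k]) {
          if (++mm > allowed) break;
        }
      }
      if (mm <= allowed) {
        int score = o - 2 * mm;
        if (score > best_score) { best_score = score; best_o = o; }
      }
    }
    if (best_o >= min_overlap) {
      std::string merged(a, la);
      merged.append(b + best_o, lb - best_o);
      out[i] = merged;
    }
  }
  return out;
}

// Best occurrence of `pattern` in each read with start position (0-based)
// in [min_start, max_start] and at most max_mm substitutions. Fewest
// mismatches wins; ties go to the leftmost start. Returns 1-based start
// positions, NA where no occurrence qualifies.
// [[Rcpp::export]]
IntegerVector cpp_find_pattern(CharacterVector reads, std::string pattern,
                               int max_mm, int min_start, int max_start) {
  R_xlen_t n = reads.size();
  int lp = pattern.size();
  const char *p = pattern.c_str();
  IntegerVector out(n, NA_INTEGER);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, i));
    int ls = LENGTH(STRING_ELT(reads, i));
    int hi = max_start < 0 ? ls - lp : std::min(max_start, ls - lp);
    int best_mm = max_mm + 1, best_pos = NA_INTEGER;
    for (int st = min_start; st <= hi; ++st) {
      int mm = 0;
      for (int k = 0; k < lp; ++k) {
        if (s[st + k] != p[k]) {
          if (++mm >= best_mm) break;
        }
      }
      if (mm < best_mm) {
        best_mm = mm;
        best_pos = st + 1;
        if (mm == 0) break;
      }
    }
    out[i] = best_pos;
  }
  return out;
}

// Nearest reference by Hamming distance under an ungapped full-length
// comparison. Only references of identical length are candidates. Returns a
// matrix with one row per query: best reference index (1-based; 0 = none
// within budget), its mismatch count, and how many references tie at that
// count (>1 = ambiguous).
// [[Rcpp::export]]
IntegerMatrix cpp_hamming_assign(CharacterVector queries, CharacterVector refs,
                                 int max_mm) {
  R_xlen_t nq = queries.size(), nr = refs.size();
  std::vector<const char *> rp(nr);
  std::vector<int> rl(nr);
  for (R_xlen_t j = 0; j < nr; ++j) {
    rp[j] = CHAR(STRING_ELT(refs, j));
    rl[j] = LENGTH(STRING_ELT(refs, j));
  }
  IntegerMatrix out(nq, 3);
  for (R_xlen_t i = 0; i < nq; ++i) {
    const char *q = CHAR(STRING_ELT(queries, i));
    int lq = LENGTH(STRING_ELT(queries, i));
    int best = max_mm + 1, best_j = 0, ties = 0;
    for (R_xlen_t j = 0; j < nr; ++j) {
      if (rl[j] != lq) continue;
      int mm = 0;
      const char *r = rp[j];
      for (int k = 0; k < lq; ++k) {
        if (q[k] != r[k]) {
          if (++mm > best) break;
        }
      }
      if (mm < best) { best = mm; best_j = (int)j + 1; ties = 1; }
      else if (mm == best && best <= max_mm) ++ties;
    }
    if (best > max_mm) { best_j = 0; ties = 0; best = NA_INTEGER; }
    out(i, 0) = best_j;
    out(i, 1) = best;
    out(i, 2) = ties;
  }
  return out;
}

// i.i.d. substitution errors at per-base rate eps, drawn from R's RNG so
// results are reproducible under set.seed(). Each error replaces the base
// with one of the three other nucleotides, uniformly.
// [[Rcpp::export]]
CharacterVector cpp_inject_errors(CharacterVector reads, double eps) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  R_xlen_t n = reads.size();
  CharacterVector out(n);
  RNGScope scope;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s(CHAR(STRING_ELT(reads, i)), LENGTH(STRING_ELT(reads, i)));
    for (size_t k = 0; k < s.size(); ++k) {
      if (unif_rand() < eps) {
        char orig = s[k];
        char sub;
        do {
          sub = bases[(int)(unif_rand() * 4) & 3];
        } while (sub == orig);
        s[k] = sub;
      }
    }
    out[i] = s;
  }
  return out;
}
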