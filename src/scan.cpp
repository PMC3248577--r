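#include <Rcpp.h>
using namespace Rcpp;

// PWM similarity scanning over integer-encoded sequences (A=0,C=1,G=2,T=3,N=4).
// Scores are plain frequency sums over matrix columns; the similarity
// threshold is pre-converted to a raw-score threshold in R (min-max scores
// are invariant under column permutation, so one threshold serves all
// permuted matrices). Windows containing N never match.

static const double EPS = 1e-9;

// Scan one sequence with one matrix; returns hit offsets (0-based) and scores.
// [[Rcpp::export]]
List scan_hits_cpp(IntegerVector code, NumericMatrix F, double threshold) {
  int L = F.ncol();
  int n = code.size();
  std::vector<int> pos;
  std::vector<double> score;
  if (n < L) return List::create(_["pos"] = IntegerVector(0),
                                 _["score"] = NumericVector(0));
  // lookahead bound: best achievable score from column k onward
  std::vector<double> suffix(L + 1, 0.0);
  for (int k = L - 1; k >= 0; --k) {
    double mx = F(0, k);
    for (int b = 1; b < 4; ++b) mx = std::max(mx, F(b, k));
    suffix[k] = suffix[k + 1] + mx;
  }
  for (int i = 0; i + L <= n; ++i) {
    double s = 0.0;
    bool ok = true;
    for (int k = 0; k < L; ++k) {
      int b = code[i + k];
      if (b > 3) { ok = false; break; }
      s += F(b, k);
      if (s + suffix[k + 1] < threshold - EPS) { ok = false; break; }
    }
    if (ok && s >= threshold - EPS) {
      pos.push_back(i);
      score.push_back(s);
    }
  }
  return List::create(_["pos"] = wrap(pos), _["score"] = wrap(score));
}

// Pooled per-window site counts over a set of equal-length sequences, for
// each column permutation of the matrix (rows of `perms`, 0-based column
// indices; an identity row gives the observed counts). Both strands are
// scanned: `codes` holds forward sequences, `rc_codes` their reverse
// complements; a reverse-strand match at rc offset i starts at forward
// coordinate span - L - i. Sites are binned by forward match start into
// non-overlapping windows of `window_width`. A position matching on both
// strands counts once: palindromic matrices match strand-symmetrically at
// every hit, and double-counting those pairs would double the observed
// count's variance relative to the (generally non-palindromic) permuted
// null.
// [[Rcpp::export]]
IntegerMatrix scan_window_counts_cpp(List codes, List rc_codes,
                                     NumericMatrix F, IntegerMatrix perms,
                                     double threshold, int window_width,
                                     int span) {
  int L = F.ncol();
  int n_perm = perms.nrow();
  int n_win = span / window_width;
  int n_seq = codes.size();
  IntegerMatrix out(n_perm, n_win);

  // pull sequences out of R structures once; inner loops touch raw ints only
  std::vector<std::vector<int>> seqs(2 * n_seq);
  for (int s_i = 0; s_i < n_seq; ++s_i) {
    IntegerVector f = codes[s_i], r = rc_codes[s_i];
    seqs[2 * s_i].assign(f.begin(), f.end());
    seqs[2 * s_i + 1].assign(r.begin(), r.end());
  }

  std::vector<double> Fp(4 * L);
  std::vector<double> suffix(L + 1);

  for (int p = 0; p < n_perm; ++p) {
    for (int k = 0; k < L; ++k) {
      int src = perms(p, k);
      for (int b = 0; b < 4; ++b) Fp[4 * k + b] = F(b, src);
    }
    suffix[L] = 0.0;
    for (int k = L - 1; k >= 0; --k) {
      double mx = Fp[4 * k];
      for (int b = 1; b < 4; ++b) mx = std::max(mx, Fp[4 * k + b]);
      suffix[k] = suffix[k + 1] + mx;
    }
    std::vector<char> hit(span);
    for (int q = 0; q < n_seq; ++q) {
      std::fill(hit.begin(), hit.end(), 0);
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int> &code = seqs[2 * q + strand];
        const int n = (int) code.size();
        for (int i = 0; i + L <= n; ++i) {
          double s = 0.0;
          bool ok = true;
          for (int k = 0; k < L; ++k) {
            int b = code[i + k];
            if (b > 3) { ok = false; break; }
            s += Fp[4 * k + b];
            if (s + suffix[k + 1] < threshold - EPS) { ok = false; break; }
          }
          if (ok && s >= threshold - EPS) {
            hit[strand == 0 ? i : span - L - i] = 1;
          }
        }
      }
      for (int i = 0; i + L <= span; ++i) {
        if (hit[i]) out(p, i / window_width) += 1;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
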