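#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Shared dynamic-programming kernels: affine-gap global alignment
// (Needleman-Wunsch), affine-gap local alignment (Smith-Waterman) and
// Nussinov-style maximum nested base pairing. 'N' never matches anything.

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

static const double NEG = -1e18;

// traceback state codes
enum { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_START = 3 };

static void check_size(size_t n, size_t m) {
  if ((n + 1) * (m + 1) > 30000000UL)
    stop("alignment problem too large (%d x %d)", (int)n, (int)m);
}

// [[Rcpp::export]]
List nw_affine_cpp(std::string a, std::string b, double match, double mismatch,
                   double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  check_size(n, m);
  const double go = gap_open + gap_ext;  // first gapped base
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  std::vector<unsigned char> tM((n + 1) * W), tX((n + 1) * W), tY((n + 1) * W);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -go - gap_ext * (i - 1);
    tX[i * W] = (i == 1) ? FROM_M : FROM_X;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -go - gap_ext * (j - 1);
    tY[j] = (j == 1) ? FROM_M : FROM_Y;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = subscore(a[i - 1], b[j - 1], match, mismatch);
      // M: a[i-1] aligned to b[j-1]
      double best = M[d]; unsigned char tb = FROM_M;
      if (X[d] > best) { best = X[d]; tb = FROM_X; }
      if (Y[d] > best) { best = Y[d]; tb = FROM_Y; }
      M[c] = best + s; tM[c] = tb;
      // X: a[i-1] aligned to a gap (vertical)
      best = M[u] - go; tb = FROM_M;
      if (X[u] - gap_ext > best) { best = X[u] - gap_ext; tb = FROM_X; }
      if (Y[u] - go > best) { best = Y[u] - go; tb = FROM_Y; }
      X[c] = best; tX[c] = tb;
      // Y: b[j-1] aligned to a gap (horizontal)
      best = M[l] - go; tb = FROM_M;
      if (Y[l] - gap_ext > best) { best = Y[l] - gap_ext; tb = FROM_Y; }
      if (X[l] - go > best) { best = X[l] - go; tb = FROM_X; }
      Y[c] = best; tY[c] = tb;
    }
  }
  const size_t e = n * W + m;
  double score = M[e]; int state = FROM_M;
  if (X[e] > score) { score = X[e]; state = FROM_X; }
  if (Y[e] > score) { score = Y[e]; state = FROM_Y; }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (state == FROM_M) {
      const int prev = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == FROM_X) {
      const int prev = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      const int prev = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
    if (i == 0 && j > 0) state = FROM_Y;
    if (j == 0 && i > 0) state = FROM_X;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}

// [[Rcpp::export]]
List sw_local_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  check_size(n, m);
  const double go = gap_open + gap_ext;
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, 0.0), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  std::vector<unsigned char> tM((n + 1) * W, FROM_START), tX((n + 1) * W), tY((n + 1) * W);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      const double s = subscore(a[i - 1], b[j - 1], match, mismatch);
      double v = M[d]; unsigned char tb = FROM_M;
      if (X[d] > v) { v = X[d]; tb = FROM_X; }
      if (Y[d] > v) { v = Y[d]; tb = FROM_Y; }
      if (v < 0.0) { v = 0.0; tb = FROM_START; }
      M[c] = v + s; tM[c] = tb;
      if (M[c] < 0.0) { M[c] = 0.0; tM[c] = FROM_START; }
      v = M[u] - go; tb = FROM_M;
      if (X[u] - gap_ext > v) { v = X[u] - gap_ext; tb = FROM_X; }
      X[c] = v; tX[c] = tb;
      v = M[l] - go; tb = FROM_M;
      if (Y[l] - gap_ext > v) { v = Y[l] - gap_ext; tb = FROM_Y; }
      Y[c] = v; tY[c] = tb;
      if (M[c] > best) { best = M[c]; bi = i; bj = j; }
    }
  }
  std::string ra, rb;
  int i = bi, j = bj, state = FROM_M;
  while (i > 0 && j > 0) {
    const size_t c = i * W + j;
    if (state == FROM_M) {
      if (tM[c] == FROM_START && M[c] == 0.0) break;
      const int prev = tM[c];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (prev == FROM_START) { state = FROM_START; break; }
      state = prev;
    } else if (state == FROM_X) {
      const int prev = tX[c];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      const int prev = tY[c];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  // i, j are now 0-based positions just before the alignment start
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = best,
                      _["start_a"] = i + 1, _["end_a"] = bi,
                      _["start_b"] = j + 1, _["end_b"] = bj);
}

static inline bool can_pair(char x, char y, bool wobble) {
  if ((x == 'A' && y == 'T') || (x == 'T' && y == 'A')) return true;
  if ((x == 'C' && y == 'G') || (x == 'G' && y == 'C')) return true;
  if (wobble && ((x == 'G' && y == 'T') || (x == 'T' && y == 'G'))) return true;
  return false;
}

// [[Rcpp::export]]
int nussinov_cpp(std::string s, bool wobble, int min_loop) {
  const int n = s.size();
  if (n == 0) return 0;
  std::vector<int> dp(n * n, 0);
  auto at = [&](int i, int j) -> int& { return dp[i * n + j]; };
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      int v = at(i + 1, j);  // i unpaired
      if (can_pair(s[i], s[j], wobble) && j - i - 1 >= min_loop) {
        const int w = 1 + (i + 1 <= j - 1 ? at(i + 1, j - 1) : 0);
        if (w > v) v = w;
      }
      for (int k = i + 1; k < j; ++k) {  // bifurcation: i pairs with k
        if (can_pair(s[i], s[k], wobble) && k - i - 1 >= min_loop) {
          const int w = 1 + (i + 1 <= k - 1 ? at(i + 1, k - 1) : 0) + at(k + 1, j);
          if (w > v) v = w;
        }
      }
      at(i, j) = v;
    }
  }
  return at(0, n - 1);
}
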