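#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>

using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
//
// Gap convention: a run of k gapped residues costs gap_open + (k-1)*gap_extend
// (the first residue of a run is charged the opening penalty).
//
// States: M = column with residues in both sequences,
//         X = gap in b (consumes a; traceback moves "up"),
//         Y = gap in a (consumes b; traceback moves "left").
// Tie-breaking is fixed everywhere as M > X > Y, which realises the
// diagonal > up > left rule and makes the traceback deterministic.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double score_at(const double* sub, char ca, char cb) {
  return sub[(unsigned char)ca + (((size_t)(unsigned char)cb) << 8)];
}

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b, NumericMatrix submat,
                      double gap_open, double gap_extend, bool local) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (submat.nrow() != 256 || submat.ncol() != 256)
    stop("substitution lookup must be 256 x 256");
  const double* subp = REAL(submat);

  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> X((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> Y((size_t)(n + 1) * W, NEG_INF);
  #define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i)
    X[IDX(i, 0)] = local ? NEG_INF : -(gap_open + (i - 1) * gap_extend);
  for (int j = 1; j <= m; ++j)
    Y[IDX(0, j)] = local ? NEG_INF : -(gap_open + (j - 1) * gap_extend);
  if (local) {
    for (int i = 0; i <= n; ++i) M[IDX(i, 0)] = 0.0;
    for (int j = 0; j <= m; ++j) M[IDX(0, j)] = 0.0;
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double s = score_at(subp, ca, b[j - 1]);
      // M: preference M > X > Y on the predecessor
      double pm = M[IDX(i - 1, j - 1)], px = X[IDX(i - 1, j - 1)],
             py = Y[IDX(i - 1, j - 1)];
      double prev = pm;
      if (px > prev) prev = px;
      if (py > prev) prev = py;
      double mval;
      if (local) {
        // local alignments start fresh when every predecessor is <= 0
        if (prev < 0.0) prev = 0.0;
        mval = prev + s;
        if (mval > best) { best = mval; best_i = i; best_j = j; }
      } else {
        mval = (prev == NEG_INF) ? NEG_INF : prev + s;
      }
      M[IDX(i, j)] = mval;
      // X: gap in b (move up)
      double xm = M[IDX(i - 1, j)] - gap_open;
      double xx = X[IDX(i - 1, j)] - gap_extend;
      double xy = Y[IDX(i - 1, j)] - gap_open;
      double xv = xm;
      if (xx > xv) xv = xx;
      if (xy > xv) xv = xy;
      X[IDX(i, j)] = xv;
      // Y: gap in a (move left)
      double ym = M[IDX(i, j - 1)] - gap_open;
      double yx = X[IDX(i, j - 1)] - gap_open;
      double yy = Y[IDX(i, j - 1)] - gap_extend;
      double yv = ym;
      if (yx > yv) yv = yx;
      if (yy > yv) yv = yy;
      Y[IDX(i, j)] = yv;
    }
  }

  std::string out_a, out_b;
  double score;
  int i, j, state; // state: 0 = M, 1 = X, 2 = Y
  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;

  if (local) {
    score = best;
    if (best <= 0.0) {
      return List::create(_["aligned_a"] = "", _["aligned_b"] = "",
                          _["score"] = 0.0, _["identities"] = 0L,
                          _["columns"] = 0L, _["a_start"] = 0L,
                          _["a_end"] = 0L, _["b_start"] = 0L,
                          _["b_end"] = 0L);
    }
    i = best_i; j = best_j; state = 0;
    a_end = best_i; b_end = best_j;
  } else {
    double em = M[IDX(n, m)], ex = X[IDX(n, m)], ey = Y[IDX(n, m)];
    state = 0; score = em;
    if (ex > score) { score = ex; state = 1; }
    if (ey > score) { score = ey; state = 2; }
    i = n; j = m;
    a_end = n; b_end = m;
  }

  while (i > 0 || j > 0) {
    if (state == 0) {
      if (local) {
        // the run of columns ends where the 0 floor was taken
        double pm = M[IDX(i - 1, j - 1)], px = X[IDX(i - 1, j - 1)],
               py = Y[IDX(i - 1, j - 1)];
        double prev = pm;
        if (px > prev) prev = px;
        if (py > prev) prev = py;
        if (prev <= 0.0) {
          out_a.push_back(a[i - 1]);
          out_b.push_back(b[j - 1]);
          i--; j--;
          break;
        }
      }
      if (i == 0 || j == 0) break; // global M at border only at (0,0)
      const double s = score_at(subp, a[i - 1], b[j - 1]);
      const double v = M[IDX(i, j)];
      double pm = M[IDX(i - 1, j - 1)], px = X[IDX(i - 1, j - 1)],
             py = Y[IDX(i - 1, j - 1)];
      out_a.push_back(a[i - 1]);
      out_b.push_back(b[j - 1]);
      if (pm + s == v) state = 0;
      else if (px + s == v) state = 1;
      else state = 2;
      i--; j--;
    } else if (state == 1) {
      const double v = X[IDX(i, j)];
      out_a.push_back(a[i - 1]);
      out_b.push_back('-');
      if (M[IDX(i - 1, j)] - gap_open == v) state = 0;
      else if (X[IDX(i - 1, j)] - gap_extend == v) state = 1;
      else state = 2;
      i--;
    } else {
      const double v = Y[IDX(i, j)];
      out_a.push_back('-');
      out_b.push_back(b[j - 1]);
      if (M[IDX(i, j - 1)] - gap_open == v) state = 0;
      else if (X[IDX(i, j - 1)] - gap_open == v) state = 1;
      else state = 2;
      j--;
    }
  }
  a_start = i + 1;
  b_start = j + 1;
  if (local && out_a.empty()) { a_start = 0; b_start = 0; }

  std::reverse(out_a.begin(), out_a.end());
  std::reverse(out_b.begin(), out_b.end());

  int identities = 0;
  for (size_t k = 0; k < out_a.size(); ++k)
    if (out_a[k] != '-' && out_a[k] == out_b[k]) identities++;

  return List::create(_["aligned_a"] = out_a, _["aligned_b"] = out_b,
                      _["score"] = score, _["identities"] = identities,
                      _["columns"] = (int)out_a.size(),
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end);
}
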