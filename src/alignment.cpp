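#include <Rcpp.h>
#include <limits>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine gap convention throughout: a gap run of length L costs
// gap_open + (L - 1) * gap_extend, both penalties negative.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct ScoreLookup {
  // 256-entry char -> row index map over the scheme alphabet
  int idx[256];
  const NumericMatrix &mat;
  ScoreLookup(const NumericMatrix &m, const CharacterVector &alphabet) : mat(m) {
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    for (int i = 0; i < alphabet.size(); ++i) {
      std::string s = as<std::string>(alphabet[i]);
      idx[(unsigned char)s[0]] = i;
    }
  }
  double operator()(char a, char b) const {
    int ia = idx[(unsigned char)a], ib = idx[(unsigned char)b];
    if (ia < 0)
      stop("illegal character '%s' for the scoring alphabet", std::string(1, a).c_str());
    if (ib < 0)
      stop("illegal character '%s' for the scoring alphabet", std::string(1, b).c_str());
    return mat(ia, ib);
  }
};

// Gotoh three-state alignment. States: 0 = M (diagonal), 1 = X (gap in b,
// consumes a, "up"), 2 = Y (gap in a, consumes b, "left").
// Traceback tie-break priority: diagonal > up > left.
// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b, NumericMatrix mat,
                     CharacterVector alphabet, double gap_open,
                     double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  ScoreLookup S(mat, alphabet);

  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + (j - 1) * gap_extend;
  if (local) {
    for (int i = 0; i <= n; ++i) M[i][0] = 0.0;
    for (int j = 0; j <= m; ++j) M[0][j] = 0.0;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      double mij = diag + S(a[i - 1], b[j - 1]);
      if (local && mij < 0) mij = 0.0;
      M[i][j] = mij;
      X[i][j] = std::max(std::max(M[i - 1][j] + gap_open, X[i - 1][j] + gap_extend),
                         Y[i - 1][j] + gap_open);
      Y[i][j] = std::max(std::max(M[i][j - 1] + gap_open, Y[i][j - 1] + gap_extend),
                         X[i][j - 1] + gap_open);
    }
  }

  int ei = n, ej = m;
  double best;
  int state; // 0 M, 1 X, 2 Y
  if (local) {
    best = 0.0; ei = 0; ej = 0; state = 0;
    for (int i = 0; i <= n; ++i)
      for (int j = 0; j <= m; ++j)
        if (M[i][j] > best) { best = M[i][j]; ei = i; ej = j; }
  } else {
    best = M[n][m]; state = 0;
    if (X[n][m] > best) { best = X[n][m]; state = 1; }
    if (Y[n][m] > best) { best = Y[n][m]; state = 2; }
  }

  std::string ra, rb;
  int i = ei, j = ej;
  if (local) {
    // start traceback in M at the maximum cell
    state = 0;
  }
  while (i > 0 || j > 0) {
    if (local && state == 0 && M[i][j] == 0.0) break;
    if (state == 0) {
      if (i == 0 || j == 0) {
        // global boundary: remaining prefix is one gap run
        state = (i > 0) ? 1 : 2;
        continue;
      }
      double prev = M[i][j] - S(a[i - 1], b[j - 1]);
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      // tie-break: diagonal > up > left
      if (M[i][j] == prev) state = 0;
      else if (X[i][j] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      double cur = X[i][j];
      --i;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      double cur = Y[i][j];
      --j;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (Y[i][j] + gap_extend == cur) state = 2;
      else state = 1; // came from X via a fresh gap open
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = best,
                      _["start_a"] = i, _["start_b"] = j);
}

// Exhaustive brute-force oracle: depth-first enumeration of every gapped
// alignment (no dynamic programming, no memoisation). prev: 0 none/match,
// 1 inside an up-gap run, 2 inside a left-gap run.
static double enum_rec(const std::string &a, const std::string &b, int i, int j,
                       int prev, const ScoreLookup &S, double open, double ext) {
  const int n = a.size(), m = b.size();
  if (i == n && j == m) return 0.0;
  double best = NEG_INF;
  if (i < n && j < m) {
    double v = S(a[i], b[j]) + enum_rec(a, b, i + 1, j + 1, 0, S, open, ext);
    if (v > best) best = v;
  }
  if (i < n) {
    double pen = (prev == 1) ? ext : open;
    double v = pen + enum_rec(a, b, i + 1, j, 1, S, open, ext);
    if (v > best) best = v;
  }
  if (j < m) {
    double pen = (prev == 2) ? ext : open;
    double v = pen + enum_rec(a, b, i, j + 1, 2, S, open, ext);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
double enumerate_align_score_cpp(std::string a, std::string b, NumericMatrix mat,
                                 CharacterVector alphabet, double gap_open,
                                 double gap_extend) {
  ScoreLookup S(mat, alphabet);
  return enum_rec(a, b, 0, 0, 0, S, gap_open, gap_extend);
}

// Mean substitution score between two profile columns; residue-vs-gap pairs
// contribute gap_extend, gap-gap pairs contribute 0.
static double col_score(const std::vector<std::string> &A, int ca,
                        const std::vector<std::string> &B, int cb,
                        const ScoreLookup &S, double ext) {
  double tot = 0.0; int cnt = 0;
  for (size_t r = 0; r < A.size(); ++r) {
    for (size_t s = 0; s < B.size(); ++s) {
      char x = A[r][ca], y = B[s][cb];
      if (x == '-' && y == '-') tot += 0.0;
      else if (x == '-' || y == '-') tot += ext;
      else tot += S(x, y);
      ++cnt;
    }
  }
  return tot / cnt;
}

// Profile-profile global alignment with affine gaps at the profile level.
// Returns the merged gapped rows (rows of A first, then rows of B).
// [[Rcpp::export]]
List profile_align_cpp(CharacterVector rows_a, CharacterVector rows_b,
                       NumericMatrix mat, CharacterVector alphabet,
                       double gap_open, double gap_extend) {
  std::vector<std::string> A, B;
  for (int k = 0; k < rows_a.size(); ++k) A.push_back(as<std::string>(rows_a[k]));
  for (int k = 0; k < rows_b.size(); ++k) B.push_back(as<std::string>(rows_b[k]));
  ScoreLookup S(mat, alphabet);
  const int n = A.empty() ? 0 : A[0].size();
  const int m = B.empty() ? 0 : B[0].size();

  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF));
  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i][0] = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y[0][j] = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double cs = col_score(A, i - 1, B, j - 1, S, gap_extend);
      M[i][j] = cs + std::max(M[i - 1][j - 1], std::max(X[i - 1][j - 1], Y[i - 1][j - 1]));
      X[i][j] = std::max(std::max(M[i - 1][j] + gap_open, X[i - 1][j] + gap_extend),
                         Y[i - 1][j] + gap_open);
      Y[i][j] = std::max(std::max(M[i][j - 1] + gap_open, Y[i][j - 1] + gap_extend),
                         X[i][j - 1] + gap_open);
    }
  }

  // traceback, tie-break diagonal > up > left
  std::vector<int> path; // 0 diag, 1 up, 2 left
  int i = n, j = m;
  double best = M[n][m]; int state = 0;
  if (X[n][m] > best) { best = X[n][m]; state = 1; }
  if (Y[n][m] > best) { best = Y[n][m]; state = 2; }
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) { state = (i > 0) ? 1 : 2; continue; }
      double cs = col_score(A, i - 1, B, j - 1, S, gap_extend);
      double prev = M[i][j] - cs;
      path.push_back(0); --i; --j;
      if (M[i][j] == prev) state = 0;
      else if (X[i][j] == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      double cur = X[i][j];
      path.push_back(1); --i;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (X[i][j] + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      double cur = Y[i][j];
      path.push_back(2); --j;
      if (M[i][j] + gap_open == cur) state = 0;
      else if (Y[i][j] + gap_extend == cur) state = 2;
      else state = 1;
    }
  }
  std::reverse(path.begin(), path.end());

  const int L = path.size();
  std::vector<std::string> out(A.size() + B.size(), std::string(L, '-'));
  int pa = 0, pb = 0;
  for (int c = 0; c < L; ++c) {
    int mv = path[c];
    if (mv == 0 || mv == 1) {
      for (size_t r = 0; r < A.size(); ++r) out[r][c] = A[r][pa];
      ++pa;
    }
    if (mv == 0 || mv == 2) {
      for (size_t r = 0; r < B.size(); ++r) out[A.size() + r][c] = B[r][pb];
      ++pb;
    }
  }
  CharacterVector rows(out.size());
  for (size_t r = 0; r < out.size(); ++r) rows[r] = out[r];
  return List::create(_["rows"] = rows, _["score"] = best);
}

// Sum-of-pairs score of an MSA: for every row pair, project (drop joint-gap
// columns) and score residue columns with the matrix and maximal gap runs
// with open + (L-1) * extend.
// [[Rcpp::export]]
double sp_score_cpp(CharacterVector rows, NumericMatrix mat,
                    CharacterVector alphabet, double gap_open, double gap_extend) {
  std::vector<std::string> R;
  for (int k = 0; k < rows.size(); ++k) R.push_back(as<std::string>(rows[k]));
  ScoreLookup S(mat, alphabet);
  double tot = 0.0;
  for (size_t r = 0; r + 1 < R.size(); ++r) {
    for (size_t s = r + 1; s < R.size(); ++s) {
      int prev = 0; // 0 none, 1 gap-in-s run, 2 gap-in-r run
      for (size_t c = 0; c < R[r].size(); ++c) {
        char x = R[r][c], y = R[s][c];
        if (x == '-' && y == '-') continue; // projection drops the column
        if (x != '-' && y != '-') { tot += S(x, y); prev = 0; }
        else if (y == '-') { tot += (prev == 1) ? gap_extend : gap_open; prev = 1; }
        else { tot += (prev == 2) ? gap_extend : gap_open; prev = 2; }
      }
    }
  }
  return tot;
}
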