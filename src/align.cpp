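#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise DP on a precomputed position-score matrix S (n x m),
// where S(i-1, j-1) scores pairing position i of "a" (rows) with position j
// of "b" (columns).  A gap of length L costs go + (L - 1) * ge.
//
// States: M = a_i paired with b_j; Y = gap in a (consumes b); X = gap in b
// (consumes a).  Co-optimal moves are broken by the fixed priority
// M > Y > X, which makes tracebacks deterministic: substitutions beat gaps,
// and gaps in "a" beat gaps in "b".
//
// local = false: global alignment (Needleman-Wunsch), end gaps penalised.
// local = true:  Smith-Waterman; an alignment may start fresh at any pair
// (pointer code 3) and the optimum always ends in the M state.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_affine_cpp(NumericMatrix S, double go, double ge, bool local) {
  const int n = S.nrow(), m = S.ncol();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // pM: predecessor state at (i-1, j-1); pY: state at (i, j-1);
  // pX: state at (i-1, j).  0 = M, 1 = Y, 2 = X, 3 = start.
  std::vector<signed char> pM((n + 1) * W, 3), pX((n + 1) * W, 3),
      pY((n + 1) * W, 3);

  M[0] = 0.0;
  if (!local) {
    for (int i = 1; i <= n; ++i) {
      X[i * W] = -(go + (i - 1) * ge);
      pX[i * W] = (i == 1) ? 0 : 2;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = -(go + (j - 1) * ge);
      pY[j] = (j == 1) ? 0 : 1;
    }
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, lf = i * W + (j - 1);
      // M: pair a_i with b_j
      double best = M[d];
      signed char ptr = 0;
      if (Y[d] > best) { best = Y[d]; ptr = 1; }
      if (X[d] > best) { best = X[d]; ptr = 2; }
      double mval = (best == NEG_INF) ? NEG_INF : best + S(i - 1, j - 1);
      if (local) {
        const double fresh = S(i - 1, j - 1);
        if (fresh > mval) { mval = fresh; ptr = 3; }
        if (mval < 0.0) mval = NEG_INF;
      }
      M[c] = mval;
      pM[c] = ptr;
      // Y: gap in a, consume b_j
      best = (M[lf] == NEG_INF) ? NEG_INF : M[lf] - go;
      ptr = 0;
      if (Y[lf] != NEG_INF && Y[lf] - ge > best) { best = Y[lf] - ge; ptr = 1; }
      if (X[lf] != NEG_INF && X[lf] - go > best) { best = X[lf] - go; ptr = 2; }
      if (local && best < 0.0) best = NEG_INF;
      Y[c] = best;
      pY[c] = ptr;
      // X: gap in b, consume a_i
      best = (M[up] == NEG_INF) ? NEG_INF : M[up] - go;
      ptr = 0;
      if (Y[up] != NEG_INF && Y[up] - go > best) { best = Y[up] - go; ptr = 1; }
      if (X[up] != NEG_INF && X[up] - ge > best) { best = X[up] - ge; ptr = 2; }
      if (local && best < 0.0) best = NEG_INF;
      X[c] = best;
      pX[c] = ptr;
    }
  }

  int ei = n, ej = m;
  signed char state = 0;
  double score;
  if (!local) {
    const int c = n * W + m;
    score = M[c];
    state = 0;
    if (Y[c] > score) { score = Y[c]; state = 1; }
    if (X[c] > score) { score = X[c]; state = 2; }
  } else {
    score = 0.0;
    ei = 0; ej = 0;
    for (int i = 1; i <= n; ++i) {      // ties: smallest i, then smallest j
      for (int j = 1; j <= m; ++j) {
        if (M[i * W + j] > score) { score = M[i * W + j]; ei = i; ej = j; }
      }
    }
    state = 0;
    if (score <= 0.0) {  // no positive-scoring pair anywhere
      return List::create(_["score"] = 0.0,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0),
                          _["a_span"] = IntegerVector::create(0, 0),
                          _["b_span"] = IntegerVector::create(0, 0));
    }
  }

  std::vector<int> ai, bi;
  int i = ei, j = ej;
  bool done = false;
  while (!done && (i > 0 || j > 0)) {
    if (state == 0) {
      const signed char p = pM[i * W + j];
      ai.push_back(i);
      bi.push_back(j);
      --i; --j;
      if (p == 3) done = true; else state = p;
    } else if (state == 1) {
      const signed char p = pY[i * W + j];
      ai.push_back(0);
      bi.push_back(j);
      --j;
      state = p;
    } else {
      const signed char p = pX[i * W + j];
      ai.push_back(i);
      bi.push_back(0);
      --i;
      state = p;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  int a_start = 0, a_end = 0, b_start = 0, b_end = 0;
  for (size_t k = 0; k < ai.size(); ++k) {
    if (ai[k] > 0) { if (a_start == 0) a_start = ai[k]; a_end = ai[k]; }
    if (bi[k] > 0) { if (b_start == 0) b_start = bi[k]; b_end = bi[k]; }
  }
  return List::create(_["score"] = score,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi),
                      _["a_span"] = IntegerVector::create(a_start, a_end),
                      _["b_span"] = IntegerVector::create(b_start, b_end));
}

// Score-only Smith-Waterman over many subjects: the inner loop of proteome
// searching.  q and each subject are 1-based residue codes into submat.
// Column sweep over subject positions j; per row i of the query:
//   Hor[i] = horizontal gap state (gap in query), persists across columns;
//   V      = vertical gap state (gap in subject), accumulates down a column.
// [[Rcpp::export]]
NumericVector sw_scores_cpp(IntegerVector q, List subjects,
                            NumericMatrix submat, double go, double ge) {
  const int n = q.size();
  const int ns = subjects.size();
  const int na = submat.nrow();
  NumericVector out(ns);
  // query profile: for each residue code r, the score of q_i against r
  std::vector<double> prof(static_cast<size_t>(na) * n);
  for (int r = 0; r < na; ++r) {
    for (int i = 0; i < n; ++i) prof[r * (size_t)n + i] = submat(q[i] - 1, r);
  }
  std::vector<double> H(n + 1), Hor(n + 1);
  for (int s = 0; s < ns; ++s) {
    IntegerVector b = subjects[s];
    const int m = b.size();
    std::fill(H.begin(), H.end(), 0.0);
    std::fill(Hor.begin(), Hor.end(), NEG_INF);
    double best = 0.0;
    for (int j = 1; j <= m; ++j) {
      const double *col = &prof[(b[j - 1] - 1) * (size_t)n];
      double V = NEG_INF;
      double diag = 0.0;      // H(i-1, j-1)
      double hprev = 0.0;     // H(i-1, j)
      for (int i = 1; i <= n; ++i) {
        const double hold = H[i];            // H(i, j-1)
        const double hz = std::max(hold - go, Hor[i] - ge);  // gap in query
        Hor[i] = hz;
        V = std::max(hprev - go, V - ge);    // gap in subject
        double h = diag + col[i - 1];
        if (hz > h) h = hz;
        if (V > h) h = V;
        if (h < 0.0) h = 0.0;
        diag = hold;
        hprev = h;
        H[i] = h;
        if (h > best) best = h;
      }
    }
    out[s] = best;
  }
  return out;
}
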