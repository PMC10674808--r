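#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps (Gotoh).
// A gap of length L costs gap_open + L * gap_ext.  Traceback is
// deterministic: on ties prefer the diagonal, then up (gap in the
// reference), then left (gap in the query).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string query, std::string ref,
                      NumericMatrix sub, std::string alphabet,
                      double gap_open, double gap_ext) {
  const int n = (int) query.size(), m = (int) ref.size();
  std::vector<int> amap(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    amap[(unsigned char) alphabet[k]] = (int) k;
  std::vector<int> qi(n), rj(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = amap[(unsigned char) query[i]];
    if (qi[i] < 0) stop("query residue '%s' not in substitution matrix",
                        std::string(1, query[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    rj[j] = amap[(unsigned char) ref[j]];
    if (rj[j] < 0) stop("reference residue '%s' not in substitution matrix",
                        std::string(1, ref[j]).c_str());
  }

  // state matrices: M = diagonal, X = gap in ref (consume query),
  // Y = gap in query (consume ref)
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) X[i * W] = -(gap_open + i * gap_ext);
  for (int j = 1; j <= m; ++j) Y[j] = -(gap_open + j * gap_ext);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j;
      double s = sub(qi[i - 1], rj[j - 1]);
      double dM = M[c - W - 1], dX = X[c - W - 1], dY = Y[c - W - 1];
      M[c] = s + std::max(dM, std::max(dX, dY));
      double uM = M[c - W], uX = X[c - W], uY = Y[c - W];
      X[c] = std::max(uM - gap_open - gap_ext,
                      std::max(uX - gap_ext, uY - gap_open - gap_ext));
      double lM = M[c - 1], lX = X[c - 1], lY = Y[c - 1];
      Y[c] = std::max(lM - gap_open - gap_ext,
                      std::max(lY - gap_ext, lX - gap_open - gap_ext));
    }
  }

  const int cend = n * W + m;
  double best = std::max(M[cend], std::max(X[cend], Y[cend]));

  // traceback; state codes 0 = M, 1 = X (up), 2 = Y (left)
  int state;
  if (M[cend] == best) state = 0;
  else if (X[cend] == best) state = 1;
  else state = 2;
  std::string aq, ar;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    int c = i * W + j;
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      double s = sub(qi[i - 1], rj[j - 1]);
      double target = M[c] - s;
      int cp = c - W - 1;
      aq.push_back(query[i - 1]);
      ar.push_back(ref[j - 1]);
      --i; --j;
      if (M[cp] >= target - eps) state = 0;
      else if (X[cp] >= target - eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      int cp = c - W;
      double v = X[c];
      aq.push_back(query[i - 1]);
      ar.push_back('-');
      --i;
      if (M[cp] - gap_open - gap_ext >= v - eps) state = 0;
      else if (X[cp] - gap_ext >= v - eps) state = 1;
      else state = 2;
    } else {
      int cp = c - 1;
      double v = Y[c];
      aq.push_back('-');
      ar.push_back(ref[j - 1]);
      --j;
      if (M[cp] - gap_open - gap_ext >= v - eps) state = 0;
      else if (X[cp] - gap_open - gap_ext >= v - eps) state = 1;
      else state = 2;  // continue the gap
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());
  return List::create(_["score"] = best, _["aligned_query"] = aq,
                      _["aligned_ref"] = ar);
}
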