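#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Smith-Waterman local alignment scores with affine gaps.
//
// Gap convention matches the usual substitution-matrix packages: a gap of
// length L costs gap_open + L * gap_ext (the first gap residue pays both).
// Only the optimal score is computed (linear memory, no traceback).
// A per-query position profile (query position x alphabet) is precomputed
// so the inner loop does one contiguous lookup per cell.

static inline void build_index(const std::string &alphabet, int *idx) {
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char) alphabet[i]] = (int) i;
}

// [[Rcpp::export(name = ".sw_score_many")]]
NumericVector sw_score_many(std::string query,
                            std::vector<std::string> subjects,
                            NumericMatrix submat,
                            std::string alphabet,
                            double gap_open, double gap_ext) {
  const double NEG = -std::numeric_limits<double>::infinity();
  int idx[256];
  build_index(alphabet, idx);
  const int xi = idx[(unsigned char) 'X'];
  const int A = (int) alphabet.size();
  const int nr = submat.nrow();
  const int m = (int) query.size();

  // profile: prof[i * A + a] = substitution score of query residue i vs a
  std::vector<double> prof((size_t) m * A);
  for (int i = 0; i < m; ++i) {
    int k = idx[(unsigned char) query[i]];
    if (k < 0) k = xi;
    for (int a = 0; a < A; ++a)
      prof[(size_t) i * A + a] = submat[k + (size_t) a * nr];
  }

  const double oe = gap_open + gap_ext;
  NumericVector out(subjects.size());
  std::vector<double> H, D;
  std::vector<int> t;

  for (size_t s = 0; s < subjects.size(); ++s) {
    const std::string &sub = subjects[s];
    const int n = (int) sub.size();
    t.resize(n);
    for (int j = 0; j < n; ++j) {
      int k = idx[(unsigned char) sub[j]];
      t[j] = (k >= 0) ? k : xi;
    }
    H.assign(n + 1, 0.0);
    D.assign(n + 1, NEG);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
      const double *srow = &prof[(size_t) (i - 1) * A];
      double prev_diag = H[0];
      double I = NEG;
      for (int j = 1; j <= n; ++j) {
        double up = H[j];
        double dj = up - oe;
        double dd = D[j] - gap_ext;
        if (dd > dj) dj = dd;
        D[j] = dj;
        double ii = H[j - 1] - oe;
        double ie = I - gap_ext;
        I = (ie > ii) ? ie : ii;
        double h = prev_diag + srow[t[j - 1]];
        prev_diag = up;
        if (dj > h) h = dj;
        if (I > h) h = I;
        if (h < 0.0) h = 0.0;
        H[j] = h;
        if (h > best) best = h;
      }
    }
    out[s] = best;
  }
  return out;
}
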