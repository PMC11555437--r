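#include <Rcpp.h>
using namespace Rcpp;

// Pairwise UniFrac-family distances from per-sample branch proportions.
//
// cum:    n x E matrix; cum(i, e) is the total relative abundance in
//         sample i of the taxa descending from branch e.
// bl:     length-E branch lengths.
// alpha:  exponents for the generalized variant (may be empty).
//
// Returns unweighted, weighted-normalized, and one generalized matrix per
// alpha.  Branches absent from both samples contribute to neither
// numerator nor denominator; a pair with an empty union is at distance 0.
//
// The exponents 0, 0.25, 0.5, 0.75 and 1 (the conventional grid) are
// computed via sqrt instead of pow; access is through a transposed
// (branch-major) copy so the inner loop is contiguous.
// [[Rcpp::export]]
List unifrac_pairwise(NumericMatrix cum, NumericVector bl,
                      NumericVector alpha) {
  const int n = cum.nrow(), E = cum.ncol(), A = alpha.size();
  NumericMatrix duw(n, n), dw(n, n);
  std::vector<NumericMatrix> gen;
  for (int a = 0; a < A; ++a) gen.push_back(NumericMatrix(n, n));

  // branch-major copy: column i holds all branches of sample i
  std::vector<double> ct(static_cast<size_t>(n) * E);
  for (int i = 0; i < n; ++i)
    for (int e = 0; e < E; ++e)
      ct[static_cast<size_t>(i) * E + e] = cum(i, e);

  // 0: alpha 0, 1: 0.25, 2: 0.5, 3: 0.75, 4: 1, 5: generic pow
  std::vector<int> kind(A);
  for (int a = 0; a < A; ++a) {
    double al = alpha[a];
    kind[a] = (al == 0.0) ? 0 : (al == 0.25) ? 1 : (al == 0.5) ? 2 :
              (al == 0.75) ? 3 : (al == 1.0) ? 4 : 5;
  }
  const bool needSqrt = [&] {
    for (int a = 0; a < A; ++a)
      if (kind[a] >= 1 && kind[a] <= 3) return true;
    return false;
  }();

  std::vector<double> gnum(A), gden(A);
  for (int i = 0; i < n; ++i) {
    const double *ci = &ct[static_cast<size_t>(i) * E];
    for (int j = i + 1; j < n; ++j) {
      const double *cj = &ct[static_cast<size_t>(j) * E];
      double uw_num = 0.0, uw_den = 0.0, w_num = 0.0, w_den = 0.0;
      std::fill(gnum.begin(), gnum.end(), 0.0);
      std::fill(gden.begin(), gden.end(), 0.0);
      for (int e = 0; e < E; ++e) {
        const double b = bl[e];
        if (b <= 0.0) continue;
        const double pi = ci[e], pj = cj[e];
        const double s = pi + pj;
        if (s <= 0.0) continue;
        const double ad = (pi > pj) ? pi - pj : pj - pi;
        // unweighted: presence/absence of the branch
        uw_den += b;
        if ((pi > 0.0) != (pj > 0.0)) uw_num += b;
        // weighted (normalized)
        w_num += b * ad;
        w_den += b * s;
        // generalized: b * s^alpha * |pi-pj|/s
        if (A > 0) {
          const double rel = ad / s;
          const double r2 = needSqrt ? std::sqrt(s) : 0.0;
          for (int a = 0; a < A; ++a) {
            double w;
            switch (kind[a]) {
            case 0: w = b; break;
            case 1: w = b * std::sqrt(r2); break;
            case 2: w = b * r2; break;
            case 3: w = b * r2 * std::sqrt(r2); break;
            case 4: w = b * s; break;
            default: w = b * std::pow(s, alpha[a]);
            }
            gnum[a] += w * rel;
            gden[a] += w;
          }
        }
      }
      duw(i, j) = duw(j, i) = (uw_den > 0.0) ? uw_num / uw_den : 0.0;
      dw(i, j) = dw(j, i) = (w_den > 0.0) ? w_num / w_den : 0.0;
      for (int a = 0; a < A; ++a)
        gen[a](i, j) = gen[a](j, i) =
            (gden[a] > 0.0) ? gnum[a] / gden[a] : 0.0;
    }
  }
  List dgen(A);
  for (int a = 0; a < A; ++a) dgen[a] = gen[a];
  return List::create(_["unweighted"] = duw, _["weighted"] = dw,
                      _["generalized"] = dgen);
}
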