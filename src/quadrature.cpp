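#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Moment-to-recurrence step of the Golub-Welsch construction.
//
// Input: raw moments m_0..m_{L-1} of a (hoped-for) positive measure and the
// number of quadrature points P with 2P <= L. The moments are rescaled as
// s_j = m_j / (m_0 c^j) with c = m_1/m_0, which removes the factorial growth
// of the raw moments; the Hankel matrix of the s_j is Cholesky-factorized in
// long double, and the three-term recurrence coefficients of the associated
// orthogonal polynomials are read off the factor. The caller assembles the
// symmetric tridiagonal Jacobi matrix, eigen-decomposes it, and rescales
// nodes by c and weights by m_0.
//
// Only the first P rows of the (P+1)-column Hankel factor are needed (they
// involve moments up to s_{2P-1}), so a P-point rule genuinely requires just
// 2P moments.
//
// Returns ok = FALSE with the failing pivot index when the Hankel matrix is
// not numerically positive definite at this P.
// [[Rcpp::export]]
List cpp_jacobi_from_moments(NumericVector moments, int n_points) {
  const int P = n_points;
  const int L = moments.size();
  if (P < 1) stop("n_points must be >= 1");
  if (2 * P > L) stop("need at least 2*n_points moments");
  if (moments[0] <= 0) stop("zeroth moment must be positive");

  long double m0 = (long double)moments[0];
  long double c = 1.0L;
  if (L >= 2 && moments[1] > 0) c = (long double)moments[1] / m0;

  // scaled moments s_0..s_{2P-1}
  std::vector<long double> s(2 * P);
  long double cp = 1.0L;
  for (int j = 0; j < 2 * P; ++j) {
    s[j] = (long double)moments[j] / (m0 * cp);
    cp *= c;
  }

  // Row-wise Cholesky of the (P+1)x(P+1) Hankel H[i][j] = s_{i+j}, rows
  // 0..P-1 only (row P would need s_{2P}). R is upper triangular.
  std::vector<std::vector<long double> > R(P, std::vector<long double>(P + 1, 0.0L));
  for (int i = 0; i < P; ++i) {
    for (int j = i; j <= P; ++j) {
      long double acc = s[i + j];
      for (int t = 0; t < i; ++t) acc -= R[t][i] * R[t][j];
      if (j == i) {
        if (!(acc > 0.0L) || !std::isfinite((double)acc))
          return List::create(_["ok"] = false, _["pivot"] = i + 1);
        R[i][i] = sqrtl(acc);
      } else {
        R[i][j] = acc / R[i][i];
      }
    }
  }

  // Recurrence coefficients: alpha_k (Jacobi diagonal) and b_k (off-diagonal)
  NumericVector alpha(P), b(std::max(P - 1, 0));
  for (int kk = 0; kk < P; ++kk) {
    long double a = R[kk][kk + 1] / R[kk][kk];
    if (kk > 0) a -= R[kk - 1][kk] / R[kk - 1][kk - 1];
    alpha[kk] = (double)a;
    if (kk >= 1) b[kk - 1] = (double)(R[kk][kk] / R[kk - 1][kk - 1]);
  }
  return List::create(_["ok"] = true, _["alpha"] = alpha, _["b"] = b,
                      _["scale"] = (double)c);
}
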