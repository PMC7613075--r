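#include <Rcpp.h>
using namespace Rcpp;

// Selection-weight kernel for the neural binding model likelihood.
//
// For every trial t and item i, integrates the item's cue decode-error
// density over the angular grid against the product of the competitors'
// survival functions:
//   s[t,i,m] = dx * sum_e fcue(m, e) * prod_{j != i} SURV(gdelta[t,j], a(i,e))
// where a(i,e) is the grid index of |wrap(delta_i + theta_e)| and
// SURV(d, a) = P(|wrap(delta_d + eps)| > a * dx) for the marginal cue
// decode error eps. Rows of the result are trial-major with item minor.
//
// gdelta: T x N integer matrix of cue-offset grid indices (0..G-1)
// surv:   G x (G/2 + 1) survival matrix
// fcue:   (M+1) x G decode-error density table (rows = spike count)
// dx:     grid step 2*pi/G
// [[Rcpp::export]]
NumericMatrix nbm_sel_kernel(IntegerMatrix gdelta, NumericMatrix surv,
                             NumericMatrix fcue, double dx) {
  const int T = gdelta.nrow();
  const int N = gdelta.ncol();
  const int G = surv.nrow();
  const int half = G / 2;
  const int M1 = fcue.nrow();
  if (fcue.ncol() != G) stop("fcue grid mismatch");
  if (surv.ncol() != half + 1) stop("surv shape mismatch");

  NumericMatrix s(T * N, M1);
  const double* survp = surv.begin();   // column-major G x (half+1)
  const double* fcuep = fcue.begin();   // column-major M1 x G
  double* sp = s.begin();               // column-major (T*N) x M1
  std::vector<double> w(G);
  std::vector<double> acc(M1);

  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      const int gi = gdelta(t, i);
      for (int e = 0; e < G; ++e) {
        int j = gi + e - half;
        j %= G;
        if (j < 0) j += G;
        int a = j - half;
        if (a < 0) a = -a;
        // surv(row = gdelta[t,k], col = a): column-major offset a*G + row
        const double* scol = survp + (std::size_t)a * G;
        double prod = 1.0;
        for (int k = 0; k < N; ++k) {
          if (k != i) prod *= scol[gdelta(t, k)];
        }
        w[e] = prod;
      }
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int e = 0; e < G; ++e) {
        const double we = w[e];
        if (we <= 0.0) continue;
        const double* fcol = fcuep + (std::size_t)e * M1;
        for (int m = 0; m < M1; ++m) acc[m] += fcol[m] * we;
      }
      const std::size_t row = (std::size_t)t * N + i;
      for (int m = 0; m < M1; ++m) sp[(std::size_t)m * T * N + row] = acc[m] * dx;
    }
  }
  return s;
}
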