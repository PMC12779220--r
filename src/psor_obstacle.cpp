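#include <Rcpp.h>
using namespace Rcpp;

// Projected SOR for the discrete zero-order obstacle problem
//
//   -D C'' + kv = 0  where C > ccrit,   C >= ccrit,
//   C(0) = Cs (surface), C'(L) = 0 (slab bottom)
//
// on a uniform grid of n nodes with spacing h. Complementarity handles the
// dead zone: wherever the unconstrained update would fall below ccrit the
// solution sits on the obstacle and the consumption switches off, which is
// exactly the masked-consumption formulation.
// [[Rcpp::export]]
NumericVector psor_obstacle(int n, double h, double D, double kv,
                            double ccrit, double Cs,
                            double omega, double tol, int maxit) {
  NumericVector C(n, Cs);
  C[0] = Cs;
  const double src = kv * h * h / D;
  for (int it = 0; it < maxit; ++it) {
    double delta = 0.0;
    for (int i = 1; i < n; ++i) {
      double gs;
      if (i < n - 1) gs = 0.5 * (C[i - 1] + C[i + 1] - src);
      else gs = C[n - 2] - 0.5 * src;       // ghost-node zero flux
      double cn = C[i] + omega * (gs - C[i]);
      if (cn < ccrit) cn = ccrit;
      double d = std::abs(cn - C[i]);
      if (d > delta) delta = d;
      C[i] = cn;
    }
    if (delta < tol) break;
  }
  return C;
}
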