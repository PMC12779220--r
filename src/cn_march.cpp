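#include <Rcpp.h>
using namespace Rcpp;

// Crank-Nicolson finite-volume march of the 1D diffusion(-reaction) problem
//
//   dC/dt = d/dz( D(z) dC/dz ) - kv * 1{C > ccrit}
//
// on an arbitrary (piecewise-uniform) node grid z[0..n-1], z[0] = dish bottom
// (zero flux), z[n-1] = top surface.  Edge j connects nodes j and j+1 and
// carries a single diffusivity Dedge[j] (layer interfaces must fall on nodes,
// so each edge lies inside one layer and interfacial flux continuity is
// automatic in the finite-volume form).
//
// top_bc: 0 = Dirichlet, value bvals[k] at time level k; 1 = sealed (no flux).
// bvals must have nsteps + 1 entries (one per time level including t = 0).
// The zero-order sink is applied explicitly and floored at ccrit so the
// dead zone of the obstacle problem sits at the critical concentration.
//
// Returns an n x length(out_times) matrix; requested times are linearly
// interpolated between the bracketing internal time levels.
// [[Rcpp::export]]
NumericMatrix cn_march(NumericVector z, NumericVector Dedge,
                       NumericVector c_init, NumericVector bvals,
                       double dt, int nsteps, int top_bc,
                       NumericVector out_times,
                       double kv, double ccrit) {
  const int n = z.size();
  const int nout = out_times.size();
  if (Dedge.size() != n - 1) stop("Dedge must have length(z) - 1 entries");
  if (c_init.size() != n) stop("c_init must match the grid");
  if (top_bc == 0 && bvals.size() < nsteps + 1)
    stop("bvals must supply one value per time level");

  // geometric factors: edge conductance g[j] = D_j / h_j, node volume v[i]
  std::vector<double> g(n - 1), v(n);
  for (int j = 0; j < n - 1; ++j) {
    double h = z[j + 1] - z[j];
    if (h <= 0) stop("grid must be strictly increasing");
    g[j] = Dedge[j] / h;
  }
  v[0] = (z[1] - z[0]) / 2.0;
  v[n - 1] = (z[n - 1] - z[n - 2]) / 2.0;
  for (int i = 1; i < n - 1; ++i) v[i] = (z[i + 1] - z[i - 1]) / 2.0;

  // constant tridiagonal CN coefficients (top row may be overwritten)
  std::vector<double> al(n), ad(n), au(n);
  for (int i = 0; i < n; ++i) {
    double gl = (i > 0) ? g[i - 1] : 0.0;
    double gu = (i < n - 1) ? g[i] : 0.0;
    al[i] = -0.5 * dt * gl / v[i];
    au[i] = -0.5 * dt * gu / v[i];
    ad[i] = 1.0 + 0.5 * dt * (gl + gu) / v[i];
  }
  if (top_bc == 0) { al[n - 1] = 0.0; ad[n - 1] = 1.0; au[n - 1] = 0.0; }

  std::vector<double> cur(c_init.begin(), c_init.end());
  std::vector<double> prev(n), rhs(n), cp(n), dp(n);
  NumericMatrix out(n, nout);

  int iout = 0;
  // snapshots at/before t = 0
  while (iout < nout && out_times[iout] <= 0.0) {
    for (int i = 0; i < n; ++i) out(i, iout) = cur[i];
    ++iout;
  }

  for (int k = 0; k < nsteps && iout < nout; ++k) {
    prev = cur;
    // explicit half of the diffusion operator + explicit sink
    for (int i = 0; i < n; ++i) {
      double gl = (i > 0) ? g[i - 1] : 0.0;
      double gu = (i < n - 1) ? g[i] : 0.0;
      double fu = (i < n - 1) ? gu * (prev[i + 1] - prev[i]) : 0.0;
      double fl = (i > 0) ? gl * (prev[i] - prev[i - 1]) : 0.0;
      rhs[i] = prev[i] + 0.5 * dt * (fu - fl) / v[i];
      if (kv > 0.0 && prev[i] > ccrit) rhs[i] -= dt * kv;
    }
    if (top_bc == 0) rhs[n - 1] = bvals[k + 1];

    // Thomas algorithm
    cp[0] = au[0] / ad[0];
    dp[0] = rhs[0] / ad[0];
    for (int i = 1; i < n; ++i) {
      double m = ad[i] - al[i] * cp[i - 1];
      cp[i] = au[i] / m;
      dp[i] = (rhs[i] - al[i] * dp[i - 1]) / m;
    }
    cur[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) cur[i] = dp[i] - cp[i] * cur[i + 1];

    if (kv > 0.0) {
      // the sink may not push a consuming cell below the critical level
      for (int i = 0; i < n; ++i)
        if (prev[i] > ccrit && cur[i] < ccrit) cur[i] = ccrit;
    }

    double t0 = k * dt, t1 = (k + 1) * dt;
    while (iout < nout && out_times[iout] <= t1 + 1e-12 * dt) {
      double w = (out_times[iout] - t0) / dt;
      if (w < 0.0) w = 0.0;
      if (w > 1.0) w = 1.0;
      for (int i = 0; i < n; ++i)
        out(i, iout) = (1.0 - w) * prev[i] + w * cur[i];
      ++iout;
    }
  }
  if (iout < nout) stop("requested output times extend beyond the march");
  return out;
}
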