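#include <Rcpp.h>
using namespace Rcpp;

// Batch Gillespie SSA for the Lotka-Volterra network
//   Y1 -> 2Y1        (rate r1 * Y1)
//   Y1 + Y2 -> 2Y2   (rate r2 * Y1 * Y2)
//   Y2 -> 0          (rate r3 * Y2)
// One exact trajectory per element of the rate vectors, all started at
// (y1_0, y2_0) and run for duration dt; returns the final states.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix lv_ssa_batch(int n, int y1_0, int y2_0,
                           NumericVector r1, NumericVector r2,
                           NumericVector r3, double dt) {
  if (y1_0 < 0 || y2_0 < 0) stop("counts must be non-negative");
  IntegerMatrix out(n, 2);
  for (int k = 0; k < n; ++k) {
    double a1 = r1[k % r1.size()];
    double a2 = r2[k % r2.size()];
    double a3 = r3[k % r3.size()];
    long y1 = y1_0, y2 = y2_0;
    double t = 0.0;
    for (;;) {
      double h1 = a1 * (double)y1;
      double h2 = a2 * (double)y1 * (double)y2;
      double h3 = a3 * (double)y2;
      double h0 = h1 + h2 + h3;
      if (h0 <= 0.0) break;              // absorbing (all-zero) state
      t += R::exp_rand() / h0;
      if (t > dt) break;
      double u = unif_rand() * h0;
      if (u < h1)            y1 += 1;    // prey birth
      else if (u < h1 + h2) { y1 -= 1; y2 += 1; } // predation
      else                   y2 -= 1;    // predator death
    }
    out(k, 0) = (int)y1;
    out(k, 1) = (int)y2;
  }
  return out;
}

// Log-density of an m-component Gaussian mixture with common bandwidth,
// evaluated by log-sum-exp at each row of `query`. `prec` is the inverse
// bandwidth matrix H^{-1}; `lconst` collects the normalising constant
// -d/2 log(2*pi) - 1/2 log det H - log m. Written in C++ because lattice
// evaluation multiplies m kernel centres by up to 128^3 lattice points.
// [[Rcpp::export]]
NumericVector gauss_mix_logpdf(NumericMatrix pts, NumericMatrix prec,
                               double lconst, NumericMatrix query) {
  const int m = pts.nrow(), d = pts.ncol(), G = query.nrow();
  if (prec.nrow() != d || prec.ncol() != d || query.ncol() != d)
    stop("dimension mismatch");
  NumericVector out(G);
  std::vector<double> terms(m);
  std::vector<double> diff(d);
  for (int g = 0; g < G; ++g) {
    double mx = R_NegInf;
    for (int j = 0; j < m; ++j) {
      double q = 0.0;
      for (int a = 0; a < d; ++a) diff[a] = query(g, a) - pts(j, a);
      for (int a = 0; a < d; ++a) {
        double s = 0.0;
        for (int b = 0; b < d; ++b) s += prec(a, b) * diff[b];
        q += s * diff[a];
      }
      double v = -0.5 * q;
      terms[j] = v;
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int j = 0; j < m; ++j) s += std::exp(terms[j] - mx);
    out[g] = mx + std::log(s) + lconst;
  }
  return out;
}
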