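#include <Rcpp.h>
using namespace Rcpp;

// Soft-margin SVM dual solved by sequential minimal optimization with
// maximal-violating-pair working-set selection.  The Gram matrix is given
// explicitly, so the same solver serves every kernel family and the MKL
// combination K(d) = sum_m d_m K_m.
//
//   max_alpha  sum alpha_i - 1/2 sum_ij alpha_i alpha_j y_i y_j K_ij
//   s.t.       0 <= alpha_i <= C,  sum_i y_i alpha_i = 0
//
// Internally minimises f(alpha) = 1/2 a'Qa - e'a with Q_ij = y_i y_j K_ij.

// [[Rcpp::export]]
List smo_solve(const NumericMatrix& K, const IntegerVector& y, double C,
               double eps = 1e-5, int max_iter = 100000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("K must be square and conformable with y");
  const double tau = 1e-12;

  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  bool converged = false;
  for (; iter < max_iter; ++iter) {
    // working-set selection: i = argmax_{I_up} -y G, j = argmin_{I_low} -y G
    int i = -1, j = -1;
    double Gmax = -INFINITY, Gmin = INFINITY;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
      bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) { converged = true; break; }

    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double ai = alpha[i], aj = alpha[j];
    const double old_ai = ai, old_aj = aj;

    // in both sign cases Qii + Qjj +/- 2Qij reduces to Kii + Kjj - 2Kij
    double quad = Kii + Kjj - 2.0 * Kij;
    if (quad <= 0) quad = tau;
    if (y[i] != y[j]) {
      double delta = (-G[i] - G[j]) / quad;
      double diff = ai - aj;
      ai += delta; aj += delta;
      if (diff > 0) {
        if (aj < 0) { aj = 0; ai = diff; }
      } else {
        if (ai < 0) { ai = 0; aj = -diff; }
      }
      if (diff > 0) {
        if (ai > C) { ai = C; aj = C - diff; }
      } else {
        if (aj > C) { aj = C; ai = C + diff; }
      }
    } else {
      double delta = (G[i] - G[j]) / quad;
      double sum = ai + aj;
      ai -= delta; aj += delta;
      if (sum > C) {
        if (ai > C) { ai = C; aj = sum - C; }
      } else {
        if (aj < 0) { aj = 0; ai = sum; }
      }
      if (sum > C) {
        if (aj > C) { aj = C; ai = sum - C; }
      } else {
        if (ai < 0) { ai = 0; aj = sum; }
      }
    }

    const double dai = ai - old_ai, daj = aj - old_aj;
    if (std::abs(dai) < tau && std::abs(daj) < tau) { converged = true; break; }
    alpha[i] = ai; alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias from free support vectors; fall back to the violating-pair midpoint
  double bsum = 0.0; int nfree = 0;
  double Gmax = -INFINITY, Gmin = INFINITY;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    bool up  = (y[t] == 1) ? (alpha[t] < C) : (alpha[t] > 0);
    bool low = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < C);
    if (up && v > Gmax) Gmax = v;
    if (low && v < Gmin) Gmin = v;
    if (alpha[t] > tau && alpha[t] < C - tau) { bsum += -y[t] * G[t]; ++nfree; }
  }
  double b = nfree > 0 ? bsum / nfree : (Gmax + Gmin) / 2.0;

  double sum_a = 0.0, aG = 0.0;
  for (int t = 0; t < n; ++t) { sum_a += alpha[t]; aG += alpha[t] * G[t]; }
  double obj = 0.5 * (sum_a - aG);  // dual objective value

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["objective"] = obj,
                      _["iterations"] = iter, _["converged"] = converged);
}

// K(d) = sum_m d_m K_m for a bank of Gram matrices
// [[Rcpp::export]]
NumericMatrix combine_kernels(const List& Ks, const NumericVector& d) {
  const int m = Ks.size();
  if (d.size() != m) stop("length(d) must equal length(Ks)");
  NumericMatrix K0 = Ks[0];
  const int nr = K0.nrow(), nc = K0.ncol();
  NumericMatrix out(nr, nc);
  for (int k = 0; k < m; ++k) {
    if (d[k] == 0.0) continue;
    NumericMatrix Km = Ks[k];
    if (Km.nrow() != nr || Km.ncol() != nc) stop("kernel dimensions differ");
    const double w = d[k];
    for (int jj = 0; jj < nc; ++jj)
      for (int ii = 0; ii < nr; ++ii)
        out(ii, jj) += w * Km(ii, jj);
  }
  return out;
}

// q_m = v' K_m v for every kernel in the bank (v = alpha * y)
// [[Rcpp::export]]
NumericVector kernel_quadforms(const List& Ks, const NumericVector& v) {
  const int m = Ks.size();
  NumericVector out(m);
  const int n = v.size();
  for (int k = 0; k < m; ++k) {
    NumericMatrix Km = Ks[k];
    if (Km.nrow() != n) stop("kernel/vector dimensions differ");
    double q = 0.0;
    for (int jj = 0; jj < n; ++jj) {
      if (v[jj] == 0.0) continue;
      double s = 0.0;
      for (int ii = 0; ii < n; ++ii) s += v[ii] * Km(ii, jj);
      q += s * v[jj];
    }
    out[k] = q;
  }
  return out;
}
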