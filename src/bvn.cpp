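#include <Rcpp.h>
using namespace Rcpp;

// Upper-tail probability P(X > h, Y > k) of a standard bivariate normal
// with correlation r, via the single integral
//   P = Phi(-h) Phi(-k) + (1/2pi) int_0^r exp(-(h^2 - 2 h k t + k^2) /
//        (2 (1 - t^2))) / sqrt(1 - t^2) dt
// evaluated with composite 16-point Gauss-Legendre quadrature on segments of
// length <= 0.05.  Absolute accuracy is well below 1e-12 for |r| <= 0.999,
// which is the clipping range used by the correlation estimators.

static const double GL_X[8] = {
  0.0950125098376374, 0.2816035507792589, 0.4580167776572274,
  0.6178762444026438, 0.7554044083550030, 0.8656312023878318,
  0.9445750230732326, 0.9894009349916499};
static const double GL_W[8] = {
  0.1894506104550685, 0.1826034150449236, 0.1691565193950025,
  0.1495959888165767, 0.1246289712555339, 0.0951585116824928,
  0.0622535239386479, 0.0271524594117541};

static double phi_lower(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

static double bvn_upper_scalar(double h, double k, double r) {
  if (r > 0.999) r = 0.999;
  if (r < -0.999) r = -0.999;
  double base = phi_lower(-h) * phi_lower(-k);
  if (r == 0.0) return base;
  int nseg = (int)std::ceil(std::fabs(r) / 0.05);
  if (nseg < 1) nseg = 1;
  double seg = r / nseg;  // signed
  double acc = 0.0;
  for (int s = 0; s < nseg; s++) {
    double a = s * seg, b = (s + 1) * seg;
    double mid = 0.5 * (a + b), half = 0.5 * (b - a);
    for (int i = 0; i < 8; i++) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        double t = mid + sgn * half * GL_X[i];
        double omt2 = 1.0 - t * t;
        double e = std::exp(-(h * h - 2.0 * h * k * t + k * k) / (2.0 * omt2));
        acc += GL_W[i] * half * e / std::sqrt(omt2);
      }
    }
  }
  double p = base + acc / (2.0 * M_PI);
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return p;
}

//' Bivariate normal upper-tail probabilities (vectorised)
//'
//' @param h,k numeric vectors of lower limits (the probability is over
//'   \code{X > h, Y > k}); recycled to common length.
//' @param r numeric vector of correlations, clipped to \code{[-0.999, 0.999]}.
//' @return numeric vector of probabilities.
//' @keywords internal
// [[Rcpp::export]]
NumericVector bvn_upper(NumericVector h, NumericVector k, NumericVector r) {
  R_xlen_t n = std::max(h.size(), std::max(k.size(), r.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double hh = h[i % h.size()], kk = k[i % k.size()], rr = r[i % r.size()];
    double res;
    if (hh == R_NegInf && kk == R_NegInf) res = 1.0;
    else if (hh == R_PosInf || kk == R_PosInf) res = 0.0;
    else if (hh == R_NegInf) res = phi_lower(-kk);
    else if (kk == R_NegInf) res = phi_lower(-hh);
    else res = bvn_upper_scalar(hh, kk, rr);
    out[i] = res;
  }
  return out;
}

// Cell probabilities of an R x C contingency table implied by a bivariate
// normal liability with correlation rho and row/column thresholds a, b
// (strictly increasing, finite).  Categories are the intervals
// (-Inf, a1], (a1, a2], ..., (a_{R-1}, Inf).
// [[Rcpp::export]]
NumericMatrix bvn_cell_probs(NumericVector a, NumericVector b, double rho) {
  int R_ = a.size() + 1, C_ = b.size() + 1;
  // Upper-tail at every threshold pair (with -Inf sentinel at index 0)
  std::vector<double> ax(R_ + 1), bx(C_ + 1);
  ax[0] = R_NegInf; bx[0] = R_NegInf;
  for (int i = 0; i < R_ - 1; i++) ax[i + 1] = a[i];
  for (int j = 0; j < C_ - 1; j++) bx[j + 1] = b[j];
  ax[R_] = R_PosInf; bx[C_] = R_PosInf;
  NumericMatrix U(R_ + 1, C_ + 1);
  for (int i = 0; i <= R_; i++)
    for (int j = 0; j <= C_; j++) {
      if (ax[i] == R_PosInf || bx[j] == R_PosInf) { U(i, j) = 0.0; continue; }
      if (ax[i] == R_NegInf && bx[j] == R_NegInf) { U(i, j) = 1.0; continue; }
      if (ax[i] == R_NegInf) { U(i, j) = phi_lower(-bx[j]); continue; }
      if (bx[j] == R_NegInf) { U(i, j) = phi_lower(-ax[i]); continue; }
      U(i, j) = bvn_upper_scalar(ax[i], bx[j], rho);
    }
  NumericMatrix P(R_, C_);
  for (int i = 0; i < R_; i++)
    for (int j = 0; j < C_; j++) {
      double p = U(i, j) - U(i + 1, j) - U(i, j + 1) + U(i + 1, j + 1);
      P(i, j) = p > 1e-300 ? p : 1e-300;
    }
  return P;
}

// Profile log-likelihood of an observed table at correlation rho given
// thresholds; used by the one-dimensional tetrachoric/polychoric optimiser.
// [[Rcpp::export]]
double bvn_table_loglik(NumericMatrix counts, NumericVector a, NumericVector b,
                        double rho) {
  NumericMatrix P = bvn_cell_probs(a, b, rho);
  double ll = 0.0;
  for (int i = 0; i < counts.nrow(); i++)
    for (int j = 0; j < counts.ncol(); j++)
      if (counts(i, j) > 0) ll += counts(i, j) * std::log(P(i, j));
  return ll;
}
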