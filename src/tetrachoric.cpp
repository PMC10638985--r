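// Tetrachoric correlation core: bivariate normal rectangle probabilities
// (Genz's port of the Drezner-Wesolowsky algorithm, abs. accuracy ~1e-15)
// and two-step ML estimation of the latent correlation from 2x2 tables.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586;

// Univariate standard normal CDF.
static double phid(double z) {
  return 0.5 * erfc(-z / M_SQRT2);
}

// Gauss-Legendre nodes/weights (positive half) for 6-, 12- and 20-point rules.
static const double GL_X[3][10] = {
  {-0.9324695142031521, -0.6612093864662645, -0.2386191860831969,
   0, 0, 0, 0, 0, 0, 0},
  {-0.9815606342467192, -0.9041172563704749, -0.7699026741943047,
   -0.5873179542866175, -0.3678314989981802, -0.1252334085114689,
   0, 0, 0, 0},
  {-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
   -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
   -0.5108670019508271, -0.3737060887154195, -0.2277858511416451,
   -0.07652652113349734}
};
static const double GL_W[3][10] = {
  {0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
   0, 0, 0, 0, 0, 0, 0},
  {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
   0.2031674267230659, 0.2334925365383548, 0.2491470458134028,
   0, 0, 0, 0},
  {0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
   0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
   0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
   0.1527533871307259}
};

// P(X > h, Y > k) for standard bivariate normal with correlation r.
static double bvnu(double h, double k, double r) {
  if (!R_finite(h) || !R_finite(k)) {
    if (h == R_PosInf || k == R_PosInf) return 0.0;
    if (h == R_NegInf) return phid(-k);
    if (k == R_NegInf) return phid(-h);
  }
  int ng;
  double ar = std::fabs(r);
  if (ar < 0.3) ng = 0; else if (ar < 0.75) ng = 1; else ng = 2;
  int lg = (ng == 0) ? 3 : (ng == 1 ? 6 : 10);
  double hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * GL_X[ng][i] + 1.0) / 2.0);
          bvn += GL_W[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * TWOPI);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
              (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
               c * d * as * as / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        double sp = std::sqrt(TWOPI) * phid(-b / a);
        bvn -= std::exp(-hk / 2.0) * sp * b *
               (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double x = a * (is * GL_X[ng][i] + 1.0);
          double xs = x * x;
          double rs = std::sqrt(1.0 - xs);
          double asr1 = -(bs / xs + hk) / 2.0;
          if (asr1 > -100.0) {
            double sp = 1.0 + c * xs * (1.0 + d * xs);
            double ep = std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs;
            bvn += a * GL_W[ng][i] * std::exp(asr1) * (ep - sp);
          }
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (r > 0) bvn += phid(-std::max(h, k));
    else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return std::max(0.0, std::min(1.0, bvn));
}

// [[Rcpp::export]]
NumericVector pbvn_cpp(NumericVector h, NumericVector k, NumericVector r) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = bvnu(-h[i], -k[i], r[i]);
  return out;
}

// Multinomial log-likelihood of a 2x2 table under the tetrachoric model,
// thresholds fixed.
static double tetra_loglik(double rho, double t1, double t2,
                           double n11, double n10, double n01, double n00) {
  double p1 = phid(-t1);   // P(X_i = 1) = P(V_i > t1)
  double p2 = phid(-t2);
  double p11 = bvnu(t1, t2, rho);
  double eps = 1e-12;
  double p10 = std::max(p1 - p11, eps);
  double p01 = std::max(p2 - p11, eps);
  double p00 = std::max(1.0 - p1 - p2 + p11, eps);
  p11 = std::max(p11, eps);
  return n11 * std::log(p11) + n10 * std::log(p10) +
         n01 * std::log(p01) + n00 * std::log(p00);
}

// Golden-section maximization over a bracketed interval (unimodal in rho).
static double golden_max(double lo, double hi, double t1, double t2,
                         double n11, double n10, double n01, double n00) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = tetra_loglik(x1, t1, t2, n11, n10, n01, n00);
  double f2 = tetra_loglik(x2, t1, t2, n11, n10, n01, n00);
  while (b - a > 1e-8) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = tetra_loglik(x2, t1, t2, n11, n10, n01, n00);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = tetra_loglik(x1, t1, t2, n11, n10, n01, n00);
    }
  }
  return (a + b) / 2.0;
}

// Two-step tetrachoric estimate for vectors of 2x2 tables.
// correct: continuity-correction constant added to all cells of tables
// containing a zero; bound: |rho| box constraint.
// [[Rcpp::export]]
List tetra_from_counts_cpp(NumericVector n11, NumericVector n10,
                           NumericVector n01, NumericVector n00,
                           double correct, double bound) {
  int m = n11.size();
  NumericVector rho(m);
  LogicalVector corrected(m), degenerate(m);
  for (int i = 0; i < m; i++) {
    double a = n11[i], b = n10[i], c = n01[i], d = n00[i];
    // a zero margin in the *raw* table carries no association information
    if (a + b <= 0.0 || c + d <= 0.0 || a + c <= 0.0 || b + d <= 0.0) {
      rho[i] = NA_REAL; degenerate[i] = true; continue;
    }
    bool zc = (a == 0.0 || b == 0.0 || c == 0.0 || d == 0.0);
    if (zc) { a += correct; b += correct; c += correct; d += correct; }
    corrected[i] = zc && correct > 0.0;
    double n = a + b + c + d;
    double p1 = (a + b) / n, p2 = (a + c) / n;
    double t1 = R::qnorm(1.0 - p1, 0.0, 1.0, 1, 0);
    double t2 = R::qnorm(1.0 - p2, 0.0, 1.0, 1, 0);
    // coarse scan to bracket the maximum, then golden-section refinement
    int ns = 41;
    double best = -bound, bestll = R_NegInf;
    for (int j = 0; j < ns; j++) {
      double r = -bound + 2.0 * bound * j / (ns - 1);
      double ll = tetra_loglik(r, t1, t2, a, b, c, d);
      if (ll > bestll) { bestll = ll; best = r; }
    }
    double step = 2.0 * bound / (ns - 1);
    double lo = std::max(-bound, best - step);
    double hi = std::min(bound, best + step);
    rho[i] = golden_max(lo, hi, t1, t2, a, b, c, d);
    if (rho[i] > bound) rho[i] = bound;
    if (rho[i] < -bound) rho[i] = -bound;
  }
  return List::create(_["rho"] = rho, _["corrected"] = corrected,
                      _["degenerate"] = degenerate);
}
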