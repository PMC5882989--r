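#include <Rcpp.h>
using namespace Rcpp;

// Wrapped Cauchy log density, log((1 - rho^2) / (2 pi (1 + rho^2 - 2 rho cos(theta - mu))))
static inline double wc_logpdf(double theta, double mu, double rho) {
  return std::log1p(-rho * rho) - std::log(2.0 * M_PI) -
         std::log1p(rho * rho - 2.0 * rho * std::cos(theta - mu));
}

// Per-step log-likelihood of the socially informed correlated random walk.
//
// Steps are flattened: neighbour arrays are sorted by step, with nbOff a
// 0-based offset vector of length n+1 delimiting each step's neighbours.
// phi uses NA for "missing environmental heading".  form: 0 none, 1 metric,
// 2 topological, 3 exponential decay.  Missing/degenerate social or
// environmental terms redistribute their weight to persistence.
// [[Rcpp::export]]
NumericVector cpp_step_loglik(NumericVector theta, NumericVector thetaPrev,
                              NumericVector phi, IntegerVector nbOff,
                              NumericVector d, NumericVector ux,
                              NumericVector uy, NumericVector hx,
                              NumericVector hy, IntegerVector nbRank,
                              int form, double r, int K, double ell,
                              double aAlign, int alignment, double alpha,
                              double beta, double gamma, double rho) {
  const int n = theta.size();
  NumericVector ll(n);
  const double a = alignment ? aAlign : 0.0;

  for (int i = 0; i < n; ++i) {
    // social heading unit vector
    double psix = 0.0, psiy = 0.0;
    bool havePsi = false;
    if (form != 0) {
      double Ax = 0.0, Ay = 0.0, Gx = 0.0, Gy = 0.0;
      for (int j = nbOff[i]; j < nbOff[i + 1]; ++j) {
        double w;
        switch (form) {
          case 1: w = (d[j] <= r) ? 1.0 : 0.0; break;
          case 2: w = (nbRank[j] <= K) ? 1.0 : 0.0; break;
          default: w = std::exp(-d[j] / ell);
        }
        if (w == 0.0) continue;
        Ax += w * ux[j];
        Ay += w * uy[j];
        if (!ISNAN(hx[j])) {
          Gx += w * hx[j];
          Gy += w * hy[j];
        }
      }
      double nA = std::sqrt(Ax * Ax + Ay * Ay);
      if (nA > 0.0) { Ax /= nA; Ay /= nA; }
      double nG = std::sqrt(Gx * Gx + Gy * Gy);
      if (nG > 0.0) { Gx /= nG; Gy /= nG; }
      double Vx = (1.0 - a) * Ax + a * Gx;
      double Vy = (1.0 - a) * Ay + a * Gy;
      double mag = std::sqrt(Vx * Vx + Vy * Vy);
      if (mag >= 1e-9) {
        psix = Vx / mag;
        psiy = Vy / mag;
        havePsi = true;
      }
    }

    double aEff = alpha, bEff = beta, gEff = gamma;
    if (!havePsi) { gEff += aEff; aEff = 0.0; }
    bool havePhi = !ISNAN(phi[i]);
    if (!havePhi) { gEff += bEff; bEff = 0.0; }

    double vx = gEff * std::cos(thetaPrev[i]) + aEff * psix;
    double vy = gEff * std::sin(thetaPrev[i]) + aEff * psiy;
    if (havePhi) {
      vx += bEff * std::cos(phi[i]);
      vy += bEff * std::sin(phi[i]);
    }
    double lam;
    if (std::sqrt(vx * vx + vy * vy) < 1e-9)
      lam = thetaPrev[i];
    else
      lam = std::atan2(vy, vx);

    ll[i] = wc_logpdf(theta[i], lam, rho);
  }
  return ll;
}
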