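// Hot numerical kernels for the quadrature evaluation of the integrated
// conditional likelihood: per-record log-densities accumulated by subject
// over a grid of random-effect values, and the first/second derivatives in
// the linear predictor used by the posterior-mode Newton steps.
#include <Rcpp.h>
using namespace Rcpp;

static inline double log_expit(double x) {
  return x > 0 ? -log1p(exp(-x)) : x - log1p(exp(x));
}
static inline double expit(double x) { return 1.0 / (1.0 + exp(-x)); }

// families: 1 = ordinal cumulative logit, 2 = binary logit (level 1 = low
// state modeled), 3 = gaussian identity, 4 = poisson log
// Cutpoints at +/-745 stand in for +/-Inf without overflowing exp().
static const double BIG = 745.0;

// log density of record r at linear predictor eta (no intercept for the
// categorical families: alpha holds the cutpoints / intercept)
static inline double record_logdens(int family, double eta, double y, int yi,
                                    const NumericVector& alpha, double sigma,
                                    int ncut) {
  switch (family) {
  case 1: {
    double u = (yi == ncut + 1) ? BIG : alpha[yi - 1] + eta;
    double l = (yi == 1) ? -BIG : alpha[yi - 2] + eta;
    return log1p(-exp(l - u)) + log_expit(u) + log_expit(-l);
  }
  case 2: {
    double e = alpha[0] + eta;
    return yi == 1 ? log_expit(e) : log_expit(-e);
  }
  case 3: {
    double z = (y - (alpha[0] + eta)) / sigma;
    return -0.5 * z * z - log(sigma) - 0.91893853320467274;
  }
  default: {
    double lmu = alpha[0] + eta;
    return y * lmu - exp(lmu) - lgamma(y + 1.0);
  }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_subject_logdens(NumericMatrix ETA, int family,
                                  NumericVector y, IntegerVector yidx,
                                  NumericVector alpha, double sigma,
                                  IntegerVector subj, int S) {
  int N = ETA.nrow(), K = ETA.ncol(), ncut = alpha.size();
  NumericMatrix A(S, K);
  for (int k = 0; k < K; ++k)
    for (int r = 0; r < N; ++r)
      A(subj[r] - 1, k) +=
        record_logdens(family, ETA(r, k), y[r], yidx[r], alpha, sigma, ncut);
  return A;
}

// [[Rcpp::export]]
List cpp_deriv_accum(NumericVector eta, int family, NumericVector y,
                     IntegerVector yidx, NumericVector alpha, double sigma,
                     NumericMatrix Z, IntegerVector subj, int S) {
  int N = eta.size(), dg = Z.ncol(), ncut = alpha.size();
  NumericMatrix G(S, dg), H(S, dg * dg);
  for (int r = 0; r < N; ++r) {
    double d1, d2;
    switch (family) {
    case 1: {
      int yi = yidx[r];
      double u = (yi == ncut + 1) ? BIG : alpha[yi - 1] + eta[r];
      double l = (yi == 1) ? -BIG : alpha[yi - 2] + eta[r];
      double Fu = expit(u), Fl = expit(l);
      double fu = Fu * (1 - Fu), fl = Fl * (1 - Fl);
      double pr = Fu - Fl;
      if (pr < 1e-300) pr = 1e-300;
      d1 = (fu - fl) / pr;
      d2 = (fu * (1 - 2 * Fu) - fl * (1 - 2 * Fl)) / pr - d1 * d1;
      break;
    }
    case 2: {
      double e = alpha[0] + eta[r];
      double F = expit(e);
      d1 = (yidx[r] == 1) ? 1 - F : -F;
      d2 = -F * (1 - F);
      break;
    }
    case 3: {
      double mu = alpha[0] + eta[r];
      d1 = (y[r] - mu) / (sigma * sigma);
      d2 = -1.0 / (sigma * sigma);
      break;
    }
    default: {
      double mu = exp(alpha[0] + eta[r]);
      d1 = y[r] - mu;
      d2 = -mu;
    }
    }
    int i = subj[r] - 1;
    for (int a = 0; a < dg; ++a) {
      G(i, a) += Z(r, a) * d1;
      for (int b = 0; b < dg; ++b)
        H(i, a * dg + b) += Z(r, a) * Z(r, b) * d2;
    }
  }
  return List::create(Named("G") = G, Named("H") = H);
}
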