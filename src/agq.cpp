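// Fused adaptive Gauss-Hermite evaluation of the integrated conditional
// log-likelihood for a block of processes whose random effects span one or
// two dimensions (the pairwise composite likelihood's hot path): per-subject
// Newton search for the posterior mode of the random effects, curvature
// Cholesky, node evaluation and log-sum-exp, all in one pass.
#include <Rcpp.h>
using namespace Rcpp;

static inline double log_expit2(double x) {
  return x > 0 ? -log1p(exp(-x)) : x - log1p(exp(x));
}
static inline double expit2(double x) { return 1.0 / (1.0 + exp(-x)); }
static const double BIG2 = 745.0;

static inline double rec_logdens(int family, double eta, double y, int yi,
                                 const double* alpha, int ncut, double sigma) {
  switch (family) {
  case 1: {
    double u = (yi == ncut + 1) ? BIG2 : alpha[yi - 1] + eta;
    double l = (yi == 1) ? -BIG2 : alpha[yi - 2] + eta;
    return log1p(-exp(l - u)) + log_expit2(u) + log_expit2(-l);
  }
  case 2: {
    double e = alpha[0] + eta;
    return yi == 1 ? log_expit2(e) : log_expit2(-e);
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

static inline void rec_deriv(int family, double eta, double y, int yi,
                             const double* alpha, int ncut, double sigma,
                             double& d1, double& d2) {
  switch (family) {
  case 1: {
    double u = (yi == ncut + 1) ? BIG2 : alpha[yi - 1] + eta;
    double l = (yi == 1) ? -BIG2 : alpha[yi - 2] + eta;
    double Fu = expit2(u), Fl = expit2(l);
    double fu = Fu * (1 - Fu), fl = Fl * (1 - Fl);
    double pr = Fu - Fl;
    if (pr < 1e-300) pr = 1e-300;
    d1 = (fu - fl) / pr;
    d2 = (fu * (1 - 2 * Fu) - fl * (1 - 2 * Fl)) / pr - d1 * d1;
    break;
  }
  case 2: {
    double F = expit2(alpha[0] + eta);
    d1 = (yi == 1) ? 1 - F : -F;
    d2 = -F * (1 - F);
    break;
  }
  case 3: {
    double mu = alpha[0] + eta;
    d1 = (y - mu) / (sigma * sigma);
    d2 = -1.0 / (sigma * sigma);
    break;
  }
  default: {
    double mu = exp(alpha[0] + eta);
    d1 = y - mu;
    d2 = -mu;
  }
  }
}

// [[Rcpp::export]]
List cpp_agq_loglik(List procs, NumericMatrix SigmaP, int S,
                    NumericMatrix zgrid, NumericVector lw, NumericVector zz2,
                    NumericMatrix mu_start, int max_iter, double tol) {
  int d = SigmaP.nrow();
  if (d > 2) stop("cpp_agq_loglik supports d <= 2");
  int K = zgrid.nrow();
  int P = procs.size();

  // prior precision and log-determinant (closed form, d <= 2)
  double O11, O12 = 0, O22 = 0, logdetS;
  if (d == 1) {
    O11 = 1.0 / SigmaP(0, 0);
    logdetS = log(SigmaP(0, 0));
  } else {
    double det = SigmaP(0, 0) * SigmaP(1, 1) - SigmaP(0, 1) * SigmaP(0, 1);
    O11 = SigmaP(1, 1) / det;
    O22 = SigmaP(0, 0) / det;
    O12 = -SigmaP(0, 1) / det;
    logdetS = log(det);
  }

  // unpack process blocks
  std::vector<NumericVector> ef(P), y(P), alpha(P);
  std::vector<IntegerVector> yi(P), subj(P);
  std::vector<NumericMatrix> Z(P);
  std::vector<IntegerVector> cols(P);
  std::vector<int> fam(P), ncut(P);
  std::vector<double> sig(P);
  for (int p = 0; p < P; ++p) {
    List pr = procs[p];
    ef[p] = as<NumericVector>(pr["ef"]);
    Z[p] = as<NumericMatrix>(pr["Z"]);
    y[p] = as<NumericVector>(pr["y"]);
    yi[p] = as<IntegerVector>(pr["yidx"]);
    subj[p] = as<IntegerVector>(pr["subj"]);
    alpha[p] = as<NumericVector>(pr["alpha"]);
    fam[p] = as<int>(pr["family"]);
    sig[p] = as<double>(pr["sigma"]);
    cols[p] = as<IntegerVector>(pr["cols"]);  // 0-based union columns
    ncut[p] = alpha[p].size();
  }

  NumericMatrix mu(S, d);
  for (int i = 0; i < S; ++i)
    for (int a = 0; a < d; ++a) mu(i, a) = mu_start(i, a);

  std::vector<double> G1(S), G2(S), H11(S), H12(S), H22(S);
  auto newton_pass = [&](bool accumulate_only) {
    for (int i = 0; i < S; ++i) {
      if (d == 1) {
        G1[i] = -O11 * mu(i, 0);
        H11[i] = -O11;
      } else {
        G1[i] = -(O11 * mu(i, 0) + O12 * mu(i, 1));
        G2[i] = -(O12 * mu(i, 0) + O22 * mu(i, 1));
        H11[i] = -O11; H12[i] = -O12; H22[i] = -O22;
      }
    }
    for (int p = 0; p < P; ++p) {
      int N = ef[p].size(), dg = Z[p].ncol();
      const double* al = alpha[p].begin();
      for (int r = 0; r < N; ++r) {
        int i = subj[p][r] - 1;
        double eta = ef[p][r];
        for (int a = 0; a < dg; ++a) eta += Z[p](r, a) * mu(i, cols[p][a]);
        double d1, d2;
        rec_deriv(fam[p], eta, y[p][r], yi[p][r], al, ncut[p], sig[p], d1, d2);
        for (int a = 0; a < dg; ++a) {
          int ca = cols[p][a];
          double za = Z[p](r, a);
          if (ca == 0) G1[i] += za * d1; else G2[i] += za * d1;
          for (int b = 0; b < dg; ++b) {
            int cb = cols[p][b];
            double w = za * Z[p](r, b) * d2;
            if (ca == 0 && cb == 0) H11[i] += w;
            else if (ca == 1 && cb == 1) H22[i] += w;
            else if (ca == 0 && cb == 1) H12[i] += w;
            // (1,0) handled by symmetry via the (0,1) term below
          }
        }
      }
    }
    (void)accumulate_only;
  };

  // Newton iterations (the record log-densities are concave in eta, so the
  // per-subject objectives are strictly concave; damped full steps)
  for (int it = 0; it < max_iter; ++it) {
    newton_pass(false);
    double maxstep = 0;
    for (int i = 0; i < S; ++i) {
      double s1, s2 = 0;
      if (d == 1) {
        s1 = G1[i] / (-H11[i]);
      } else {
        double h11 = -H11[i], h12 = -H12[i], h22 = -H22[i];
        double det = h11 * h22 - h12 * h12;
        s1 = (h22 * G1[i] - h12 * G2[i]) / det;
        s2 = (h11 * G2[i] - h12 * G1[i]) / det;
      }
      double nrm = sqrt(s1 * s1 + s2 * s2);
      if (nrm > 4.0) { s1 *= 4.0 / nrm; s2 *= 4.0 / nrm; }
      mu(i, 0) += s1;
      if (d == 2) mu(i, 1) += s2;
      if (nrm > maxstep) maxstep = nrm;
    }
    if (maxstep < tol) break;
  }
  newton_pass(true);  // curvature at the final mode

  // lower Cholesky L of (-H)^{-1} and log|L| per subject
  NumericVector logdetL(S);
  std::vector<double> L11(S), L21(S), L22(S);
  for (int i = 0; i < S; ++i) {
    if (d == 1) {
      double h = -H11[i];
      L11[i] = 1.0 / sqrt(h);
      logdetL[i] = -0.5 * log(h);
    } else {
      double h11 = -H11[i], h12 = -H12[i], h22 = -H22[i];
      double det = h11 * h22 - h12 * h12;
      double v11 = h22 / det, v21 = -h12 / det, v22 = h11 / det;
      L11[i] = sqrt(v11);
      L21[i] = v21 / L11[i];
      L22[i] = sqrt(v22 - L21[i] * L21[i]);
      logdetL[i] = -0.5 * log(det);
    }
  }

  // node values per subject: b_ik = mu_i + L_i z_k
  NumericMatrix B1(S, K), B2(d == 2 ? S : 1, d == 2 ? K : 1);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < S; ++i) {
      B1(i, k) = mu(i, 0) + L11[i] * zgrid(k, 0);
      if (d == 2)
        B2(i, k) = mu(i, 1) + L21[i] * zgrid(k, 0) + L22[i] * zgrid(k, 1);
    }

  // accumulate record log-densities per subject per node
  NumericMatrix A(S, K);
  for (int p = 0; p < P; ++p) {
    int N = ef[p].size(), dg = Z[p].ncol();
    const double* al = alpha[p].begin();
    for (int k = 0; k < K; ++k)
      for (int r = 0; r < N; ++r) {
        int i = subj[p][r] - 1;
        double eta = ef[p][r];
        for (int a = 0; a < dg; ++a) {
          double bval = (cols[p][a] == 0) ? B1(i, k) : B2(i, k);
          eta += Z[p](r, a) * bval;
        }
        A(i, k) += rec_logdens(fam[p], eta, y[p][r], yi[p][r], al, ncut[p], sig[p]);
      }
  }

  // prior density, weights, log-sum-exp
  const double LOG2PI = 1.8378770664093453;
  NumericVector ll(S);
  for (int i = 0; i < S; ++i) {
    double mx = R_NegInf;
    for (int k = 0; k < K; ++k) {
      double b1 = B1(i, k), q;
      if (d == 1) q = O11 * b1 * b1;
      else {
        double b2 = B2(i, k);
        q = O11 * b1 * b1 + 2 * O12 * b1 * b2 + O22 * b2 * b2;
      }
      double v = A(i, k) - 0.5 * (d * LOG2PI + logdetS + q) + lw[k] + zz2[k];
      A(i, k) = v;
      if (v > mx) mx = v;
    }
    double sum = 0;
    for (int k = 0; k < K; ++k) sum += exp(A(i, k) - mx);
    ll[i] = mx + log(sum) + logdetL[i] + 0.5 * d * M_LN2;
  }
  return List::create(Named("ll") = ll, Named("mu") = mu);
}
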