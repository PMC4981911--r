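#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bivariate random-intercept model with cluster-constant fixed effects
// (outcome-specific intercept + treatment). Collapsing each cluster to its
// outcome-mean pair decomposes the likelihood exactly: within-cluster
// deviations contribute through the pooled deviation cross-product W with
// covariance Sigma, and the cluster mean pairs ybar_j are independent
// N(mu_k, V_j) with V_j = Sigma / n_j + Phi. The per-arm means mu_k are
// profiled out by GLS at each variance-parameter value; the restricted
// criterion adds log|sum_j V_j^-1| per arm. All 2x2 algebra is written out
// so one evaluation costs O(J) flops.

struct BvmmStats {
  arma::mat ybar;   // J x 2 cluster outcome means
  arma::vec nj;     // cluster sizes
  arma::ivec arm;   // 0/1 per cluster
  arma::mat W;      // 2x2 pooled within-cluster deviation SSCP
  double Ntot;      // total individuals
};

static const double BIG = 1e12;

static inline double clamp15(double x) {
  return x < -15.0 ? -15.0 : (x > 15.0 ? 15.0 : x);
}

struct Cov6 {
  double s11, s12, s22;  // Sigma
  double p11, p12, p22;  // Phi
};

static Cov6 theta_to_cov(const arma::vec& th) {
  double s1 = std::exp(clamp15(th(0))), s2 = std::exp(clamp15(th(1)));
  double rho = std::tanh(th(2));
  double t1 = std::exp(clamp15(th(3))), t2 = std::exp(clamp15(th(4)));
  double phi = std::tanh(th(5));
  Cov6 c;
  c.s11 = s1 * s1; c.s22 = s2 * s2; c.s12 = rho * s1 * s2;
  c.p11 = t1 * t1; c.p22 = t2 * t2; c.p12 = phi * t1 * t2;
  return c;
}

// -2 log (restricted) likelihood, profiled over the per-arm means; fills
// the GLS means and per-arm precision sums when requested.
static double bvmm_m2ll(const arma::vec& th, const BvmmStats& D, bool reml,
                        double* mu_out = nullptr,
                        double* prec_out = nullptr) {
  const int J = D.ybar.n_rows;
  Cov6 c = theta_to_cov(th);

  double det_s = c.s11 * c.s22 - c.s12 * c.s12;
  if (!(det_s > 0) || !std::isfinite(det_s)) return BIG;
  double si11 = c.s22 / det_s, si22 = c.s11 / det_s, si12 = -c.s12 / det_s;

  // per-cluster V_j^-1, and GLS accumulators per arm
  std::vector<double> vi(3 * J);
  double prec[2][3] = {{0, 0, 0}, {0, 0, 0}};   // [arm][v11, v12, v22]
  double rhs[2][2] = {{0, 0}, {0, 0}};
  double sum_ldet_vj = 0.0;
  for (int j = 0; j < J; ++j) {
    double inj = 1.0 / D.nj(j);
    double v11 = c.s11 * inj + c.p11;
    double v12 = c.s12 * inj + c.p12;
    double v22 = c.s22 * inj + c.p22;
    double det_v = v11 * v22 - v12 * v12;
    if (!(det_v > 0)) return BIG;
    sum_ldet_vj += 2.0 * std::log(D.nj(j)) + std::log(det_v);
    double i11 = v22 / det_v, i22 = v11 / det_v, i12 = -v12 / det_v;
    vi[3 * j] = i11; vi[3 * j + 1] = i12; vi[3 * j + 2] = i22;
    int k = D.arm(j);
    prec[k][0] += i11; prec[k][1] += i12; prec[k][2] += i22;
    double y1 = D.ybar(j, 0), y2 = D.ybar(j, 1);
    rhs[k][0] += i11 * y1 + i12 * y2;
    rhs[k][1] += i12 * y1 + i22 * y2;
  }

  double mu[2][2];
  double ldet_prec = 0.0;
  for (int k = 0; k < 2; ++k) {
    double det_p = prec[k][0] * prec[k][2] - prec[k][1] * prec[k][1];
    if (!(det_p > 0)) return BIG;
    mu[k][0] = (prec[k][2] * rhs[k][0] - prec[k][1] * rhs[k][1]) / det_p;
    mu[k][1] = (prec[k][0] * rhs[k][1] - prec[k][1] * rhs[k][0]) / det_p;
    ldet_prec += std::log(det_p);
  }

  double quad = si11 * D.W(0, 0) + 2.0 * si12 * D.W(0, 1) + si22 * D.W(1, 1);
  for (int j = 0; j < J; ++j) {
    int k = D.arm(j);
    double r1 = D.ybar(j, 0) - mu[k][0], r2 = D.ybar(j, 1) - mu[k][1];
    quad += vi[3 * j] * r1 * r1 + 2.0 * vi[3 * j + 1] * r1 * r2 +
      vi[3 * j + 2] * r2 * r2;
  }

  double m2ll = 2.0 * D.Ntot * std::log(2.0 * M_PI) +
    (D.Ntot - J) * std::log(det_s) + sum_ldet_vj + quad;
  if (reml) m2ll += ldet_prec;
  if (!std::isfinite(m2ll)) return BIG;

  if (mu_out) {
    mu_out[0] = mu[0][0]; mu_out[1] = mu[0][1];
    mu_out[2] = mu[1][0]; mu_out[3] = mu[1][1];
  }
  if (prec_out) {
    for (int k = 0; k < 2; ++k)
      for (int t = 0; t < 3; ++t) prec_out[3 * k + t] = prec[k][t];
  }
  return m2ll;
}

// Plain Nelder-Mead on the 6 transformed variance parameters.
static arma::vec nelder_mead(const arma::vec& start, const BvmmStats& D,
                             bool reml, double step, int maxit, double tol,
                             double& fmin, bool& converged, int& evals) {
  const int d = 6;
  arma::mat S(d, d + 1);
  arma::vec f(d + 1);
  for (int i = 0; i <= d; ++i) {
    S.col(i) = start;
    if (i > 0) S(i - 1, i) += step;
    f(i) = bvmm_m2ll(S.col(i), D, reml);
  }
  evals = d + 1;
  converged = false;
  for (int it = 0; it < maxit; ++it) {
    arma::uvec ord = arma::sort_index(f);
    S = S.cols(ord); f = f(ord);
    if (std::fabs(f(d) - f(0)) < tol * (std::fabs(f(0)) + tol)) {
      converged = true;
      break;
    }
    arma::vec centroid = arma::mean(S.cols(0, d - 1), 1);
    arma::vec xr = centroid + (centroid - S.col(d));
    double fr = bvmm_m2ll(xr, D, reml); ++evals;
    if (fr < f(0)) {
      arma::vec xe = centroid + 2.0 * (centroid - S.col(d));
      double fe = bvmm_m2ll(xe, D, reml); ++evals;
      if (fe < fr) { S.col(d) = xe; f(d) = fe; }
      else { S.col(d) = xr; f(d) = fr; }
    } else if (fr < f(d - 1)) {
      S.col(d) = xr; f(d) = fr;
    } else {
      arma::vec xc = centroid + 0.5 * (S.col(d) - centroid);
      double fc = bvmm_m2ll(xc, D, reml); ++evals;
      if (fc < f(d)) { S.col(d) = xc; f(d) = fc; }
      else {
        for (int i = 1; i <= d; ++i) {
          S.col(i) = S.col(0) + 0.5 * (S.col(i) - S.col(0));
          f(i) = bvmm_m2ll(S.col(i), D, reml); ++evals;
        }
      }
    }
  }
  arma::uword best = f.index_min();
  fmin = f(best);
  return S.col(best);
}

static BvmmStats make_stats(const arma::mat& ybar, const arma::vec& nj,
                            const arma::ivec& arm, const arma::mat& W,
                            double Ntot) {
  BvmmStats D;
  D.ybar = ybar; D.nj = nj; D.arm = arm; D.W = W; D.Ntot = Ntot;
  return D;
}

// Evaluate the profiled log-likelihood (or restricted log-likelihood) at
// given variance components; used by tests against a direct multivariate-
// normal evaluation.
// [[Rcpp::export]]
double bvmm_loglik_cpp(double sigma1, double sigma2, double rho,
                       double tau1, double tau2, double phi,
                       const arma::mat& ybar, const arma::vec& nj,
                       const arma::ivec& arm, const arma::mat& W,
                       double Ntot, bool reml) {
  arma::vec th = {std::log(sigma1), std::log(sigma2), std::atanh(rho),
                  std::log(std::max(tau1, 1e-12)),
                  std::log(std::max(tau2, 1e-12)), std::atanh(phi)};
  return -0.5 * bvmm_m2ll(th, make_stats(ybar, nj, arm, W, Ntot), reml);
}

// [[Rcpp::export]]
List bvmm_fit_cpp(const arma::mat& ybar, const arma::vec& nj,
                  const arma::ivec& arm, const arma::mat& W, double Ntot,
                  bool reml, const arma::vec& theta0, int maxit, double tol,
                  int restarts) {
  BvmmStats D = make_stats(ybar, nj, arm, W, Ntot);

  double fbest = BIG;
  arma::vec best = theta0;
  bool conv = false;
  int evals_total = 0;
  // deterministic jitters keep the fit reproducible without touching the RNG
  const double jit[4] = {0.0, 0.4, -0.6, 0.9};
  for (int attempt = 0; attempt <= restarts; ++attempt) {
    arma::vec start = (attempt == 0) ? theta0 : best;
    if (attempt > 0)
      for (int i = 0; i < 6; ++i)
        start(i) += jit[attempt % 4] * ((i % 2 == 0) ? 1.0 : -1.0);
    double fmin; bool c; int ev;
    arma::vec th = nelder_mead(start, D, reml, attempt == 0 ? 0.4 : 0.15,
                               maxit, tol, fmin, c, ev);
    // polish from the incumbent with a tighter simplex
    double fmin2; bool c2; int ev2;
    arma::vec th2 = nelder_mead(th, D, reml, 0.02, maxit, tol, fmin2, c2, ev2);
    evals_total += ev + ev2;
    if (fmin2 < fbest) { fbest = fmin2; best = th2; conv = c && c2; }
    if (conv) break;
  }

  double mu[4], prec[6];
  double m2ll = bvmm_m2ll(best, D, reml, mu, prec);
  Cov6 c = theta_to_cov(best);

  arma::mat vcov_treat(2, 2), vcov_int(2, 2);
  {
    double v0[3], v1[3];
    double det0 = prec[0] * prec[2] - prec[1] * prec[1];
    double det1 = prec[3] * prec[5] - prec[4] * prec[4];
    v0[0] = prec[2] / det0; v0[1] = -prec[1] / det0; v0[2] = prec[0] / det0;
    v1[0] = prec[5] / det1; v1[1] = -prec[4] / det1; v1[2] = prec[3] / det1;
    vcov_treat = {{v0[0] + v1[0], v0[1] + v1[1]}, {v0[1] + v1[1], v0[2] + v1[2]}};
    vcov_int = {{v0[0], v0[1]}, {v0[1], v0[2]}};
  }

  arma::vec beta = {mu[2] - mu[0], mu[3] - mu[1]};
  arma::vec intercept = {mu[0], mu[1]};
  return List::create(
    _["theta"] = best,
    _["sigma1"] = std::sqrt(c.s11), _["sigma2"] = std::sqrt(c.s22),
    _["rho"] = c.s12 / std::sqrt(c.s11 * c.s22),
    _["tau1"] = std::sqrt(c.p11), _["tau2"] = std::sqrt(c.p22),
    _["phi"] = c.p12 / std::sqrt(c.p11 * c.p22),
    _["intercept"] = intercept, _["beta"] = beta,
    _["vcov_treat"] = vcov_treat, _["vcov_intercept"] = vcov_int,
    _["m2ll"] = m2ll, _["loglik"] = -0.5 * m2ll,
    _["converged"] = conv, _["evals"] = evals_total);
}
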