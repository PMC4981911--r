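#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 2x2 symmetric matrices are carried as (a11, a12, a22) triples; the Gibbs
// sampler below touches them hundreds of thousands of times per imputation
// stack, so the algebra is written out rather than routed through LAPACK.

struct Sym2 { double a11, a12, a22; };

static inline Sym2 inv2(const Sym2& s) {
  double det = s.a11 * s.a22 - s.a12 * s.a12;
  Sym2 r;
  r.a11 = s.a22 / det; r.a22 = s.a11 / det; r.a12 = -s.a12 / det;
  return r;
}

// lower Cholesky factor (l11, l21, l22)
static inline void chol2(const Sym2& s, double& l11, double& l21,
                         double& l22) {
  l11 = std::sqrt(s.a11);
  l21 = s.a12 / l11;
  l22 = std::sqrt(std::max(s.a22 - l21 * l21, 0.0));
}

// Draw from inverse-Wishart(df, S) (density ~ |X|^-(df+d+1)/2
// exp(-tr(S X^-1)/2)): precision ~ Wishart(df, S^-1) by Bartlett, d = 2.
static Sym2 rinvwish2(double df, const Sym2& S) {
  Sym2 Sinv = inv2(S);
  double l11, l21, l22;
  chol2(Sinv, l11, l21, l22);
  double a11 = std::sqrt(R::rchisq(df));
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  double a21 = R::norm_rand();
  // LA = chol(Sinv) * A (both lower triangular)
  double m11 = l11 * a11;
  double m21 = l21 * a11 + l22 * a21;
  double m22 = l22 * a22;
  Sym2 W;
  W.a11 = m11 * m11;
  W.a12 = m11 * m21;
  W.a22 = m21 * m21 + m22 * m22;
  return inv2(W);
}

// Gibbs sampler for the bivariate random-intercept imputation model of one
// treatment arm:
//   y_i = B' x_i + u_{c(i)} + e_i,  e_i ~ N(0, Sigma),  u_j ~ N(0, Phi)
// with a flat prior on B and IW(prior_df, prior_scale) priors on Sigma and
// Phi. Missing y entries (r == 1) are part of the chain state. Completed
// copies of y are recorded after `burn_in` iterations and every `thin`
// iterations thereafter, M in total, together with the parameter draws at
// those points. Uses R's RNG, so results are governed by set.seed().
// [[Rcpp::export]]
List gibbs_bivariate_impute(arma::mat y, const arma::mat& X,
                            const arma::ivec& cluster, const arma::imat& r,
                            int M, int burn_in, int thin,
                            double prior_df, const arma::mat& prior_scale) {
  RNGScope scope;
  const int n = y.n_rows, p = X.n_cols;
  const int J = cluster.max() + 1;

  arma::vec nj(J, arma::fill::zeros);
  for (int i = 0; i < n; ++i) nj(cluster(i)) += 1.0;

  arma::mat XtXinv = arma::inv_sympd(arma::symmatu(X.t() * X));
  arma::mat Lx = arma::chol(XtXinv, "lower");
  Sym2 S0 = {prior_scale(0, 0), prior_scale(0, 1), prior_scale(1, 1)};

  // initialise missing entries at the observed per-outcome means
  std::vector<int> miss_rows;
  for (int i = 0; i < n; ++i)
    if (r(i, 0) == 1 || r(i, 1) == 1) miss_rows.push_back(i);
  for (int l = 0; l < 2; ++l) {
    double s = 0.0; int m_obs = 0;
    for (int i = 0; i < n; ++i)
      if (r(i, l) == 0) { s += y(i, l); ++m_obs; }
    if (m_obs == 0) stop("an outcome has no observed values in this arm");
    double mean_l = s / m_obs;
    for (int i = 0; i < n; ++i)
      if (r(i, l) == 1) y(i, l) = mean_l;
  }

  arma::mat B = XtXinv * (X.t() * y);
  arma::mat E0 = y - X * B;
  double d0 = 1.0 / std::max(n - p, 3);
  Sym2 Sigma = {arma::dot(E0.col(0), E0.col(0)) * d0,
                arma::dot(E0.col(0), E0.col(1)) * d0,
                arma::dot(E0.col(1), E0.col(1)) * d0};
  Sym2 Phi = {0.1 * Sigma.a11 + 1e-4, 0.1 * Sigma.a12,
              0.1 * Sigma.a22 + 1e-4};
  arma::mat U(J, 2, arma::fill::zeros);

  List imputations(M);
  arma::mat sigma_draws(M, 3), phi_draws(M, 3);
  arma::mat beta_draws(M, 2 * p);

  arma::mat R1(n, 2), Z(p, 2);
  const int total = burn_in + (M - 1) * thin + 1;
  int stored = 0;
  for (int t = 1; t <= total; ++t) {
    // (a) cluster effects from their bivariate-normal full conditionals
    Sym2 Sinv = inv2(Sigma), Pinv = inv2(Phi);
    R1 = y - X * B;                       // residuals sans cluster effects
    std::vector<double> s1(J, 0.0), s2(J, 0.0);
    for (int i = 0; i < n; ++i) {
      int j = cluster(i);
      s1[j] += R1(i, 0);
      s2[j] += R1(i, 1);
    }
    double psum11 = 0, psum12 = 0, psum22 = 0;   // U'U accumulator
    for (int j = 0; j < J; ++j) {
      Sym2 prec = {nj(j) * Sinv.a11 + Pinv.a11, nj(j) * Sinv.a12 + Pinv.a12,
                   nj(j) * Sinv.a22 + Pinv.a22};
      Sym2 cov = inv2(prec);
      double b1 = Sinv.a11 * s1[j] + Sinv.a12 * s2[j];
      double b2 = Sinv.a12 * s1[j] + Sinv.a22 * s2[j];
      double m1 = cov.a11 * b1 + cov.a12 * b2;
      double m2 = cov.a12 * b1 + cov.a22 * b2;
      double l11, l21, l22;
      chol2(cov, l11, l21, l22);
      double z1 = R::norm_rand(), z2 = R::norm_rand();
      double u1 = m1 + l11 * z1;
      double u2 = m2 + l21 * z1 + l22 * z2;
      U(j, 0) = u1; U(j, 1) = u2;
      psum11 += u1 * u1; psum12 += u1 * u2; psum22 += u2 * u2;
    }

    // (b) cluster-effect covariance
    Phi = rinvwish2(prior_df + J,
                    {S0.a11 + psum11, S0.a12 + psum12, S0.a22 + psum22});

    // (c) residual covariance from E = R1 - U rows
    double e11 = 0, e12 = 0, e22 = 0;
    for (int i = 0; i < n; ++i) {
      int j = cluster(i);
      double d1 = R1(i, 0) - U(j, 0), d2 = R1(i, 1) - U(j, 1);
      e11 += d1 * d1; e12 += d1 * d2; e22 += d2 * d2;
    }
    Sigma = rinvwish2(prior_df + n,
                      {S0.a11 + e11, S0.a12 + e12, S0.a22 + e22});
    if (!std::isfinite(Sigma.a11) || !std::isfinite(Phi.a11))
      stop("non-finite covariance draw at iteration %d", t);

    // (d) coefficients given Sigma and the cluster effects
    arma::mat ystar = y;
    for (int i = 0; i < n; ++i) {
      int j = cluster(i);
      ystar(i, 0) -= U(j, 0);
      ystar(i, 1) -= U(j, 1);
    }
    arma::mat Bhat = XtXinv * (X.t() * ystar);
    for (int a = 0; a < p; ++a)
      for (int b = 0; b < 2; ++b) Z(a, b) = R::norm_rand();
    double c11, c21, c22;
    chol2(Sigma, c11, c21, c22);
    // B = Bhat + Lx Z R  with R = upper Cholesky of Sigma ([c11 c21; 0 c22])
    arma::mat LxZ = Lx * Z;
    for (int a = 0; a < p; ++a) {
      B(a, 0) = Bhat(a, 0) + LxZ(a, 0) * c11;
      B(a, 1) = Bhat(a, 1) + LxZ(a, 0) * c21 + LxZ(a, 1) * c22;
    }

    // (e) missing outcomes from their conditional normals
    if (!miss_rows.empty()) {
      double l11, l21, l22;
      chol2(Sigma, l11, l21, l22);
      double sd1g2 = std::sqrt(std::max(
        Sigma.a11 - Sigma.a12 * Sigma.a12 / Sigma.a22, 0.0));
      double sd2g1 = std::sqrt(std::max(
        Sigma.a22 - Sigma.a12 * Sigma.a12 / Sigma.a11, 0.0));
      for (size_t ii = 0; ii < miss_rows.size(); ++ii) {
        int i = miss_rows[ii];
        int j = cluster(i);
        double m1 = U(j, 0), m2 = U(j, 1);
        for (int a = 0; a < p; ++a) {
          m1 += X(i, a) * B(a, 0);
          m2 += X(i, a) * B(a, 1);
        }
        if (r(i, 0) == 1 && r(i, 1) == 1) {
          double z1 = R::norm_rand(), z2 = R::norm_rand();
          y(i, 0) = m1 + l11 * z1;
          y(i, 1) = m2 + l21 * z1 + l22 * z2;
        } else if (r(i, 0) == 1) {
          y(i, 0) = m1 + Sigma.a12 / Sigma.a22 * (y(i, 1) - m2) +
            sd1g2 * R::norm_rand();
        } else {
          y(i, 1) = m2 + Sigma.a12 / Sigma.a11 * (y(i, 0) - m1) +
            sd2g1 * R::norm_rand();
        }
      }
    }

    if (t > burn_in && (t - burn_in - 1) % thin == 0 && stored < M) {
      imputations[stored] = y;
      sigma_draws(stored, 0) = Sigma.a11;
      sigma_draws(stored, 1) = Sigma.a22;
      sigma_draws(stored, 2) = Sigma.a12;
      phi_draws(stored, 0) = Phi.a11;
      phi_draws(stored, 1) = Phi.a22;
      phi_draws(stored, 2) = Phi.a12;
      for (int a = 0; a < p; ++a) {
        beta_draws(stored, a) = B(a, 0);
        beta_draws(stored, p + a) = B(a, 1);
      }
      ++stored;
    }
  }

  return List::create(_["imputations"] = imputations,
                      _["sigma"] = sigma_draws,
                      _["phi"] = phi_draws,
                      _["beta"] = beta_draws);
}
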