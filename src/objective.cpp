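// Normal-theory discrepancy and augmented-Lagrangian objective for the
// extended (oblique) bi-factor model, with analytic gradients over the
// unconstrained parameter vector theta = (vec(Lambda), beta, omega),
// where Lambda is J x (G+1) (column 0 = general factor), beta are the
// row-normalized Cholesky parameters of the group-factor correlation
// block, and psi = exp(omega).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the G x G lower-triangular matrix L whose row i is
// (beta_{i,1..i-1}, 1) scaled to unit norm; Phi_G = L L^T.
static mat build_L(const vec& beta, const int G) {
  mat L(G, G, fill::zeros);
  int pos = 0;
  for (int i = 0; i < G; ++i) {
    vec v(i + 1);
    for (int k = 0; k < i; ++k) v(k) = beta(pos + k);
    v(i) = 1.0;
    pos += i;
    const double nrm = norm(v, 2);
    for (int c = 0; c <= i; ++c) L(i, c) = v(c) / nrm;
  }
  return L;
}

// Full (G+1) x (G+1) factor correlation: identity row/col for the general
// factor, L L^T in the group block.
static mat build_Phi(const vec& beta, const int G) {
  mat Phi(G + 1, G + 1, fill::eye);
  if (G > 0) {
    const mat L = build_L(beta, G);
    Phi.submat(1, 1, G, G) = L * L.t();
  }
  return Phi;
}

// [[Rcpp::export(name = ".cpp_build_phi")]]
Rcpp::NumericMatrix cpp_build_phi(const arma::vec& beta, const int G) {
  return Rcpp::wrap(build_Phi(beta, G));
}

// Core evaluation. Returns the augmented-Lagrangian value and, if
// want_grad, its gradient w.r.t. theta. With mu = 0 and empty multipliers
// this is the plain discrepancy l(Sigma, S).
//
// constraint_form: 0 = pairwise (c_{j,g<g'} = lambda_{jg} lambda_{jg'},
// ordered j fastest within pair, pairs in (g,g') lexicographic order),
// 1 = row_aggregate (c_j = sum_{g<g'} lambda_{jg}^2 lambda_{jg'}^2).
// [[Rcpp::export(name = ".cpp_al_objective")]]
Rcpp::List cpp_al_objective(const arma::vec& theta,
                            const arma::mat& S,
                            const int J, const int G,
                            const double logdetS,
                            const arma::vec& multipliers,
                            const double mu,
                            const int constraint_form,
                            const bool want_grad) {
  const int nL = J * (G + 1);
  const int nB = G * (G - 1) / 2;
  const mat Lambda(theta.memptr(), J, G + 1);
  const vec beta = nB > 0 ? theta.subvec(nL, nL + nB - 1) : vec();
  const vec omega = theta.subvec(nL + nB, nL + nB + J - 1);
  const vec psi = exp(omega);

  mat L;
  mat Phi(G + 1, G + 1, fill::eye);
  if (G > 0) {
    L = build_L(beta, G);
    Phi.submat(1, 1, G, G) = L * L.t();
  }

  mat Sigma = Lambda * Phi * Lambda.t();
  Sigma.diag() += psi;

  mat C;
  if (!chol(C, Sigma)) {
    return Rcpp::List::create(Rcpp::Named("value") = R_PosInf,
                              Rcpp::Named("gradient") = R_NilValue,
                              Rcpp::Named("ok") = false);
  }
  const double logdetSigma = 2.0 * accu(log(C.diag()));
  const mat Sigma_inv = inv_sympd(Sigma);
  const double loss = logdetSigma + accu(Sigma_inv % S) - logdetS - (double)J;

  // constraint contribution
  double penal = 0.0;
  vec cvec;
  const bool with_constraints = (G >= 2) && (multipliers.n_elem > 0 || mu > 0);
  if (with_constraints) {
    if (constraint_form == 0) {
      cvec.set_size(J * G * (G - 1) / 2);
      int k = 0;
      for (int g = 1; g <= G - 1; ++g)
        for (int gp = g + 1; gp <= G; ++gp)
          for (int j = 0; j < J; ++j, ++k)
            cvec(k) = Lambda(j, g) * Lambda(j, gp);
    } else {
      cvec.set_size(J);
      for (int j = 0; j < J; ++j) {
        // sum of squared pairwise products: exactly zero on bi-factor rows
        double cj = 0.0;
        for (int g = 1; g <= G - 1; ++g)
          for (int gp = g + 1; gp <= G; ++gp) {
            const double pr = Lambda(j, g) * Lambda(j, gp);
            cj += pr * pr;
          }
        cvec(j) = cj;
      }
    }
    penal = (multipliers.n_elem > 0 ? dot(multipliers, cvec) : 0.0) +
            0.5 * mu * dot(cvec, cvec);
  }

  const double value = loss + penal;
  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("value") = value,
                              Rcpp::Named("constraints") = cvec,
                              Rcpp::Named("loss") = loss,
                              Rcpp::Named("ok") = true);
  }

  // dl/dSigma = Sigma^-1 - Sigma^-1 S Sigma^-1
  const mat W = Sigma_inv - Sigma_inv * S * Sigma_inv;
  mat gL = 2.0 * W * Lambda * Phi;
  vec gB(nB, fill::zeros);
  if (G >= 2) {
    const mat Gfull = Lambda.t() * W * Lambda;
    const mat Ggrp = Gfull.submat(1, 1, G, G);
    const mat M = Ggrp * L; // dl/dL = 2 M elementwise on lower triangle
    int pos = 0;
    for (int i = 1; i < G; ++i) { // row i has i free betas
      vec v(i + 1);
      for (int k = 0; k < i; ++k) v(k) = beta(pos + k);
      v(i) = 1.0;
      const double nrm = norm(v, 2);
      const double n3 = nrm * nrm * nrm;
      for (int k = 0; k < i; ++k) {
        // dL(i, c)/dbeta_k = delta_{ck}/nrm - v_c v_k / nrm^3, c = 0..i
        double acc2 = 0.0;
        for (int c = 0; c <= i; ++c) {
          double d = -v(c) * v(k) / n3;
          if (c == k) d += 1.0 / nrm;
          acc2 += M(i, c) * d;
        }
        gB(pos + k) = 2.0 * acc2;
      }
      pos += i;
    }
  }
  vec gO(J);
  for (int j = 0; j < J; ++j) gO(j) = psi(j) * W(j, j);

  // gradient of the multiplier + penalty terms (group columns only)
  if (with_constraints) {
    const bool has_mult = multipliers.n_elem > 0;
    if (constraint_form == 0) {
      int k = 0;
      for (int g = 1; g <= G - 1; ++g)
        for (int gp = g + 1; gp <= G; ++gp)
          for (int j = 0; j < J; ++j, ++k) {
            const double a = (has_mult ? multipliers(k) : 0.0) + mu * cvec(k);
            gL(j, g)  += a * Lambda(j, gp);
            gL(j, gp) += a * Lambda(j, g);
          }
    } else {
      for (int j = 0; j < J; ++j) {
        double ssq = 0.0;
        for (int g = 1; g <= G; ++g) ssq += Lambda(j, g) * Lambda(j, g);
        const double a = (has_mult ? multipliers(j) : 0.0) + mu * cvec(j);
        for (int g = 1; g <= G; ++g) {
          const double x = Lambda(j, g);
          gL(j, g) += a * 2.0 * x * (ssq - x * x);
        }
      }
    }
  }

  vec grad(nL + nB + J);
  grad.subvec(0, nL - 1) = vectorise(gL);
  if (nB > 0) grad.subvec(nL, nL + nB - 1) = gB;
  grad.subvec(nL + nB, nL + nB + J - 1) = gO;

  return Rcpp::List::create(Rcpp::Named("value") = value,
                            Rcpp::Named("gradient") = grad,
                            Rcpp::Named("constraints") = cvec,
                            Rcpp::Named("loss") = loss,
                            Rcpp::Named("ok") = true);
}

// Exploratory factor analysis objective with echelon identification:
// Lambda is J x K with lambda_{jk} = 0 for k > j, Phi = I. theta_free
// holds the free loadings in column-major order followed by omega.
// [[Rcpp::export(name = ".cpp_efa_objective")]]
Rcpp::List cpp_efa_objective(const arma::vec& theta_free,
                             const arma::mat& S,
                             const int J, const int K,
                             const double logdetS,
                             const bool want_grad) {
  mat Lambda(J, K, fill::zeros);
  int pos = 0;
  for (int k = 0; k < K; ++k)
    for (int j = k; j < J; ++j) Lambda(j, k) = theta_free(pos++);
  const vec omega = theta_free.subvec(pos, pos + J - 1);
  const vec psi = exp(omega);

  mat Sigma = Lambda * Lambda.t();
  Sigma.diag() += psi;
  mat C;
  if (!chol(C, Sigma)) {
    return Rcpp::List::create(Rcpp::Named("value") = R_PosInf,
                              Rcpp::Named("gradient") = R_NilValue,
                              Rcpp::Named("ok") = false);
  }
  const double logdetSigma = 2.0 * accu(log(C.diag()));
  const mat Sigma_inv = inv_sympd(Sigma);
  const double loss = logdetSigma + accu(Sigma_inv % S) - logdetS - (double)J;
  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("value") = loss,
                              Rcpp::Named("ok") = true);
  }
  const mat W = Sigma_inv - Sigma_inv * S * Sigma_inv;
  const mat gL = 2.0 * W * Lambda;
  vec grad(theta_free.n_elem);
  pos = 0;
  for (int k = 0; k < K; ++k)
    for (int j = k; j < J; ++j) grad(pos++) = gL(j, k);
  for (int j = 0; j < J; ++j) grad(pos + j) = psi(j) * W(j, j);
  return Rcpp::List::create(Rcpp::Named("value") = loss,
                            Rcpp::Named("gradient") = grad,
                            Rcpp::Named("ok") = true);
}
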