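// Kalman filter / RTS fixed-interval smoother kernel for the 3-state
// skin-conductance model. Kept generic in the state dimension; the package
// always calls it with n = 3. The smoother also returns the lag-one smoothed
// cross-covariances needed by the EM M-step.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat sim_forward_cpp(const arma::mat& A, const arma::vec& B,
                          const arma::vec& u, const arma::vec& x0) {
  const uword K = u.n_elem;
  mat X(A.n_rows, K);
  vec x = x0;
  for (uword k = 0; k < K; ++k) {
    x = A * x + B * u(k);
    X.col(k) = x;
  }
  return X;
}

static inline mat symm(const mat& M) { return 0.5 * (M + M.t()); }

// Forward Kalman filter + backward RTS smoother with time-varying process
// noise Q (n x n x K). Observation model: y_k = C x_k + v_k,
// v_k ~ N(0, sigma2). Prior x_0 ~ N(x0, P0); states x_1..x_K are filtered
// and smoothed, and the smoothed x_0 is returned in column 0.
// [[Rcpp::export]]
Rcpp::List fis_smooth_cpp(const arma::mat& A, const arma::rowvec& C,
                          const arma::vec& y, const arma::cube& Q,
                          const double sigma2, const arma::vec& x0,
                          const arma::mat& P0) {
  const uword K = y.n_elem;
  const uword n = A.n_rows;
  if (Q.n_slices != K) Rcpp::stop("Q must have one slice per observation");

  mat Xf(n, K + 1), Xp(n, K);
  cube Pf(n, n, K + 1), Pp(n, n, K);
  Xf.col(0) = x0;
  Pf.slice(0) = symm(P0);

  const mat I = eye(n, n);
  vec Kgain_last(n, fill::zeros);
  double loglik = 0.0;

  for (uword k = 0; k < K; ++k) {
    vec xp = A * Xf.col(k);
    mat Ppred = symm(A * Pf.slice(k) * A.t() + Q.slice(k));
    Xp.col(k) = xp;
    Pp.slice(k) = Ppred;

    double S = as_scalar(C * Ppred * C.t()) + sigma2;
    if (!(S > 0.0) || !std::isfinite(S))
      Rcpp::stop("innovation covariance degenerate at sample %d", (int)(k + 1));
    vec Kg = (Ppred * C.t()) / S;
    double innov = y(k) - as_scalar(C * xp);
    Xf.col(k + 1) = xp + Kg * innov;
    mat IKC = I - Kg * C;
    Pf.slice(k + 1) = symm(IKC * Ppred * IKC.t() + (Kg * Kg.t()) * sigma2);
    loglik += -0.5 * (std::log(2.0 * M_PI * S) + innov * innov / S);
    if (k == K - 1) Kgain_last = Kg;
  }

  // backward pass
  mat Xs(n, K + 1);
  cube Ps(n, n, K + 1), Plag1(n, n, K), Js(n, n, K);
  Xs.col(K) = Xf.col(K);
  Ps.slice(K) = Pf.slice(K);
  for (uword k = K; k-- > 0;) {
    mat J;
    bool ok = solve(J, Pp.slice(k).t(), (Pf.slice(k) * A.t()).t());
    if (!ok)
      Rcpp::stop("prediction covariance singular at sample %d", (int)(k + 1));
    J = J.t();  // J_k = Pf_k A' Pp_{k+1}^{-1}
    Js.slice(k) = J;
    Xs.col(k) = Xf.col(k) + J * (Xs.col(k + 1) - Xp.col(k));
    Ps.slice(k) = symm(Pf.slice(k) + J * (Ps.slice(k + 1) - Pp.slice(k)) * J.t());
  }

  // lag-one smoothed cross-covariances Cov(x_k, x_{k-1} | Y), k = 1..K
  // (slice k-1). Standard recursion initialized at the filter endpoint.
  Plag1.slice(K - 1) = (I - Kgain_last * C) * A * Pf.slice(K - 1);
  for (uword k = K - 1; k-- > 0;) {
    // slice k holds Cov(x_{k+1}, x_k | Y)
    Plag1.slice(k) = Pf.slice(k + 1) * Js.slice(k).t() +
      Js.slice(k + 1) * (Plag1.slice(k + 1) - A * Pf.slice(k + 1)) *
      Js.slice(k).t();
  }

  return Rcpp::List::create(
    Rcpp::Named("x_smooth") = Xs, Rcpp::Named("P_smooth") = Ps,
    Rcpp::Named("x_filt") = Xf, Rcpp::Named("P_filt") = Pf,
    Rcpp::Named("P_lag1") = Plag1, Rcpp::Named("loglik") = loglik);
}
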