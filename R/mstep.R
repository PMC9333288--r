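#' Gaussian priors on the physiological time constants
#'
#' Prior means, variances and regularization weights for
#' `(tau_r, tau_p, tau_d)`. The defaults sit near the population estimates
#' this class of model reports for adult participants (rise around 2 s, fast
#' decay around 5-6 s, slow decay around 80-90 s) with generous spreads, so
#' the data term dominates whenever the record is informative.
#'
#' @param means Prior means, seconds.
#' @param sds Prior standard deviations, seconds.
#' @param weights Regularization multipliers (0 disables a prior).
#' @return A list of class `prior_spec`.
#' @export
prior_spec <- function(means = c(2, 6, 85), sds = c(1, 2, 30),
                       weights = c(1, 1, 1)) {
  stopifnot(length(means) == 3, length(sds) == 3, length(weights) == 3,
            all(sds > 0), all(weights >= 0))
  structure(list(means = means, sds = sds, weights = weights),
            class = "prior_spec")
}

#' Inequality and equality constraints on the model parameters
#'
#' Encodes the physiological feasibility region: `tau_r >= tau_r_min`,
#' `tau_p > beta1 tau_r`, `tau_d > beta2 tau_p` (strict inequalities relaxed
#' to `>=` with a small margin), and the equality `eta_p = 1 - eta`,
#' `eta_d = eta` fixing the secretion split.
#'
#' @param beta1 Ratio bound `tau_p / tau_r`.
#' @param beta2 Ratio bound `tau_d / tau_p`.
#' @param eta Diffusion fraction (`eta_d`); `eta_p = 1 - eta`.
#' @param tau_r_min Lower bound on the rise time, seconds.
#' @param margin Slack replacing strict inequalities.
#' @return A list of class `constraint_spec`.
#' @export
constraint_spec <- function(beta1 = 2, beta2 = 15, eta = 0.5,
                            tau_r_min = 0.2, margin = 1e-9) {
  stopifnot(beta1 > 0, beta2 > 0, eta >= 0, eta <= 1, tau_r_min > 0)
  structure(list(beta1 = beta1, beta2 = beta2, eta = eta,
                 tau_r_min = tau_r_min, margin = margin),
            class = "constraint_spec")
}

#' Constraint matrices for the full parameter vector
#'
#' Returns the linear system `R theta <= s` (inequalities) and
#' `Re theta = se` (equalities) over
#' `theta = (tau_r, tau_p, tau_d, eta_p, eta_d)`.
#'
#' @param spec A [constraint_spec()].
#' @return List with `R`, `s`, `Re`, `se`.
#' @export
build_constraints <- function(spec = constraint_spec()) {
  R <- rbind(
    c(-1, 0, 0, 0, 0),                  # tau_r >= tau_r_min
    c(0, -1, 0, 0, 0),                  # tau_p > 0
    c(0, 0, -1, 0, 0),                  # tau_d > 0
    c(spec$beta1, -1, 0, 0, 0),         # tau_p >= beta1 tau_r (+margin)
    c(0, spec$beta2, -1, 0, 0)          # tau_d >= beta2 tau_p (+margin)
  )
  s <- c(-spec$tau_r_min, -spec$margin, -spec$margin,
         -spec$margin, -spec$margin)
  Re <- rbind(c(0, 0, 0, 1, 0), c(0, 0, 0, 0, 1))
  se <- c(1 - spec$eta, spec$eta)
  list(R = R, s = s, Re = Re, se = se)
}

#' Check feasibility of a parameter vector
#'
#' @param theta A [physiological_params()] object or 5-vector
#'   `(tau_r, tau_p, tau_d, eta_p, eta_d)`.
#' @param spec A [constraint_spec()].
#' @param tol Equality tolerance.
#' @return Logical.
#' @export
is_feasible <- function(theta, spec = constraint_spec(), tol = 1e-8) {
  v <- theta_vector(theta)
  con <- build_constraints(spec)
  all(con$R %*% v <= con$s + tol) &&
    all(abs(con$Re %*% v - con$se) <= tol)
}

theta_vector <- function(theta) {
  if (inherits(theta, "physiological_params"))
    c(theta$tau_r, theta$tau_p, theta$tau_d, theta$eta_p, theta$eta_d)
  else as.numeric(theta)
}

#' Sufficient statistics for the M-step
#'
#' Accumulates the second-moment sums the M-step objective needs from the
#' final E-step iterate. With `x_hat` the smoothed means, `P` the smoothed
#' covariances and `P_lag1` the lag-one smoothed cross-covariances, the
#' full-record accumulators are
#' `S00 = sum_k E(x_{k-1} x_{k-1}')`, `S10 = sum_k E(x_k x_{k-1}')`,
#' `S11 = sum_k E(x_k x_k')` (each `E(x x') = mean mean' + P`). Because the
#' innovation variance depends on the activation, per-sample moment blocks
#' are additionally kept at the (sparse) support of the activation train.
#'
#' @param estep An `estep_output` from [run_estep()].
#' @param y Observations.
#' @return A list of class `mstep_inputs`.
#' @export
mstep_inputs <- function(estep, y) {
  K <- length(y)
  X0 <- estep$x[, 1:K, drop = FALSE]
  X1 <- estep$x[, 2:(K + 1), drop = FALSE]
  u <- estep$u$amplitudes
  P <- estep$smoother$P_smooth
  PL <- estep$smoother$P_lag1
  supp <- which(u > 0)
  # per-support-sample moment blocks, stored row-wise (n_supp x 9) so the
  # objective can evaluate all samples with three matrix-vector products
  stack9 <- function(f) {
    out <- matrix(0, length(supp), 9)
    for (i in seq_along(supp)) out[i, ] <- as.numeric(f(supp[i]))
    out
  }
  structure(
    list(S00 = tcrossprod(X0) + rowSums(P[, , 1:K, drop = FALSE], dims = 2),
         S10 = X1 %*% t(X0) + rowSums(PL, dims = 2),
         S11 = tcrossprod(X1) + rowSums(P[, , 2:(K + 1), drop = FALSE],
                                        dims = 2),
         supp = supp,
         M11v = stack9(function(k) tcrossprod(X1[, k]) + P[, , k + 1]),
         M10v = stack9(function(k) tcrossprod(X1[, k], X0[, k]) + PL[, , k]),
         M00v = stack9(function(k) tcrossprod(X0[, k]) + P[, , k]),
         u_supp = u[supp],
         lambda = tail(estep$lambda_used, 1), K = K),
    class = "mstep_inputs"
  )
}

#' Expected complete-data objective as a function of the time constants
#'
#' Negative expected complete-data log-likelihood of the re-weighted
#' Gaussian state-space model, as a function of
#' `tau = (tau_r, tau_p, tau_d)` through `A(tau)` and `B(tau)` (the
#' secretion split is fixed by the equality constraints). Writing
#' `r_k = x_k - A x_{k-1}` for the innovation and
#' `Q_k = lambda^{-1} (B u_k^2 B' + eps^2 I)^{(2-p)/2}` for its
#' re-weighting covariance, the terms kept (dropping additive constants
#' free of `tau`) are
#' \deqn{\sum_k \tfrac12 \log\det Q_k(\tau)
#'   + \tfrac12 E\{r_k' Q_k(\tau)^{-1} r_k\}
#'   + \sum_j \rho_j (\tau_j - \bar\tau_j)^2 / (2 \sigma_{\tau j}^2),}
#' with the expectation over the smoothed state posterior
#' (`E(x x') = mean mean' + P`, including lag-one cross terms). The
#' observation term is free of `tau` (the observation row is fixed) and is
#' omitted. The rank-one structure of `Q_k` makes every sample with zero
#' activation contribute only through the pooled accumulators, so
#' evaluation is O(support size).
#'
#' @param tau Free parameters `(tau_r, tau_p, tau_d)`.
#' @param inputs An [mstep_inputs()] accumulator.
#' @param priors A [prior_spec()].
#' @param spec A [constraint_spec()] (fixes the secretion split).
#' @param cfg An [estep_config()] (norm order and perturbation).
#' @param Ts Sampling period, seconds.
#' @return Scalar objective value (up to additive constants free of `tau`).
#' @export
expected_objective <- function(tau, inputs, priors = prior_spec(),
                               spec = constraint_spec(),
                               cfg = estep_config(), Ts = 0.25) {
  d <- dsys_from_tau(tau, spec, Ts)
  A <- d$A
  B <- as.numeric(d$B)
  s <- (2 - cfg$p) / 2
  eps2 <- cfg$epsilon^2
  nb2 <- sum(B^2)
  b <- B / sqrt(nb2)
  lam <- inputs$lambda
  base <- eps2^(-s)                     # Q^-1 weight off the input direction
  tr_part <- sum(diag(inputs$S11)) - 2 * sum(A * inputs$S10) +
    sum(diag(A %*% inputs$S00 %*% t(A)))
  quad <- lam * base * tr_part
  logdet <- 0
  if (length(inputs$supp)) {
    u2 <- inputs$u_supp^2
    g <- (eps2 + u2 * nb2)^(-s)
    w <- as.numeric(crossprod(A, b))          # A' b
    # b' E(r r') b per sample: b'M11 b - 2 tr(M10' b w') + w' M00 w
    bb <- as.numeric(tcrossprod(b))
    bw <- as.numeric(tcrossprod(b, w))        # vec(b w') matches M10 layout
    ww <- as.numeric(tcrossprod(w))
    bErrb <- inputs$M11v %*% bb - 2 * (inputs$M10v %*% bw) +
      inputs$M00v %*% ww
    quad <- quad + lam * sum((g - base) * bErrb)
    logdet <- sum(s * log(eps2 + u2 * nb2))
  }
  0.5 * quad + 0.5 * logdet +
    sum(priors$weights * (tau - priors$means)^2 / (2 * priors$sds^2))
}

# discrete system from the 3 free time constants, secretion split fixed by
# the constraint spec; closed-form matrix exponential of the triangular
# system (hot path of the M-step line search)
dsys_from_tau <- function(tau, spec, Ts) {
  r1 <- -1 / tau[1]; r2 <- -1 / tau[2]; r3 <- -1 / tau[3]
  c2 <- (1 - spec$eta) / tau[1]
  c3 <- spec$eta / tau[1]
  e1 <- exp(r1 * Ts); e2 <- exp(r2 * Ts); e3 <- exp(r3 * Ts)
  cross <- function(c, ra, rb, ea, eb) {
    if (abs(ra - rb) < 1e-12) c * Ts * ea else c * (ea - eb) / (ra - rb)
  }
  A <- matrix(0, 3, 3)
  A[1, 1] <- e1; A[2, 2] <- e2; A[3, 3] <- e3
  A[2, 1] <- cross(c2, r1, r2, e1, e2)
  A[3, 1] <- cross(c3, r1, r3, e1, e3)
  # B = Ac^-1 (A - I) Bc for the triangular Ac, solved in closed form
  b1 <- (e1 - 1) / r1
  b2 <- (A[2, 1] - c2 * b1) / r2
  b3 <- (A[3, 1] - c3 * b1) / r3
  list(A = A, B = matrix(c(b1, b2, b3), 3, 1), C = matrix(c(0, 1, 1), 1, 3),
       Ts = Ts)
}

#' Constrained M-step over the physiological time constants
#'
#' Minimizes [expected_objective()] over `(tau_r, tau_p, tau_d)` subject to
#' the feasibility region of the [constraint_spec()], using a logarithmic
#' barrier (interior-point) method around Nelder-Mead, warm-started from the
#' current parameter estimate (projected strictly inside the region). If the
#' solver fails to improve on the warm start, the warm start is returned
#' with attribute `improved = FALSE`.
#'
#' @param inputs An [mstep_inputs()] accumulator.
#' @param priors A [prior_spec()].
#' @param spec A [constraint_spec()].
#' @param theta_warm Warm start ([physiological_params()] or 3-vector of
#'   time constants).
#' @param cfg An [estep_config()].
#' @param Ts Sampling period.
#' @return A [physiological_params()] object with attributes `objective`
#'   and `improved`.
#' @export
solve_mstep <- function(inputs, priors = prior_spec(),
                        spec = constraint_spec(), theta_warm,
                        cfg = estep_config(), Ts = 0.25) {
  tau0 <- theta_vector(theta_warm)[1:3]
  tau0 <- project_interior(tau0, spec)
  ui <- rbind(c(1, 0, 0), c(-spec$beta1, 1, 0), c(0, -spec$beta2, 1))
  ci <- c(spec$tau_r_min, spec$margin, spec$margin)
  f <- function(tau) expected_objective(tau, inputs, priors, spec, cfg, Ts)
  f0 <- f(tau0)
  solve_from <- function(start) {
    tryCatch(
      constrOptim(start, f, grad = NULL, ui = ui, ci = ci,
                  control = list(reltol = 1e-9, maxit = 300),
                  outer.iterations = 25, outer.eps = 1e-7),
      error = function(e) NULL
    )
  }
  # the EM path often rides the feasibility cone; give the simplex room by
  # starting strictly inside (relative slack), and retry from a deeper
  # interior point if the first solve cannot improve on the warm start
  fit <- solve_from(project_interior(tau0, spec, rel_slack = 1e-4))
  if (is.null(fit) || !is.finite(fit$value) || fit$value > f0 + 1e-10) {
    deep <- tau0
    deep[1] <- deep[1] * 0.98
    deep <- project_interior(deep, spec, rel_slack = 5e-3)
    fit2 <- solve_from(deep)
    if (!is.null(fit2) && is.finite(fit2$value) &&
        (is.null(fit) || fit2$value < fit$value)) fit <- fit2
  }
  if (is.null(fit) || !is.finite(fit$value) || fit$value > f0 + 1e-10) {
    tau <- tau0; val <- f0; improved <- FALSE
  } else {
    tau <- fit$par; val <- fit$value; improved <- TRUE
  }
  out <- physiological_params(tau[1], tau[2], tau[3],
                              eta_p = 1 - spec$eta, eta_d = spec$eta)
  attr(out, "objective") <- val
  attr(out, "improved") <- improved
  out
}

# push a point strictly inside the feasibility cone; rel_slack scales the
# margin with the parameter magnitude (used for solver starting points)
project_interior <- function(tau, spec, slack = 1e-6, rel_slack = 0) {
  tau[1] <- max(tau[1], spec$tau_r_min + slack)
  tau[2] <- max(tau[2], spec$beta1 * tau[1] * (1 + rel_slack) + slack)
  tau[3] <- max(tau[3], spec$beta2 * tau[2] * (1 + rel_slack) + slack)
  tau
}
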