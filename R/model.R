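#' Physiological parameters of the three-compartment skin-conductance model
#'
#' Bundles the time constants and secretion fractions that define the
#' compartmental model of sweat dynamics: sweat is produced in the duct
#' (compartment 1, rise time `tau_r`), secreted to the surface through pore
#' opening (compartment 2, fast decay `tau_p`, the phasic pathway) and
#' diffused through the duct wall into the stratum corneum (compartment 3,
#' slow decay `tau_d`, the tonic pathway). A fraction `eta_p` of the cleared
#' sweat takes the pore-opening route and `eta_d = 1 - eta_p` the diffusion
#' route.
#'
#' Physiological feasibility requires `tau_r >= 0.2` s, `tau_p > 2 tau_r`,
#' `tau_d > 15 tau_p`, and `eta_p + eta_d = 1` with both fractions in
#' `[0, 1]`.
#'
#' @param tau_r Rise time constant (duct clearance), seconds.
#' @param tau_p Fast decay time constant (phasic re-absorption), seconds.
#' @param tau_d Slow decay time constant (tonic elimination), seconds.
#' @param eta_p Fraction of sweat secreted via pore opening.
#' @param eta_d Fraction of sweat secreted via diffusion.
#' @return An object of class `physiological_params`.
#' @examples
#' physiological_params(tau_r = 2, tau_p = 5.5, tau_d = 82)
#' @export
physiological_params <- function(tau_r, tau_p, tau_d,
                                 eta_p = 0.5, eta_d = 1 - eta_p) {
  p <- structure(
    list(tau_r = tau_r, tau_p = tau_p, tau_d = tau_d,
         eta_p = eta_p, eta_d = eta_d),
    class = "physiological_params"
  )
  validate_params(p)
  p
}

#' @export
print.physiological_params <- function(x, ...) {
  cat("Physiological parameters (3-compartment SC model)\n")
  cat(sprintf("  tau_r = %.4f s   (rise / duct clearance)\n", x$tau_r))
  cat(sprintf("  tau_p = %.4f s   (fast decay, phasic)\n", x$tau_p))
  cat(sprintf("  tau_d = %.4f s   (slow decay, tonic)\n", x$tau_d))
  cat(sprintf("  eta_p = %.3f, eta_d = %.3f\n", x$eta_p, x$eta_d))
  invisible(x)
}

validate_params <- function(p, beta1 = 2, beta2 = 15) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("constraint violated: ", msg,
                                                 call. = FALSE)
  with(p, {
    chk(all(is.finite(c(tau_r, tau_p, tau_d, eta_p, eta_d))),
        "all parameters must be finite")
    chk(tau_r >= 0.2, "tau_r >= 0.2 s")
    chk(tau_p > 0 && tau_d > 0, "tau_p > 0 and tau_d > 0")
    # ratio bounds accepted at equality (estimates often sit on the boundary)
    tol <- 1e-9
    chk(tau_p >= beta1 * tau_r * (1 - tol), sprintf("tau_p >= %g * tau_r", beta1))
    chk(tau_d >= beta2 * tau_p * (1 - tol), sprintf("tau_d >= %g * tau_p", beta2))
    chk(eta_p >= 0 && eta_p <= 1 && eta_d >= 0 && eta_d <= 1,
        "eta_p, eta_d in [0, 1]")
    chk(abs(eta_p + eta_d - 1) < 1e-12, "eta_p + eta_d = 1")
  })
  invisible(p)
}

#' Continuous-time state-space matrices of the linear compartment model
#'
#' Builds the lower-triangular continuous system
#' \deqn{\dot x = A_c x + B_c u, \quad y = C_c x}
#' with states (duct sweat, surface sweat via pore opening, diffused sweat).
#' The observed conductance is the sum of the phasic (`x2`) and tonic (`x3`)
#' states.
#'
#' @param params A [physiological_params()] object.
#' @return A list of class `continuous_system` with elements `Ac` (3x3),
#'   `Bc` (3x1), `Cc` (1x3) and the originating `params`.
#' @export
build_continuous <- function(params) {
  validate_params(params)
  Ac <- matrix(0, 3, 3)
  Ac[1, 1] <- -1 / params$tau_r
  Ac[2, 2] <- -1 / params$tau_p
  Ac[3, 3] <- -1 / params$tau_d
  Ac[2, 1] <- params$eta_p / params$tau_r
  Ac[3, 1] <- params$eta_d / params$tau_r
  structure(
    list(Ac = Ac, Bc = matrix(c(1, 0, 0), 3, 1), Cc = matrix(c(0, 1, 1), 1, 3),
         params = params),
    class = "continuous_system"
  )
}

#' Zero-order-hold discretization of the continuous model
#'
#' Discretizes exactly under the assumption that the input is constant over
#' each sampling interval: `A = expm(Ac Ts)` and
#' `B = integral_0^Ts expm(Ac (Ts - rho)) Bc drho`, evaluated in closed form
#' as `Ac^{-1} (A - I) Bc` (the decay rates make `Ac` always invertible).
#'
#' @param sys A `continuous_system` from [build_continuous()].
#' @param Ts Sampling period in seconds (default 0.25 s, i.e. 4 Hz).
#' @return A list of class `discrete_system` with `A`, `B`, `C`, `Ts` and
#'   `params`.
#' @export
discretize <- function(sys, Ts = 0.25) {
  if (!inherits(sys, "continuous_system")) sys <- build_continuous(sys)
  if (!is.numeric(Ts) || length(Ts) != 1L || !is.finite(Ts) || Ts <= 0)
    stop("Ts must be a positive scalar", call. = FALSE)
  A <- as.matrix(Matrix::expm(sys$Ac * Ts))
  B <- solve(sys$Ac, (A - diag(3)) %*% sys$Bc)
  structure(
    list(A = A, B = B, C = sys$Cc, Ts = Ts, params = sys$params),
    class = "discrete_system"
  )
}

#' @export
print.discrete_system <- function(x, ...) {
  cat(sprintf("Discrete SC system at Ts = %g s (%g Hz)\n", x$Ts, 1 / x$Ts))
  cat("A =\n"); print(signif(x$A, 5))
  cat("B =", paste(signif(x$B, 5), collapse = " "), "\n")
  invisible(x)
}

#' Simulate the discrete linear model forward
#'
#' Iterates `x_k = A x_{k-1} + B u_k` from `x0` and returns the noiseless
#' observation together with its phasic (`x2`) and tonic (`x3`) components.
#' The impulse `u_k` acts between samples `k-1` and `k`.
#'
#' @param dsys A `discrete_system`.
#' @param u Non-negative ANS activation amplitudes (uS/s), one per sample.
#' @param x0 Initial state (3-vector, default rest).
#' @return A list of class `state_trajectory` with `x` (3 x K matrix),
#'   `y_clean`, `y_phasic`, `y_tonic` (length-K vectors) and `Ts`.
#' @export
simulate_sc <- function(dsys, u, x0 = c(0, 0, 0)) {
  u <- as_impulse_amplitudes(u)
  stopifnot(length(u) >= 1L, length(x0) == 3L, all(is.finite(x0)))
  X <- sim_forward_cpp(dsys$A, dsys$B, as.numeric(u), as.numeric(x0))
  trajectory_from_states(X, dsys$Ts)
}

trajectory_from_states <- function(X, Ts) {
  structure(
    list(x = X, y_phasic = X[2, ], y_tonic = X[3, ],
         y_clean = X[2, ] + X[3, ], Ts = Ts),
    class = "state_trajectory"
  )
}

as_impulse_amplitudes <- function(u) {
  if (inherits(u, "impulse_train")) u <- u$amplitudes
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("u must be finite numeric", call. = FALSE)
  if (any(u < 0))
    stop("ANS activation amplitudes must be non-negative", call. = FALSE)
  u
}

#' Simulate the nonlinear gated compartment model
#'
#' Integrates the full nonlinear dynamics in which the split between the
#' pore-opening and diffusion pathways depends on the duct state through a
#' sigmoid gate: `eta_p(x1) = S(alpha x1 + beta)`,
#' `eta_d(x1) = 1 - eta_p(x1)`, with `S` the logistic function. With
#' `alpha = 0` the gates are constant and the model reduces to the linear
#' system.
#'
#' The activation train is applied either as a zero-order-hold input (each
#' `u_k` held constant over its sampling interval, matching the linear
#' discretization; the default) or as instantaneous jumps of the duct state
#' at the impulse times (`input = "jump"`).
#'
#' @param params A [physiological_params()] object (or a plain list with the
#'   same fields when `validate = FALSE`; infinite `tau_p`/`tau_d` are then
#'   allowed to switch off elimination).
#' @param gates List with sigmoid parameters `alpha` (per-uS.s) and `beta`.
#' @param u Activation amplitudes (uS/s), one per sample.
#' @param Ts Sampling period, seconds.
#' @param x0 Initial state.
#' @param input `"zoh"` or `"jump"` (see Details).
#' @param validate Check physiological constraints on `params`.
#' @param ... Passed to [deSolve::ode()] (e.g. `rtol`, `atol`).
#' @return A `state_trajectory` sampled at `Ts` (K samples, the state after
#'   each interval).
#' @export
simulate_sc_nonlinear <- function(params, gates = list(alpha = 0, beta = 0),
                                  u, Ts = 0.25, x0 = c(0, 0, 0),
                                  input = c("zoh", "jump"), validate = TRUE,
                                  ...) {
  input <- match.arg(input)
  u <- as_impulse_amplitudes(u)
  if (validate) validate_params(params)
  if (!all(is.finite(c(gates$alpha, gates$beta))))
    stop("gate parameters must be finite", call. = FALSE)
  K <- length(u)
  inv_tp <- if (is.finite(params$tau_p)) 1 / params$tau_p else 0
  inv_td <- if (is.finite(params$tau_d)) 1 / params$tau_d else 0
  rhs <- function(t, x, parms) {
    eta_p <- plogis(gates$alpha * x[1] + gates$beta)
    clear <- x[1] / params$tau_r
    list(c(parms - clear,
           eta_p * clear - inv_tp * x[2],
           (1 - eta_p) * clear - inv_td * x[3]))
  }
  # integrate one sampling interval at a time so the piecewise-constant (or
  # impulsive) input never interacts with the adaptive step interpolation
  X <- matrix(0, 3, K)
  x <- as.numeric(x0)
  for (k in seq_len(K)) {
    drive <- 0
    if (u[k] > 0) {
      if (input == "zoh") drive <- u[k] else x[1] <- x[1] + u[k]
    }
    sol <- deSolve::ode(y = x, times = c(0, Ts), func = rhs, parms = drive,
                        method = "lsoda", ...)
    if (!is.matrix(sol) || nrow(sol) != 2L || any(!is.finite(sol[2L, -1L])))
      stop("nonlinear integration failed at sample ", k,
           " (t = ", (k - 1) * Ts, " s)", call. = FALSE)
    x <- as.numeric(sol[2L, -1L])
    X[, k] <- x
  }
  trajectory_from_states(X, Ts)
}
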