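# shared fixtures: population-mean parameters and small synthetic bundles
pop_params <- function() physiological_params(2.0040, 5.4545, 81.8175)

small_bundle <- function(K = 300, n_impulses = 8, snr_db = Inf, seed = 1) {
  generate_bundle(pop_params(), K = K, n_impulses = n_impulses,
                  snr_db = snr_db, seed = seed)
}

# random feasible parameter draw for property loops
random_params <- function() {
  tau_r <- runif(1, 0.3, 4)
  tau_p <- runif(1, 2 * tau_r + 0.05, 3.8 * tau_r + 0.5)
  tau_d <- runif(1, 15 * tau_p + 0.5, 25 * tau_p)
  eta <- runif(1, 0.05, 0.95)
  physiological_params(tau_r, tau_p, tau_d, eta_p = eta, eta_d = 1 - eta)
}

# 4th-order Runge-Kutta integration of xdot = Ac x + Bc * u_const over one
# sampling period; independent oracle for the zero-order-hold discretization
rk4_step_oracle <- function(Ac, Bc, Ts, dt = 1e-3, x0 = c(0, 0, 0),
                            u_const = 1) {
  f <- function(x) as.numeric(Ac %*% x + Bc * u_const)
  x <- x0
  n <- round(Ts / dt)
  for (i in seq_len(n)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}
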