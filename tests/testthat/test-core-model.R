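test_that("continuous system matrices match the compartment structure", {
  sys <- build_continuous(physiological_params(2, 5, 82))
  expect_equal(diag(sys$Ac), c(-0.5, -0.2, -1 / 82))
  expect_equal(sys$Ac[2, 1], 0.25)
  expect_equal(sys$Ac[3, 1], 0.25)
  expect_equal(sys$Ac[upper.tri(sys$Ac)], c(0, 0, 0))
  expect_equal(as.numeric(sys$Bc), c(1, 0, 0))
  expect_equal(as.numeric(sys$Cc), c(0, 1, 1))

  # eta_p = 1 removes the diffusion coupling
  sys1 <- build_continuous(physiological_params(2, 5, 82, eta_p = 1))
  expect_equal(sys1$Ac[3, 1], 0)

  # eigenvalues of a lower-triangular system are the negative decay rates
  p <- physiological_params(1.3, 4.2, 70)
  e <- sort(eigen(build_continuous(p)$Ac)$values)
  expect_equal(e, sort(c(-1 / p$tau_r, -1 / p$tau_p, -1 / p$tau_d)))
})

test_that("invalid parameters are rejected with the violated constraint", {
  expect_error(physiological_params(0.1, 5, 82), "tau_r")
  expect_error(physiological_params(2, 3.9, 82), "tau_p")
  expect_error(physiological_params(2, 5, 60), "tau_d")
  expect_error(physiological_params(2, 5, 82, eta_p = 0.7, eta_d = 0.4),
               "eta")
  # the ratio bounds are accepted at equality (population means sit there)
  expect_silent(physiological_params(2.0040, 5.4545, 81.8175))
})

test_that("zero-order-hold discretization matches an ODE oracle", {
  p <- physiological_params(2, 5.5, 83)
  sys <- build_continuous(p)
  d <- discretize(sys, 0.25)
  # eigenvalues of the triangular transition matrix
  expect_equal(sort(diag(d$A)),
               sort(exp(-0.25 / c(p$tau_r, p$tau_p, p$tau_d))))
  # A columns and B against Runge-Kutta integration of one step
  for (j in 1:3) {
    e_j <- replace(numeric(3), j, 1)
    expect_equal(as.numeric(d$A[, j]),
                 rk4_step_oracle(sys$Ac, sys$Bc, 0.25, x0 = e_j,
                                 u_const = 0),
                 tolerance = 1e-8)
  }
  expect_equal(as.numeric(d$B),
               rk4_step_oracle(sys$Ac, sys$Bc, 0.25, u_const = 1),
               tolerance = 1e-8)
  expect_error(discretize(sys, 0), "Ts")
})

test_that("discretization oracle holds over random parameter draws", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    sys <- build_continuous(p)
    d <- discretize(sys, 0.25)
    ref <- rk4_step_oracle(sys$Ac, sys$Bc, 0.25, u_const = 1)
    expect_lt(max(abs(as.numeric(d$B) - ref)) / max(abs(ref)), 1e-6)
    expect_lt(max(abs(eigen(d$A)$values)), 1)   # stability
    expect_true(all(as.numeric(d$B) >= 0))
  }
})

test_that("closed-form hot-path discretization agrees with Matrix::expm", {
  set.seed(12)
  for (i in 1:10) {
    p <- random_params()
    spec <- constraint_spec(eta = p$eta_d)
    d1 <- discretize(build_continuous(p), 0.25)
    d2 <- scdeconv:::dsys_from_tau(c(p$tau_r, p$tau_p, p$tau_d), spec, 0.25)
    expect_equal(d1$A, d2$A, tolerance = 1e-12)
    expect_equal(as.numeric(d1$B), as.numeric(d2$B), tolerance = 1e-12)
  }
})

test_that("forward simulation obeys the state recursion and linearity", {
  p <- pop_params()
  d <- discretize(build_continuous(p))
  set.seed(3)
  u1 <- rbinom(60, 1, 0.1) * runif(60, 0.3, 3)
  u2 <- rbinom(60, 1, 0.1) * runif(60, 0.3, 3)
  tr <- simulate_sc(d, u1)
  # recursion check
  x_prev <- c(0, 0, 0)
  for (k in 1:60) {
    expect_equal(tr$x[, k], as.numeric(d$A %*% x_prev + d$B * u1[k]))
    x_prev <- tr$x[, k]
  }
  expect_equal(tr$y_clean, tr$y_phasic + tr$y_tonic)
  # zero input from rest stays at zero
  expect_equal(simulate_sc(d, numeric(30))$y_clean, numeric(30))
  # superposition
  both <- simulate_sc(d, u1 + u2)
  expect_equal(both$x, simulate_sc(d, u1)$x + simulate_sc(d, u2)$x,
               tolerance = 1e-12)
  expect_error(simulate_sc(d, c(1, -0.5)), "non-negative")
})

test_that("impulse response matches the modal (partial fraction) expansion", {
  p <- pop_params()
  d <- discretize(build_continuous(p))
  K <- 200
  tr <- simulate_sc(d, c(1, numeric(K - 1)))
  ev <- eigen(d$A)
  w <- as.numeric((d$C %*% ev$vectors) * t(solve(ev$vectors, d$B)))
  y_modal <- sapply(1:K, function(k) sum(w * ev$values^(k - 1)))
  expect_equal(tr$y_clean, Re(y_modal), tolerance = 1e-8)
})

test_that("states stay non-negative and impulse response is unimodal", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_params()
    d <- discretize(build_continuous(p))
    u <- rbinom(300, 1, 0.05) * runif(300, 0.3, 3)
    tr <- simulate_sc(d, u)
    expect_true(all(tr$x >= -1e-12))
  }
  # single impulse from rest: one sign change in the differences of x2, x3
  d <- discretize(build_continuous(pop_params()))
  tr <- simulate_sc(d, c(1, numeric(799)))
  for (comp in c("y_phasic", "y_tonic")) {
    s <- diff(tr[[comp]])
    expect_lte(sum(diff(sign(s[s != 0])) != 0), 1)
  }
})

test_that("nonlinear simulator reduces to the linear model when alpha = 0", {
  p <- pop_params()
  d <- discretize(build_continuous(p))
  u <- c(numeric(5), 1.5, numeric(20), 0.8, numeric(13))
  lin <- simulate_sc(d, u)
  beta <- log(p$eta_p / (1 - p$eta_p))   # S(beta) = eta_p
  nl <- simulate_sc_nonlinear(p, gates = list(alpha = 0, beta = beta), u = u,
                              rtol = 1e-10, atol = 1e-12)
  expect_equal(nl$y_clean, lin$y_clean, tolerance = 1e-6)
  expect_equal(nl$x, lin$x, tolerance = 1e-6)
  # zero input from rest
  z <- simulate_sc_nonlinear(p, u = numeric(10))
  expect_equal(z$y_clean, numeric(10))
})

test_that("nonlinear simulator conserves mass without elimination", {
  # clearance out of the system disabled (infinite decay times); the
  # x1 -> x2,x3 transfer with eta_p + eta_d = 1 conserves total sweat mass
  p <- list(tau_r = 2, tau_p = Inf, tau_d = Inf, eta_p = 0.5, eta_d = 0.5)
  u <- c(numeric(3), 2, numeric(16), 1, numeric(20))
  tr <- simulate_sc_nonlinear(p, gates = list(alpha = 0.3, beta = 0), u = u,
                              validate = FALSE, rtol = 1e-10, atol = 1e-12)
  total_in <- sum(u) * 0.25            # ZOH input mass
  total_state <- sum(tr$x[, ncol(tr$x)])
  expect_equal(total_state, total_in, tolerance = 1e-6)
})
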