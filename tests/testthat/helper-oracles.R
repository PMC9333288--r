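# batch MAP oracle: solve the full normal equations of the quadratic
# smoothing objective over (x_0 .. x_K) by dense linear algebra
batch_map_oracle <- function(dsys, y, Q, s2, x0, P0) {
  K <- length(y)
  n <- 3 * (K + 1)
  idx <- function(k) (3 * k + 1):(3 * k + 3)
  H <- matrix(0, n, n)
  g <- numeric(n)
  H[idx(0), idx(0)] <- solve(P0)
  g[idx(0)] <- solve(P0) %*% x0
  A <- dsys$A; C <- dsys$C
  for (k in 1:K) {
    Qi <- solve(Q[, , k])
    H[idx(k), idx(k)] <- H[idx(k), idx(k)] + Qi + crossprod(C) / s2
    H[idx(k - 1), idx(k - 1)] <- H[idx(k - 1), idx(k - 1)] +
      t(A) %*% Qi %*% A
    H[idx(k), idx(k - 1)] <- H[idx(k), idx(k - 1)] - Qi %*% A
    H[idx(k - 1), idx(k)] <- H[idx(k - 1), idx(k)] - t(A) %*% Qi
    g[idx(k)] <- g[idx(k)] + as.numeric(t(C)) * y[k] / s2
  }
  S <- solve(H)
  list(x = matrix(S %*% g, 3), S = S, idx = idx)
}

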