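#' E-step configuration
#'
#' Tuning parameters of the sparse-recovery E-step. Defaults follow the
#' operating point used throughout the package: generalized-Gaussian norm
#' order `p = 0.5`, covariance perturbation `epsilon = 1e-5`, activation
#' floor 0.03 uS/s during initialization and 0.25 uS/s during the main EM
#' phase, constant initialization input `u_alpha = 1` uS/s, observation
#' noise variance `1e-8` uS^2, up to 10 re-weighting iterations, GCV window
#' of 100 samples and regularization search ceiling `1e-4`.
#'
#' @param p Norm order of the sparsity prior, in (0, 2).
#' @param epsilon Covariance perturbation for numerical stability.
#' @param u_th_init,u_th_main Minimum activation amplitude (uS/s) during the
#'   initialization and main phases.
#' @param u_alpha Constant activation used to seed each initialization
#'   iteration (uS/s).
#' @param sigma_nu_sq Observation noise variance (uS^2).
#' @param n_reweight Re-weighting iterations per E-step (with early exit on
#'   relative change `< reweight_tol`).
#' @param gamma_max Ceiling of the heuristic regularization schedule.
#' @param M_gcv GCV window length, samples.
#' @param gamma_bound Upper bound of the GCV search for gamma.
#' @param lambda_floor Lower clip for lambda (avoids division blow-ups).
#' @param reweight_tol Early-exit tolerance on the re-weighted train.
#' @param P0_scale Diffuse prior scale: `P0 = P0_scale * I`, `x0 = 0`.
#' @param lambda_scale Multiplier applied to every selected lambda
#'   (default 1); used by sparsity-trend experiments.
#' @return A list of class `estep_config`.
#' @export
estep_config <- function(p = 0.5, epsilon = 1e-5, u_th_init = 0.03,
                         u_th_main = 0.25, u_alpha = 1, sigma_nu_sq = 1e-8,
                         n_reweight = 10L, gamma_max = 1e-4, M_gcv = 100L,
                         gamma_bound = 1e-4, lambda_floor = 1e-12,
                         reweight_tol = 1e-6, P0_scale = 10,
                         lambda_scale = 1) {
  cfg <- list(p = p, epsilon = epsilon, u_th_init = u_th_init,
              u_th_main = u_th_main, u_alpha = u_alpha,
              sigma_nu_sq = sigma_nu_sq, n_reweight = as.integer(n_reweight),
              gamma_max = gamma_max, M_gcv = as.integer(M_gcv),
              gamma_bound = gamma_bound, lambda_floor = lambda_floor,
              reweight_tol = reweight_tol, P0_scale = P0_scale,
              lambda_scale = lambda_scale)
  stopifnot(cfg$p > 0, cfg$p < 2, cfg$epsilon > 0,
            cfg$u_th_init > 0, cfg$u_th_main >= cfg$u_th_init,
            cfg$sigma_nu_sq > 0, cfg$M_gcv >= 4, cfg$gamma_bound >= 0)
  class(cfg) <- "estep_config"
  cfg
}

#' Re-weighting covariance for one sample
#'
#' Gaussian re-approximation of the generalized-Gaussian prior on the
#' innovation `B u_k`:
#' \deqn{Q_k = \lambda^{-1}\,(B u_k^2 B^\top + \epsilon^2 I)^{(2-p)/2},}
#' the fractional matrix power taken on the whole symmetric PSD matrix via
#' eigendecomposition (eigenvalues clamped at zero).
#'
#' @param B Input column (3-vector).
#' @param u_k Current activation value (uS/s).
#' @param lambda Positive regularization weight.
#' @param p Norm order in (0, 2).
#' @param epsilon Perturbation.
#' @return Symmetric positive-definite 3x3 matrix.
#' @export
compute_Q <- function(B, u_k, lambda, p = 0.5, epsilon = 1e-5) {
  B <- as.numeric(B)
  if (!all(is.finite(c(B, u_k, lambda, p, epsilon))) || lambda <= 0)
    stop("compute_Q requires finite inputs and lambda > 0", call. = FALSE)
  M <- tcrossprod(B) * u_k^2 + diag(epsilon^2, length(B))
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 0)^((2 - p) / 2)
  (e$vectors %*% (vals * t(e$vectors))) / lambda
}

# Fast rank-one closed form of compute_Q for a whole train: the argument
# eps^2 I + u^2 B B' has eigenvalue eps^2 + u^2 |B|^2 along b = B/|B| and
# eps^2 on its orthogonal complement, so
#   Q_k = lambda^-1 [ eps^(2-p) I + (c_k - eps^(2-p)) b b' ],
#   c_k = (eps^2 + u_k^2 |B|^2)^((2-p)/2).
# Returns a 3 x 3 x K cube.
build_Q_seq <- function(B, u, lambda, p, epsilon) {
  B <- as.numeric(B)
  nb2 <- sum(B^2)
  b <- B / sqrt(nb2)
  s <- (2 - p) / 2
  base <- epsilon^(2 * s)
  cvec <- (epsilon^2 + u^2 * nb2)^s
  K <- length(u)
  Q <- array(0, dim = c(3, 3, K))
  bb <- tcrossprod(b)
  I3 <- diag(3)
  for (k in seq_len(K))
    Q[, , k] <- (base * I3 + (cvec[k] - base) * bb) / lambda
  Q
}

#' Fixed-interval smoothing with time-varying process noise
#'
#' Runs a forward Kalman filter and backward Rauch-Tung-Striebel smoother
#' for the model `x_k = A x_{k-1} + w_k`, `w_k ~ N(0, Q_k)`,
#' `y_k = C x_k + v_k`, `v_k ~ N(0, sigma_nu_sq)`, in O(K) time, and returns
#' smoothed means, filtered/smoothed covariances and the lag-one smoothed
#' cross-covariances that the M-step needs.
#'
#' @param dsys A `discrete_system`.
#' @param y Observations (length K).
#' @param Q_seq 3 x 3 x K array of process-noise covariances.
#' @param sigma_nu_sq Observation noise variance.
#' @param x0 Prior mean of the pre-sample state (default 0).
#' @param P0 Prior covariance of the pre-sample state (default diffuse 10 I).
#' @return A list of class `smoother_result`: `x_smooth` (3 x (K+1), column 1
#'   is the smoothed pre-sample state), `P_smooth` (3 x 3 x (K+1)), `x_filt`,
#'   `P_filt`, `P_lag1` (3 x 3 x K, slice k is Cov(x_k, x_{k-1} | Y)), and
#'   `loglik_proxy`.
#' @export
fixed_interval_smooth <- function(dsys, y, Q_seq, sigma_nu_sq,
                                  x0 = c(0, 0, 0), P0 = diag(10, 3)) {
  stopifnot(length(y) == dim(Q_seq)[3])
  out <- fis_smooth_cpp(dsys$A, dsys$C, as.numeric(y), Q_seq,
                        sigma_nu_sq, as.numeric(x0), P0)
  structure(
    list(x_smooth = out$x_smooth, P_smooth = out$P_smooth,
         x_filt = out$x_filt, P_filt = out$P_filt, P_lag1 = out$P_lag1,
         loglik_proxy = out$loglik),
    class = "smoother_result"
  )
}

#' Project smoothed innovations onto the input direction
#'
#' Recovers the activation candidate at every sample by least-squares
#' projection of the smoothed one-step innovation on the input column:
#' `c_k = (B'B)^{-1} B' (x_k - A x_{k-1})`. Returns both the raw projections
#' and the thresholded working values `max(u_th, c_k)` used inside the
#' re-weighting loop.
#'
#' @param x_smooth 3 x (K+1) smoothed states (column 1 = pre-sample state).
#' @param dsys A `discrete_system`.
#' @param u_th Minimum activation amplitude (uS/s).
#' @return List with `raw` (projections) and `floored` (working train).
#' @export
update_u <- function(x_smooth, dsys, u_th) {
  B <- as.numeric(dsys$B)
  nb2 <- sum(B^2)
  if (nb2 <= 0) stop("B'B is zero; projection undefined", call. = FALSE)
  K <- ncol(x_smooth) - 1L
  innov <- x_smooth[, 2:(K + 1), drop = FALSE] -
    dsys$A %*% x_smooth[, 1:K, drop = FALSE]
  raw <- as.numeric(crossprod(B, innov)) / nb2
  list(raw = raw, floored = pmax(u_th, raw))
}

#' Prune sub-threshold activations
#'
#' Final sparsification of the activation train: entries whose raw
#' projection falls below the activation floor are set to zero, the rest keep
#' their raw (un-floored) value. The pruned train is what enters the next
#' re-weighting covariance and what the method reports.
#'
#' @param raw_projections Raw projections from [update_u()].
#' @param u_th Minimum activation amplitude (uS/s).
#' @return Numeric vector of pruned amplitudes.
#' @export
refine_u <- function(raw_projections, u_th) {
  ifelse(raw_projections >= u_th, raw_projections, 0)
}

#' Heuristic regularization schedule
#'
#' FOCUSS-style schedule used during initialization: the fraction of signal
#' energy already explained scales the regularization toward its ceiling,
#' \deqn{\gamma = (1 - \sum_k (y_k - \hat y_k)^2 / \sum_k y_k^2)\,
#'   \gamma_{max},}
#' clipped below at zero, then `lambda = gamma / ||B||_p^p` (clipped at the
#' lambda floor).
#'
#' @param y Observations.
#' @param y_pred Current predictions `C x_k` (`NULL` counts as all-zero).
#' @param B Input column.
#' @param cfg An [estep_config()].
#' @return List with `lambda` and `gamma`.
#' @export
heuristic_lambda <- function(y, y_pred, B, cfg = estep_config()) {
  sy <- sum(y^2)
  if (sy <= 0) stop("all-zero observations; schedule undefined", call. = FALSE)
  if (is.null(y_pred)) y_pred <- numeric(length(y))
  gamma <- (1 - sum((y - y_pred)^2) / sy) * cfg$gamma_max
  gamma <- max(gamma, 0)
  lambda <- max(gamma / sum(abs(as.numeric(B))^cfg$p), cfg$lambda_floor)
  list(lambda = lambda, gamma = gamma)
}

# GCV score of one window from its SVD ingredients: yhat_rot = U' (y_window
# minus the anchor response), kappa the singular values of D P^{1/2} padded
# with zeros to the window length M.
gcv_score <- function(gamma, yhat_rot, kappa, M) {
  filt <- gamma / (kappa^2 + gamma)
  num <- M * sum(yhat_rot^2 * filt^2)
  den <- sum(filt)^2
  if (den <= 0) Inf else num / den
}

#' Windowed SVD-based generalized cross-validation for lambda
#'
#' Splits the record into windows of `M_gcv` samples. Within window `n` the
#' observations obey `y_n = F_n x_n + D_n u_n` with `F_n` stacking `C A^k`
#' rows (the response to the window's first smoothed state) and `D_n` the
#' lower-triangular Toeplitz of impulse-response terms `C A^(k-1) B`. With
#' `P_u = diag(|u|^(2-p))` and the SVD `D_n P_u^(1/2) = U S V'`, the GCV
#' score
#' \deqn{G_n(\gamma) = M \sum_i \hat y_i^2 \gamma^2/(\kappa_i^2+\gamma)^2
#'   \,/\, (\sum_i \gamma/(\kappa_i^2+\gamma))^2}
#' is minimized over `0 <= gamma <= gamma_bound`; the median over windows
#' gives gamma, and `lambda = gamma / ||B||_p^p`.
#'
#' Windows whose current activation is identically zero are skipped
#' (degenerate weight matrix); if every window degenerates the heuristic
#' schedule is used instead. A trailing short window is kept when at least
#' `M_gcv / 2` samples long, otherwise merged into the previous window.
#'
#' @param dsys A `discrete_system`.
#' @param y Observations.
#' @param u_current Current activation estimate (length K).
#' @param x_anchor 3 x (K+1) smoothed states supplying each window's anchor
#'   (the smoothed state at the window's first sample).
#' @param cfg An [estep_config()].
#' @return List with `lambda`, `gamma`, and `gamma_windows`.
#' @export
gcv_lambda <- function(dsys, y, u_current, x_anchor, cfg = estep_config()) {
  K <- length(y)
  M <- cfg$M_gcv
  if (K < M) stop("record shorter than one GCV window", call. = FALSE)
  bounds <- gcv_windows(K, M)
  # impulse response h_m = C A^(m-1) B for the Toeplitz blocks
  Mmax <- max(bounds[, 2] - bounds[, 1] + 1L)
  h <- impulse_response(dsys, Mmax)
  gammas <- numeric(0)
  for (w in seq_len(nrow(bounds))) {
    ks <- bounds[w, 1]:bounds[w, 2]
    uw <- u_current[ks]
    if (all(uw == 0)) next
    Mw <- length(ks)
    # anchor response: y minus C A^j x_anchor, j = 0..Mw-1
    v <- x_anchor[, ks[1] + 1L]       # smoothed state at first window sample
    yhat <- numeric(Mw)
    for (j in seq_len(Mw)) {
      yhat[j] <- y[ks[j]] - sum(as.numeric(dsys$C) * v)
      v <- as.numeric(dsys$A %*% v)
    }
    D <- toeplitz_lower(h, Mw)
    DP <- D * rep(abs(uw)^((2 - cfg$p) / 2), each = Mw)
    sv <- svd(DP, nu = Mw, nv = 0)
    kappa <- c(sv$d, numeric(Mw - length(sv$d)))
    yrot <- as.numeric(crossprod(sv$u, yhat))
    g <- optimize(gcv_score, c(0, cfg$gamma_bound), yhat_rot = yrot,
                  kappa = kappa, M = Mw)$minimum
    # compare against the boundary values too
    cand <- c(g, 0, cfg$gamma_bound)
    scores <- vapply(cand, gcv_score, numeric(1), yhat_rot = yrot,
                     kappa = kappa, M = Mw)
    gammas <- c(gammas, cand[which.min(scores)])
  }
  if (!length(gammas)) {
    out <- heuristic_lambda(y, NULL, dsys$B, cfg)
    return(list(lambda = out$lambda, gamma = out$gamma,
                gamma_windows = numeric(0)))
  }
  gamma <- median(gammas)
  lambda <- max(gamma / sum(abs(as.numeric(dsys$B))^cfg$p), cfg$lambda_floor)
  list(lambda = lambda, gamma = gamma, gamma_windows = gammas)
}

# window boundaries: full windows of M; trailing remainder kept separately
# when >= M/2, merged into the last window otherwise
gcv_windows <- function(K, M) {
  n_full <- K %/% M
  rem <- K - n_full * M
  starts <- (seq_len(n_full) - 1L) * M + 1L
  ends <- starts + M - 1L
  if (rem > 0) {
    if (rem >= M / 2 || n_full == 0) {
      starts <- c(starts, n_full * M + 1L)
      ends <- c(ends, K)
    } else {
      ends[n_full] <- K
    }
  }
  cbind(start = starts, end = ends)
}

impulse_response <- function(dsys, M) {
  h <- numeric(M)
  v <- as.numeric(dsys$B)
  for (m in seq_len(M)) {
    h[m] <- sum(as.numeric(dsys$C) * v)
    v <- as.numeric(dsys$A %*% v)
  }
  h
}

# strictly-lower Toeplitz: D[j, i] = h[j - i] for j > i, zero diagonal
toeplitz_lower <- function(h, M) {
  D <- matrix(0, M, M)
  idx <- outer(seq_len(M), seq_len(M), "-")
  pos <- idx > 0
  D[pos] <- h[idx[pos]]
  D
}

#' Run one sparse-recovery E-step
#'
#' Iteratively re-weighted fixed-interval smoothing: each re-weighting pass
#' selects the regularization weight (heuristic schedule during the
#' initialization phase, windowed GCV during the main phase), prunes the
#' current activation train, rebuilds the per-sample process-noise
#' covariances, smooths, and re-projects the innovations. Exits early when
#' successive activation trains agree to `reweight_tol` relative change.
#'
#' @param theta A [physiological_params()] object (or `discrete_system`).
#' @param y Observations (uS).
#' @param u_init Initial activation train (length K).
#' @param phase `"init"` (heuristic lambda, low floor) or `"main"`
#'   (GCV lambda, main floor).
#' @param cfg An [estep_config()].
#' @param x_prev Optional 3 x (K+1) smoothed states from the previous E-step
#'   (used by the lambda schedules before the first smoothing pass).
#' @param Ts Sampling period (used when `theta` is a parameter object).
#' @return A list of class `estep_output`: `x` (smoothed states), `u`
#'   (pruned [impulse_train()]), `u_raw`, `lambda_used`, `smoother`
#'   (a `smoother_result`), `n_reweight_done`.
#' @export
run_estep <- function(theta, y, u_init = NULL, phase = c("main", "init"),
                      cfg = estep_config(), x_prev = NULL, Ts = 0.25) {
  phase <- match.arg(phase)
  dsys <- if (inherits(theta, "discrete_system")) theta
          else discretize(build_continuous(theta), Ts)
  K <- length(y)
  u_th <- if (phase == "init") cfg$u_th_init else cfg$u_th_main
  u_cur <- if (is.null(u_init)) rep(cfg$u_alpha, K)
           else as_impulse_amplitudes(u_init)
  stopifnot(length(u_cur) == K)
  lambda_used <- numeric(0)
  sm <- NULL; upd <- NULL
  x_sm <- x_prev
  for (r in seq_len(cfg$n_reweight)) {
    y_pred <- if (is.null(x_sm)) NULL
              else as.numeric(dsys$C %*% x_sm[, -1, drop = FALSE])
    lam <- if (phase == "init" || is.null(x_sm)) {
      heuristic_lambda(y, y_pred, dsys$B, cfg)
    } else {
      gcv_lambda(dsys, y, u_cur, x_sm, cfg)
    }
    lam$lambda <- max(lam$lambda * cfg$lambda_scale, cfg$lambda_floor)
    lambda_used <- c(lambda_used, lam$lambda)
    u_prev <- u_cur
    Q_seq <- build_Q_seq(dsys$B, u_cur, lam$lambda, cfg$p, cfg$epsilon)
    sm <- fixed_interval_smooth(dsys, y, Q_seq, cfg$sigma_nu_sq,
                                x0 = c(0, 0, 0),
                                P0 = diag(cfg$P0_scale, 3))
    x_sm <- sm$x_smooth
    upd <- update_u(x_sm, dsys, u_th)
    u_cur <- refine_u(upd$raw, u_th)
    rel <- sum(abs(u_cur - u_prev)) / max(sum(abs(u_prev)), 1e-12)
    if (rel < cfg$reweight_tol) break
  }
  structure(
    list(x = x_sm, u = impulse_train(u_cur, dsys$Ts), u_raw = upd$raw,
         lambda_used = lambda_used, smoother = sm, n_reweight_done = r,
         dsys = dsys),
    class = "estep_output"
  )
}
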