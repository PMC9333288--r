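#' Sparse non-negative impulse train
#'
#' Constructor for the ANS activation representation used throughout the
#' package: a vector of non-negative amplitudes (uS/s) on the sampling grid,
#' mostly zero.
#'
#' @param amplitudes Non-negative amplitudes, one per sample.
#' @param Ts Sampling period, seconds.
#' @return An object of class `impulse_train` with fields `amplitudes`,
#'   `support` (indices of nonzeros), `K` and `Ts`.
#' @export
impulse_train <- function(amplitudes, Ts = 0.25) {
  amplitudes <- as_impulse_amplitudes(amplitudes)
  structure(
    list(amplitudes = amplitudes, support = which(amplitudes > 0),
         K = length(amplitudes), Ts = Ts),
    class = "impulse_train"
  )
}

#' @export
print.impulse_train <- function(x, ...) {
  cat(sprintf("Impulse train: K = %d samples (Ts = %g s), %d nonzero\n",
              x$K, x$Ts, length(x$support)))
  if (length(x$support))
    cat(sprintf("  amplitudes in [%.3g, %.3g] uS/s\n",
                min(x$amplitudes[x$support]), max(x$amplitudes[x$support])))
  invisible(x)
}

#' Generate a random sparse activation train
#'
#' Places `n_impulses` impulses uniformly at random on the sample grid with a
#' minimum pairwise separation, with amplitudes drawn uniformly from
#' `amp_range`. Placement and amplitudes use separate random streams derived
#' from `seed` so either can be varied in isolation.
#'
#' @param K Number of samples.
#' @param n_impulses Number of nonzero impulses.
#' @param amp_range Amplitude range (min, max) in uS/s.
#' @param min_separation Minimum spacing between impulses, in samples.
#' @param seed Integer seed.
#' @param Ts Sampling period, seconds.
#' @return An [impulse_train()].
#' @export
generate_impulse_train <- function(K, n_impulses, amp_range = c(0.3, 3),
                                   min_separation = 16L, seed = 1L,
                                   Ts = 0.25) {
  stopifnot(K >= 1, n_impulses >= 0, amp_range[1] > 0 || n_impulses == 0)
  if (n_impulses * min_separation >= K)
    stop("cannot place ", n_impulses, " impulses with separation ",
         min_separation, " in ", K, " samples", call. = FALSE)
  u <- numeric(K)
  if (n_impulses > 0) {
    # sample positions with a spacing constraint by drawing gaps: choose
    # n ordered positions from the grid shrunk by the mandatory gaps
    support <- with_local_seed(seed, {
      free <- K - (n_impulses - 1L) * min_separation
      pos <- sort(sample.int(free, n_impulses))
      pos + (seq_len(n_impulses) - 1L) * min_separation
    })
    amps <- with_local_seed(seed + 1000003L, {
      runif(n_impulses, amp_range[1], amp_range[2])
    })
    u[support] <- amps
  }
  impulse_train(u, Ts = Ts)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Add measurement noise at a phasic-referenced SNR
#'
#' Adds Gaussian white or pink (1/f) noise to the full clean signal
#' (phasic + tonic). The noise variance is set in expectation so that
#' `10 log10(P_phasic / sigma^2) = snr_db`, i.e. the SNR is referenced to the
#' power of the phasic component, the part of the signal the impulses drive
#' directly. Pink noise is generated by shaping a white spectrum with an
#' `f^(-1/2)` amplitude profile and rescaling to the same target power.
#'
#' @param clean A `state_trajectory` from [simulate_sc()].
#' @param snr_db Signal-to-noise ratio in dB relative to the phasic power.
#'   `Inf` returns the clean signal unchanged.
#' @param kind `"gaussian"` or `"pink"`.
#' @param seed Integer seed for the noise stream.
#' @return Numeric vector of noisy observations (uS).
#' @export
add_noise <- function(clean, snr_db, kind = c("gaussian", "pink"), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(clean, "state_trajectory"))
  if (!is.finite(snr_db)) {
    if (snr_db > 0) return(clean$y_clean)
    stop("snr_db must be finite or +Inf", call. = FALSE)
  }
  p_phasic <- mean(clean$y_phasic^2)
  if (p_phasic <= 0)
    stop("phasic component has zero power; SNR undefined", call. = FALSE)
  sigma <- sqrt(p_phasic / 10^(snr_db / 10))
  K <- length(clean$y_clean)
  noise <- with_local_seed(seed, {
    if (kind == "gaussian") {
      rnorm(K, sd = sigma)
    } else {
      pink_noise(K, sigma)
    }
  })
  clean$y_clean + noise
}

# unit-variance-target 1/f noise via frequency-domain amplitude shaping
pink_noise <- function(K, sigma) {
  w <- rnorm(K)
  W <- fft(w)
  f <- c(1, seq_len(K - 1))          # avoid the DC singularity
  shaped <- Re(fft(W / sqrt(f), inverse = TRUE)) / K
  shaped <- shaped - mean(shaped)
  shaped * sigma / sqrt(mean(shaped^2))
}

#' Generate a complete synthetic validation bundle
#'
#' Draws a sparse ground-truth activation train, simulates the clean SC
#' signal from the linear compartment model, and adds noise at the requested
#' phasic-referenced SNR. The impulse and noise streams are seeded
#' separately (`seed` and `seed + 5000011`).
#'
#' @param params Ground-truth [physiological_params()].
#' @param K Number of samples.
#' @param n_impulses Number of ground-truth impulses.
#' @param snr_db Noise level (dB, phasic-referenced); `Inf` for noiseless.
#' @param kind Noise kind, `"gaussian"` or `"pink"`.
#' @param seed Integer seed.
#' @param Ts Sampling period, seconds.
#' @param amp_range,min_separation Passed to [generate_impulse_train()]
#'   (`min_separation` in seconds here; default 4 s).
#' @return A list of class `synthetic_bundle` with `truth_params`, `truth_u`,
#'   `clean` (a `state_trajectory`), `observed`, `Ts`, `snr_db`, `kind`,
#'   `seed`.
#' @export
generate_bundle <- function(params, K = 800L, n_impulses = 25L, snr_db = 25,
                            kind = "gaussian", seed = 1L, Ts = 0.25,
                            amp_range = c(0.3, 3), min_separation = 4) {
  validate_params(params)
  u <- generate_impulse_train(K, n_impulses, amp_range = amp_range,
                              min_separation = max(1L,
                                as.integer(round(min_separation / Ts))),
                              seed = seed, Ts = Ts)
  dsys <- discretize(build_continuous(params), Ts)
  clean <- simulate_sc(dsys, u)
  observed <- if (n_impulses == 0 && !is.finite(snr_db)) {
    clean$y_clean
  } else if (is.finite(snr_db)) {
    add_noise(clean, snr_db, kind = kind, seed = seed + 5000011L)
  } else clean$y_clean
  structure(
    list(truth_params = params, truth_u = u, clean = clean,
         observed = observed, Ts = Ts, snr_db = snr_db, kind = kind,
         seed = seed),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf("Synthetic SC bundle: K = %d (%.0f s at %g Hz), %d impulses, ",
              length(x$observed), length(x$observed) * x$Ts, 1 / x$Ts,
              length(x$truth_u$support)))
  cat(if (is.finite(x$snr_db))
    sprintf("%g dB %s noise\n", x$snr_db, x$kind) else "noiseless\n")
  invisible(x)
}

#' Write / read a synthetic bundle as CSV + JSON sidecar
#'
#' The signal goes to `<path>.csv` (columns `time_s`, `observed_uS`) and the
#' ground truth (parameters, impulse support and amplitudes, seed, noise
#' spec) to `<path>.json`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param path Output path stem (no extension).
#' @return `write_bundle` returns `path` invisibly; `read_bundle` the
#'   reconstructed bundle.
#' @export
write_bundle <- function(bundle, path) {
  df <- data.frame(time_s = seq_along(bundle$observed) * bundle$Ts,
                   observed_uS = bundle$observed)
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  side <- list(
    params = unclass(bundle$truth_params),
    impulse_support = bundle$truth_u$support,
    impulse_amplitudes = bundle$truth_u$amplitudes[bundle$truth_u$support],
    K = bundle$truth_u$K, Ts = bundle$Ts,
    snr_db = if (is.finite(bundle$snr_db)) bundle$snr_db else "Inf",
    kind = bundle$kind, seed = bundle$seed
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- read.csv(paste0(path, ".csv"))
  params <- do.call(physiological_params, as.list(side$params))
  u <- numeric(side$K)
  u[side$impulse_support] <- side$impulse_amplitudes
  snr <- if (identical(side$snr_db, "Inf")) Inf else as.numeric(side$snr_db)
  dsys <- discretize(build_continuous(params), side$Ts)
  structure(
    list(truth_params = params, truth_u = impulse_train(u, side$Ts),
         clean = simulate_sc(dsys, u), observed = df$observed_uS,
         Ts = side$Ts, snr_db = snr, kind = side$kind, seed = side$seed),
    class = "synthetic_bundle"
  )
}
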