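#' Read a skin-conductance recording from CSV/TSV
#'
#' Accepts either a two-column file (`time_s`, conductance in uS; any header
#' names, first column taken as time) or a single-column file with the
#' sampling rate declared by the caller. Time must be strictly increasing
#' and approximately uniform; gaps wider than two sample periods are
#' reported in the result.
#'
#' @param path File path (comma- or tab-separated, with header).
#' @param declared_rate Sampling rate in Hz, required for single-column
#'   files.
#' @return List with `y` (uS), `rate` (Hz), `time` (s) and `gaps` (indices
#'   after which a gap > 2 sample periods occurs).
#' @export
read_sc <- function(path, declared_rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep)
  if (ncol(df) >= 2) {
    tm <- as.numeric(df[[1]]); y <- as.numeric(df[[2]])
    if (any(!is.finite(tm)) || any(!is.finite(y)))
      stop("non-finite values in ", path, call. = FALSE)
    if (is.unsorted(tm, strictly = TRUE))
      stop("time column must be strictly increasing", call. = FALSE)
    dt <- diff(tm)
    rate <- 1 / median(dt)
    gaps <- which(dt > 2.5 * median(dt))
  } else {
    if (is.null(declared_rate))
      stop("single-column file requires a declared sampling rate",
           call. = FALSE)
    y <- as.numeric(df[[1]])
    if (any(!is.finite(y))) stop("non-finite values in ", path, call. = FALSE)
    rate <- declared_rate
    tm <- seq_along(y) / rate
    gaps <- integer(0)
  }
  list(y = y, rate = rate, time = tm, gaps = gaps)
}

#' Preprocess a recording for deconvolution
#'
#' Standard conditioning chain: optional median-filter despiking (0.75 s
#' window), zero-phase low-pass anti-aliasing, polyphase resampling to the
#' target rate (default 4 Hz), and optional front padding by reflecting the
#' initial segment so the smoother warms up on signal-like data. The padded
#' region is flagged so downstream results can be trimmed.
#'
#' @param y Samples (uS).
#' @param rate Input sampling rate, Hz.
#' @param target_rate Output rate, Hz (default 4).
#' @param pad_s Seconds of front padding (default 0; 20-30 s recommended
#'   when the record starts mid-activity).
#' @param despike Apply median-filter despiking.
#' @param lowpass_hz Anti-alias / smoothing cutoff, Hz (default 1.5;
#'   `NA` skips smoothing, though an anti-alias filter at
#'   `0.45 * target_rate` is still applied before any resampling).
#' @return List with `y`, `rate`, `padded` (logical mask over the output
#'   samples, `TRUE` inside the padding).
#' @export
preprocess_sc <- function(y, rate, target_rate = 4, pad_s = 0,
                          despike = TRUE, lowpass_hz = 1.5) {
  stopifnot(rate > 0, target_rate > 0)
  if (rate < target_rate)
    stop("upsampling from ", rate, " to ", target_rate,
         " Hz is not supported", call. = FALSE)
  if (despike && length(y) > 8) {
    win <- max(3L, as.integer(round(0.75 * rate)))
    if (win %% 2 == 0) win <- win + 1L
    if (win < length(y)) y <- as.numeric(runmed(y, win, endrule = "keep"))
  }
  cutoff <- lowpass_hz
  if (rate != target_rate && !(is.finite(cutoff) &&
                               cutoff <= 0.5 * target_rate)) {
    cutoff <- 0.45 * target_rate        # anti-alias guard
  }
  if (is.finite(cutoff) && cutoff < rate / 2) {
    bf <- signal::butter(4, cutoff / (rate / 2), type = "low")
    y <- as.numeric(signal::filtfilt(bf, y))
  }
  if (rate != target_rate) {
    # the signal is band-limited by the zero-phase filter above, so
    # unit-gain resampling reduces to interpolation on the target grid
    t_in <- (seq_along(y) - 1) / rate
    t_out <- seq(0, t_in[length(t_in)], by = 1 / target_rate)
    y <- spline(t_in, y, xout = t_out)$y
  }
  n_pad <- as.integer(round(pad_s * target_rate))
  padded <- rep(FALSE, length(y) + n_pad)
  if (n_pad > 0) {
    if (n_pad >= length(y)) {
      warning("signal shorter than the padding; padding with first value",
              call. = FALSE)
      pad <- rep(y[1], n_pad)
    } else {
      pad <- rev(y[seq_len(n_pad)])   # reflect the initial segment
    }
    y <- c(pad, y)
    padded[seq_len(n_pad)] <- TRUE
  }
  list(y = y, rate = target_rate, padded = padded)
}

#' Read an event schedule
#'
#' Single-column CSV of stimulus onset times in seconds.
#'
#' @param path File path.
#' @return Ascending numeric vector of onset times.
#' @export
read_events <- function(path) {
  ev <- as.numeric(read.csv(path)[[1]])
  if (any(!is.finite(ev)) || any(ev < 0) || is.unsorted(ev, strictly = TRUE))
    stop("events must be non-negative, finite, strictly increasing",
         call. = FALSE)
  ev
}

#' Write a deconvolution result
#'
#' Writes `<path>.csv` (time, observed, reconstructed, phasic, tonic,
#' activation, burn-in flag) and `<path>.json` (parameters, fit summary,
#' iteration log).
#'
#' @param result An `sc_deconvolution`.
#' @param path Output path stem.
#' @return `path`, invisibly.
#' @export
write_deconvolution <- function(result, path) {
  K <- length(result$y)
  tm <- seq_len(K) * result$Ts
  df <- data.frame(
    time_s = tm, observed_uS = result$y,
    reconstructed_uS = result$y_reconstructed,
    phasic_uS = result$y_phasic, tonic_uS = result$y_tonic,
    u_uS_per_s = result$u$amplitudes,
    burn_in = tm <= result$burn_in_s
  )
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  side <- list(
    theta = unclass(result$theta), r_squared = result$r_squared,
    n_pulses = result$n_pulses, converged = result$converged,
    Ts = result$Ts, burn_in_s = result$burn_in_s,
    iteration_log = result$iteration_log
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
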