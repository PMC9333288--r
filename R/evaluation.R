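#' Coefficient of determination of a reconstruction
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y Reference signal.
#' @param y_hat Reconstruction.
#' @return Scalar (at most 1; negative when the fit is worse than the mean).
#' @export
r_squared <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("zero-variance reference; R^2 undefined", call. = FALSE)
  1 - sum((y - y_hat)^2) / sst
}

#' Average amplitude error of an estimated activation train
#'
#' `| ||u_hat||_1 - ||u||_1 | / ||u||_0`: the gap in total activation mass
#' per true impulse.
#'
#' @param u_hat Estimated train ([impulse_train()] or numeric).
#' @param u_true Ground-truth train.
#' @return Scalar, uS/s.
#' @export
amplitude_error <- function(u_hat, u_true) {
  uh <- if (inherits(u_hat, "impulse_train")) u_hat$amplitudes else u_hat
  ut <- if (inherits(u_true, "impulse_train")) u_true$amplitudes else u_true
  l0 <- sum(ut > 0)
  if (l0 == 0) stop("ground truth has no impulses", call. = FALSE)
  abs(sum(abs(uh)) - sum(abs(ut))) / l0
}

#' Event-related ROC of detected activations
#'
#' Labels every detected impulse positive when it falls within
#' `(e, e + window_s]` of a stimulus onset `e` (an impulse covers only the
#' nearest preceding event when windows overlap) and negative otherwise,
#' scores impulses by amplitude (optionally max-normalized for pooling
#' across signals), and computes the ROC curve and AUC.
#'
#' @param u_hat Estimated [impulse_train()].
#' @param events Stimulus onset times, seconds, ascending.
#' @param window_s Detection window after each event, seconds (default 5).
#' @param normalize Divide scores by the train's maximum amplitude.
#' @return List with `roc` (a [pROC::roc] object), `auc`, `labels`,
#'   `scores`, `times`.
#' @export
event_roc <- function(u_hat, events, window_s = 5, normalize = FALSE) {
  stopifnot(inherits(u_hat, "impulse_train"), length(events) >= 1,
            !is.unsorted(events, strictly = TRUE), all(events >= 0))
  if (!length(u_hat$support)) stop("no detected impulses", call. = FALSE)
  times <- u_hat$support * u_hat$Ts
  scores <- u_hat$amplitudes[u_hat$support]
  if (normalize) scores <- scores / max(scores)
  labels <- vapply(times, function(t) {
    prev <- events[events < t]
    length(prev) > 0 && t - max(prev) <= window_s
  }, logical(1))
  if (length(unique(labels)) < 2L)
    return(list(roc = NULL, auc = NA_real_, labels = labels,
                scores = scores, times = times,
                note = "single-class labeling; AUC undefined"))
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  list(roc = roc, auc = as.numeric(pROC::auc(roc)), labels = labels,
       scores = scores, times = times)
}

#' Count stimulations with no detected response
#'
#' @param u_hat Estimated [impulse_train()].
#' @param events Stimulus onset times, seconds.
#' @param window_s Detection window, seconds.
#' @return Number of events with no impulse in `(e, e + window_s]`.
#' @export
undetected_events <- function(u_hat, events, window_s = 5) {
  times <- u_hat$support * u_hat$Ts
  sum(vapply(events, function(e) {
    !any(times > e & times <= e + window_s)
  }, logical(1)))
}

#' Relative estimation error of the time constants
#'
#' @param theta_hat,theta_true [physiological_params()] objects (or numeric
#'   vectors `(tau_r, tau_p, tau_d)`).
#' @return Named vector of absolute relative errors in percent.
#' @export
parameter_errors <- function(theta_hat, theta_true) {
  h <- theta_vector(theta_hat)[1:3]
  t <- theta_vector(theta_true)[1:3]
  stopifnot(all(t > 0))
  out <- abs(t - h) / t * 100
  names(out) <- c("tau_r", "tau_p", "tau_d")
  out
}

#' RMSE of the reconstructed components
#'
#' @param est,truth `state_trajectory` objects of equal length.
#' @return Named vector `(total, phasic, tonic)` in uS.
#' @export
component_rmse <- function(est, truth) {
  stopifnot(length(est$y_clean) == length(truth$y_clean))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  c(total = rmse(est$y_clean, truth$y_clean),
    phasic = rmse(est$y_phasic, truth$y_phasic),
    tonic = rmse(est$y_tonic, truth$y_tonic))
}

#' Metrics report for one deconvolved signal
#'
#' Collects the quantitative metrics for a deconvolution run against ground
#' truth: reconstruction `R^2`, component RMSEs, amplitude error, parameter
#' errors, and (when an event schedule is supplied) event-related AUC and
#' undetected-event count.
#'
#' @param result An `sc_deconvolution`.
#' @param bundle A `synthetic_bundle` ground truth (or `NULL`).
#' @param events Optional stimulus onsets, seconds.
#' @param window_s Detection window, seconds.
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(result, bundle = NULL, events = NULL,
                           window_s = 5) {
  rep <- list(r_squared_obs = result$r_squared, n_pulses = result$n_pulses)
  if (!is.null(bundle)) {
    rep$r_squared_clean <- r_squared(bundle$clean$y_clean,
                                     result$y_reconstructed)
    rep$rmse <- component_rmse(result$states, bundle$clean)
    rep$amplitude_error <- amplitude_error(result$u, bundle$truth_u)
    rep$parameter_errors <- parameter_errors(result$theta,
                                             bundle$truth_params)
  }
  if (!is.null(events) && length(events) && result$n_pulses > 0) {
    er <- event_roc(result$u, events, window_s)
    rep$auc <- er$auc
    rep$n_undetected <- undetected_events(result$u, events, window_s)
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Deconvolution metrics\n")
  if (!is.null(x$r_squared_clean))
    cat(sprintf("  R^2 vs clean truth: %.4f\n", x$r_squared_clean))
  if (!is.null(x$r_squared_obs) && !is.na(x$r_squared_obs))
    cat(sprintf("  R^2 vs observations: %.4f\n", x$r_squared_obs))
  cat(sprintf("  pulses: %d\n", x$n_pulses))
  if (!is.null(x$rmse))
    cat(sprintf("  RMSE (uS): total %.4g, phasic %.4g, tonic %.4g\n",
                x$rmse["total"], x$rmse["phasic"], x$rmse["tonic"]))
  if (!is.null(x$parameter_errors))
    cat(sprintf("  tau errors (%%): r %.3g, p %.3g, d %.3g\n",
                x$parameter_errors["tau_r"], x$parameter_errors["tau_p"],
                x$parameter_errors["tau_d"]))
  if (!is.null(x$amplitude_error))
    cat(sprintf("  amplitude error: %.4g uS/s\n", x$amplitude_error))
  if (!is.null(x$auc)) cat(sprintf("  event AUC: %.4f (%d undetected)\n",
                                   x$auc, x$n_undetected))
  invisible(x)
}

#' Flatten a metrics report to one CSV-ready row
#'
#' @param rep A [metrics_report()].
#' @return A one-row data frame.
#' @export
metrics_row <- function(rep) {
  data.frame(
    r_squared_obs = rep$r_squared_obs %||% NA_real_,
    r_squared_clean = rep$r_squared_clean %||% NA_real_,
    n_pulses = rep$n_pulses,
    rmse_total = if (is.null(rep$rmse)) NA_real_ else rep$rmse[["total"]],
    rmse_phasic = if (is.null(rep$rmse)) NA_real_ else rep$rmse[["phasic"]],
    rmse_tonic = if (is.null(rep$rmse)) NA_real_ else rep$rmse[["tonic"]],
    amplitude_error = rep$amplitude_error %||% NA_real_,
    err_tau_r = if (is.null(rep$parameter_errors)) NA_real_
                else rep$parameter_errors[["tau_r"]],
    err_tau_p = if (is.null(rep$parameter_errors)) NA_real_
                else rep$parameter_errors[["tau_p"]],
    err_tau_d = if (is.null(rep$parameter_errors)) NA_real_
                else rep$parameter_errors[["tau_d"]],
    auc = rep$auc %||% NA_real_,
    n_undetected = rep$n_undetected %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
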