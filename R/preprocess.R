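#' Bandpass filter specification
#'
#' First-order Butterworth bandpass with the conventional fNIRS band
#' 0.01–0.6 Hz: the high-pass edge removes slow drifts, the low-pass edge
#' attenuates cardiac pulsation while keeping the functional hemodynamic
#' band.  Applied forward–backward (zero-phase) by default because entropy
#' estimates are sensitive to waveform distortion; set `zero_phase = FALSE`
#' for a causal single pass.
#'
#' @param order filter order (per-edge pole count of the analog prototype).
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param zero_phase apply forward–backward filtering.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 1, low_hz = 0.01, high_hz = 0.6,
                        zero_phase = TRUE) {
  if (order < 1 || order != round(order)) stop_invalid("order must be a positive integer")
  if (!(low_hz > 0 && high_hz > low_hz))
    stop_invalid("band edges must satisfy 0 < low_hz < high_hz")
  structure(list(order = as.integer(order), low_hz = low_hz, high_hz = high_hz,
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Butterworth bandpass design by the standard analog-prototype route:
# lowpass prototype poles -> lowpass-to-bandpass transform -> bilinear
# transform with prewarped edges.  Returns list(b, a) with a[1] = 1.
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  if (high_hz >= fs / 2)
    stop_invalid("high_hz (%.3g) must be below Nyquist (%.3g Hz)", high_hz, fs / 2)
  K <- 2 * fs
  w1 <- K * tan(pi * low_hz / fs)      # prewarped analog edges
  w2 <- K * tan(pi * high_hz / fs)
  B <- w2 - w1
  w0sq <- w1 * w2

  # analog lowpass prototype poles (Butterworth, left half-plane)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bandpass transform: each prototype pole yields two poles
  p_bp <- c()
  for (p in p_lp) {
    disc <- sqrt((B * p)^2 - 4 * w0sq + 0i)
    p_bp <- c(p_bp, (B * p + disc) / 2, (B * p - disc) / 2)
  }
  # analog zeros: `order` at s = 0 (the rest at infinity)
  z_bp <- rep(0 + 0i, order)

  # bilinear transform of poles/zeros; zeros at infinity map to z = -1
  zd <- (K + z_bp) / (K - z_bp)
  pd <- (K + p_bp) / (K - p_bp)
  zd <- c(zd, rep(-1 + 0i, length(p_bp) - length(z_bp)))

  poly_from_roots <- function(r) {
    coef <- 1 + 0i
    for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
    coef
  }
  b <- poly_from_roots(zd)
  a <- poly_from_roots(pd)
  a <- Re(a); b <- Re(b)
  # normalize to unit gain at the (warped) centre frequency
  wc <- 2 * atan(sqrt(w0sq) / K)
  ejw <- exp(-1i * wc * (seq_along(b) - 1))
  gain <- abs(sum(b * ejw) / sum(a * ejw))
  b <- b / gain
  list(b = b / a[1], a = a / a[1])
}

# Direct-form IIR filtering with zero initial conditions.  The moving-average
# part is done by zero-padded convolution and the recursive part by
# stats::filter (C implementation).
iir_filter <- function(x, b, a) {
  n <- length(x)
  xp <- c(rep(0, length(b) - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[length(b):(length(b) + n - 1)]
  if (length(a) > 1) {
    v <- stats::filter(v, -a[-1], method = "recursive")
    v <- as.numeric(v)
  }
  v
}

#' Apply a Butterworth bandpass filter
#'
#' @param series numeric vector (one channel) or a channels-x-samples matrix
#'   (each row filtered independently).
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return Filtered series, same shape as the input.
#' @details Zero-phase filtering uses odd-reflection padding at both ends
#'   before the forward–backward pass; the pad length is capped at the series
#'   length.  With a 0.01 Hz high-pass edge the filter memory is long
#'   (~`fs/low_hz` samples), so short series are rejected: the minimum
#'   accepted length is `3 * (2 * order + 1)` samples.
#' @export
bandpass_filter <- function(series, fs, spec = filter_spec()) {
  if (is.matrix(series))
    return(t(apply(series, 1, bandpass_filter, fs = fs, spec = spec)))
  n <- length(series)
  min_n <- 3 * (2 * spec$order + 1)
  if (n < min_n)
    stop_invalid("series too short to filter: %d samples < minimum %d", n, min_n)
  check_finite(series, "series")
  co <- butter_bandpass(spec$order, spec$low_hz, spec$high_hz, fs)
  if (!spec$zero_phase) return(iir_filter(series, co$b, co$a))
  # odd-reflection padding to suppress edge transients
  pad <- min(n - 1, ceiling(3 * fs / spec$low_hz))
  pre <- 2 * series[1] - series[seq(pad + 1, 2)]
  post <- 2 * series[n] - series[seq(n - 1, n - pad)]
  y <- iir_filter(c(pre, series, post), co$b, co$a)
  y <- rev(iir_filter(rev(y), co$b, co$a))
  y[(pad + 1):(pad + n)]
}

#' Remove a least-squares linear trend
#'
#' Fits `value ~ time index` by ordinary least squares and returns the
#' residuals, so the output has zero mean and zero linear trend.
#'
#' @param series numeric vector (length >= 2) or channels-x-samples matrix.
#' @return Detrended series, same shape.
#' @export
detrend_linear <- function(series) {
  if (is.matrix(series)) return(t(apply(series, 1, detrend_linear)))
  n <- length(series)
  if (n < 2) stop_invalid("detrend_linear needs at least 2 samples")
  check_finite(series, "series")
  t <- seq_len(n)
  tc <- t - mean(t)
  slope <- sum(tc * series) / sum(tc^2)
  series - mean(series) - slope * tc
}

#' Fit a skin-blood-flow (SBF) model on rest data
#'
#' The superficial skin-blood-flow signal is shared across channels and
#' dominates the rest period, so its spatial subspace is estimated as the
#' leading principal components of the channel covariance of the
#' mean-centered rest matrix.
#'
#' @param rest channels x samples matrix of preprocessed rest data.
#' @param n_components number of leading components to keep (0 allowed).
#' @return An object of class `sbf_model`: orthonormal `component_vectors`
#'   (channels x n_components, descending eigenvalue order), the
#'   `channel_means` used for centering, and the full `eigenvalues`.
#' @export
fit_sbf <- function(rest, n_components = 3) {
  rest <- as.matrix(rest)
  nc <- nrow(rest)
  if (ncol(rest) < 2) stop_invalid("rest needs at least 2 samples")
  if (n_components < 0 || n_components > nc)
    stop_invalid("n_components must be in 0..%d (channel count)", nc)
  check_finite(rest, "rest")
  mu <- rowMeans(rest)
  xc <- rest - mu
  cov <- tcrossprod(xc) / (ncol(rest) - 1)
  eg <- eigen(cov, symmetric = TRUE)
  v <- eg$vectors[, seq_len(n_components), drop = FALSE]
  rownames(v) <- rownames(rest)
  structure(list(n_components = as.integer(n_components),
                 component_vectors = v,
                 channel_means = mu,
                 eigenvalues = eg$values),
            class = "sbf_model")
}

#' Project out the skin-blood-flow subspace
#'
#' Removes from every time sample of `task` its projection (after centering
#' with the rest-period channel means) onto the span of the SBF component
#' vectors.  The operation is an orthogonal projection, hence idempotent and
#' energy-contracting on the centered data.
#'
#' @param task channels x samples matrix.
#' @param model an [fit_sbf()] model with matching channel count.
#' @return Matrix of the same shape with the SBF subspace removed.
#' @export
remove_sbf <- function(task, model) {
  stopifnot(inherits(model, "sbf_model"))
  task <- as.matrix(task)
  if (nrow(task) != length(model$channel_means))
    stop_invalid("task has %d channels but the SBF model was fitted on %d",
                 nrow(task), length(model$channel_means))
  if (model$n_components == 0) return(task)
  v <- model$component_vectors
  xc <- task - model$channel_means
  task - v %*% (t(v) %*% xc)
}

#' Preprocess one session
#'
#' Runs the full chain in the stated order on each channel: bandpass filter,
#' linear detrend, then skin-blood-flow removal, where the SBF spatial model
#' is fitted on the identically filtered and detrended rest segment of the
#' same session.  The returned session's `rest` is the filtered + detrended
#' rest matrix (the data the SBF model saw), kept for audit.
#'
#' @param session a [nirs_session()].
#' @param filter_spec a [filter_spec()].
#' @param n_components number of SBF components to remove (default 3).
#' @return A preprocessed [nirs_session()]; the fitted [fit_sbf()] model is
#'   attached as attribute `sbf_model`.
#' @export
preprocess_session <- function(session, filter_spec = nirsmse::filter_spec(),
                               n_components = 3) {
  stopifnot(inherits(session, "nirs_session"))
  if (ncol(session$task) == 0 || ncol(session$rest) == 0)
    stop_invalid("session has an empty rest or task matrix")
  fs <- session$sampling_rate_hz
  rest_p <- detrend_linear(bandpass_filter(session$rest, fs, filter_spec))
  task_p <- detrend_linear(bandpass_filter(session$task, fs, filter_spec))
  model <- fit_sbf(rest_p, n_components)
  task_c <- remove_sbf(task_p, model)
  out <- nirs_session(session$participant_id, session$medium,
                      rest_p, task_c,
                      sampling_rate_hz = fs,
                      channel_labels = session$channel_labels,
                      fatigue_score = session$fatigue_score)
  attr(out, "sbf_model") <- model
  out
}
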