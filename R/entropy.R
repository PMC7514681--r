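#' Multiscale-entropy parameters
#'
#' @param m pattern (template) length; matches of length `m` are tested for
#'   extension to `m + 1`.
#' @param r_coeff similarity criterion as a fraction of the series SD; the
#'   absolute tolerance is `r_coeff * sigma` with sigma taken once from the
#'   scale-1 series (population SD) and held fixed across all scales, the
#'   convention of the original coarse-graining procedure.
#' @param scales strictly increasing positive integer scale factors.
#' @return An object of class `mse_params`.
#' @export
mse_params <- function(m = 2, r_coeff = 0.15, scales = 1:20) {
  if (m < 1 || m != round(m)) stop_invalid("m must be a positive integer")
  if (!(r_coeff > 0)) stop_invalid("r_coeff must be > 0")
  scales <- as.integer(scales)
  if (length(scales) == 0 || any(scales < 1) || any(diff(scales) <= 0))
    stop_invalid("scales must be strictly increasing positive integers")
  structure(list(m = as.integer(m), r_coeff = r_coeff, scales = scales),
            class = "mse_params")
}

#' Coarse-grain a series
#'
#' Replaces non-overlapping windows of `tau` consecutive samples by their
#' mean; the trailing remainder (fewer than `tau` samples) is dropped, so the
#' output length is `floor(n / tau)`.
#'
#' @param series numeric vector.
#' @param tau integer scale factor, `1 <= tau <= length(series)`.
#' @return Numeric vector of length `floor(length(series) / tau)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5, 6), 2)  # 1.5 3.5 5.5
#' @export
coarse_grain <- function(series, tau) {
  n <- length(series)
  if (tau < 1 || tau != round(tau)) stop_invalid("tau must be a positive integer")
  if (tau > n) stop_invalid("tau (%d) exceeds series length (%d)", tau, n)
  if (tau == 1) return(series)
  nw <- n %/% tau
  colMeans(matrix(series[seq_len(nw * tau)], nrow = tau))
}

#' Template-match counts for sample entropy
#'
#' Exposes the integer counts underlying [sample_entropy()]: `B` pairs of
#' distinct length-`m` templates within Chebyshev distance `r_tol`, and `A`
#' of those whose length-`m + 1` extensions also match.  Both counts run over
#' the same `n - m` template positions and exclude self-matches.
#'
#' @inheritParams sample_entropy
#' @return Named numeric vector `c(A = , B = )`.
#' @export
sampen_counts <- function(series, m = 2, r_tol) {
  if (!(r_tol > 0)) stop_invalid("r_tol must be > 0")
  n <- length(series)
  if (n <= m + 1)
    stop_invalid("series length (%d) must exceed m + 1 = %d", n, m + 1)
  check_finite(series, "series")
  .sampen_counts(as.numeric(series), as.integer(m), as.numeric(r_tol))
}

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A / B): the negative log conditional probability that
#' two sequences matching for `m` points (Chebyshev distance <= `r_tol`,
#' self-matches excluded) also match for `m + 1` points.  Lower values mean
#' more regularity; white noise at r = 0.15 sigma gives about 2.47.
#'
#' @param series numeric vector, length > `m + 1`.
#' @param m template length.
#' @param r_tol absolute similarity tolerance (> 0); note this is the
#'   absolute tolerance, not the fraction of SD.
#' @return The entropy in nats, or `NA` when no template pair matches at
#'   length `m` or none extends to `m + 1` (the estimate is undefined).
#' @export
sample_entropy <- function(series, m = 2, r_tol) {
  ab <- sampen_counts(series, m, r_tol)
  if (ab[["A"]] == 0 || ab[["B"]] == 0) return(NA_real_)
  -log(ab[["A"]] / ab[["B"]])
}

#' Multiscale entropy profile
#'
#' Computes sample entropy on successively coarse-grained copies of the
#' series.  The tolerance `r = r_coeff * sigma` is fixed from the scale-1
#' series and reused at every scale, so the profile reflects genuine
#' structure across time scales rather than per-scale renormalization.
#' Scales where the estimate is undefined (no matching templates, or a
#' coarse series too short for `m`) are recorded and excluded from the
#' scale-averaged summary rather than imputed.
#'
#' @param series numeric vector.
#' @param params an [mse_params()].
#' @param channel optional channel label stored in the profile.
#' @return An object of class `mse_profile`: `scales`, `values` (NA where
#'   undefined), `averaged_mse` (mean over defined scales), the
#'   `undefined_scales`, and the `r_tol`/`sigma` actually used.
#' @details A warning is emitted when the coarsest scale retains fewer than
#'   100 points, where sample-entropy estimates become high-variance.  A
#'   constant series (sigma = 0) yields a profile with every scale
#'   undefined and `averaged_mse = NA`.
#' @export
multiscale_entropy <- function(series, params = mse_params(), channel = NA_character_) {
  n <- length(series)
  max_tau <- max(params$scales)
  if (n %/% max_tau <= params$m + 1)
    stop_invalid(paste0("series too short for MSE: floor(%d/%d) = %d points at the ",
                        "coarsest scale; need more than m + 1 = %d"),
                 n, max_tau, n %/% max_tau, params$m + 1)
  if (n %/% max_tau < 100)
    warning(sprintf("only %d points at scale %d; coarse-scale entropy estimates are high-variance",
                    n %/% max_tau, max_tau), call. = FALSE)
  sigma <- sd_pop(series)
  values <- rep(NA_real_, length(params$scales))
  names(values) <- params$scales
  if (sigma > 0) {
    r_tol <- params$r_coeff * sigma
    for (k in seq_along(params$scales)) {
      cg <- coarse_grain(series, params$scales[k])
      if (length(cg) > params$m + 1)
        values[k] <- sample_entropy(cg, params$m, r_tol)
    }
  } else {
    r_tol <- NA_real_
  }
  defined <- !is.na(values)
  structure(list(channel = channel,
                 scales = params$scales,
                 values = values,
                 averaged_mse = if (any(defined)) mean(values[defined]) else NA_real_,
                 undefined_scales = params$scales[!defined],
                 r_tol = r_tol, sigma = sigma,
                 m = params$m, r_coeff = params$r_coeff),
            class = "mse_profile")
}

#' @export
print.mse_profile <- function(x, ...) {
  cat(sprintf("MSE profile%s: m = %d, r = %.2f sigma, scales %d..%d\n",
              if (is.na(x$channel)) "" else paste0(" [", x$channel, "]"),
              x$m, x$r_coeff, min(x$scales), max(x$scales)))
  cat(sprintf("  averaged MSE = %s over %d defined scales\n",
              format(round(x$averaged_mse, 4)), sum(!is.na(x$values))))
  invisible(x)
}

#' Grand-average MSE profile
#'
#' Per-scale arithmetic mean over a list of profiles computed with identical
#' scales; a scale contributes the mean over the profiles where it is
#' defined.  The scale-averaged summary is recomputed from the averaged
#' profile.
#'
#' @param profiles non-empty list of [multiscale_entropy()] profiles.
#' @return An `mse_profile` with channel label `"grand_average"` (or the
#'   common channel label when all profiles share one).
#' @export
grand_average_profiles <- function(profiles) {
  if (length(profiles) == 0) stop_invalid("profiles must be a non-empty list")
  stopifnot(all(vapply(profiles, inherits, logical(1), "mse_profile")))
  scales <- profiles[[1]]$scales
  for (p in profiles)
    if (!identical(p$scales, scales))
      stop_invalid("all profiles must share identical scales")
  vals <- vapply(profiles, function(p) p$values, numeric(length(scales)))
  vals <- matrix(vals, nrow = length(scales))
  avg <- rowMeans(vals, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  names(avg) <- scales
  chans <- unique(vapply(profiles, function(p) p$channel, character(1)))
  defined <- !is.na(avg)
  structure(list(channel = if (length(chans) == 1) chans else "grand_average",
                 scales = scales,
                 values = avg,
                 averaged_mse = if (any(defined)) mean(avg[defined]) else NA_real_,
                 undefined_scales = scales[!defined],
                 r_tol = NA_real_, sigma = NA_real_,
                 m = profiles[[1]]$m, r_coeff = profiles[[1]]$r_coeff),
            class = "mse_profile")
}

#' Averaged MSE of one preprocessed channel
#'
#' Convenience wrapper: extract a channel from a (preprocessed) session,
#' compute its MSE profile, and return it.
#'
#' @param session a [nirs_session()], normally after [preprocess_session()].
#' @param channel channel label (default `"L3"`, the left 3 cm channel).
#' @param params an [mse_params()].
#' @return An `mse_profile` for that channel.
#' @export
session_mse <- function(session, channel = "L3", params = mse_params()) {
  stopifnot(inherits(session, "nirs_session"))
  if (!channel %in% session$channel_labels)
    stop_invalid("channel '%s' not among session channels (%s)", channel,
                 paste(session$channel_labels, collapse = ", "))
  multiscale_entropy(session$task[channel, ], params, channel = channel)
}
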