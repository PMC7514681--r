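#' Specify a synthetic fNIRS cohort
#'
#' Describes the generative world used by [generate_cohort()]: a repeated-
#' measures storytelling study in which each participant is recorded once per
#' communication medium with a forehead-mounted 4-channel fNIRS device
#' (channels `L1`, `L3`, `R1`, `R3`; the 3 cm channels carry cortical signal)
#' at 10 Hz, with a ~60 s eyes-closed rest segment followed by a ~180 s
#' listening task, and an 8-point fatigue self-report per session.
#'
#' Each task series is the sum of three components, all expressed relative to
#' a unit-variance neural signal:
#' \itemize{
#'   \item a power-law ("colored") neural component whose spectral exponent
#'     beta is set per medium by `spectral_exponents` plus a participant-level
#'     offset (SD `participant_beta_sd`) shared across that participant's
#'     sessions — the planted complexity effect;
#'   \item quasi-sinusoidal systemic physiology (cardiac ~1.1 Hz, respiratory
#'     ~0.3 Hz, Mayer waves ~0.1 Hz) identical across channels;
#'   \item a low-rank skin-blood-flow (SBF) component: `sbf_rank` slow latent
#'     series mixed across channels through a per-session spatial mixing
#'     matrix, scaled by `sbf_amplitude`.  This is the component the
#'     rest-period eigen-decomposition stage is designed to remove.
#' }
#' The rest segment shares the session's artifact and SBF structure but
#' carries baseline (pink, beta = 1) neural noise in every medium.
#'
#' Fatigue scores are drawn from a latent Gaussian coupled to the
#' participant's planted complexity so that, per medium, the Spearman
#' correlation between complexity and fatigue approximates `fatigue_link`
#' (a Gaussian copula with the rank-correlation inversion
#' rho_pearson = 2 sin(pi * rho_spearman / 6)), then discretized to 1..8.
#'
#' @param n_participants number of participants (>= 2).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param rest_duration_s,task_duration_s segment durations in seconds.
#' @param media ordered condition labels.
#' @param spectral_exponents named numeric map condition -> beta in \[0, 2\]
#'   (0 = white, 1 = pink).  Within the hemodynamic band a whiter spectrum
#'   (lower beta) is the more entropic, "more complex" signal, so averaged
#'   MSE after the band-limited preprocessing DECREASES with beta.  Defaults
#'   are calibrated so the default pipeline reproduces the between-medium
#'   averaged-MSE differences typical of prefrontal total-hemoglobin
#'   studies: telenoid highest, then face-to-face, speaker, video chat,
#'   with a telenoid minus video-chat gap of about 0.12.
#' @param artifact_amplitudes named numeric: SD of each systemic component
#'   (`cardiac`, `respiratory`, `mayer`) relative to the neural SD.
#' @param sbf_rank number of latent skin-blood-flow series (0 disables).
#' @param sbf_amplitude SD of each mixed SBF component relative to neural SD.
#'   Superficial flow dominates long-channel fNIRS, hence the default > 1.
#' @param fatigue_link named numeric map condition -> target Spearman rho
#'   between measured averaged MSE and fatigue (conditions omitted get 0).
#' @param participant_log_fc_sd SD of the participant-level log hemodynamic
#'   knee frequency: each participant's vascular response speed scales the
#'   0.05 Hz spectral knee by a log-normal factor shared across their
#'   sessions.  A faster (broader-band) response is the more entropic,
#'   "more complex" brain; this trait is the planted complexity the fatigue
#'   link couples to.
#' @param n_missing_fatigue number of participants (taken from the end of the
#'   roster) whose fatigue self-report is missing in every session.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full spec including the seed.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_participants = 16,
                        sampling_rate_hz = 10.0,
                        rest_duration_s = 60,
                        task_duration_s = 180,
                        media = c("speaker", "video_chat", "telenoid", "face_to_face"),
                        spectral_exponents = c(speaker = 0.92, video_chat = 1.19,
                                               telenoid = 0.55, face_to_face = 0.66),
                        artifact_amplitudes = c(cardiac = 0.4, respiratory = 0.25,
                                                mayer = 0.3),
                        sbf_rank = 3,
                        sbf_amplitude = 2.5,
                        fatigue_link = c(telenoid = -0.57),
                        participant_log_fc_sd = 0.35,
                        n_missing_fatigue = 0,
                        seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 2)
    stop_invalid("n_participants must be >= 2")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop_invalid("sampling_rate_hz must be > 0")
  if (rest_duration_s <= 0 || task_duration_s <= 0)
    stop_invalid("durations must be > 0")
  media <- as.character(media)
  if (anyDuplicated(media)) stop_invalid("media labels must be unique")
  # fill unlisted media with defaults (beta = 0.5, link = 0)
  se <- spectral_exponents
  if (is.null(names(se)) && length(se) == length(media)) names(se) <- media
  if (!all(names(se) %in% media))
    stop_invalid("spectral_exponents names must appear in media")
  beta <- stats::setNames(rep(0.5, length(media)), media)
  beta[names(se)] <- se
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 2))
    stop_invalid("spectral exponents must be finite and in [0, 2]")
  fl <- fatigue_link
  if (length(fl) && !all(names(fl) %in% media))
    stop_invalid("fatigue_link names must appear in media")
  link <- stats::setNames(rep(0, length(media)), media)
  link[names(fl)] <- fl
  if (any(abs(link) > 1)) stop_invalid("fatigue_link values must be in [-1, 1]")
  amps <- c(cardiac = 0, respiratory = 0, mayer = 0)
  if (length(artifact_amplitudes)) {
    if (!all(names(artifact_amplitudes) %in% names(amps)))
      stop_invalid("artifact_amplitudes names must be cardiac/respiratory/mayer")
    amps[names(artifact_amplitudes)] <- artifact_amplitudes
  }
  if (sbf_rank < 0 || sbf_rank > 4)
    stop_invalid("sbf_rank must be in 0..4 (4 recording channels)")
  if (n_missing_fatigue < 0 || n_missing_fatigue >= n_participants)
    stop_invalid("n_missing_fatigue must be in 0..(n_participants - 1)")

  structure(list(
    n_participants = as.integer(n_participants),
    sampling_rate_hz = sampling_rate_hz,
    rest_duration_s = rest_duration_s,
    task_duration_s = task_duration_s,
    media = media,
    spectral_exponents = beta,
    artifact_amplitudes = amps,
    sbf_rank = as.integer(sbf_rank),
    sbf_amplitude = sbf_amplitude,
    fatigue_link = link,
    participant_log_fc_sd = participant_log_fc_sd,
    n_missing_fatigue = as.integer(n_missing_fatigue),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic fNIRS cohort spec\n")
  cat(sprintf("  %d participants x %d media (%s)\n", x$n_participants,
              length(x$media), paste(x$media, collapse = ", ")))
  cat(sprintf("  fs = %g Hz, rest %g s, task %g s\n", x$sampling_rate_hz,
              x$rest_duration_s, x$task_duration_s))
  cat(sprintf("  beta: %s\n",
              paste(sprintf("%s=%.2f", names(x$spectral_exponents),
                            x$spectral_exponents), collapse = " ")))
  cat(sprintf("  SBF rank %d amplitude %.1f; seed %d\n",
              x$sbf_rank, x$sbf_amplitude, x$seed))
  invisible(x)
}

#' Construct a single fNIRS session
#'
#' A session is one participant x medium recording: a rest and a task matrix
#' (channels x samples, total-hemoglobin arbitrary units), the sampling rate,
#' and an optional integer fatigue self-report on a 1..8 scale.
#'
#' @param participant_id,medium identifiers.
#' @param rest,task numeric matrices, channels in rows, identical channel
#'   ordering.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param channel_labels channel names; defaults to rownames of `rest`.
#' @param fatigue_score integer in 1..8, or `NA` when the self-report is
#'   missing.
#' @return An object of class `nirs_session`.
#' @export
nirs_session <- function(participant_id, medium, rest, task,
                         sampling_rate_hz = 10.0,
                         channel_labels = rownames(rest),
                         fatigue_score = NA_integer_) {
  rest <- as.matrix(rest); task <- as.matrix(task)
  if (nrow(rest) != nrow(task))
    stop_invalid("rest and task must have the same channel count")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(rest)))
  if (length(channel_labels) != nrow(rest))
    stop_invalid("channel_labels length must equal channel count")
  if (!is.na(fatigue_score)) {
    if (fatigue_score < 1 || fatigue_score > 8)
      stop_invalid("fatigue_score must lie in [1, 8]")
    fatigue_score <- as.integer(fatigue_score)
  } else {
    fatigue_score <- NA_integer_
  }
  rownames(rest) <- rownames(task) <- channel_labels
  structure(list(
    participant_id = as.character(participant_id),
    medium = as.character(medium),
    sampling_rate_hz = sampling_rate_hz,
    channel_labels = as.character(channel_labels),
    rest = rest, task = task,
    fatigue_score = fatigue_score
  ), class = "nirs_session")
}

#' @export
print.nirs_session <- function(x, ...) {
  cat(sprintf("fNIRS session %s / %s: %d ch, rest %d + task %d samples @ %g Hz, fatigue %s\n",
              x$participant_id, x$medium, nrow(x$task), ncol(x$rest),
              ncol(x$task), x$sampling_rate_hz,
              ifelse(is.na(x$fatigue_score), "NA", x$fatigue_score)))
  invisible(x)
}

# ---- primitive generators ----------------------------------------------

# Fixed physiological constants of the generative world (see the methods
# vignette for the calibration): the neural component is low-passed with a
# second-order spectral knee at 0.05 Hz, emulating the smoothing of the
# hemodynamic response, and the latent fatigue coupling is inflated by a
# de-attenuation factor so that the *measured* averaged-MSE vs fatigue
# Spearman correlation, after discretization to the 8-point scale and MSE
# estimation noise, approximates the requested fatigue_link.
.hemo_fc <- 0.05   # Hz, hemodynamic spectral knee
.hemo_q <- 2       # knee order (power rolloff 1/(1 + (f/fc)^(2q)))
.link_deattenuation <- 1.24
.rest_neural_sd <- 0.5     # eyes-closed baseline neural SD relative to task

# Frequency-domain synthesis of 1/f^beta noise drawing from the current RNG
# stream: power-law amplitudes, uniform random phases, Hermitian spectrum,
# then normalized to zero mean and unit (population) variance.  An optional
# low-pass knee (fc in Hz, requires fs) multiplies the power spectrum by
# 1/(1 + (f/fc)^(2q)); it is used by the cohort generator to keep the neural
# component inside the hemodynamic band.
colored_noise_core <- function(n, beta, fs = NULL, fc = NULL, q = 2) {
  half <- (n - 1) %/% 2                      # strictly-positive non-Nyquist bins
  spec <- complex(n)
  knee <- function(k) {
    if (is.null(fc)) return(1)
    f <- k * fs / n
    1 / sqrt(1 + (f / fc)^(2 * q))
  }
  if (half >= 1) {
    k <- seq_len(half)
    amp <- k^(-beta / 2) * knee(k)
    phi <- runif(half, 0, 2 * pi)
    spec[1 + k] <- amp * exp(1i * phi)
    spec[n + 1 - k] <- Conj(spec[1 + k])
  }
  if (n %% 2 == 0) {                         # Nyquist bin must be real
    kn <- n / 2
    spec[1 + kn] <- kn^(-beta / 2) * knee(kn) * sign(runif(1) - 0.5)
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- sd_pop(x)
  if (s > 0) x <- x / s
  x
}

# Neural (cortical hemodynamic) component: power-law complexity inside the
# hemodynamic band; fc defaults to the population knee but is shifted per
# participant by the vascular-speed trait.
neural_noise_core <- function(n, fs, beta, fc = .hemo_fc) {
  colored_noise_core(n, beta, fs = fs, fc = fc, q = .hemo_q)
}

#' Generate power-law (colored) noise
#'
#' Synthesizes a zero-mean, unit-variance series whose expected power
#' spectrum is proportional to 1/f^beta: `beta = 0` gives white noise,
#' `beta = 1` pink (1/f) noise.  Synthesis is done in the frequency domain
#' with random phases, which pins the spectral exponent exactly in
#' expectation.
#'
#' @param n series length (>= 2).
#' @param beta spectral exponent in \[0, 2\].
#' @param seed integer seed; identical arguments give identical output.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- generate_colored_noise(1024, beta = 1, seed = 1)
#' @export
generate_colored_noise <- function(n, beta, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop_invalid("n must be a single integer >= 2")
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) ||
      beta < 0 || beta > 2)
    stop_invalid("beta must be finite and in [0, 2]")
  with_seed(seed, colored_noise_core(as.integer(n), beta))
}

# Centre frequencies (Hz) of the modeled systemic components.
.artifact_freqs <- c(cardiac = 1.1, respiratory = 0.3, mayer = 0.1)

artifacts_core <- function(n, fs, amplitudes) {
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (comp in names(.artifact_freqs)) {
    a <- if (comp %in% names(amplitudes)) amplitudes[[comp]] else 0
    # draw jitter/phase even for silent components so that switching an
    # amplitude on/off does not reshuffle the other components' draws
    f <- .artifact_freqs[[comp]] * (1 + runif(1, -0.05, 0.05))
    phi <- runif(1, 0, 2 * pi)
    if (a == 0) next
    if (.artifact_freqs[[comp]] >= fs / 2)
      stop_invalid("artifact frequency %.2f Hz >= Nyquist (fs/2 = %.2f Hz)",
                   .artifact_freqs[[comp]], fs / 2)
    # scale so the component SD equals `a` (in neural-SD units)
    out <- out + a * sqrt(2) * sin(2 * pi * f * t + phi)
  }
  out
}

#' Generate systemic physiological artifacts
#'
#' Sum of quasi-sinusoids modeling the systemic components that contaminate
#' fNIRS recordings: cardiac pulsation (~1.1 Hz), respiration (~0.3 Hz) and
#' Mayer waves (~0.1 Hz).  Each component gets a small random frequency
#' jitter (+-5%) and a random phase; `amplitudes` give each component's SD
#' relative to the unit-variance neural signal.
#'
#' @param n series length.
#' @param fs sampling rate in Hz; must exceed twice every active component's
#'   centre frequency.
#' @param amplitudes named numeric (`cardiac`, `respiratory`, `mayer`).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
generate_systemic_artifacts <- function(n, fs,
                                        amplitudes = c(cardiac = 0.5,
                                                       respiratory = 0.3,
                                                       mayer = 0.4),
                                        seed = NULL) {
  if (n < 1) stop_invalid("n must be >= 1")
  if (fs <= 0) stop_invalid("fs must be > 0")
  with_seed(seed, artifacts_core(as.integer(n), fs, amplitudes))
}

# ---- cohort assembly ----------------------------------------------------

.channels <- c("L1", "L3", "R1", "R3")

#' Generate a synthetic fNIRS cohort
#'
#' Assembles `n_participants x length(media)` sessions according to a
#' [cohort_spec()].  The condition effect is planted purely through the
#' neural component's spectral exponent; the participant effect is a
#' log-normal shift of the hemodynamic spectral knee shared across that
#' participant's sessions.  Fatigue scores are coupled to the participant
#' trait per medium so the measured averaged-MSE vs fatigue Spearman
#' correlation approximates `fatigue_link`.
#'
#' The generated object carries the planted ground truth as attributes
#' (`planted_beta`: participants x media matrix of spectral exponents;
#' `planted_complexity` / `participant_log_fc`: the participant
#' vascular-speed trait), which tests use for parameter-recovery checks.
#'
#' @param spec a [cohort_spec()].
#' @return A list of [nirs_session()] objects of class `nirs_cohort`, ordered
#'   participant-major.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_participants = 2,
#'                                       rest_duration_s = 10,
#'                                       task_duration_s = 20, seed = 7))
#' length(cohort)  # 2 participants x 4 media
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fs <- spec$sampling_rate_hz
  n_rest <- round(spec$rest_duration_s * fs)
  n_task <- round(spec$task_duration_s * fs)
  n_chan <- length(.channels)
  media <- spec$media
  np <- spec$n_participants

  with_seed(spec$seed, {
    # participant vascular-speed trait: log-normal shift of the hemodynamic
    # knee, shared across the participant's sessions
    zeta <- rnorm(np, 0, spec$participant_log_fc_sd)
    fc_i <- .hemo_fc * exp(zeta)
    beta_mat <- outer(rep(1, np), spec$spectral_exponents[media])
    dimnames(beta_mat) <- list(paste0("P", sprintf("%02d", seq_len(np))), media)

    # Fatigue: Gaussian copula against the participant's planted complexity
    # (the vascular-speed trait zeta: broader band = more entropic = more
    # complex).  The latent Spearman target is inflated by the calibrated
    # de-attenuation factor so the measured averaged-MSE vs fatigue
    # correlation approximates fatigue_link after discretization to the
    # 8-point scale and MSE estimation noise.
    fat <- matrix(NA_integer_, np, length(media), dimnames = dimnames(beta_mat))
    z <- (zeta - mean(zeta)) / max(sd_pop(zeta), .Machine$double.eps)
    for (j in seq_along(media)) {
      rho_s <- spec$fatigue_link[[media[j]]]
      rho_lat <- max(-0.95, min(0.95, .link_deattenuation * rho_s))
      rho_p <- 2 * sin(pi * rho_lat / 6)
      lat <- rho_p * z + sqrt(max(0, 1 - rho_p^2)) * rnorm(np)
      fat[, j] <- pmin(8L, pmax(1L, as.integer(round(4.5 + 2.0 * lat))))
    }
    if (spec$n_missing_fatigue > 0) {
      drop <- seq(np - spec$n_missing_fatigue + 1, np)
      fat[drop, ] <- NA_integer_
    }

    sessions <- vector("list", np * length(media))
    idx <- 0L
    for (i in seq_len(np)) {
      pid <- rownames(beta_mat)[i]
      for (j in seq_along(media)) {
        # Per-session spatial SBF mixing: unit-norm random columns.  The
        # systemic artifacts ride the superficial perfusion, so their spatial
        # loading lives inside the SBF subspace (and is therefore removable
        # by the rest-period eigen-decomposition); cardiac pulsation is in
        # any case killed by the 0.6 Hz low-pass edge.  Without an SBF
        # component the artifacts load uniformly across channels.
        mix <- NULL
        if (spec$sbf_rank > 0) {
          mix <- matrix(rnorm(n_chan * spec$sbf_rank), n_chan, spec$sbf_rank)
          mix <- sweep(mix, 2, sqrt(colSums(mix^2)), `/`)
          w <- rnorm(spec$sbf_rank)
          art_load <- as.vector(mix %*% (w / sqrt(sum(w^2))))
        } else {
          art_load <- rep(1, n_chan)
        }
        make_segment <- function(n, beta, neural_sd = 1) {
          art <- artifacts_core(n, fs, spec$artifact_amplitudes)
          ramp <- seq_len(n) - (n + 1) / 2
          ramp <- ramp / sd_pop(ramp)
          seg <- matrix(0, n_chan, n, dimnames = list(.channels, NULL))
          for (c in seq_len(n_chan)) {
            # slow instrumental drift (SD 0.3 neural units), removed by the
            # linear-detrend stage
            seg[c, ] <- neural_sd * neural_noise_core(n, fs, beta, fc = fc_i[i]) +
              art_load[c] * art + rnorm(1, 0, 0.3) * ramp
          }
          if (!is.null(mix)) {
            # SBF latents are slow perfusion signals: steep power law with
            # a 0.08 Hz knee
            lat <- vapply(seq_len(spec$sbf_rank),
                          function(k) colored_noise_core(n, 2, fs = fs, fc = 0.08),
                          numeric(n))
            seg <- seg + spec$sbf_amplitude * (mix %*% t(lat))
          }
          seg
        }
        # baseline: pink neural at reduced eyes-closed amplitude
        rest <- make_segment(n_rest, 1, neural_sd = .rest_neural_sd)
        task <- make_segment(n_task, beta_mat[i, j])
        idx <- idx + 1L
        sessions[[idx]] <- nirs_session(pid, media[j], rest, task,
                                        sampling_rate_hz = fs,
                                        channel_labels = .channels,
                                        fatigue_score = fat[i, j])
      }
    }
    structure(sessions, class = "nirs_cohort",
              planted_beta = beta_mat, participant_log_fc = zeta,
              planted_complexity = zeta, spec = spec)
  })
}

#' @export
print.nirs_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Synthetic fNIRS cohort: %d sessions (%d participants x %d media), seed %d\n",
              length(x), spec$n_participants, length(spec$media), spec$seed))
  invisible(x)
}
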