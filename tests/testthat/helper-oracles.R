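# Independent oracles used across the suite.  These deliberately re-derive
# quantities from first principles (brute force / closed form / reference
# implementations) and must stay independent of the package's own code paths.

# Exhaustive O(n^2) sample-entropy template counting (Richman-Moorman
# convention: i < j over the n - m template positions, Chebyshev distance).
brute_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

# Least-squares log-log slope of the periodogram (direct FFT), excluding the
# DC bin.
spectral_slope <- function(x) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  k <- 2:floor(n / 2)
  f <- (k - 1) / n
  unname(stats::coef(stats::lm(log(P[k]) ~ log(f)))[2])
}

# Frequency of the dominant periodogram peak, in Hz.
dominant_freq <- function(x, fs) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  k <- 2:floor(n / 2)
  (which.max(P[k]) ) * fs / n
}

# Magnitude response of a digital IIR filter b/a at frequency f (Hz).
digital_gain <- function(co, f, fs) {
  w <- 2 * pi * f / fs
  eb <- exp(-1i * w * (seq_along(co$b) - 1))
  ea <- exp(-1i * w * (seq_along(co$a) - 1))
  abs(sum(co$b * eb) / sum(co$a * ea))
}

# Small synthetic session for structural tests: iid noise with an optional
# planted rank-1 shared component.
tiny_session <- function(seed = 1, n_rest = 120, n_task = 240, shared = 0) {
  set.seed(seed)
  mk <- function(n) {
    m <- matrix(rnorm(4 * n), 4, n, dimnames = list(c("L1", "L3", "R1", "R3"), NULL))
    if (shared > 0) m <- m + shared * outer(c(1, 2, -1, 0.5), rnorm(n))
    m
  }
  nirs_session("P01", "telenoid", mk(n_rest), mk(n_task),
               sampling_rate_hz = 10, fatigue_score = 3L)
}

rms <- function(x) sqrt(mean(x^2))
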