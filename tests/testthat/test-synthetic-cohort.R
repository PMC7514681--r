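# synthetic cohort generator

test_that("colored noise has the requested spectral exponent", {
  # averaged periodogram over 50 seeds, log-log LS slope oracle
  for (beta in c(0, 1)) {
    slopes <- vapply(1:50, function(s)
      spectral_slope(generate_colored_noise(4096, beta, seed = s)), numeric(1))
    expect_lt(abs(mean(slopes) - (-beta)), 0.15)
  }
})

test_that("colored noise is normalized, deterministic, and validates input", {
  x <- generate_colored_noise(1024, 0.7, seed = 3)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-12)
  expect_identical(x, generate_colored_noise(1024, 0.7, seed = 3))

  x2 <- generate_colored_noise(2, 0, seed = 7)
  expect_length(x2, 2)
  expect_equal(mean(x2), 0, tolerance = 1e-12)

  expect_error(generate_colored_noise(1, 0, seed = 1), "n must be")
  expect_error(generate_colored_noise(100, NaN, seed = 1), "beta")
  expect_error(generate_colored_noise(100, 2.5, seed = 1), "beta")
})

test_that("systemic artifacts peak at the cardiac frequency and respect Nyquist", {
  z <- generate_systemic_artifacts(1000, 10, c(cardiac = 0, respiratory = 0, mayer = 0),
                                   seed = 1)
  expect_identical(z, rep(0, 1000))

  x <- generate_systemic_artifacts(6000, 10, c(cardiac = 1, respiratory = 0, mayer = 0),
                                   seed = 3)
  expect_lt(abs(dominant_freq(x, 10) - 1.1), 0.1)
  expect_identical(x, generate_systemic_artifacts(6000, 10,
                                                  c(cardiac = 1, respiratory = 0, mayer = 0),
                                                  seed = 3))
  expect_error(generate_systemic_artifacts(100, 2, c(cardiac = 1), seed = 1),
               "Nyquist")
})

test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_participants = 1), "n_participants")
  expect_error(cohort_spec(sampling_rate_hz = 0), "sampling_rate_hz")
  expect_error(cohort_spec(rest_duration_s = 0), "durations")
  expect_error(cohort_spec(fatigue_link = c(robot = -0.5)), "fatigue_link")
  expect_error(cohort_spec(spectral_exponents = c(robot = 1)), "spectral_exponents")
  expect_error(cohort_spec(spectral_exponents = c(telenoid = 2.4)), "exponents")
})

test_that("generate_cohort builds the full session grid deterministically", {
  spec <- cohort_spec(n_participants = 3, rest_duration_s = 12,
                      task_duration_s = 30, seed = 11)
  co <- generate_cohort(spec)
  expect_length(co, 12)
  expect_s3_class(co[[1]], "nirs_session")
  for (s in co) {
    expect_identical(s$channel_labels, c("L1", "L3", "R1", "R3"))
    expect_identical(dim(s$rest), c(4L, 120L))
    expect_identical(dim(s$task), c(4L, 300L))
    expect_true(is.na(s$fatigue_score) ||
                  (s$fatigue_score >= 1 && s$fatigue_score <= 8))
    expect_false(anyNA(s$rest) || anyNA(s$task))
    expect_true(all(apply(s$task, 1, var) > 0))
  }
  co2 <- generate_cohort(spec)
  expect_identical(co[[5]]$task, co2[[5]]$task)
  expect_identical(vapply(co, `[[`, integer(1), "fatigue_score"),
                   vapply(co2, `[[`, integer(1), "fatigue_score"))
})

test_that("fatigue scores land in 1..8 and missingness is honored", {
  co <- generate_cohort(cohort_spec(n_participants = 16, rest_duration_s = 5,
                                    task_duration_s = 10, n_missing_fatigue = 5,
                                    seed = 2))
  expect_length(co, 64)
  fat <- vapply(co, `[[`, integer(1), "fatigue_score")
  expect_identical(sum(is.na(fat)), 20L)   # 5 participants x 4 media
  expect_true(all(fat[!is.na(fat)] %in% 1:8))
})

test_that("planted complexity-fatigue link approximates the target at large n", {
  spec <- cohort_spec(n_participants = 200, rest_duration_s = 3,
                      task_duration_s = 6, fatigue_link = c(telenoid = -0.57),
                      seed = 11)
  co <- generate_cohort(spec)
  fat <- vapply(co, `[[`, integer(1), "fatigue_score")
  med <- vapply(co, `[[`, character(1), "medium")
  complexity <- attr(co, "planted_complexity")
  rho <- cor(rank(complexity), rank(fat[med == "telenoid"]))
  expect_lt(abs(rho - (-0.57)), 0.15)
  # unlinked media hover near zero
  rho0 <- cor(rank(complexity), rank(fat[med == "speaker"]))
  expect_lt(abs(rho0), 0.2)
})

test_that("without shared components the channels decorrelate", {
  # Isolates the SBF claim (artifacts are also shared, so they are disabled).
  # The band-limited neural component has only ~10 effective degrees of
  # freedom per 180 s series, so single-session |cor| between independent
  # channels is large by chance; independence shows up as the seed-averaged
  # signed correlation vanishing.
  C_acc <- matrix(0, 4, 4)
  n_seeds <- 40
  for (s in 1:n_seeds) {
    co <- generate_cohort(cohort_spec(n_participants = 2, media = "speaker",
                                      spectral_exponents = c(speaker = 0.92),
                                      task_duration_s = 180,
                                      rest_duration_s = 5,
                                      sbf_rank = 0, sbf_amplitude = 0,
                                      artifact_amplitudes = c(cardiac = 0),
                                      fatigue_link = c(), seed = 40 + s))
    C_acc <- C_acc + cor(t(co[[1]]$task))
  }
  C_bar <- C_acc / n_seeds
  expect_lt(mean(abs(C_bar[upper.tri(C_bar)])), 0.1)

  # positive control: a strong rank-1 SBF drives every channel pair to
  # near-perfect correlation in a single session
  co <- generate_cohort(cohort_spec(n_participants = 2, media = "speaker",
                                    spectral_exponents = c(speaker = 0.92),
                                    task_duration_s = 180, rest_duration_s = 5,
                                    sbf_rank = 1, sbf_amplitude = 10,
                                    fatigue_link = c(), seed = 99))
  Cs <- cor(t(co[[1]]$task))
  expect_gt(mean(abs(Cs[upper.tri(Cs)])), 0.8)
})

test_that("a strong rank-3 SBF dominates the rest-period covariance", {
  co <- generate_cohort(cohort_spec(n_participants = 2, sbf_amplitude = 10,
                                    rest_duration_s = 60, task_duration_s = 10,
                                    seed = 5))
  ev <- eigen(cov(t(co[[1]]$rest)), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(sum(ev[1:3]) / sum(ev), 0.90)
})
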