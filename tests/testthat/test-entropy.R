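# coarse-graining, sample entropy, MSE profiles

test_that("coarse_grain implements non-overlapping window means", {
  expect_identical(coarse_grain(c(1, 5, 2, 9), 1), c(1, 5, 2, 9))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))  # remainder dropped
  # length contract for every tau
  set.seed(1); x <- rnorm(37)
  for (tau in 1:37) expect_length(coarse_grain(x, tau), 37 %/% tau)
  expect_error(coarse_grain(x, 0), "tau")
  expect_error(coarse_grain(x, 38), "exceeds")
})

test_that("sample entropy counts match brute-force enumeration exactly", {
  # the spec's fixture series
  fx <- c(0.2, 0.9, 0.1, 0.8, 0.3, 0.7, 0.15, 0.85)
  expect_identical(unname(sampen_counts(fx, 2, 0.2)),
                   as.numeric(brute_sampen_counts(fx, 2, 0.2)))
  set.seed(42)
  for (i in 1:8) {
    x <- runif(sample(20:80, 1))
    m <- sample(1:3, 1)
    r <- runif(1, 0.05, 0.4)
    expect_identical(unname(sampen_counts(x, m, r)),
                     as.numeric(brute_sampen_counts(x, m, r)),
                     label = sprintf("fixture %d (n=%d m=%d)", i, length(x), m))
  }
})

test_that("periodic series have zero sample entropy", {
  x <- rep(c(1, 2), 50)
  expect_equal(sample_entropy(x, 2, 0.1), 0)
})

test_that("sample entropy is affine-invariant when the tolerance is scaled", {
  set.seed(3); x <- rnorm(150)
  a <- -2.5; b <- 7
  expect_identical(sampen_counts(x, 2, 0.3),
                   sampen_counts(a * x + b, 2, 0.3 * abs(a)))
})

test_that("degenerate inputs are signalled or undefined", {
  expect_error(sample_entropy(rnorm(100), 2, 0), "r_tol")
  expect_error(sample_entropy(rnorm(3), 2, 0.1), "length")
  # widely separated values: no template matches -> undefined
  expect_true(is.na(sample_entropy(seq(0, 1000, by = 10), 2, 0.1)))
})

test_that("multiscale_entropy profiles have the documented structure", {
  set.seed(5)
  x <- rnorm(2400)
  p <- multiscale_entropy(x, mse_params(), channel = "L3")
  expect_s3_class(p, "mse_profile")
  expect_identical(p$scales, 1:20)
  expect_length(p$values, 20)
  defined <- !is.na(p$values)
  expect_equal(p$averaged_mse, mean(p$values[defined]))
  expect_true(all(p$values[defined] >= 0))
  expect_equal(p$r_tol, 0.15 * nirsmse:::sd_pop(x))
  # scale-1 value equals a direct sample_entropy call
  expect_equal(unname(p$values["1"]), sample_entropy(x, 2, p$r_tol))
  # deterministic
  expect_identical(p$values, multiscale_entropy(x, mse_params(), channel = "L3")$values)
})

test_that("short or constant series are handled explicitly", {
  expect_error(multiscale_entropy(rnorm(50), mse_params()), "too short")
  expect_warning(p <- multiscale_entropy(rnorm(1800), mse_params()), "high-variance")
  k <- suppressWarnings(multiscale_entropy(rep(1, 3000), mse_params()))
  expect_identical(k$undefined_scales, 1:20)
  expect_true(is.na(k$averaged_mse))
})

test_that("white-noise MSE decreases with scale in expectation", {
  set.seed(9)
  vals <- sapply(1:10, function(i)
    suppressWarnings(multiscale_entropy(generate_colored_noise(2000, 0, seed = i)))$values)
  avg <- rowMeans(vals, na.rm = TRUE)
  expect_true(all(diff(avg[c(2, 5, 10, 15, 20)]) < 0))
})

test_that("grand averaging is an element-wise mean", {
  set.seed(6)
  profs <- lapply(1:16, function(i)
    suppressWarnings(multiscale_entropy(rnorm(1800), mse_params(), channel = "L3")))
  g <- grand_average_profiles(profs)
  oracle <- rowMeans(vapply(profs, `[[`, numeric(20), "values"))
  expect_equal(unname(g$values), unname(oracle), tolerance = 1e-12)
  expect_equal(g$averaged_mse, mean(oracle))
  expect_identical(g$channel, "L3")

  expect_equal(grand_average_profiles(profs[1])$values, profs[[1]]$values)

  # two profiles with values v and -v + 2c average to the constant c
  p1 <- profs[[1]]; p2 <- profs[[2]]
  p2$values <- -p1$values + 2 * 0.4
  expect_equal(unname(grand_average_profiles(list(p1, p2))$values),
               rep(0.4, 20), tolerance = 1e-12)

  expect_error(grand_average_profiles(list()), "non-empty")
  p3 <- profs[[3]]; p3$scales <- 1:19; p3$values <- p3$values[1:19]
  expect_error(grand_average_profiles(list(profs[[1]], p3)), "identical scales")
})

test_that("planted spectral complexity is recovered through the full pipeline", {
  # Within the hemodynamic band the whiter spectrum (beta = 0) is the more
  # entropic signal, so after the band-limited preprocessing its averaged MSE
  # is systematically ABOVE the pink (beta = 1) condition; a paired one-sided
  # test at alpha = 0.05 with 30 participants must detect the planted
  # ordering.
  co <- generate_cohort(cohort_spec(n_participants = 30,
                                    media = c("white", "pink"),
                                    spectral_exponents = c(white = 0, pink = 1),
                                    fatigue_link = c(), seed = 77))
  pre <- lapply(co, preprocess_session)
  avg <- vapply(pre, function(p)
    suppressWarnings(session_mse(p))$averaged_mse, numeric(1))
  med <- vapply(pre, `[[`, character(1), "medium")
  pid <- vapply(pre, `[[`, character(1), "participant_id")
  w <- avg[med == "white"][order(pid[med == "white"])]
  p <- avg[med == "pink"][order(pid[med == "pink"])]
  expect_gt(mean(w) - mean(p), 0)
  expect_lt(t.test(w, p, paired = TRUE, alternative = "greater")$p.value, 0.05)
})

test_that("session_mse extracts the requested channel", {
  s <- tiny_session(seed = 11, n_task = 2400)
  pr <- suppressWarnings(session_mse(s, channel = "R3"))
  expect_identical(pr$channel, "R3")
  direct <- suppressWarnings(multiscale_entropy(s$task["R3", ], mse_params()))
  expect_equal(pr$values, direct$values)
  expect_error(session_mse(s, channel = "Z9"), "not among")
})
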