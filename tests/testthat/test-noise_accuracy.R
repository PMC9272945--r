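test_that("expected magnitude follows the noise-floor approximation", {
  expect_equal(rician_expected_signal(0, 1), sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(rician_expected_signal(3, 0), 3, tolerance = 1e-12)
  expect_equal(rician_expected_signal(1, 0.5),
               sqrt(1 + 0.25 * pi / 2), tolerance = 1e-12)  # ~1.1801
  expect_error(rician_expected_signal(-1, 1), "nonnegative")
  # cross-check against a large Monte-Carlo Rice mean at SNR = 2; the
  # approximation's true error there is ~3.9%, inside the 5% band that
  # holds for all SNR >= 1
  set.seed(21)
  m <- mean(sample_magnitude(1, 0.5, n_draws = 1e6))
  expect_lt(abs(rician_expected_signal(1, 0.5) - m) / m, 0.05)
})

test_that("the approximation stays within 5% of the exact Rice mean", {
  # grid over signal levels at SNR >= 1
  for (sigma in c(0.1, 0.5, 1)) {
    for (snr_level in c(1, 2, 5, 20, 100)) {
      S <- snr_level * sigma
      approx <- rician_expected_signal(S, sigma)
      exact <- rice_mean_exact(S, sigma)
      expect_lt(abs(approx - exact) / exact, 0.05)
    }
  }
})

test_that("magnitude sampling matches Rayleigh/Rice moments and is seeded", {
  expect_equal(sample_magnitude(2, 0, n_draws = 5), rep(2, 5))
  # Rayleigh mean at S = 0
  draws <- sample_magnitude(0, rician_noise(0.014, seed = 4), n_draws = 1e4)
  se <- 0.014 * sqrt((2 - pi / 2)) / sqrt(1e4)
  expect_lt(abs(mean(draws) - 0.014 * sqrt(pi / 2)), 3 * se)
  # negligible bias at SNR ~ 71
  d2 <- sample_magnitude(1, 0.014, n_draws = 1e4, seed = 8)
  expect_lt(abs(mean(d2) - 1), 1e-3)
  # determinism under a fixed seed
  expect_identical(sample_magnitude(1, 0.3, n_draws = 100, seed = 9),
                   sample_magnitude(1, 0.3, n_draws = 100, seed = 9))
})

test_that("SNFR and SNR definitions are consistent", {
  expect_equal(snr(1, 0.014), 71.43, tolerance = 1e-3)
  expect_equal(snr(6, 0.014), 428.6, tolerance = 1e-3)
  expect_equal(snfr(2.7, 0.31) / snr(2.7, 0.31), 1 / sqrt(pi / 2),
               tolerance = 1e-12)
  expect_error(snfr(1, 0), "positive")
  expect_error(snr(1, 0), "positive")
  # SNFR is linear in the aspect factor (signal ~ voxel volume)
  expect_equal(snfr(2 * 1, 0.1), 2 * snfr(1, 0.1), tolerance = 1e-12)
})

test_that("mono-exponential water signal evaluates in closed form", {
  expect_equal(monoexp_signal(1.5, 2.2, 3, 0), 4.5)
  expect_equal(monoexp_signal(1, 2.2, 1, 1), exp(-2.2), tolerance = 1e-12)
  expect_equal(monoexp_signal(1, 0, 2, c(0, 1, 3)), rep(2, 3))
  expect_error(monoexp_signal(1, 2.2, 1, -1), "nonnegative")
})

test_that("biased mono-exponential fit recovers parameters", {
  b <- seq(0, 3, by = 0.3)
  # noiseless (no floor term): exact recovery, sigma -> 0
  m0 <- monoexp_signal(1, 2.2, 1, b)
  f0 <- fit_biased_monoexp(m0, b, 1)
  expect_equal(f0$s0, 1, tolerance = 1e-5)
  expect_equal(f0$diffusivity, 2.2, tolerance = 1e-5)
  expect_lt(f0$sigma, 1e-4)
  # the published simulation design: 1e4 draws, sigma = 0.014
  set.seed(31)
  draws <- sample_magnitude(monoexp_signal(1, 2.2, 1, b), 0.014,
                            n_draws = 1e4)
  f1 <- fit_biased_monoexp(rowMeans(draws), b, 1)
  expect_lt(abs(f1$sigma - 0.014) / 0.014, 0.10)
  expect_lt(abs(f1$diffusivity - 2.2) / 2.2, 0.02)
  # joint multi-alpha fit on forward model data: exact recovery
  alphas <- rep(1:6, each = length(b))
  bb <- rep(b, 6)
  mm <- rician_expected_signal(monoexp_signal(0.9, 2.2, alphas, bb), 0.02)
  fj <- fit_biased_monoexp(mm, bb, alphas)
  expect_equal(fj$s0, 0.9, tolerance = 1e-6)
  expect_equal(fj$diffusivity, 2.2, tolerance = 1e-6)
  expect_equal(fj$sigma, 0.02, tolerance = 1e-5)
  expect_error(fit_biased_monoexp(mm[1:5], bb[1:3]), "lengths")
  expect_error(fit_biased_monoexp(c(1, 2, 3), c(1, 2, 3)), "include 0")
})

test_that("threshold attenuation reproduces the published b-value gains", {
  t1 <- threshold_attenuation(snfr = 60, f = 1.05, diffusivity = 2.2)
  t6 <- threshold_attenuation(snfr = 360, f = 1.05, diffusivity = 2.2)
  expect_equal(t1$b_thr, 1.32, tolerance = 0.02)
  expect_equal(t6$b_thr, 2.13, tolerance = 0.02)
  # attenuation-coefficient gain from alpha 1 to 6 is ~62%
  gain <- t6$beta_thr / t1$beta_thr - 1
  expect_lt(abs(gain - 0.62), 0.02)
  # parameterization through (s0, alpha, sigma)
  ts <- threshold_attenuation(s0 = 1, aspect_factor = 6, sigma = 0.014,
                              f = 1.05)
  expect_equal(ts$beta_thr, log(snfr(6, 0.014) * sqrt(1.05^2 - 1)),
               tolerance = 1e-12)
  # boundary and error cases (the boundary itself carries the warning)
  edge <- suppressWarnings(
    threshold_attenuation(snfr = 1 / sqrt(1.05^2 - 1), f = 1.05))
  expect_equal(edge$beta_thr, 0, tolerance = 1e-12)
  expect_error(threshold_attenuation(snfr = 60, f = 1), "exceed")
  expect_warning(threshold_attenuation(snfr = 1, f = 1.05), "b = 0")
})

test_that("empirical bias onset agrees with the threshold formula", {
  # simulate the decay with Rician noise and find where the mean magnitude
  # exceeds the noiseless signal by 5%
  b <- seq(0, 3, by = 0.3)
  sigma <- 0.014
  alpha <- 2
  strue <- monoexp_signal(1, 2.2, alpha, b)
  set.seed(41)
  mbar <- rowMeans(sample_magnitude(strue, sigma, n_draws = 2e4))
  b_emp <- b[which(mbar / strue > 1.05)[1L]]
  b_eq <- threshold_attenuation(s0 = 1, aspect_factor = alpha,
                                sigma = sigma, f = 1.05,
                                diffusivity = 2.2)$b_thr
  expect_lt(abs(b_emp - b_eq), 0.3 + 1e-9)  # within the b-grid step
})

test_that("dot model and dot-fraction estimation behave as documented", {
  expect_equal(dot_signal(0.1, 0, 1, 1, 4), 0.1 + 0.9 * exp(-4),
               tolerance = 1e-12)  # ~0.1165
  # the ratio estimate is an upper bound, overshooting by (1-f) e^{-bD}
  est <- estimate_fdot(dot_signal(0.1, 0, 1, 1, 4), 1)
  expect_equal(as.numeric(est) - 0.1, 0.9 * exp(-4), tolerance = 1e-12)
  # f_dot = 0: estimate decays to zero with b
  ests <- vapply(c(2, 4, 8), function(b)
    as.numeric(estimate_fdot(dot_signal(0, 0, 1, 1, b), 1)), numeric(1L))
  expect_true(all(diff(ests) < 0))
  expect_lt(ests[3L], 1e-3)
  # masking and clipping
  f <- estimate_fdot(c(0.2, 0.5, 0.3), c(1, 0, 0.2))
  expect_true(is.na(f[2L]))
  expect_identical(attr(f, "n_above_one"), 1L)
  fc <- estimate_fdot(c(0.3), c(0.2), clip = TRUE)
  expect_equal(as.numeric(fc), 1)
  expect_error(dot_signal(1.2, 0, 1, 1, 1), "0, 1")
  expect_error(dot_signal(0.1, 2, 1, 1, 1), "exceed")
})

test_that("contrast ratios respond to the noise floor as expected", {
  img <- matrix(c(rep(1.86, 50), rep(1, 50)), 10, 10)
  roi_a <- matrix(rep(c(TRUE, FALSE), each = 50), 10, 10)
  expect_equal(contrast_ratio(img, roi_a, !roi_a), 1.86, tolerance = 1e-12)
  expect_equal(contrast_ratio(img, roi_a, roi_a), 1)
  # a common additive floor compresses contrast toward 1
  floor_val <- 0.5
  cr <- contrast_ratio(img + floor_val, roi_a, !roi_a)
  expect_lt(cr, 1.86)
  expect_gt(cr, 1)
  expect_error(contrast_ratio(img, roi_a & FALSE, !roi_a), "non-empty")
})

test_that("synthetic two-region phantom with noise floor recovers contrast", {
  set.seed(51)
  n_draws <- 4000
  sigma <- 0.05
  a_draws <- sample_magnitude(1.86, sigma, n_draws = n_draws)
  b_draws <- sample_magnitude(1.00, sigma, n_draws = n_draws)
  ratio <- mean(a_draws) / mean(b_draws)
  # at SNR ~ 20-37 the floor bias is negligible; sampling error dominates
  expect_equal(ratio, 1.86, tolerance = 0.01)
})
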