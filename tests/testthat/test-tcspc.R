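# Reconvolution fitting and the lifetime summaries.

test_that("convolve_model matches the brute-force convolution sum", {
  cfg <- instrument_config(channel_width = 0.008, n_channels = 512,
                           rep_rate = 2e8, irf_position = 0.5)
  irf <- simulate_irf(cfg, seed = 51)
  mu <- convolve_model(irf, lifetimes = 2.65, amplitudes = 1000,
                       background = 3)
  oracle <- brute_convolve(irf, 2.65, 1000, background = 3)
  expect_lt(max(abs(mu - oracle)) / max(oracle), 1e-10)

  # multi-component with shift = 0, tri-exponential
  mu3 <- convolve_model(irf, c(2.65, 1.3, 0.3), c(300, 300, 600))
  or3 <- brute_convolve(irf, c(2.65, 1.3, 0.3), c(300, 300, 600))
  expect_lt(max(abs(mu3 - or3)) / max(or3), 1e-10)

  # background only: flat curve
  flat <- convolve_model(irf, 1, 0, background = 7)
  expect_lt(diff(range(flat)), 1e-9)

  # delta IRF: pure exponential
  delta <- decay_histogram(c(1, rep(0, 511)), cfg$channel_width, "irf")
  t0 <- (seq_len(512) - 1) * cfg$channel_width
  expect_equal(convolve_model(delta, 1.5, 100), 100 * exp(-t0 / 1.5),
               tolerance = 1e-10)

  # total signal counts preserved by the normalized-IRF convolution
  kern_sum <- sum(100 * exp(-t0 / 1.5))
  expect_equal(sum(convolve_model(irf, 1.5, 100)), kern_sum,
               tolerance = 1e-10)

  expect_error(fit_reconvolution(
    simulate_decay(cy3b_model(), cfg, irf, seed = 1),
    irf_small(), 1), "different channel grids")
})

test_that("noiseless mono-exponential decay is recovered exactly", {
  cfg <- cfg_small()
  irf0 <- simulate_irf(cfg, noise = FALSE)
  dec <- simulate_decay(photophysics_model(2, 1), cfg, irf0, noise = FALSE)
  fit <- fit_reconvolution(dec, irf0, 1, n_starts = 2)
  expect_equal(fit$lifetimes, 2.0, tolerance = 0.002 / 2)
  expect_lt(fit$chi2_reduced, 1e-6)
})

test_that("tri-exponential reconvolution recovers the Cy3 conformer lifetimes", {
  cfg <- cfg_small()
  irf <- irf_small(seed = 61)
  dec <- simulate_decay(cy3_abasic_model(), cfg, irf, seed = 62)
  fit <- fit_reconvolution(dec, irf, 3)
  expect_equal(fit$lifetimes[3], 0.30, tolerance = 0.15)
  expect_equal(fit$lifetimes[2], 1.30, tolerance = 0.10)
  expect_equal(fit$chi2_reduced, 1.0, tolerance = 0.1)
  expect_equal(sort(coef(fit)[c("alpha1", "alpha2", "alpha3")],
                    decreasing = TRUE)[[1]], 0.5, tolerance = 0.15)
})

test_that("parameter recovery is stable across seeds", {
  model <- cy3_abasic_model()
  cfg <- cfg_small()
  errs <- sapply(1:12, function(s) {
    irf <- simulate_irf(cfg, seed = 100 + s)
    dec <- simulate_decay(model, cfg, irf, seed = 200 + s)
    fit <- suppressWarnings(
      fit_reconvolution(dec, irf, 3, n_starts = 2,
                        init = list(lifetimes = c(0.2, 0.8, 3))))
    c(abs(fit$lifetimes - model$lifetimes) / model$lifetimes,
      abs(fractional_intensities(fit) - fractional_intensities(model)),
      fit$chi2_reduced)
  })
  med <- apply(errs, 1, median)
  expect_lt(med[1], 0.15)  # tau long
  expect_lt(med[2], 0.15)  # tau intermediate
  expect_lt(med[3], 0.15)  # tau short
  expect_lt(med[4], 0.05)  # f long
  expect_lt(med[5], 0.05)  # f intermediate
  expect_lt(med[6], 0.05)  # f short
  expect_gt(mean(errs[7, ]), 0.9)  # chi2_red centred near 1
  expect_lt(mean(errs[7, ]), 1.1)
})

test_that("goodness of fit flags misspecification and accepts the truth", {
  cfg <- cfg_small()
  irf <- irf_small(seed = 71)
  dec <- simulate_decay(cy3_abasic_model(), cfg, irf, seed = 72)
  f1 <- suppressWarnings(fit_reconvolution(dec, irf, 1, n_starts = 2))
  g1 <- goodness_of_fit(f1)
  expect_gt(g1$chi2_reduced, 3)
  expect_lt(g1$residual_randomness_p, 0.01)

  ok <- sapply(1:10, function(s) {
    d <- simulate_decay(cy3_abasic_model(), cfg, irf, seed = 300 + s)
    f <- suppressWarnings(
      fit_reconvolution(d, irf, 3, n_starts = 1,
                        init = list(lifetimes = c(0.2, 0.8, 3))))
    g <- goodness_of_fit(f)
    g$residual_randomness_p > 0.01 && abs(g$chi2_reduced - 1) < 0.2
  })
  expect_gte(mean(ok), 0.8)

  # zero-noise fit: chi2_reduced ~ 0
  irf0 <- simulate_irf(cfg, noise = FALSE)
  d0 <- simulate_decay(cy3b_model(), cfg, irf0, noise = FALSE)
  f0 <- fit_reconvolution(d0, irf0, 1, n_starts = 2)
  expect_lt(goodness_of_fit(f0)$chi2_reduced, 1e-6)
})

test_that("model selection chooses the true component count", {
  cfg <- cfg_small()
  irf <- irf_small(seed = 81)
  sel3 <- select_n_components(
    simulate_decay(cy3_abasic_model(), cfg, irf, seed = 82), irf)
  expect_identical(as.integer(sel3), 3L)
  expect_false(attr(sel3, "fallback"))

  sel1 <- select_n_components(
    simulate_decay(cy3b_model(), cfg, irf, seed = 83), irf)
  expect_identical(as.integer(sel1), 1L)

  sel2 <- select_n_components(
    simulate_decay(photophysics_model(c(3, 0.4), c(0.5, 0.5)), cfg, irf,
                   seed = 84), irf)
  expect_identical(as.integer(sel2), 2L)
})

test_that("lifetime summaries evaluate the printed formulas", {
  expect_equal(amplitude_weighted_lifetime(
    list(lifetimes = 2.4, amplitudes = 1)), 2.4)
  expect_equal(amplitude_weighted_lifetime(
    list(lifetimes = c(2, 1), amplitudes = c(0.5, 0.5))), 1.5)
  expect_equal(amplitude_weighted_lifetime(
    list(lifetimes = c(2.6, 1.3, 0.3), amplitudes = c(0.25, 0.25, 0.5))),
    1.125)

  expect_equal(intensity_weighted_lifetime(
    list(lifetimes = 2.4, amplitudes = 1)), 2.4)
  expect_equal(intensity_weighted_lifetime(
    list(lifetimes = c(2, 1), amplitudes = c(0.5, 0.5))), 5 / 3,
    tolerance = 1e-6)
  expect_equal(intensity_weighted_lifetime(
    list(lifetimes = c(2.6, 1.3, 0.3), amplitudes = c(0.25, 0.25, 0.5))),
    1.9178, tolerance = 1e-4)

  expect_equal(fractional_intensities(
    list(lifetimes = 2, amplitudes = 1)), 1)
  expect_equal(fractional_intensities(
    list(lifetimes = c(2.6, 1.3, 0.3), amplitudes = c(0.25, 0.25, 0.5))),
    c(0.578, 0.289, 0.133), tolerance = 2e-3)
  # equal alpha*tau products give equal fractions
  expect_equal(fractional_intensities(
    list(lifetimes = c(4, 2, 1), amplitudes = c(1, 2, 4) / 7)),
    rep(1 / 3, 3))

  expect_error(amplitude_weighted_lifetime(
    list(lifetimes = c(1, 2), amplitudes = c(0, 0))), "zero")
})

test_that("intensity-weighted lifetime dominates the amplitude-weighted one", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(1:4, 1)
    cmp <- list(lifetimes = sort(runif(n, 0.05, 5), decreasing = TRUE),
                amplitudes = as.numeric(stats::rmultinom(1, 100, rep(1, n))) / 100)
    cmp$amplitudes <- pmax(cmp$amplitudes, 1e-3)
    ti <- intensity_weighted_lifetime(cmp)
    ta <- amplitude_weighted_lifetime(cmp)
    expect_gte(ti + 1e-12, ta)
    expect_equal(sum(fractional_intensities(cmp)), 1, tolerance = 1e-12)
    if (n == 1) expect_equal(ti, ta)
  }
})
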