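# Profile aggregation, damped-cosine period estimation, peak/crossings and
# the stacked/unstacked anticorrelation.

summary_profile <- function(seed = 1, ...) {
  summarize_profile(simulate_position_profile(profile_sim_config(...),
                                              seed = seed,
                                              mode = "summary"))
}

test_that("profile aggregation computes mean and SEM per position", {
  tab <- data.frame(position = rep(c(5, 7), each = 3),
                    experiment = rep(1:3, 2), replicate = rep(1:3, 2),
                    tau_amp = c(1, 1, 1, 1, 2, 3))
  prof <- summarize_profile(tab)
  expect_equal(prof$stats$tau_amp_mean, c(1, 2))
  expect_equal(prof$stats$tau_amp_sem, c(0, sd(c(1, 2, 3)) / sqrt(3)))
  expect_equal(prof$stats$tau_amp_sem[2], 0.577, tolerance = 1e-3)

  # a single-replicate position is dropped with a warning
  tab2 <- rbind(tab, data.frame(position = 9, experiment = 1,
                                replicate = 1, tau_amp = 5))
  expect_warning(p2 <- summarize_profile(tab2), "fewer than 2")
  expect_false(9 %in% p2$stats$position)
})

test_that("noiseless cosine profiles give the exact period", {
  prof <- summary_profile(seed = 11, noise_sd = 0,
                          nearfield_dip = list(depth = 0, center = 2.5,
                                               width = 1.5))
  fit <- fit_periodic_model(prof, n_boot = 0)
  expect_equal(fit$period, 10, tolerance = 1e-4)
  expect_equal(fit$amplitude, 0.08 * exp(-10 / 30) / exp(-10 / 30),
               tolerance = 0.02)
  expect_equal(fit$phase %% 10, 5, tolerance = 0.01)  # maximum at 15 bp

  # flat profile: no significant modulation
  flat <- summary_profile(seed = 12, noise_sd = 0, mod_amplitude = 0,
                          nearfield_dip = list(depth = 0, center = 2.5,
                                               width = 1.5))
  ffit <- fit_periodic_model(flat, n_boot = 0)
  expect_true(ffit$no_significant_modulation)
})

test_that("the helical period is recovered at experimental noise", {
  ds <- simulate_position_profile(profile_sim_config(), seed = 21,
                                  mode = "summary")
  prof <- summarize_profile(ds)
  fit <- fit_periodic_model(prof, n_boot = 99, seed = 22)
  expect_equal(fit$period, 10, tolerance = 0.1)
  expect_true(fit$period_ci[1] <= fit$period &&
                fit$period <= fit$period_ci[2])

  pg <- profile_periodogram(prof)
  expect_equal(attr(pg, "peak_period"), 10, tolerance = 0.1)
})

test_that("period recovery works across generator periods", {
  hits <- sapply(c(8, 10, 12), function(P) {
    ok <- sapply(1:100, function(s) {
      prof <- summary_profile(seed = 4000 + 101 * P + s, period = P)
      abs(fit_periodic_model(prof, n_boot = 0)$period - P) <= 1
    })
    mean(ok)
  })
  expect_true(all(hits >= 0.9))
})

test_that("near-field exclusion does not disturb the period estimate", {
  # with the dip confined below 5 bp, widening the excluded window beyond
  # it typically leaves the period unchanged
  diffs <- sapply(1:5, function(s) {
    prof <- summary_profile(seed = 30 + s)
    g6 <- fit_periodic_model(prof, exclude_below = 6, n_boot = 0)
    g8 <- fit_periodic_model(prof, exclude_below = 8, n_boot = 0)
    abs(g6$period - g8$period)
  })
  expect_lt(median(diffs), 0.5)
})

test_that("peak position and baseline crossings are located", {
  prof <- summary_profile(seed = 41)
  pc <- peak_and_crossings(prof)
  expect_equal(pc$peak, 15, tolerance = 1 / 15)
  expect_false(pc$all_equal)
  # the profile returns through the control baseline on both flanks of
  # the 15 bp peak
  expect_true(any(pc$crossings > 9 & pc$crossings < 15))
  expect_true(any(pc$crossings > 15 & pc$crossings < 21))

  # profile identical to the control: flagged, no crossings
  flat <- summary_profile(seed = 42, noise_sd = 0, mod_amplitude = 0,
                          nearfield_dip = list(depth = 0, center = 2.5,
                                               width = 1.5))
  pc2 <- peak_and_crossings(flat)
  expect_true(pc2$all_equal)
  expect_length(pc2$crossings, 0)

  # monotone profile: at most one crossing
  tab <- data.frame(position = rep(seq(6, 20, by = 2), each = 2),
                    experiment = 1:2, replicate = 1:2,
                    tau_amp = rep(seq(1, 1.5, length.out = 8), each = 2))
  tab <- rbind(tab, data.frame(position = NA, experiment = 1:2,
                               replicate = 1:2, tau_amp = 1.2))
  mono <- summarize_profile(tab)
  expect_lte(length(peak_and_crossings(mono)$crossings), 1L)
})

test_that("stacked/unstacked exchange shows up as anticorrelation", {
  # constructed exchange: f_long = c - f_short exactly
  x <- seq(6, 20, by = 2)
  fs <- 0.1 + 0.05 * cos(x)
  tab <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(position = x, experiment = r, replicate = r,
               f_short = fs, f_long = 0.7 - fs)
  }))
  prof <- summarize_profile(tab)
  ac <- component_anticorrelation(prof, n_boot = 0)
  expect_equal(ac$r, -1, tolerance = 1e-12)

  # simulated profile: negative correlation, CI excluding 0
  prof2 <- summary_profile(seed = 51)
  ac2 <- component_anticorrelation(prof2, n_boot = 99, seed = 52)
  expect_lt(ac2$r, 0)
  expect_lt(ac2$ci[2], 0)

  # independent noise: correlation near zero, CI spans 0
  set.seed(53)
  tab3 <- do.call(rbind, lapply(1:3, function(r) {
    data.frame(position = x, experiment = r, replicate = r,
               f_short = 0.2 + rnorm(length(x), 0, 0.05),
               f_long = 0.5 + rnorm(length(x), 0, 0.05))
  }))
  ac3 <- component_anticorrelation(summarize_profile(tab3), n_boot = 199,
                                   seed = 54)
  expect_lt(abs(ac3$r), 0.6)
  expect_true(ac3$ci[1] < 0 && ac3$ci[2] > 0)

  # zero variance: undefined
  tab4 <- do.call(rbind, lapply(1:2, function(r) {
    data.frame(position = x, experiment = r, replicate = r,
               f_short = 0.2, f_long = 0.5)
  }))
  expect_error(component_anticorrelation(summarize_profile(tab4),
                                         n_boot = 0), "zero variance")
})

test_that("fractional intensities still sum to one after aggregation", {
  ds <- simulate_position_profile(profile_sim_config(), seed = 61,
                                  mode = "summary")
  prof <- summarize_profile(ds)
  s <- prof$stats
  expect_equal(s$f_long_mean + s$f_mid_mean + s$f_short_mean,
               rep(1, nrow(s)), tolerance = 1e-12)
})

test_that("the decay route and the summary route agree", {
  cfg <- profile_sim_config(positions = c(7, 9, 11, 13, 15, 17),
                            n_decays_total = 3)
  inst <- instrument_config()
  ds <- simulate_position_profile(cfg, seed = 71, mode = "decays",
                                  instrument = inst)
  prof_fit <- summarize_profile(fit_decays(ds))
  truth <- profile_truth(cfg, cfg$positions)
  expect_equal(prof_fit$stats$tau_amp_mean, truth, tolerance = 0.06)
})
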