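# Shared fixtures. Most unit tests use a reduced channel grid (2048
# channels, 16.4 ns window at 50 MHz) so each reconvolution fit costs a few
# hundred ms; the acceptance tests use the full default instrument.

cfg_small <- function(...) {
  instrument_config(channel_width = 0.008, n_channels = 2048,
                    rep_rate = 5e7, irf_position = 0.8, ...)
}

irf_small <- function(seed = 1, noise = TRUE) {
  simulate_irf(cfg_small(), seed = seed, noise = noise)
}

# intensity trace built directly from a vector (bypasses the simulator)
make_trace <- function(intensities, frame_time = 0.05, truth = NULL) {
  structure(list(intensities = intensities, frame_time = frame_time,
                 truth_state = truth, truth_frac_closed = NULL,
                 truth_events = NULL, bleach_frame = NA_integer_,
                 config = NULL, seed = NA),
            class = "intensity_trace")
}

# brute-force O(N^2) circular convolution of a normalized IRF with a
# multi-exponential kernel: independent oracle for convolve_model()
brute_convolve <- function(irf, lifetimes, amplitudes, background = 0) {
  n <- length(irf$counts)
  cw <- irf$channel_width
  w <- irf$counts / sum(irf$counts)
  t0 <- (seq_len(n) - 1) * cw
  kern <- rowSums(sapply(seq_along(lifetimes), function(i) {
    amplitudes[i] * exp(-t0 / lifetimes[i])
  }))
  out <- numeric(n)
  for (k in seq_len(n)) {
    idx <- ((k - seq_len(n)) %% n) + 1L
    out[k] <- sum(w * kern[idx])
  }
  out + background
}
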