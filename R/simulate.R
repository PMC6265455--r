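#' Simulate a measured instrument response function
#'
#' Generates a Gaussian IRF histogram on the instrument's channel grid with
#' the configured FWHM, centered at `cfg$irf_position`, with Poisson counting
#' noise (or the noiseless expected curve).
#'
#' @param cfg an [instrument_config()].
#' @param seed integer seed for reproducibility, or `NULL`.
#' @param noise draw Poisson counts (`TRUE`, default) or return the expected
#'   curve scaled to `cfg$irf_total_counts`.
#' @return A [decay_histogram()] of kind `"irf"`.
#' @export
simulate_irf <- function(cfg, seed = NULL, noise = TRUE) {
  stopifnot(inherits(cfg, "instrument_config"))
  if (cfg$irf_fwhm < 2 * cfg$channel_width)
    stop("irf_fwhm narrower than 2 channels cannot be represented")
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(cfg$n_channels) - 0.5) * cfg$channel_width
  sigma <- cfg$irf_fwhm / (2 * sqrt(2 * log(2)))
  shape <- exp(-(t - cfg$irf_position)^2 / (2 * sigma^2))
  mu <- shape / sum(shape) * cfg$irf_total_counts
  counts <- if (noise) stats::rpois(length(mu), mu) else mu
  decay_histogram(counts, cfg$channel_width, kind = "irf",
                  metadata = list(channel_width_ps = cfg$channel_width * 1e3,
                                  rep_rate_MHz = cfg$rep_rate / 1e6,
                                  irf_fwhm_ps = cfg$irf_fwhm * 1e3,
                                  seed = if (is.null(seed)) NA else seed))
}

#' Simulate a TCSPC fluorescence decay
#'
#' Forward model of the TCSPC measurement: the multi-exponential decay of
#' `model` is circularly convolved with the (normalized) IRF over the
#' repetition window, scaled so the expected peak-channel count equals
#' `cfg$peak_target` (the accumulate-to-N stopping rule), background is
#' added, and Poisson counts are drawn.
#'
#' @param model a [photophysics_model()].
#' @param cfg an [instrument_config()].
#' @param irf a [decay_histogram()] of the IRF on the same channel grid; if
#'   `NULL` a noiseless IRF is generated from `cfg`.
#' @param seed integer seed, or `NULL`.
#' @param noise draw Poisson counts (default `TRUE`).
#' @return A [decay_histogram()] of kind `"decay"` whose `metadata$truth`
#'   records the ground-truth model.
#' @export
simulate_decay <- function(model, cfg, irf = NULL, seed = NULL, noise = TRUE) {
  stopifnot(inherits(model, "photophysics_model"),
            inherits(cfg, "instrument_config"))
  if (is.null(irf)) irf <- simulate_irf(cfg, noise = FALSE)
  if (length(irf$counts) != cfg$n_channels ||
      abs(irf$channel_width - cfg$channel_width) > 1e-12)
    stop("IRF and instrument config are on different channel grids")
  if (any(model$lifetimes < cfg$channel_width))
    warning("lifetime shorter than one channel is unresolvable")
  if (!is.null(seed)) set.seed(seed)
  shape <- reconv_curve(irf, lifetimes = model$lifetimes,
                        amplitudes = model$amplitudes)
  scale <- (cfg$peak_target - cfg$background_rate) / max(shape)
  if (scale <= 0) stop("peak_target must exceed the background rate")
  mu <- scale * shape + cfg$background_rate
  counts <- if (noise) stats::rpois(length(mu), mu) else mu
  decay_histogram(counts, cfg$channel_width, kind = "decay",
                  metadata = list(channel_width_ps = cfg$channel_width * 1e3,
                                  rep_rate_MHz = cfg$rep_rate / 1e6,
                                  peak_target = cfg$peak_target,
                                  seed = if (is.null(seed)) NA else seed,
                                  truth = list(lifetimes = model$lifetimes,
                                               amplitudes = model$amplitudes,
                                               label = model$label)))
}

#' Simulate a two-state single-molecule intensity trace
#'
#' Simulates the hidden open/closed state path as a continuous-time Markov
#' chain (opening rate `k_open`, closing rate `k_close`), then emits one
#' intensity per frame as the exact time-weighted mixture of the open and
#' closed (enhanced) brightness within that frame, plus counting noise.
#' The ground-truth state path (majority occupancy per frame) is returned
#' alongside.
#'
#' @param cfg a [trace_sim_config()].
#' @param seed integer seed, or `NULL`.
#' @return An object of class `intensity_trace` with elements `intensities`,
#'   `frame_time`, `truth_state` (factor open/closed, `NA` after bleaching),
#'   `truth_frac_closed` and `bleach_frame`.
#' @export
simulate_trace <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_frames <- floor(cfg$duration / cfg$frame_time)
  if (n_frames < 10) stop("duration must cover at least 10 frames")
  dur <- n_frames * cfg$frame_time

  # stationary start, then alternate exponential dwells
  p_closed <- if (cfg$k_open + cfg$k_close > 0)
    cfg$k_close / (cfg$k_open + cfg$k_close) else 0.5
  state <- if (stats::runif(1) < p_closed) "closed" else "open"
  t_ev <- 0
  ev_times <- numeric(0)   # switch times
  ev_state <- character(0) # state entered before each interval
  repeat {
    ev_times <- c(ev_times, t_ev)
    ev_state <- c(ev_state, state)
    rate <- if (state == "closed") cfg$k_open else cfg$k_close
    dwell <- if (rate > 0) stats::rexp(1, rate) else Inf
    t_ev <- t_ev + dwell
    if (t_ev >= dur) break
    state <- if (state == "closed") "open" else "closed"
  }
  bounds <- c(ev_times, dur)
  closed_len <- ifelse(ev_state == "closed", diff(bounds), 0)
  cum_closed <- c(0, cumsum(closed_len))
  closed_time_at <- function(tt) {
    i <- findInterval(tt, bounds, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(ev_state))
    cum_closed[i] + ifelse(ev_state[i] == "closed", tt - bounds[i], 0)
  }
  edges <- seq(0, dur, by = cfg$frame_time)[seq_len(n_frames + 1L)]
  frac_closed <- diff(closed_time_at(edges)) / cfg$frame_time
  frac_closed <- pmin(pmax(frac_closed, 0), 1)

  mu <- cfg$i_open * (1 + (cfg$enhancement - 1) * frac_closed) + cfg$background
  bleach_frame <- NA_integer_
  if (cfg$bleach_rate > 0) {
    t_bleach <- stats::rexp(1, cfg$bleach_rate)
    if (t_bleach < dur) {
      bleach_frame <- floor(t_bleach / cfg$frame_time) + 1L
      mu[seq.int(bleach_frame, n_frames)] <- cfg$background
    }
  }
  intens <- stats::rpois(n_frames, mu)
  if (cfg$noise_model == "poisson+gaussian_background")
    intens <- intens + stats::rnorm(n_frames, 0, cfg$background_sd)
  truth <- factor(ifelse(frac_closed > 0.5, "closed", "open"),
                  levels = c("open", "closed"))
  if (!is.na(bleach_frame)) truth[seq.int(bleach_frame, n_frames)] <- NA
  structure(list(intensities = intens, frame_time = cfg$frame_time,
                 truth_state = truth, truth_frac_closed = frac_closed,
                 truth_events = data.frame(time = ev_times, state = ev_state),
                 bleach_frame = bleach_frame, config = cfg,
                 seed = if (is.null(seed)) NA else seed),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("single-molecule intensity trace: %d frames of %.0f ms\n",
              length(x$intensities), x$frame_time * 1e3))
  if (!is.null(x$truth_state))
    cat(sprintf("  ground truth: %.1f%% of frames closed\n",
                100 * mean(x$truth_state == "closed", na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.intensity_trace <- function(x, xlab = "time (s)",
                                 ylab = "intensity (counts/frame)", ...) {
  t <- (seq_along(x$intensities) - 0.5) * x$frame_time
  graphics::plot(t, x$intensities, type = "s", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Simulate an abasic-position lifetime profile dataset
#'
#' Generates the dataset behind a lifetime-versus-abasic-position experiment.
#' The ground-truth amplitude-weighted lifetime follows
#' `baseline + dip(x) + A cos(2 pi (x - phase)/period) exp(-x/damping)`
#' (see [profile_truth()]). Position-dependence is realized by exchanging
#' amplitude between the stacked (long) and unstacked (short) components of
#' the Cy3 abasic preset, which also produces the anticorrelation of their
#' fractional intensities. Per-decay replicate noise of s.d. `noise_sd` is
#' added to the lifetime target before simulating.
#'
#' @param cfg a [profile_sim_config()].
#' @param seed integer seed.
#' @param mode `"decays"` (default) simulates a full TCSPC decay per
#'   replicate, to be fitted with [fit_decays()]; `"summary"` emits the
#'   per-decay lifetime summaries directly (fast path).
#' @param instrument an [instrument_config()] for `"decays"` mode.
#' @return An object of class `profile_dataset`: a list with `table` (one row
#'   per decay: position, experiment, replicate, and in summary mode the
#'   metrics), `decays` (in decays mode), `irf`, `control` rows for the
#'   no-abasic construct, and `truth`.
#' @export
simulate_position_profile <- function(cfg, seed = NULL,
                                      mode = c("decays", "summary"),
                                      instrument = instrument_config()) {
  stopifnot(inherits(cfg, "profile_sim_config"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  base_model <- cy3_abasic_model()
  tau <- base_model$lifetimes
  span <- tau[1] - tau[3]

  # experiment split: as even as possible, e.g. 13 -> 4/4/5
  n_per_exp <- diff(round(seq(0, cfg$n_decays_total,
                              length.out = cfg$n_experiments + 1)))
  design <- do.call(rbind, lapply(c(cfg$positions, NA), function(p) {
    data.frame(position = p,
               experiment = rep(seq_len(cfg$n_experiments), n_per_exp),
               replicate = seq_len(cfg$n_decays_total))
  }))
  truth_tau <- ifelse(is.na(design$position), cfg$baseline_tau,
                      profile_truth(cfg, design$position))
  target <- truth_tau + stats::rnorm(nrow(design), 0, cfg$noise_sd)

  # exchange amplitude between long and short components to hit the target
  delta <- (target - sum(base_model$amplitudes * tau)) / span
  delta <- pmin(pmax(delta, -base_model$amplitudes[1] + 0.01),
                base_model$amplitudes[3] - 0.01)
  amps <- cbind(base_model$amplitudes[1] + delta,
                base_model$amplitudes[2],
                base_model$amplitudes[3] - delta)

  irf <- simulate_irf(instrument, noise = FALSE)
  decays <- NULL
  tab <- design
  if (mode == "decays") {
    decays <- lapply(seq_len(nrow(design)), function(i) {
      simulate_decay(photophysics_model(tau, amps[i, ]), instrument, irf)
    })
  } else {
    f <- amps * rep(tau, each = nrow(amps))
    f <- f / rowSums(f)
    tab$tau_amp <- rowSums(amps * rep(tau, each = nrow(amps)))
    tab$tau_int <- rowSums(amps * rep(tau^2, each = nrow(amps))) / tab$tau_amp
    tab$f_long <- f[, 1]; tab$f_mid <- f[, 2]; tab$f_short <- f[, 3]
  }
  structure(list(table = tab, decays = decays, irf = irf,
                 instrument = if (mode == "decays") instrument else NULL,
                 config = cfg, mode = mode,
                 truth = data.frame(position = cfg$positions,
                                    tau_amp = profile_truth(cfg,
                                                            cfg$positions)),
                 seed = if (is.null(seed)) NA else seed),
            class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat(sprintf(paste0("abasic-position profile dataset: %d positions, ",
                     "%d experiments, %d decays/position (%s mode)\n"),
              length(x$config$positions), x$config$n_experiments,
              x$config$n_decays_total, x$mode))
  invisible(x)
}
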