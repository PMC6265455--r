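#' TCSPC instrument configuration
#'
#' Parameters of the simulated TCSPC instrument. Defaults mirror the setup
#' used throughout this package's analyses: 8 ps time channels, a ~120 ps
#' FWHM instrument response, 10 MHz pulsed excitation and accumulation to
#' twenty thousand counts in the peak channel.
#'
#' @param channel_width time channel width in ns (default 0.008, i.e. 8 ps).
#' @param n_channels number of channels; the default fills the full
#'   repetition window (1/rep_rate).
#' @param irf_fwhm IRF full width at half maximum in ns (default 0.120).
#' @param rep_rate laser repetition rate in Hz (default 1e7).
#' @param peak_target counts accumulated in the peak channel (default 20000).
#' @param background_rate mean background counts per channel (default 0).
#' @param irf_position time of the IRF maximum in ns (default 2).
#' @param irf_total_counts expected total counts in a measured IRF
#'   (default 5e5).
#'
#' @return A list of class `instrument_config`.
#' @export
instrument_config <- function(channel_width = 0.008,
                              n_channels = NULL,
                              irf_fwhm = 0.120,
                              rep_rate = 1e7,
                              peak_target = 20000,
                              background_rate = 0,
                              irf_position = 2,
                              irf_total_counts = 5e5) {
  if (channel_width <= 0) stop("channel_width must be > 0")
  if (irf_fwhm <= 0) stop("irf_fwhm must be > 0")
  if (peak_target < 1) stop("peak_target must be >= 1")
  window <- 1e9 / rep_rate  # ns
  if (is.null(n_channels)) n_channels <- floor(window / channel_width)
  if (n_channels * channel_width > window + 1e-9)
    stop("n_channels x channel_width exceeds the repetition window 1/rep_rate")
  structure(list(channel_width = channel_width, n_channels = n_channels,
                 irf_fwhm = irf_fwhm, rep_rate = rep_rate,
                 peak_target = peak_target,
                 background_rate = background_rate,
                 irf_position = irf_position,
                 irf_total_counts = irf_total_counts,
                 window = n_channels * channel_width),
            class = "instrument_config")
}

#' Multi-exponential photophysics model
#'
#' Ground-truth excited-state model for the decay simulator: a mixture of
#' exponential decay components with lifetimes `tau` (ns) and fractional
#' amplitudes `alpha` (pre-exponential weights, summing to 1).
#'
#' @param lifetimes component lifetimes in ns, all positive.
#' @param amplitudes non-negative fractional amplitudes; normalized to sum
#'   to 1.
#' @param label free-text label (e.g. conformer assignment).
#' @return A list of class `photophysics_model`.
#' @export
photophysics_model <- function(lifetimes, amplitudes, label = "") {
  if (length(lifetimes) != length(amplitudes))
    stop("lifetimes and amplitudes must have equal length")
  if (any(lifetimes <= 0)) stop("all lifetimes must be > 0")
  if (any(amplitudes < 0) || sum(amplitudes) <= 0)
    stop("amplitudes must be non-negative and not all zero")
  o <- order(lifetimes, decreasing = TRUE)
  structure(list(lifetimes = lifetimes[o],
                 amplitudes = amplitudes[o] / sum(amplitudes),
                 label = label),
            class = "photophysics_model")
}

#' Preset: Cy3 on the abasic-site hairpins
#'
#' Tri-exponential Cy3 model for the nicked hairpins carrying a single abasic
#' site: a stacked conformation at 2.65 ns, an intermediate conformation at
#' 1.3 ns and unstacked Cy3 at 300 ps, with amplitudes 0.25/0.25/0.5.
#'
#' @return A [photophysics_model()].
#' @export
cy3_abasic_model <- function() {
  photophysics_model(c(2.65, 1.3, 0.30), c(0.25, 0.25, 0.50),
                     label = "stacked/intermediate/unstacked")
}

#' Preset: Cy3B control
#'
#' Cy3B is a rigidified Cy3 analogue that cannot photoisomerize; its decay is
#' mono-exponential. Used as the no-enhancement control.
#'
#' @return A [photophysics_model()].
#' @export
cy3b_model <- function() {
  photophysics_model(2.8, 1, label = "Cy3B")
}

#' Two-state single-molecule trace simulation settings
#'
#' Settings for simulating an intensity time trace of a surface-immobilized
#' hairpin switching between an open (dim) and closed (bright, dye stacked)
#' conformation. Dye photophysics is far faster than the 50 ms frame time,
#' so each frame reports the time-averaged intensity of the underlying state
#' path within the frame.
#'
#' @param k_open opening rate (closed to open) in s^-1.
#' @param k_close closing rate (open to closed) in s^-1.
#' @param frame_time camera frame time in s (default 0.05).
#' @param i_open mean counts/frame in the open state (default 300).
#' @param enhancement closed/open intensity ratio, >= 1 (default 2.5).
#' @param bleach_rate photobleaching rate in s^-1 (default 0).
#' @param duration trace length in s (default 100).
#' @param noise_model `"poisson"` or `"poisson+gaussian_background"`.
#' @param background mean background counts/frame (default 0).
#' @param background_sd read-noise s.d. for the gaussian background model.
#' @return A list of class `trace_sim_config`.
#' @export
trace_sim_config <- function(k_open = 1, k_close = 1, frame_time = 0.05,
                             i_open = 300, enhancement = 2.5,
                             bleach_rate = 0, duration = 100,
                             noise_model = c("poisson",
                                             "poisson+gaussian_background"),
                             background = 0, background_sd = 5) {
  noise_model <- match.arg(noise_model)
  if (k_open < 0 || k_close < 0 || bleach_rate < 0)
    stop("rates must be >= 0")
  if (enhancement < 1) stop("enhancement must be >= 1")
  if (frame_time <= 0) stop("frame_time must be > 0")
  if (duration < 10 * frame_time)
    stop("duration must cover at least 10 frames")
  structure(list(k_open = k_open, k_close = k_close, frame_time = frame_time,
                 i_open = i_open, enhancement = enhancement,
                 bleach_rate = bleach_rate, duration = duration,
                 noise_model = noise_model, background = background,
                 background_sd = background_sd),
            class = "trace_sim_config")
}

#' Abasic-position profile simulation settings
#'
#' Settings for the generator of per-position lifetime profiles: a baseline
#' amplitude-weighted lifetime modulated by a damped cosine with the helical
#' period, plus a localized dip in the near-nick region where the dye can
#' insert directly into the abasic site. Positions are in bp from the nick,
#' 1-based (position 1 is adjacent to the nick).
#'
#' @param positions abasic-site positions in bp from the nick (strictly
#'   increasing, >= 1). Default: the 12 positions 1-21 bp.
#' @param baseline_tau control (no abasic site) amplitude-weighted lifetime
#'   in ns; the default is the Cy3 abasic preset value.
#' @param mod_amplitude modulation amplitude in ns (default 0.08).
#' @param period modulation period in bp (default 10, the B-DNA pitch).
#' @param phase position (bp) of a modulation maximum (default 15).
#' @param damping_length 1/e decay length of the modulation in bp
#'   (default 30).
#' @param nearfield_dip list with `depth` (ns), `center` and `width` (bp) for
#'   the near-nick Gaussian dip (default depth 0.25 ns at 2.5 +/- 1.5 bp).
#' @param noise_sd replicate-to-replicate s.d. of the per-decay lifetime
#'   target in ns (default 0.03).
#' @param n_experiments number of independent experiments (default 3).
#' @param n_decays_total decay measurements per position, split across
#'   experiments (default 13, split 4/4/5).
#' @return A list of class `profile_sim_config`.
#' @export
profile_sim_config <- function(positions = c(1, 3, 5, 7, 9, 11, 13, 15,
                                             17, 19, 20, 21),
                               baseline_tau = 1.1375,
                               mod_amplitude = 0.08,
                               period = 10,
                               phase = 15,
                               damping_length = 30,
                               nearfield_dip = list(depth = 0.25,
                                                    center = 2.5,
                                                    width = 1.5),
                               noise_sd = 0.03,
                               n_experiments = 3,
                               n_decays_total = 13) {
  if (is.unsorted(positions, strictly = TRUE) || any(positions < 1))
    stop("positions must be strictly increasing and >= 1")
  if (period <= 0) stop("period must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_experiments < 1 || n_decays_total < n_experiments)
    stop("need at least one decay per experiment")
  structure(list(positions = positions, baseline_tau = baseline_tau,
                 mod_amplitude = mod_amplitude, period = period,
                 phase = phase, damping_length = damping_length,
                 nearfield_dip = nearfield_dip, noise_sd = noise_sd,
                 n_experiments = n_experiments,
                 n_decays_total = n_decays_total),
            class = "profile_sim_config")
}

#' Ground-truth lifetime profile of a simulation config
#'
#' Evaluates the noiseless mean amplitude-weighted lifetime at abasic
#' positions `x`: baseline + near-nick dip + damped cosine.
#'
#' @param cfg a [profile_sim_config()].
#' @param x positions in bp from the nick.
#' @return lifetimes in ns.
#' @export
profile_truth <- function(cfg, x) {
  dip <- -cfg$nearfield_dip$depth *
    exp(-((x - cfg$nearfield_dip$center) / cfg$nearfield_dip$width)^2)
  cfg$baseline_tau + dip +
    cfg$mod_amplitude * cos(2 * pi * (x - cfg$phase) / cfg$period) *
      exp(-x / cfg$damping_length)
}

#' Linker and dye parameters for accessible-volume calculations
#'
#' Geometric parameters of the dye tether used by [compute_av()]. The
#' defaults describe a sulfo-Cy3 on a long NHS-ester linker as commonly
#' parameterized for accessible-volume screening: they are configuration
#' defaults of this package, not measured values.
#'
#' @param linker_length maximum linker length in Angstrom (default 20).
#' @param linker_width linker width in Angstrom (default 4.5).
#' @param dye_radii one (AV1) or three (AV3) dye radii in Angstrom
#'   (default 3.5).
#' @param grid_spacing search grid spacing in Angstrom (default 0.9).
#' @return A list of class `linker_dye_params`.
#' @export
linker_dye_params <- function(linker_length = 20, linker_width = 4.5,
                              dye_radii = 3.5, grid_spacing = 0.9) {
  if (any(c(linker_length, linker_width, dye_radii, grid_spacing) <= 0))
    stop("all linker/dye parameters must be positive")
  if (!length(dye_radii) %in% c(1L, 3L))
    stop("dye_radii must contain one (AV1) or three (AV3) radii")
  if (grid_spacing > linker_width)
    stop("grid_spacing must not exceed linker_width")
  structure(list(linker_length = linker_length, linker_width = linker_width,
                 dye_radii = dye_radii, grid_spacing = grid_spacing),
            class = "linker_dye_params")
}
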