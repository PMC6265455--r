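#' TCSPC decay histogram
#'
#' Container for a time-correlated single-photon counting (TCSPC) histogram:
#' photon counts per time channel, either a fluorescence decay or a measured
#' instrument response function (IRF).
#'
#' @param counts integer vector of non-negative photon counts per channel.
#' @param channel_width channel width in ns (8 ps channels are 0.008).
#' @param kind `"decay"` or `"irf"`.
#' @param metadata named list of header metadata (seed, instrument settings,
#'   ...); unknown keys are preserved on round-trip through [write_decay()].
#'
#' @return An object of class `decay_histogram`.
#' @seealso [simulate_irf()], [simulate_decay()], [read_decay()]
#' @export
decay_histogram <- function(counts, channel_width, kind = c("decay", "irf"),
                            metadata = list()) {
  kind <- match.arg(kind)
  counts <- as.numeric(counts)
  if (length(counts) < 16L)
    stop("a decay histogram needs at least 16 channels")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and finite")
  if (!is.numeric(channel_width) || length(channel_width) != 1L ||
      channel_width <= 0)
    stop("channel_width must be a single positive number (ns)")
  structure(
    list(counts = counts, channel_width = channel_width, kind = kind,
         metadata = metadata),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC %s histogram: %d channels of %.3g ps, %.4g total counts\n",
              x$kind, length(x$counts), x$channel_width * 1e3,
              sum(x$counts)))
  pk <- which.max(x$counts)
  cat(sprintf("  peak: %d counts in channel %d (t = %.3f ns)\n",
              round(max(x$counts)), pk, channel_times(x)[pk]))
  invisible(x)
}

#' @export
plot.decay_histogram <- function(x, log = "y", xlab = "time (ns)",
                                 ylab = "counts", ...) {
  y <- x$counts
  if (grepl("y", log)) y <- pmax(y, 0.5)
  graphics::plot(channel_times(x), y, type = "s", log = log,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Channel center times of a histogram
#'
#' @param hist a [decay_histogram()].
#' @return numeric vector of channel center times in ns.
#' @export
channel_times <- function(hist) {
  (seq_along(hist$counts) - 0.5) * hist$channel_width
}

#' Measure the FWHM of a histogram peak
#'
#' Full width at half maximum by linear interpolation of the histogram at
#' half of its peak value, the usual way an IRF width is quoted.
#'
#' @param hist a [decay_histogram()] (typically an IRF).
#' @return FWHM in ns.
#' @export
measure_fwhm <- function(hist) {
  y <- hist$counts
  t <- channel_times(hist)
  pk <- which.max(y)
  half <- y[pk] / 2
  # walk left and right from the peak to the first crossing of half max
  left <- pk
  while (left > 1L && y[left] > half) left <- left - 1L
  right <- pk
  n <- length(y)
  while (right < n && y[right] > half) right <- right + 1L
  if (y[left] > half || y[right] > half)
    stop("histogram does not fall below half maximum on both sides of the peak")
  interp <- function(i0, i1) {
    # crossing between channels i0 (below half) and i1 (above half)
    t[i0] + (half - y[i0]) / (y[i1] - y[i0]) * (t[i1] - t[i0])
  }
  t_left <- interp(left, left + 1L)
  t_right <- interp(right, right - 1L)
  t_right - t_left
}
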