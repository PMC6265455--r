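# Two-state analysis of single-molecule intensity traces: threshold
# segmentation from a Gaussian-mixture fit of the intensity histogram,
# dwell-time extraction with censoring of the first and last dwells, and
# exponential rate estimation with a frame-discretization correction.

#' Segment an intensity trace into open and closed states
#'
#' Fits a 1- or 2-component Gaussian mixture to the intensity histogram. If
#' two modes are supported, the threshold is set at the midpoint of the two
#' component means and frames are labelled open (dim) or closed (bright) by
#' thresholding. A unimodal histogram returns a single-state segmentation
#' with `no_transitions = TRUE`. A terminal drop below the open level minus
#' three s.d. without recovery is flagged as photobleaching and excluded.
#'
#' @param trace an `intensity_trace` (see [simulate_trace()] or
#'   [read_trace()]).
#' @return An object of class `state_segmentation`: per-frame `states`
#'   (factor open/closed, `NA` after bleaching), `threshold`, `level_means`,
#'   `level_sds`, `bleach_frame`, `no_transitions`.
#' @export
segment_trace <- function(trace) {
  stopifnot(inherits(trace, "intensity_trace"))
  x <- as.numeric(trace$intensities)
  if (length(x) < 10) stop("trace must have at least 10 frames")

  ux <- unique(x)
  if (length(ux) <= 2L) {
    # degenerate noise-free input: EM has nothing to estimate
    unimodal <- length(ux) == 1L
    m <- sort(ux)
    sd2 <- c(0, 0)
  } else {
    # Mclust resolves mclustBIC in the caller's frame; bind it locally so
    # the mixture fit works with mclust imported but not attached
    mclustBIC <- mclust::mclustBIC
    mix <- tryCatch(
      mclust::Mclust(x, G = 1:2, modelNames = c("E", "V"), verbose = FALSE),
      error = function(e) NULL)
    unimodal <- is.null(mix) || mix$G == 1L
    if (!unimodal) {
      m <- sort(mix$parameters$mean)
      sd2 <- sqrt(mix$parameters$variance$sigmasq)
      if (length(sd2) == 1) sd2 <- rep(sd2, 2)
      # modes closer than their widths: no resolvable dynamics
      if (diff(m) < 2 * max(sd2)) unimodal <- TRUE
    }
  }
  n <- length(x)
  if (unimodal) {
    return(structure(list(
      states = factor(rep("open", n), levels = c("open", "closed")),
      threshold = NA_real_, level_means = c(open = mean(x), closed = NA),
      level_sds = c(open = stats::sd(x), closed = NA),
      bleach_frame = NA_integer_, no_transitions = TRUE,
      frame_time = trace$frame_time), class = "state_segmentation"))
  }
  threshold <- mean(m)
  states <- factor(ifelse(x > threshold, "closed", "open"),
                   levels = c("open", "closed"))

  # bleaching: terminal run below open - 3 sd without recovery
  bleach_frame <- NA_integer_
  floor_level <- m[1] - 3 * sd2[1]
  below <- x < floor_level
  if (below[n]) {
    bleach_frame <- n - (rle(rev(below))$lengths[1]) + 1L
    states[seq.int(bleach_frame, n)] <- NA
  }
  ok <- !is.na(states)
  lv <- tapply(x[ok], states[ok], mean)
  lsd <- tapply(x[ok], states[ok], stats::sd)
  structure(list(states = states, threshold = threshold,
                 level_means = c(open = unname(lv["open"]),
                                 closed = unname(lv["closed"])),
                 level_sds = c(open = unname(lsd["open"]),
                               closed = unname(lsd["closed"])),
                 bleach_frame = bleach_frame,
                 no_transitions = length(unique(stats::na.omit(states))) < 2,
                 frame_time = trace$frame_time),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  if (x$no_transitions) {
    cat("single-state segmentation (no resolvable dynamics)\n")
  } else {
    cat(sprintf("two-state segmentation: threshold %.1f, open %.1f / closed %.1f counts\n",
                x$threshold, x$level_means["open"], x$level_means["closed"]))
  }
  invisible(x)
}

#' Extract dwell times from a segmentation
#'
#' Converts consecutive same-state runs to durations. The first and last
#' dwells are censored (their true start/end was not observed) and excluded
#' from rate fitting by default, which avoids the upward rate bias of
#' truncated dwells.
#'
#' @param seg a `state_segmentation`.
#' @param frame_time frame time in s; defaults to the segmentation's.
#' @param min_frames minimum dwell length kept, in frames (default 1).
#' @return An object of class `dwell_set`: data frames `open` and `closed`
#'   with columns `duration` (s), `frames` and `censored`, plus
#'   `no_transitions`.
#' @export
extract_dwells <- function(seg, frame_time = NULL, min_frames = 1L) {
  stopifnot(inherits(seg, "state_segmentation"))
  if (is.null(frame_time)) frame_time <- seg$frame_time
  st <- seg$states[!is.na(seg$states)]
  if (seg$no_transitions || length(unique(st)) < 2) {
    empty <- data.frame(duration = numeric(0), frames = integer(0),
                        censored = logical(0))
    return(structure(list(open = empty, closed = empty,
                          frame_time = frame_time, no_transitions = TRUE),
                     class = "dwell_set"))
  }
  r <- rle(as.character(st))
  cens <- seq_along(r$lengths) %in% c(1L, length(r$lengths))
  keep <- r$lengths >= min_frames
  d <- data.frame(state = r$values[keep],
                  frames = r$lengths[keep],
                  duration = r$lengths[keep] * frame_time,
                  censored = cens[keep])
  structure(list(open = d[d$state == "open", c("duration", "frames",
                                               "censored")],
                 closed = d[d$state == "closed", c("duration", "frames",
                                                   "censored")],
                 frame_time = frame_time, no_transitions = FALSE,
                 discretized = TRUE),
            class = "dwell_set")
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("dwell set: %d open, %d closed dwells (%d censored)\n",
              nrow(x$open), nrow(x$closed),
              sum(x$open$censored) + sum(x$closed$censored)))
  invisible(x)
}

#' Pool dwell sets from several molecules
#'
#' @param dwell_list list of `dwell_set` objects.
#' @return A pooled `dwell_set` with an `n_molecules` field.
#' @export
pool_dwells <- function(dwell_list) {
  dwell_list <- Filter(function(d) !d$no_transitions, dwell_list)
  if (!length(dwell_list)) stop("no dwell sets with transitions to pool")
  structure(list(
    open = do.call(rbind, lapply(dwell_list, `[[`, "open")),
    closed = do.call(rbind, lapply(dwell_list, `[[`, "closed")),
    frame_time = dwell_list[[1]]$frame_time,
    no_transitions = FALSE, n_molecules = length(dwell_list),
    discretized = isTRUE(dwell_list[[1]]$discretized)),
    class = "dwell_set")
}

#' Build a dwell set from raw durations
#'
#' Convenience constructor for rate fitting of externally obtained dwells.
#'
#' @param open,closed dwell durations in s.
#' @param frame_time frame time in s used for discretization.
#' @return A `dwell_set`.
#' @export
dwell_set <- function(open, closed, frame_time) {
  mk <- function(d) data.frame(duration = d,
                               frames = pmax(1L, round(d / frame_time)),
                               censored = FALSE)
  structure(list(open = mk(open), closed = mk(closed),
                 frame_time = frame_time, no_transitions = FALSE,
                 discretized = FALSE),
            class = "dwell_set")
}

# Rate MLE for one state's dwells. Frame-quantized dwells (run lengths
# from a segmentation) follow a geometric law on 1, 2, ... frames, and the
# log transform corrects for the frame clock; continuous durations use the
# plain exponential MLE 1/mean.
.fit_state_rate <- function(d, frame_time, discretized) {
  n <- nrow(d)
  if (discretized) {
    p_hat <- n / sum(d$frames)
    k <- -log(1 - p_hat) / frame_time
    var_p <- p_hat^2 * (1 - p_hat) / n  # Fisher information
    se <- sqrt(var_p) / ((1 - p_hat) * frame_time)
  } else {
    k <- 1 / mean(d$duration)
    se <- k / sqrt(n)
  }
  c(rate = k, se = se)
}

# Least-squares fit of an exponential to the 1-frame-binned dwell histogram
# (first bin excluded: dwells of a single frame are undercounted).
.fit_state_rate_ls <- function(frames, frame_time) {
  tab <- table(frames)
  m <- as.integer(names(tab))
  cnt <- as.numeric(tab)
  keep <- m > 1L
  if (sum(keep) < 3) stop("too few histogram bins for the least-squares mode")
  m <- m[keep]; cnt <- cnt[keep]
  # log-linear start, then least squares on the raw counts (a log-scale
  # fit is biased by the low-count tail bins)
  start <- stats::coef(stats::lm(log(cnt) ~ m, weights = cnt))
  fit <- stats::nls(cnt ~ exp(a + b * m),
                    start = list(a = start[[1]], b = start[[2]]))
  k <- -unname(stats::coef(fit)["b"]) / frame_time
  se <- unname(sqrt(stats::vcov(fit)["b", "b"])) / frame_time
  c(rate = k, se = se)
}

#' Estimate opening and closing rates from dwell times
#'
#' Exponential-dwell rate estimation by maximum likelihood on frame counts
#' (geometric likelihood, which corrects for the discreteness of the frame
#' clock), or by least squares on the 1-frame-binned dwell histogram for
#' parity with histogram-fitting workflows. Censored dwells are excluded.
#' The opening rate comes from closed-state dwells and vice versa.
#'
#' @param dwells a `dwell_set` (typically pooled over molecules).
#' @param method `"mle"` (default) or `"ls"`.
#' @param min_dwells minimum number of uncensored dwells per state
#'   (default 20).
#' @return An object of class `rate_estimates`: `k_open`, `k_close` (s^-1),
#'   `se_open`, `se_close`, `n_transitions`, `n_molecules`.
#' @export
fit_dwell_times <- function(dwells, method = c("mle", "ls"),
                            min_dwells = 20L) {
  stopifnot(inherits(dwells, "dwell_set"))
  method <- match.arg(method)
  oc <- dwells$open[!dwells$open$censored, ]
  cc <- dwells$closed[!dwells$closed$censored, ]
  if (nrow(cc) < min_dwells)
    stop("too few uncensored dwells in the closed state (",
         nrow(cc), " < ", min_dwells, ")")
  if (nrow(oc) < min_dwells)
    stop("too few uncensored dwells in the open state (",
         nrow(oc), " < ", min_dwells, ")")
  if (method == "mle") {
    disc <- isTRUE(dwells$discretized)
    kc <- .fit_state_rate(cc, dwells$frame_time, disc)  # opening rate
    ko <- .fit_state_rate(oc, dwells$frame_time, disc)  # closing rate
  } else {
    kc <- .fit_state_rate_ls(cc$frames, dwells$frame_time)
    ko <- .fit_state_rate_ls(oc$frames, dwells$frame_time)
  }
  structure(list(k_open = unname(kc["rate"]), se_open = unname(kc["se"]),
                 k_close = unname(ko["rate"]), se_close = unname(ko["se"]),
                 n_transitions = nrow(oc) + nrow(cc),
                 n_molecules = if (!is.null(dwells$n_molecules))
                   dwells$n_molecules else 1L,
                 method = method),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("two-state rates (%s, %d transitions, %d molecules):\n",
              x$method, x$n_transitions, x$n_molecules))
  cat(sprintf("  k_open  = %.3f +/- %.3f s^-1\n", x$k_open, x$se_open))
  cat(sprintf("  k_close = %.3f +/- %.3f s^-1\n", x$k_close, x$se_close))
  invisible(x)
}

#' @export
coef.rate_estimates <- function(object, ...) {
  c(k_open = object$k_open, k_close = object$k_close)
}

#' Fluorescence enhancement factor of the closed state
#'
#' Ratio of background-subtracted state-conditional mean intensities
#' (closed/open). Frames at the boundaries of each dwell are excluded by
#' default because they mix occupancy of both states within the frame. The
#' standard error is propagated from the standard errors of the two state
#' means.
#'
#' @param trace an `intensity_trace`.
#' @param seg its `state_segmentation`.
#' @param background mean background counts/frame to subtract (default 0).
#' @param trim_boundary drop the first and last frame of every dwell
#'   (default `TRUE`).
#' @return A list with `enhancement`, `se`, and the two level means.
#' @export
enhancement_factor <- function(trace, seg, background = 0,
                               trim_boundary = TRUE) {
  stopifnot(inherits(trace, "intensity_trace"),
            inherits(seg, "state_segmentation"))
  st <- seg$states
  x <- as.numeric(trace$intensities)
  ok <- !is.na(st)
  if (trim_boundary && !seg$no_transitions) {
    r <- rle(as.character(st[ok]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    drop <- unique(c(starts, ends))
    idx <- which(ok)
    ok[idx[drop]] <- FALSE
  }
  xo <- x[ok & st == "open"] - background
  xc <- x[ok & st == "closed"] - background
  if (!length(xo) || !length(xc))
    stop("both states must be populated to compute an enhancement factor")
  mo <- mean(xo); mc <- mean(xc)
  if (mo <= 0)
    stop("open-state mean does not exceed the background")
  seo <- stats::sd(xo) / sqrt(length(xo))
  sec <- stats::sd(xc) / sqrt(length(xc))
  if (!is.finite(seo)) seo <- 0
  if (!is.finite(sec)) sec <- 0
  r <- mc / mo
  list(enhancement = r, se = r * sqrt((seo / mo)^2 + (sec / mc)^2),
       open_mean = mo, closed_mean = mc)
}
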