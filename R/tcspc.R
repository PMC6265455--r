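# Reconvolution machinery. Expected decays are the circular convolution of
# the normalized IRF with a multi-exponential kernel over the repetition
# window; the wrap-around accounts for incomplete decay between pulses.

# Cached-FFT convolution closure for one IRF grid. Fractional IRF shift is a
# linear interpolation of the IRF, applied exactly in the Fourier domain.
.make_reconv <- function(irf) {
  n <- length(irf$counts)
  cw <- irf$channel_width
  irf_fft <- stats::fft(irf$counts / sum(irf$counts))
  omega <- 2 * pi * (seq_len(n) - 1) / n
  t0 <- (seq_len(n) - 1) * cw
  function(lifetimes, scales, irf_shift = 0) {
    kern <- rowSums(vapply(seq_along(lifetimes), function(i) {
      scales[i] * exp(-t0 / lifetimes[i])
    }, numeric(n)))
    s <- irf_shift / cw
    k <- floor(s); f <- s - k
    shift_filt <- ((1 - f) + f * exp(-1i * omega)) * exp(-1i * omega * k)
    out <- Re(stats::fft(irf_fft * shift_filt * stats::fft(kern),
                         inverse = TRUE)) / n
    pmax(out, 0)
  }
}

# Expected-curve helper used by the simulator (normalized amplitudes).
reconv_curve <- function(irf, lifetimes, amplitudes, irf_shift = 0) {
  .make_reconv(irf)(lifetimes, amplitudes, irf_shift)
}

#' Expected decay curve of a multi-exponential model
#'
#' Circular (wrap-around) convolution of the normalized IRF with
#' `sum_i a_i exp(-t/tau_i)` over the repetition window, shifted by
#' `irf_shift`, plus a constant background. Total signal counts are
#' preserved by the convolution because the IRF is normalized to unit sum.
#'
#' @param irf a [decay_histogram()] holding the IRF.
#' @param lifetimes component lifetimes in ns.
#' @param amplitudes per-component pre-exponential amplitudes, in expected
#'   counts per channel at t = 0.
#' @param background expected background counts per channel.
#' @param irf_shift IRF shift in ns (fractional channels allowed).
#' @return numeric vector of expected counts per channel.
#' @export
convolve_model <- function(irf, lifetimes, amplitudes, background = 0,
                           irf_shift = 0) {
  stopifnot(inherits(irf, "decay_histogram"))
  if (length(lifetimes) != length(amplitudes))
    stop("lifetimes and amplitudes must have equal length")
  reconv_curve(irf, lifetimes, amplitudes, irf_shift) + background
}

# Default fit range: 10 channels before the IRF peak to the last channel
# with counts >= max(estimated background, 5).
.default_fit_range <- function(decay, irf) {
  pk <- which.max(irf$counts)
  lo <- max(1L, pk - 10L)
  bg0 <- if (lo > 30L) mean(decay$counts[seq_len(lo - 20L)]) else 0
  thr <- max(5, bg0)
  hi <- max(which(decay$counts >= thr))
  if (hi <= lo) stop("decay has no channels above threshold after the IRF")
  c(lo, hi)
}

.weighted_resid <- function(y, mu, weighting) {
  if (weighting == "neyman") {
    (mu - y) / sqrt(pmax(y, 1))
  } else { # Poisson-MLE via signed deviance residuals
    mu <- pmax(mu, 1e-9)
    d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
    sign(y - mu) * sqrt(pmax(d, 0))
  }
}

#' Fit a decay histogram by iterative reconvolution
#'
#' Fits `sum_i a_i exp(-t/tau_i)` convolved with the measured IRF (plus a
#' constant background and a fractional-channel IRF shift) to a TCSPC decay
#' by weighted least squares, using Levenberg-Marquardt with multi-start
#' initialization over log-spaced lifetime ladders. The default Neyman
#' weighting (1/max(counts, 1)) reproduces the chi-square convention of
#' standard TCSPC analysis software; Poisson maximum likelihood is available
#' for low-count data.
#'
#' @param decay a [decay_histogram()] of kind `"decay"`.
#' @param irf a [decay_histogram()] of the IRF, same channel grid.
#' @param n_components number of exponential components (1 to 4).
#' @param init optional list with starting values: `lifetimes` (ns), and
#'   optionally `background` and `irf_shift`. Used as the first start.
#' @param weighting `"neyman"` (default) or `"mle"`.
#' @param fit_range integer `c(first, last)` channel of the fitted window;
#'   default per the rule described above.
#' @param n_starts number of multi-start initializations (default 5).
#'
#' @return An object of class `decay_fit` with components sorted by
#'   descending lifetime: `lifetimes` (ns), `amplitudes` (normalized
#'   fractional amplitudes), `scales` (absolute pre-exponential counts),
#'   `background`, `irf_shift` (ns), `chi2_reduced`, `residuals` (weighted,
#'   over `fit_range`), `fit_range`, `covariance` and `se` (on the natural
#'   scale), plus a `collapsed` flag when two lifetimes differ by less than
#'   a factor 1.2.
#' @examples
#' cfg <- instrument_config(n_channels = 4096)
#' irf <- simulate_irf(cfg, seed = 1)
#' dec <- simulate_decay(photophysics_model(2, 1), cfg, irf, seed = 2)
#' fit <- fit_reconvolution(dec, irf, n_components = 1)
#' coef(fit)
#' @export
fit_reconvolution <- function(decay, irf, n_components, init = NULL,
                              weighting = c("neyman", "mle"),
                              fit_range = NULL, n_starts = 5) {
  stopifnot(inherits(decay, "decay_histogram"),
            inherits(irf, "decay_histogram"))
  weighting <- match.arg(weighting)
  n <- as.integer(n_components)
  if (n < 1L || n > 4L) stop("n_components must be between 1 and 4")
  if (length(decay$counts) != length(irf$counts) ||
      abs(decay$channel_width - irf$channel_width) > 1e-12)
    stop("decay and IRF are on different channel grids")
  if (is.null(fit_range)) fit_range <- .default_fit_range(decay, irf)
  rng <- seq.int(fit_range[1], fit_range[2])
  if (sum(decay$counts[rng] > 0) < 10 * (2 * n + 2))
    stop("too few non-empty channels in the fit range for ", n, " components")

  y <- decay$counts
  yr <- y[rng]
  cw <- decay$channel_width
  window <- length(y) * cw
  reconv <- .make_reconv(irf)
  p_free <- 2L * n + 2L

  resid_fun <- function(par) {
    tau <- exp(par[seq_len(n)])
    a <- exp(par[n + seq_len(n)])
    bg <- par[2 * n + 1]
    shift <- par[2 * n + 2]
    mu <- reconv(tau, a, shift) + bg
    .weighted_resid(yr, mu[rng], weighting)
  }

  # linear LS amplitudes for a given lifetime ladder
  amp_init <- function(tau, shift = 0) {
    B <- vapply(tau, function(tt) reconv(tt, 1, shift)[rng], numeric(length(rng)))
    X <- cbind(B, 1)
    w <- 1 / pmax(yr, 1)
    cf <- tryCatch(stats::lm.wfit(X, yr, w)$coefficients,
                   error = function(e) rep(NA_real_, n + 1))
    cf[!is.finite(cf)] <- 0
    list(a = pmax(cf[seq_len(n)], max(yr) * 1e-4),
         bg = max(cf[n + 1], 0))
  }

  lo_tau <- max(2 * cw, 0.02)
  hi_tau <- window / 3
  ladders <- list(c(lo_tau * 2, hi_tau / 4),
                  c(lo_tau * 5, hi_tau / 10),
                  c(lo_tau * 2, hi_tau),
                  c(lo_tau * 10, hi_tau / 3),
                  c(lo_tau * 4, hi_tau / 20))
  starts <- lapply(seq_len(n_starts), function(s) {
    rngl <- ladders[[(s - 1) %% length(ladders) + 1]]
    if (n == 1) sqrt(rngl[1] * rngl[2])
    else exp(seq(log(rngl[1]), log(rngl[2]), length.out = n))
  })
  if (!is.null(init)) starts <- c(list(sort(init$lifetimes)), starts)
  starts <- starts[seq_len(if (is.null(init)) n_starts else n_starts + 1L)]

  best <- NULL
  diagnostics <- character(0)
  for (tau0 in starts) {
    sh0 <- if (!is.null(init$irf_shift)) init$irf_shift else 0
    ai <- amp_init(tau0, sh0)
    bg0 <- if (!is.null(init$background)) init$background else ai$bg
    par0 <- c(log(tau0), log(ai$a), bg0, sh0)
    # nls.lm warns when it stops at maxiter; that case is handled below
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par0, fn = resid_fun,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, maxfev = 3000,
                             ptol = 1e-12, ftol = 1e-12))),
      error = function(e) e)
    if (inherits(res, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(res))
      next
    }
    # info 1-4: formal convergence; -1/5: iteration budget reached, still a
    # usable candidate (common on noiseless data where ftol is unreachable)
    if (!res$info %in% c(-1, 1, 2, 3, 4, 5) ||
        !is.finite(res$deviance)) {
      diagnostics <- c(diagnostics, res$message)
      next
    }
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("reconvolution fit did not converge from any start: ",
         paste(unique(diagnostics), collapse = "; "))

  par <- unname(best$par)
  tau <- exp(par[seq_len(n)])
  a <- exp(par[n + seq_len(n)])
  bg <- par[2 * n + 1]
  shift <- par[2 * n + 2]
  o <- order(tau, decreasing = TRUE)
  tau <- tau[o]; a <- a[o]

  mu <- reconv(tau, a, shift) + bg
  wres <- .weighted_resid(yr, mu[rng], weighting)
  chi2_red <- sum(wres^2) / (length(rng) - p_free)

  # covariance on the natural scale via the delta method for log parameters
  cov_nat <- se <- NULL
  cov_tr <- tryCatch(solve(best$hessian) * max(chi2_red, 1e-12),
                     error = function(e) NULL)
  if (!is.null(cov_tr)) {
    perm <- c(order(exp(best$par[seq_len(n)]), decreasing = TRUE),
              n + order(exp(best$par[seq_len(n)]), decreasing = TRUE),
              2 * n + 1, 2 * n + 2)
    cov_tr <- cov_tr[perm, perm, drop = FALSE]
    g <- c(tau, a, 1, 1)
    cov_nat <- cov_tr * tcrossprod(g)
    se <- sqrt(pmax(diag(cov_nat), 0))
    names(se) <- c(paste0("tau", seq_len(n)), paste0("a", seq_len(n)),
                   "background", "irf_shift")
  }

  collapsed <- n > 1 && any(tau[-n] / tau[-1] < 1.2)
  if (collapsed)
    warning("fitted lifetimes differ by less than a factor 1.2 ",
            "(collapsed components)")

  structure(list(lifetimes = tau, amplitudes = a / sum(a), scales = a,
                 background = bg, irf_shift = shift,
                 chi2_reduced = chi2_red, residuals = wres,
                 fit_range = fit_range, covariance = cov_nat, se = se,
                 n_components = n, weighting = weighting,
                 fitted_counts = mu, decay = decay, irf = irf,
                 collapsed = collapsed, info = best$info,
                 niter = best$niter),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("%d-exponential reconvolution fit (%s weighting)\n",
              x$n_components, x$weighting))
  tab <- data.frame(tau_ns = round(x$lifetimes, 4),
                    alpha = round(x$amplitudes, 4),
                    f_intensity = round(fractional_intensities(x), 4))
  print(tab, row.names = paste0("  comp", seq_len(x$n_components)))
  cat(sprintf("  <tau> = %.4f ns, tau_bar = %.4f ns, chi2_red = %.3f\n",
              amplitude_weighted_lifetime(x), intensity_weighted_lifetime(x),
              x$chi2_reduced))
  if (x$collapsed) cat("  warning: collapsed components\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  n <- object$n_components
  c(stats::setNames(object$lifetimes, paste0("tau", seq_len(n))),
    stats::setNames(object$amplitudes, paste0("alpha", seq_len(n))),
    background = object$background, irf_shift = object$irf_shift)
}

#' @export
fitted.decay_fit <- function(object, ...) object$fitted_counts

#' @export
residuals.decay_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  rng <- seq.int(object$fit_range[1], object$fit_range[2])
  if (type == "weighted") object$residuals
  else object$decay$counts[rng] - object$fitted_counts[rng]
}

#' @export
predict.decay_fit <- function(object, irf = NULL, ...) {
  if (is.null(irf)) return(object$fitted_counts)
  convolve_model(irf, object$lifetimes, object$scales,
                 object$background, object$irf_shift)
}

#' @export
summary.decay_fit <- function(object, ...) {
  gof <- goodness_of_fit(object)
  structure(list(fit = object,
                 table = data.frame(
                   tau_ns = object$lifetimes,
                   alpha = object$amplitudes,
                   f_intensity = fractional_intensities(object)),
                 tau_amp = amplitude_weighted_lifetime(object),
                 tau_int = intensity_weighted_lifetime(object),
                 chi2_reduced = gof$chi2_reduced,
                 residual_randomness_p = gof$residual_randomness_p),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  runs-test p for residual randomness: %.3g\n",
              x$residual_randomness_p))
  invisible(x)
}

#' @export
plot.decay_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  rng <- seq.int(x$fit_range[1], x$fit_range[2])
  t <- channel_times(x$decay)[rng]
  graphics::plot(t, pmax(x$decay$counts[rng], 0.5), log = "y", pch = ".",
                 xlab = "", ylab = "counts", ...)
  graphics::lines(t, pmax(x$fitted_counts[rng], 0.5), col = 2)
  graphics::plot(t, x$residuals, type = "h", xlab = "time (ns)",
                 ylab = "weighted residual")
  graphics::abline(h = 0, col = 2)
  invisible(x)
}

#' Simulate decays from a fitted model
#'
#' Draws Poisson replicates of the fitted expected curve, for parametric-
#' bootstrap style checks.
#'
#' @param object a `decay_fit`.
#' @param nsim number of replicate histograms.
#' @param seed integer seed or `NULL`.
#' @param ... unused.
#' @return A list of [decay_histogram()] objects.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted_counts
  lapply(seq_len(nsim), function(i) {
    decay_histogram(stats::rpois(length(mu), mu), object$decay$channel_width,
                    kind = "decay",
                    metadata = list(
                      channel_width_ps = object$decay$channel_width * 1e3,
                      simulated_from = "decay_fit"))
  })
}
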