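# Position-profile analysis: aggregate per-decay lifetime summaries by
# abasic position, fit the damped-cosine modulation, and quantify the
# exchange between stacked and unstacked components.

#' Fit every decay of a profile dataset
#'
#' Runs tri-exponential reconvolution on each simulated decay of a
#' `profile_dataset` (decays mode) and attaches the lifetime summaries to
#' the dataset table.
#'
#' @param dataset a `profile_dataset` from [simulate_position_profile()] in
#'   `"decays"` mode.
#' @param n_components components per fit (default 3).
#' @param n_starts multi-start count per fit; the default 2 keeps the
#'   per-decay cost low and is sufficient because every decay shares the
#'   same instrument settings.
#' @param init optional initial lifetime ladder passed to
#'   [fit_reconvolution()]; default log-spaced 0.2-3 ns.
#' @return The dataset with metric columns (`tau_amp`, `tau_int`, `f_long`,
#'   `f_mid`, `f_short`) filled in.
#' @export
fit_decays <- function(dataset, n_components = 3, n_starts = 2,
                       init = list(lifetimes = c(0.2, 0.8, 3.0))) {
  stopifnot(inherits(dataset, "profile_dataset"))
  if (dataset$mode != "decays")
    stop("dataset already carries summary metrics")
  res <- lapply(dataset$decays, function(d) {
    fit <- suppressWarnings(
      fit_reconvolution(d, dataset$irf, n_components, init = init,
                        n_starts = n_starts))
    c(tau_amp = amplitude_weighted_lifetime(fit),
      tau_int = intensity_weighted_lifetime(fit),
      f = fractional_intensities(fit))
  })
  res <- do.call(rbind, res)
  dataset$table$tau_amp <- res[, 1]
  dataset$table$tau_int <- res[, 2]
  dataset$table$f_long <- res[, 3]
  dataset$table$f_mid <- res[, 4]
  dataset$table$f_short <- res[, 5]
  dataset$mode <- "summary"
  dataset
}

#' Aggregate per-decay summaries into a position profile
#'
#' Per-position mean and standard error of the mean (SEM) of each lifetime
#' metric, over the decay-level replicates. Rows with `position = NA` are
#' the fully complementary control construct and are aggregated separately.
#' The decay-level table is kept for replicate bootstraps.
#'
#' @param dataset a `profile_dataset` whose table carries metric columns
#'   (from [fit_decays()] or summary-mode simulation), or a data.frame with
#'   columns position, experiment, replicate and the metrics.
#' @param min_replicates positions with fewer replicates are dropped with a
#'   warning (default 2).
#' @return An object of class `position_profile`: `stats` (position, n, and
#'   mean/sem per metric), `control` (same for the control rows), `data`
#'   (decay-level rows).
#' @export
summarize_profile <- function(dataset, min_replicates = 2L) {
  tab <- if (inherits(dataset, "profile_dataset")) dataset$table else dataset
  metrics <- intersect(c("tau_amp", "tau_int", "f_long", "f_mid", "f_short"),
                       names(tab))
  if (!length(metrics))
    stop("no metric columns; run fit_decays() first")
  agg <- function(rows) {
    out <- list(n = nrow(rows))
    for (mname in metrics) {
      v <- rows[[mname]]
      out[[paste0(mname, "_mean")]] <- mean(v)
      out[[paste0(mname, "_sem")]] <- stats::sd(v) / sqrt(length(v))
    }
    as.data.frame(out)
  }
  is_ctrl <- is.na(tab$position)
  pos_tab <- tab[!is_ctrl, , drop = FALSE]
  counts <- table(pos_tab$position)
  bad <- as.numeric(names(counts))[counts < min_replicates]
  if (length(bad)) {
    warning("dropping positions with fewer than ", min_replicates,
            " replicates: ", paste(bad, collapse = ", "))
    pos_tab <- pos_tab[!pos_tab$position %in% bad, , drop = FALSE]
  }
  stats_df <- do.call(rbind, lapply(split(pos_tab, pos_tab$position), agg))
  stats_df <- cbind(position = as.numeric(rownames(stats_df)), stats_df)
  rownames(stats_df) <- NULL
  stats_df <- stats_df[order(stats_df$position), ]
  control <- if (any(is_ctrl)) agg(tab[is_ctrl, , drop = FALSE]) else NULL
  structure(list(stats = stats_df, control = control,
                 data = tab, metrics = metrics),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, digits = 4, ...) {
  cat(sprintf("lifetime profile over %d abasic positions (%d decays each)\n",
              nrow(x$stats), x$stats$n[1]))
  print(format(x$stats, digits = digits), row.names = FALSE)
  if (!is.null(x$control))
    cat(sprintf("control: <tau> = %.4g +/- %.4g ns (n = %d)\n",
                x$control$tau_amp_mean, x$control$tau_amp_sem, x$control$n))
  invisible(x)
}

#' @export
plot.position_profile <- function(x, metric = "tau_amp", ...) {
  s <- x$stats
  m <- s[[paste0(metric, "_mean")]]
  e <- s[[paste0(metric, "_sem")]]
  graphics::plot(s$position, m, ylim = range(m - e, m + e), pch = 19,
                 xlab = "abasic position (bp from nick)", ylab = metric, ...)
  graphics::arrows(s$position, m - e, s$position, m + e, angle = 90,
                   code = 3, length = 0.03)
  if (!is.null(x$control)) {
    cm <- x$control[[paste0(metric, "_mean")]]
    ce <- x$control[[paste0(metric, "_sem")]]
    graphics::rect(graphics::par("usr")[1], cm - ce,
                   graphics::par("usr")[2], cm + ce,
                   col = grDevices::adjustcolor("pink", 0.5), border = NA)
    graphics::abline(h = cm, col = "red3", lty = 2)
  }
  invisible(x)
}

# weighted LS of baseline + A cos(2 pi (x - x0)/P) exp(-x/lambda) for fixed
# (P, lambda): linear in (baseline, B, C) via the cos/sin expansion
.wls_periodic <- function(x, y, w, period, lambda) {
  damp <- exp(-x / lambda)
  X <- cbind(1, cos(2 * pi * x / period) * damp,
             sin(2 * pi * x / period) * damp)
  fit <- stats::lm.wfit(X, y, w)
  cf <- fit$coefficients
  list(rss = sum(w * fit$residuals^2), coef = cf, X = X)
}

.periodic_point_fit <- function(x, y, w, period_grid, lambda_grid) {
  best <- NULL
  for (P in period_grid) for (lam in lambda_grid) {
    f <- .wls_periodic(x, y, w, P, lam)
    if (is.null(best) || f$rss < best$rss) {
      best <- f; best$period <- P; best$lambda <- lam
    }
  }
  # local refinement of (P, log lambda)
  obj <- function(par) .wls_periodic(x, y, w, par[1], exp(par[2]))$rss
  opt <- stats::optim(c(best$period, log(best$lambda)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  P <- opt$par[1]; lam <- exp(opt$par[2])
  f <- .wls_periodic(x, y, w, P, lam)
  B <- f$coef[2]; C <- f$coef[3]
  x0 <- (atan2(C, B) * P / (2 * pi)) %% P
  list(period = P, lambda = lam, baseline = unname(f$coef[1]),
       amplitude = unname(sqrt(B^2 + C^2)), phase = unname(x0), rss = f$rss,
       coef = f$coef, X = f$X)
}

#' Fit the damped-cosine position modulation
#'
#' Weighted least squares of
#' `tau(x) = baseline + A cos(2 pi (x - x0)/P) exp(-x/lambda)` to the
#' per-position means (weights 1/SEM^2), with a period grid search followed
#' by local refinement, and a bootstrap confidence interval on the period
#' that resamples experiments and decays within experiments. Near-nick
#' positions (direct stacking into the abasic site, a different mechanism)
#' are excluded below `exclude_below`.
#'
#' @param profile a `position_profile`.
#' @param metric which metric to fit (default `"tau_amp"`).
#' @param exclude_below smallest position retained in bp (default 6).
#' @param period_grid candidate periods in bp (default 6-16 by 0.1).
#' @param lambda_grid candidate damping lengths in bp.
#' @param n_boot bootstrap replicates (default 199; 0 disables).
#' @param conf confidence level (default 0.95).
#' @param seed seed for the bootstrap.
#' @return An object of class `period_fit`: `period` (bp), `amplitude`,
#'   `phase` (bp position of a maximum), `baseline`, `damping_length`,
#'   `residual_rms`, `period_ci`, `amplitude_se` and the flag
#'   `no_significant_modulation` (amplitude < 2 SE).
#' @export
fit_periodic_model <- function(profile, metric = "tau_amp",
                               exclude_below = 6,
                               period_grid = seq(6, 16, by = 0.1),
                               lambda_grid = c(10, 20, 40, 80, 1e6),
                               n_boot = 199, conf = 0.95, seed = NULL) {
  stopifnot(inherits(profile, "position_profile"))
  s <- profile$stats[profile$stats$position >= exclude_below, ]
  if (nrow(s) < 6)
    stop("need at least 6 positions beyond the excluded near-field")
  x <- s$position
  y <- s[[paste0(metric, "_mean")]]
  sem <- s[[paste0(metric, "_sem")]]
  w <- if (any(sem <= 0)) rep(1, length(x)) else 1 / sem^2

  fit <- .periodic_point_fit(x, y, w, period_grid, lambda_grid)

  # amplitude SE from the WLS covariance of (B, C) at the optimum
  dof <- max(length(x) - 5, 1)
  sigma2 <- fit$rss / dof
  XtWX <- crossprod(fit$X * sqrt(w))
  amp_se <- tryCatch({
    V <- solve(XtWX) * sigma2
    B <- fit$coef[2]; C <- fit$coef[3]; a <- fit$amplitude
    if (a > 0) sqrt((B / a)^2 * V[2, 2] + (C / a)^2 * V[3, 3] +
                      2 * (B / a) * (C / a) * V[2, 3]) else sqrt(V[2, 2])
  }, error = function(e) NA_real_)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    dat <- profile$data[!is.na(profile$data$position), ]
    dat <- dat[dat$position >= exclude_below, ]
    exps <- unique(dat$experiment)
    boot_p <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(exps, length(exps), replace = TRUE)
      res <- do.call(rbind, lapply(pick, function(e) {
        rows <- dat[dat$experiment == e, ]
        do.call(rbind, lapply(split(rows, rows$position), function(g) {
          g[sample(nrow(g), replace = TRUE), ]
        }))
      }))
      bs <- summarize_profile(res, min_replicates = 1L)$stats
      xb <- bs$position
      yb <- bs[[paste0(metric, "_mean")]]
      sb <- bs[[paste0(metric, "_sem")]]
      wb <- if (any(sb <= 0)) rep(1, length(xb)) else 1 / sb^2
      .periodic_point_fit(xb, yb, wb, period_grid, lambda_grid)$period
    }, numeric(1))
    al <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot_p, c(al, 1 - al), na.rm = TRUE))
  }

  structure(list(period = fit$period, amplitude = fit$amplitude,
                 phase = fit$phase, baseline = fit$baseline,
                 damping_length = fit$lambda,
                 residual_rms = sqrt(fit$rss / length(x)),
                 period_ci = ci, amplitude_se = amp_se,
                 no_significant_modulation = is.finite(amp_se) &&
                   fit$amplitude <= 2 * amp_se + 1e-9,
                 metric = metric, exclude_below = exclude_below,
                 x = x, y = y, w = w, n_boot = n_boot, conf = conf),
            class = "period_fit")
}

#' @export
print.period_fit <- function(x, ...) {
  cat(sprintf("damped-cosine fit to %s: period %.2f bp", x$metric, x$period))
  if (all(is.finite(x$period_ci)))
    cat(sprintf(" (%d%% CI %.2f-%.2f)", round(100 * x$conf),
                x$period_ci[1], x$period_ci[2]))
  cat("\n")
  cat(sprintf("  amplitude %.4g +/- %.4g, maximum at %.1f bp, baseline %.4g, damping %.3g bp\n",
              x$amplitude, x$amplitude_se, x$phase, x$baseline,
              x$damping_length))
  if (x$no_significant_modulation)
    cat("  no significant modulation (amplitude < 2 SE)\n")
  invisible(x)
}

#' @export
coef.period_fit <- function(object, ...) {
  c(period = object$period, amplitude = object$amplitude,
    phase = object$phase, baseline = object$baseline,
    damping_length = object$damping_length)
}

#' @export
predict.period_fit <- function(object, x = object$x, ...) {
  object$baseline + object$amplitude *
    cos(2 * pi * (x - object$phase) / object$period) *
    exp(-x / object$damping_length)
}

#' @export
plot.period_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 19,
                 xlab = "abasic position (bp from nick)", ylab = x$metric,
                 ...)
  xf <- seq(min(x$x), max(x$x), length.out = 300)
  graphics::lines(xf, predict(x, xf), col = 2)
  invisible(x)
}

#' Nonparametric periodogram of the position profile
#'
#' Lomb-Scargle style least-squares periodogram on the de-trended
#' per-position means: for each candidate period the fractional reduction
#' in weighted residual variance of a plain (undamped) cosine fit.
#' Cross-check for the parametric damped-cosine fit.
#'
#' @inheritParams fit_periodic_model
#' @return data.frame with `period` and `power`; the attribute
#'   `peak_period` holds the argmax.
#' @export
profile_periodogram <- function(profile, metric = "tau_amp",
                                exclude_below = 6,
                                period_grid = seq(6, 16, by = 0.1)) {
  stopifnot(inherits(profile, "position_profile"))
  s <- profile$stats[profile$stats$position >= exclude_below, ]
  x <- s$position
  y <- s[[paste0(metric, "_mean")]]
  sem <- s[[paste0(metric, "_sem")]]
  w <- if (any(sem <= 0)) rep(1, length(x)) else 1 / sem^2
  rss0 <- sum(w * (y - stats::weighted.mean(y, w))^2)
  pw <- vapply(period_grid, function(P) {
    1 - .wls_periodic(x, y, w, P, 1e6)$rss / rss0
  }, numeric(1))
  out <- data.frame(period = period_grid, power = pw)
  attr(out, "peak_period") <- period_grid[which.max(pw)]
  out
}

#' Peak position and control-baseline crossings
#'
#' The position of the fitted modulation maximum beyond the near-field
#' window, and the positions where the measured profile crosses the control
#' baseline (sign changes of profile minus control, linearly interpolated).
#'
#' @param profile a `position_profile` (control required for crossings).
#' @param fit optional `period_fit`; computed from `profile` if missing.
#' @param metric metric name (default `"tau_amp"`).
#' @param exclude_below near-field exclusion in bp (default 6).
#' @return A list with `peak` (bp), `crossings` (bp vector) and
#'   `all_equal` flag (profile indistinguishable from control everywhere).
#' @export
peak_and_crossings <- function(profile, fit = NULL, metric = "tau_amp",
                               exclude_below = 6) {
  stopifnot(inherits(profile, "position_profile"))
  if (is.null(fit))
    fit <- fit_periodic_model(profile, metric = metric,
                              exclude_below = exclude_below, n_boot = 0)
  xf <- seq(exclude_below, max(profile$stats$position), by = 0.01)
  peak <- xf[which.max(predict(fit, xf))]

  crossings <- numeric(0)
  all_equal <- FALSE
  if (!is.null(profile$control)) {
    s <- profile$stats
    d <- s[[paste0(metric, "_mean")]] -
      profile$control[[paste0(metric, "_mean")]]
    if (all(abs(d) < 1e-10)) {
      all_equal <- TRUE
    } else {
      sgn <- sign(d)
      for (i in seq_len(length(d) - 1)) {
        if (sgn[i] != sgn[i + 1] && sgn[i] != 0) {
          x1 <- s$position[i]; x2 <- s$position[i + 1]
          crossings <- c(crossings,
                         x1 + (0 - d[i]) / (d[i + 1] - d[i]) * (x2 - x1))
        }
      }
    }
  }
  list(peak = peak, crossings = crossings, all_equal = all_equal)
}

#' Anticorrelation of short and long fractional intensities
#'
#' Pearson correlation between the per-position mean fractional intensities
#' of the short (unstacked) and long (stacked) components, with a replicate
#' bootstrap CI, computed separately for the near-field (positions <=
#' `boundary`) and far-field windows. Exchange of amplitude between the
#' stacked and unstacked conformations shows up as strongly negative
#' correlation.
#'
#' @param profile a `position_profile` with `f_short` and `f_long` columns.
#' @param window `"far"` (default), `"near"` or `"all"`.
#' @param boundary near/far split position in bp (default 5).
#' @param n_boot bootstrap replicates (default 199).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return A list with `r`, `ci`, `window`, `n_positions`.
#' @export
component_anticorrelation <- function(profile, window = c("far", "near",
                                                          "all"),
                                      boundary = 5, n_boot = 199,
                                      conf = 0.95, seed = NULL) {
  stopifnot(inherits(profile, "position_profile"))
  window <- match.arg(window)
  pick_rows <- function(s) switch(window,
    far = s[s$position > boundary, , drop = FALSE],
    near = s[s$position <= boundary, , drop = FALSE],
    all = s)
  s <- pick_rows(profile$stats)
  if (nrow(s) < 5)
    stop("need at least 5 positions in the ", window, " window")
  fs <- s$f_short_mean; fl <- s$f_long_mean
  if (stats::sd(fs) == 0 || stats::sd(fl) == 0)
    stop("zero variance in a component: correlation undefined")
  r <- stats::cor(fs, fl)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    dat <- profile$data[!is.na(profile$data$position), ]
    exps <- unique(dat$experiment)
    boot_r <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(exps, length(exps), replace = TRUE)
      res <- do.call(rbind, lapply(pick, function(e) {
        rows <- dat[dat$experiment == e, ]
        do.call(rbind, lapply(split(rows, rows$position), function(g) {
          g[sample(nrow(g), replace = TRUE), ]
        }))
      }))
      sb <- pick_rows(summarize_profile(res, min_replicates = 1L)$stats)
      if (stats::sd(sb$f_short_mean) == 0 ||
          stats::sd(sb$f_long_mean) == 0) return(NA_real_)
      stats::cor(sb$f_short_mean, sb$f_long_mean)
    }, numeric(1))
    al <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot_r, c(al, 1 - al), na.rm = TRUE))
  }
  list(r = r, ci = ci, window = window, n_positions = nrow(s))
}
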