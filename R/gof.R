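# Fit acceptance follows the usual TCSPC practice: reduced chi-square close
# to 1 and residuals randomly distributed around zero (Wald-Wolfowitz runs
# test on the signs of the weighted residuals).

# Two-sided runs test on the signs of x (normal approximation).
.runs_test_p <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(0)
  z <- (runs - mu) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

#' Goodness of fit of a reconvolution fit
#'
#' Reduced chi-square over the fit range (chi-square divided by channels
#' minus free parameters) and a runs-test p-value for the randomness of the
#' weighted residuals around zero. A good fit has chi2_reduced close to 1
#' and a non-small runs p-value.
#'
#' @param fit a `decay_fit` from [fit_reconvolution()].
#' @return A list with `chi2_reduced` and `residual_randomness_p`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  n_range <- fit$fit_range[2] - fit$fit_range[1] + 1L
  p_free <- 2L * fit$n_components + 2L
  if (n_range < 2L * p_free)
    stop("fit range shorter than twice the number of free parameters")
  list(chi2_reduced = fit$chi2_reduced,
       residual_randomness_p = .runs_test_p(fit$residuals))
}

#' Choose the number of decay components
#'
#' Fits 1..`max_n` components and returns the smallest number whose fit has
#' reduced chi-square within `1 +/- delta` and residuals that pass the runs
#' test at level `alpha`. If none passes, the best-chi-square model is
#' returned with attribute `fallback = TRUE`.
#'
#' @param decay,irf as in [fit_reconvolution()].
#' @param max_n largest model considered (default 4).
#' @param delta half-width of the accepted chi2_reduced band (default 0.2).
#' @param alpha runs-test level (default 0.01).
#' @param ... passed to [fit_reconvolution()].
#' @return integer number of components, with attributes `fits` (the fitted
#'   models, indexed by n) and `fallback`.
#' @export
select_n_components <- function(decay, irf, max_n = 4, delta = 0.2,
                                alpha = 0.01, ...) {
  fits <- vector("list", max_n)
  for (n in seq_len(max_n)) {
    fit <- tryCatch(
      suppressWarnings(fit_reconvolution(decay, irf, n, ...)),
      error = function(e) NULL)
    fits[[n]] <- fit
    if (is.null(fit)) next
    gof <- goodness_of_fit(fit)
    if (abs(gof$chi2_reduced - 1) <= delta &&
        gof$residual_randomness_p > alpha) {
      return(structure(n, fits = fits[seq_len(n)], fallback = FALSE))
    }
  }
  chi2 <- vapply(fits, function(f) if (is.null(f)) Inf else f$chi2_reduced,
                 numeric(1))
  if (all(!is.finite(chi2))) stop("no model converged up to n = ", max_n)
  n_best <- which.min(abs(chi2 - 1))
  structure(n_best, fits = fits, fallback = TRUE)
}
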