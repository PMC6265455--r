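# Lifetime summaries. The two averages answer different questions:
# <tau> = sum(alpha tau)/sum(alpha) is proportional to the steady-state
# intensity, while tau_bar = sum(alpha tau^2)/sum(alpha tau) is the mean
# time spent in the excited state.

.fit_components <- function(fit) {
  if (inherits(fit, "decay_fit"))
    list(tau = fit$lifetimes, alpha = fit$amplitudes)
  else if (is.list(fit) && !is.null(fit$lifetimes) &&
           !is.null(fit$amplitudes))
    list(tau = fit$lifetimes, alpha = fit$amplitudes)
  else stop("fit must be a decay_fit or a list with lifetimes and amplitudes")
}

#' Amplitude-weighted average lifetime
#'
#' `<tau> = sum(alpha_i tau_i) / sum(alpha_i)`, the lifetime average that is
#' proportional to steady-state emission intensity.
#'
#' @param fit a `decay_fit` or any list with `lifetimes` and `amplitudes`.
#' @return lifetime in ns.
#' @export
amplitude_weighted_lifetime <- function(fit) {
  cmp <- .fit_components(fit)
  if (sum(cmp$alpha) <= 0) stop("amplitudes sum to zero")
  sum(cmp$alpha * cmp$tau) / sum(cmp$alpha)
}

#' Intensity-weighted average lifetime
#'
#' `tau_bar = sum(alpha_i tau_i^2) / sum(alpha_i tau_i)`, the mean time spent
#' in the excited state. Always >= the amplitude-weighted average, with
#' equality only for a single component.
#'
#' @inheritParams amplitude_weighted_lifetime
#' @return lifetime in ns.
#' @export
intensity_weighted_lifetime <- function(fit) {
  cmp <- .fit_components(fit)
  denom <- sum(cmp$alpha * cmp$tau)
  if (denom <= 0) stop("sum(alpha * tau) is zero")
  sum(cmp$alpha * cmp$tau^2) / denom
}

#' Fractional intensities of the decay components
#'
#' `f_i = alpha_i tau_i / sum_j(alpha_j tau_j)`: each conformation's share of
#' the steady-state emission. Sums to 1.
#'
#' @inheritParams amplitude_weighted_lifetime
#' @return numeric vector of fractions, ordered like the fit's components
#'   (descending lifetime).
#' @export
fractional_intensities <- function(fit) {
  cmp <- .fit_components(fit)
  prod <- cmp$alpha * cmp$tau
  if (sum(prod) <= 0) stop("sum(alpha * tau) is zero")
  prod / sum(prod)
}

#' All lifetime summaries of a fit
#'
#' @inheritParams amplitude_weighted_lifetime
#' @return A list with `tau_amp`, `tau_int` and `f` (fractional intensities).
#' @export
lifetime_summary <- function(fit) {
  list(tau_amp = amplitude_weighted_lifetime(fit),
       tau_int = intensity_weighted_lifetime(fit),
       f = fractional_intensities(fit))
}
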