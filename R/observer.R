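#' Simulated observer with a Weibull psychometric function
#'
#' Stand-in for a human participant in the two-alternative (above/below
#' fixation) target localization task. The probability of a correct response
#' at contrast c is the cumulative Weibull
#' \deqn{p(c) = \gamma + (1 - \gamma - \lambda)\,(1 - e^{-(c/\alpha)^\beta})}
#' with guess rate \eqn{\gamma = 0.5} for the two-alternative task, lapse
#' rate \eqn{\lambda}, threshold \eqn{\alpha} (per condition) and slope
#' \eqn{\beta}.
#'
#' @param alpha Named numeric vector of Weibull thresholds (linear contrast),
#'   one entry per condition label.
#' @param beta Psychometric slope (default 3.5).
#' @param gamma Guess rate (default 0.5).
#' @param lapse Lapse rate (default 0.01).
#' @return An object of class `cfs_observer`.
#' @export
observer_model <- function(alpha, beta = 3.5, gamma = 0.5, lapse = 0.01) {
  if (is.null(names(alpha)) || any(!nzchar(names(alpha)))) {
    stop_invalid("alpha must be a named vector (one entry per condition)")
  }
  if (any(alpha <= 0) || beta <= 0) stop_invalid("alpha and beta must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lapse = lapse),
            class = "cfs_observer")
}

#' Probability of a correct response
#'
#' @param observer A [observer_model()].
#' @param condition Condition label (must be present in `observer$alpha`).
#' @param contrast Stimulus contrast (linear units).
#' @return Probability of a correct response.
#' @export
p_correct <- function(observer, condition, contrast) {
  stopifnot(inherits(observer, "cfs_observer"))
  a <- observer$alpha[[condition]]
  if (is.null(a)) stop_invalid("observer has no threshold for condition ", condition)
  observer$gamma + (1 - observer$gamma - observer$lapse) *
    (1 - exp(-(contrast / a)^observer$beta))
}

#' Contrast at which an observer attains a given percent correct
#'
#' Inverts the Weibull psychometric; used as the oracle for staircase
#' convergence (a one-up-two-down staircase converges where
#' `p = sqrt(1/2) = 0.7071`).
#'
#' @param observer A [observer_model()].
#' @param condition Condition label.
#' @param p Target probability correct (default `sqrt(0.5)`).
#' @return Contrast (linear units).
#' @export
psychometric_inverse <- function(observer, condition, p = sqrt(0.5)) {
  stopifnot(inherits(observer, "cfs_observer"))
  a <- observer$alpha[[condition]]
  span <- 1 - observer$gamma - observer$lapse
  q <- (p - observer$gamma) / span
  if (q <= 0 || q >= 1) stop_invalid("p is outside the attainable range")
  a * (-log(1 - q))^(1 / observer$beta)
}
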