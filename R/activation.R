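#' Logistic activation function of a Wilson-Cowan unit
#'
#' Constructs the sigmoid firing-rate function used by the discrete chain and
#' the single-node model.  The function is the symmetric logistic
#' \deqn{g(x) = \frac{4}{q}\left[\sigma(q(x-\theta)) - \sigma(-q\theta)\right],}
#' where \eqn{\sigma} is the standard logistic and \eqn{q} the gain.  The
#' offset guarantees \eqn{g(0) = 0}, so the quiescent state of an unstimulated
#' circuit is always a fixed point.  At \eqn{\theta = 0} the small-signal slope
#' is exactly 1, the saturation level is \eqn{2/q}, and the cubic Taylor
#' coefficient of \eqn{g(x) \approx x - \gamma x^3} is \eqn{\gamma = q^2/12};
#' this is the coefficient that enters the continuum equations as the
#' amplitude-damping nonlinearity.
#'
#' @param gain Logistic steepness \eqn{q > 0}.  Larger values saturate earlier
#'   (saturation = `2/gain`) and imply a stronger cubic nonlinearity.
#' @param threshold Activation threshold \eqn{\theta} (default 0, which keeps
#'   the small-signal gain at exactly 1).
#' @return An object of class `nw_activation`: a function of `x` with fields
#'   `gain`, `threshold`, and `gamma` (the implied cubic coefficient, exact
#'   only at `threshold = 0`).
#' @examples
#' g <- logistic_activation(gain = 2)
#' g(0)           # 0: quiescence is a fixed point
#' g(1e-6) / 1e-6 # ~1: unit small-signal slope
#' @export
logistic_activation <- function(gain = 1, threshold = 0) {
  stopifnot(is.numeric(gain), length(gain) == 1L, gain > 0,
            is.numeric(threshold), length(threshold) == 1L)
  q <- gain
  theta <- threshold
  offset <- stats::plogis(-q * theta)
  f <- function(x) (4 / q) * (stats::plogis(q * (x - theta)) - offset)
  structure(f, gain = q, threshold = theta, gamma = q^2 / 12,
            class = c("nw_activation", "function"))
}

#' Linear (identity) activation
#'
#' Identity activation used to run the chain in a strictly linear regime, e.g.
#' when cross-validating the discrete simulation against the analytic Green's
#' function.
#'
#' @return An `nw_activation` object with zero cubic coefficient.
#' @export
linear_activation <- function() {
  structure(function(x) x, gain = Inf, threshold = 0, gamma = 0,
            class = c("nw_activation", "function"))
}

#' Cubic coefficient implied by an activation function
#'
#' @param act An `nw_activation` object.
#' @return The coefficient \eqn{\gamma \ge 0} of the cubic term in the Taylor
#'   expansion \eqn{g(x) \approx x - \gamma x^3} around 0.
#' @export
activation_gamma <- function(act) {
  stopifnot(inherits(act, "nw_activation"))
  attr(act, "gamma")
}
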