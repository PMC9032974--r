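# Temporal interference in a single motif: brief pulses evoke damped
# oscillations in time; successive pulses superpose constructively or
# destructively depending on their spacing relative to the natural period.

#' Natural oscillation of a single motif
#'
#' Linearizes a single Wilson-Cowan motif around quiescence and returns its
#' natural (damped) oscillation parameters from the eigenvalues of the
#' Jacobian `[(w_EE - 1)/tau_E, -w_EI/tau_E; w_IE, -(w_II + 1)]`.
#'
#' @param m An `nw_motif_weights` object (neighbor weights are ignored).
#' @return List with `omega_0` (angular frequency), `period`, `decay`
#'   (damping rate, positive when stable), `oscillatory` (logical) and
#'   `stable` (logical).
#' @export
node_natural_frequency <- function(m) {
  stopifnot(inherits(m, "nw_motif_weights"))
  J <- matrix(c((m$w_EE - 1) / m$tau_E, -m$w_EI / m$tau_E,
                m$w_IE, -(m$w_II + 1)), 2, byrow = TRUE)
  ev <- eigen(J, only.values = TRUE)$values
  osc <- is.complex(ev) && abs(Im(ev[1])) > 1e-12
  list(omega_0 = if (osc) abs(Im(ev[1])) else NA_real_,
       period = if (osc) 2 * pi / abs(Im(ev[1])) else NA_real_,
       decay = -max(Re(ev)), oscillatory = osc,
       stable = max(Re(ev)) < 0)
}

#' Single-node response to a pulse train
#'
#' Integrates one Wilson-Cowan motif driven by a train of brief rectangular
#' input pulses.  In the damped-oscillatory regime each pulse launches a
#' decaying oscillation; pulses spaced by whole natural periods interfere
#' constructively, pulses spaced by half periods destructively.  In the
#' linear regime the trace equals the superposition of time-shifted
#' single-pulse responses.
#'
#' @param m An `nw_motif_weights` object.
#' @param pulse_times Onset times of the pulses.
#' @param pulse_amplitudes Pulse amplitudes (recycled to the number of
#'   pulses).
#' @param t_grid Output time grid (uniform; also sets the integration step).
#' @param pulse_width Duration of each rectangular pulse.
#' @param overdamped_ok If `FALSE` (default), an overdamped node (no
#'   oscillation to interfere) raises an error.
#' @return A data.frame with columns `t`, `r_E`, `r_I`, with the node's
#'   natural parameters in attribute `natural`.
#' @export
node_oscillation <- function(m, pulse_times, pulse_amplitudes = 1,
                             t_grid = seq(0, 50, by = 0.01),
                             pulse_width = 0.1, overdamped_ok = FALSE) {
  stopifnot(inherits(m, "nw_motif_weights"))
  nat <- node_natural_frequency(m)
  if (!nat$oscillatory && !overdamped_ok)
    stop("overdamped regime: the node has no natural oscillation to interfere")
  amp <- rep_len(pulse_amplitudes, length(pulse_times))
  jfun <- function(t) {
    j <- 0
    for (i in seq_along(pulse_times))
      j <- j + amp[i] * (t >= pulse_times[i] & t < pulse_times[i] + pulse_width)
    j
  }
  dt <- t_grid[2] - t_grid[1]
  rhs <- function(t, y, parms) {
    j <- jfun(t)
    CE <- m$w_EE * y[1] - m$w_EI * y[2] + m$alpha * j
    CI <- m$w_IE * y[1] - m$w_II * y[2] + (1 - m$alpha) * j
    list(c((-y[1] + m$act_E(CE)) / m$tau_E, -y[2] + m$act_I(CI)))
  }
  out <- deSolve::ode(y = c(0, 0), times = t_grid, func = rhs, parms = NULL,
                      method = "rk4", hini = min(dt, pulse_width / 4))
  if (any(!is.finite(out))) stop("single-node integration diverged")
  structure(data.frame(t = out[, 1], r_E = out[, 2], r_I = out[, 3]),
            natural = nat)
}

# Fixed-step RK4 for a single node under constant input j, from state y0.
# Returns the state trajectory (n+1 x 2) over n steps of size dt.
node_integrate <- function(m, y0, j, n, dt) {
  aE <- m$act_E; aI <- m$act_I
  iE <- m$alpha * j; iI <- (1 - m$alpha) * j
  tauE <- m$tau_E
  f <- function(y) {
    c((-y[1] + aE(m$w_EE * y[1] - m$w_EI * y[2] + iE)) / tauE,
      -y[2] + aI(m$w_IE * y[1] - m$w_II * y[2] + iI))
  }
  out <- matrix(NA_real_, n + 1, 2)
  out[1, ] <- y <- y0
  for (i in seq_len(n)) {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- y
  }
  if (any(!is.finite(out))) stop("single-node integration diverged")
  out
}

#' Duration threshold of a single node
#'
#' Smallest stimulus duration at which a constant-contrast step input makes
#' the node's excitatory activity satisfy a detection criterion.  Two
#' criteria are available: `"peak"` (activity exceeds `theta` at any time,
#' the default) and `"integral"` (the time-integral of supra-zero excitatory
#' activity exceeds `theta`).  The onset response is integrated once up to
#' the longest candidate duration; each candidate then only integrates its
#' own offset tail, where rebound oscillations may still cross threshold.
#'
#' @param contrast Stimulus amplitude (> 0).
#' @param m An `nw_motif_weights` object; its `alpha` sets the
#'   excitation/inhibition balance of the input.
#' @param theta Detection threshold.
#' @param criterion `"peak"` or `"integral"`.
#' @param durations Candidate durations, scanned in increasing order
#'   (rounded onto the integration grid).
#' @param t_pad Time simulated beyond stimulus offset (response may peak
#'   after offset).
#' @param dt Integration step.
#' @return The threshold duration, or `NA` (with attribute
#'   `"never_detected" = TRUE`) if no candidate duration meets the
#'   criterion.
#' @export
duration_threshold <- function(contrast, m, theta,
                               criterion = c("peak", "integral"),
                               durations = seq(0.1, 12, by = 0.1),
                               t_pad = 15, dt = 0.02) {
  stopifnot(contrast > 0, theta >= 0)
  criterion <- match.arg(criterion)
  durations <- sort(durations)
  steps <- pmax(1L, as.integer(round(durations / dt)))
  on <- node_integrate(m, c(0, 0), contrast, max(steps), dt)
  n_pad <- as.integer(round(t_pad / dt))
  for (i in seq_along(durations)) {
    n_on <- steps[i]
    off <- node_integrate(m, on[n_on + 1, ], 0, n_pad, dt)
    rE <- c(on[seq_len(n_on + 1), 1], off[-1, 1])
    stat <- if (criterion == "peak") max(rE) else sum(pmax(rE, 0)) * dt
    if (stat >= theta) return(durations[i])
  }
  structure(NA_real_, never_detected = TRUE)
}

#' Duration-threshold curve over contrast
#'
#' Sweeps [duration_threshold()] over stimulus contrasts and annotates
#' whether the resulting curve is monotone decreasing (the
#' excitation-dominated prediction) or nonmonotonic (the
#' inhibition-dominated prediction).
#'
#' @param contrasts Increasing contrast values.
#' @param m,theta,criterion,durations,t_pad,dt As in [duration_threshold()].
#' @return An object of class `nw_duration_curve`: data.frame `contrast`,
#'   `threshold` with attributes `alpha` and `shape`
#'   (`"monotone_decreasing"` or `"nonmonotonic"`; `NA` thresholds are
#'   flagged `never_detected`).
#' @export
duration_threshold_curve <- function(contrasts, m, theta,
                                     criterion = c("peak", "integral"),
                                     durations = seq(0.1, 12, by = 0.1),
                                     t_pad = 15, dt = 0.02) {
  criterion <- match.arg(criterion)
  th <- vapply(contrasts, function(ct)
    as.numeric(duration_threshold(ct, m, theta, criterion, durations,
                                  t_pad, dt)), numeric(1))
  ok <- !is.na(th)
  shape <- if (sum(ok) < 3) NA_character_
  else {
    d <- diff(th[ok])
    if (all(d <= 0)) "monotone_decreasing"
    else if (all(d >= 0)) "monotone_increasing"
    else "nonmonotonic"
  }
  structure(data.frame(contrast = contrasts, threshold = th),
            alpha = m$alpha, shape = shape,
            class = c("nw_duration_curve", "data.frame"))
}
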