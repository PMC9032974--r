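#' @importFrom deSolve ode
NULL

new_response_field <- function(grid, r_E, r_I, meta) {
  stopifnot(all(is.finite(r_E)), all(is.finite(r_I)))
  strip <- function(v) if (is.matrix(v)) unname(v) else unname(as.numeric(v))
  structure(list(grid = unname(grid), r_E = strip(r_E), r_I = strip(r_I),
                 meta = meta),
            class = "nw_response_field")
}

#' @export
print.nw_response_field <- function(x, ...) {
  cat("<nw_response_field>\n")
  cat(sprintf("  %d grid points, dx = %.4g\n", length(x$grid),
              x$grid[2] - x$grid[1]))
  if (!is.null(x$meta$steady_state))
    cat(sprintf("  steady state: %s (max |dr/dt| = %.3g)\n",
                x$meta$steady_state, x$meta$max_drdt))
  invisible(x)
}

# Single real root of y + gamma * y^3 = C, vectorized over C.  Used to make
# the continuum equations explicit in the time derivative: the cubic damping
# acts on y = tau * dr/dt + r, so the instantaneous y solves this cubic.
solve_gain_cubic <- function(C, gamma) {
  if (gamma <= 0) return(C)
  # depressed cubic t^3 + p t + q = 0 with p = 1/gamma > 0, q = -C/gamma:
  # unique real root via the hyperbolic (sinh) method, numerically stable.
  p <- 1 / gamma
  q <- -C / gamma
  -2 * sqrt(p / 3) * sinh(asinh(1.5 * q / p * sqrt(3 / p)) / 3)
}

#' Simulate the discrete motif chain
#'
#' Explicitly integrates the chain of Wilson-Cowan motifs
#' \deqn{\tau_E \dot r_E(l) = -r_E + g_E(C_E),\qquad
#'       \dot r_I(l) = -r_I + g_I(C_I),}
#' where `C_E`, `C_I` sum within-motif and nearest-neighbor contributions
#' plus the input currents `i_E = alpha * j` and `i_I = (1 - alpha) * j`.
#' Chain ends are absorbing: terminal motifs simply lack one neighbor.
#'
#' @param m An `nw_motif_weights` object.
#' @param s An `nw_stimulus1d`.  Point positions must fall on the motif grid
#'   (integer spacing, centered on zero).
#' @param n_motifs Number of motifs (>= 3; odd numbers center the chain on 0).
#' @param t_end Integration time.
#' @param dt Fixed integration step (classical Runge-Kutta).
#' @param steady_tol Steady state is declared when `max |dr/dt| < steady_tol`.
#' @param validate_dt If `TRUE`, re-integrates at `dt/2` and errors when the
#'   final states differ by more than `dt_check_tol` (step-halving stability
#'   check).
#' @param dt_check_tol Tolerance of the step-halving check (max absolute
#'   difference of final states).
#' @param save_times Optional times at which to store the full state; by
#'   default only the final state is kept.
#' @return An `nw_response_field`.  `grid` holds motif positions (spacing 1);
#'   `meta$steady_state` reports whether `steady_tol` was met, with a warning
#'   (not an error) on non-convergence.  When `save_times` is given, `r_E`
#'   and `r_I` are matrices of `length(save_times)` rows.
#' @export
simulate_chain <- function(m, s, n_motifs = 101, t_end = 100, dt = 0.05,
                           steady_tol = 1e-8, validate_dt = FALSE,
                           dt_check_tol = 1e-4, save_times = NULL) {
  stopifnot(inherits(m, "nw_motif_weights"), inherits(s, "nw_stimulus1d"))
  if (n_motifs < 3) stop("n_motifs must be >= 3")
  l <- seq_len(n_motifs) - (n_motifs + 1) / 2
  j <- stimulus_on_grid(s, l)
  run <- function(dt) {
    times <- if (is.null(save_times)) c(0, t_end) else
      sort(unique(c(0, save_times, t_end)))
    out <- deSolve::ode(
      y = numeric(2 * n_motifs), times = times, func = chain_rhs,
      parms = list(m = m, j = j, omega = s$omega, n = n_motifs),
      method = "rk4", hini = dt)
    if (any(!is.finite(out)))
      stop(sprintf(paste0("chain integration diverged (dt = %g); reduce dt ",
                          "or check weights"), dt))
    out
  }
  out <- run(dt)
  final <- out[nrow(out), -1]
  if (validate_dt) {
    final2 <- run(dt / 2)[nrow(out), -1]
    if (max(abs(final - final2)) > dt_check_tol)
      stop(sprintf(paste0("step-halving check failed: dt = %g changes the ",
                          "final state by %.3g"), dt,
                   max(abs(final - final2))))
  }
  drdt <- chain_rhs(t_end, final,
                    list(m = m, j = j, omega = s$omega, n = n_motifs))[[1]]
  steady <- max(abs(drdt)) < steady_tol
  if (!steady && s$omega == 0)
    warning(sprintf("steady state not reached within t_end = %g (max |dr/dt| = %.3g)",
                    t_end, max(abs(drdt))))
  sel <- function(M, cols) if (is.null(save_times)) M[nrow(M), cols] else
    M[, cols, drop = FALSE]
  rE <- sel(out, 1 + seq_len(n_motifs))
  rI <- sel(out, 1 + n_motifs + seq_len(n_motifs))
  new_response_field(l, rE, rI,
    meta = list(model = "chain", steady_state = steady,
                max_drdt = max(abs(drdt)), dt = dt, t_end = t_end,
                times = if (is.null(save_times)) t_end else out[, 1],
                params = m, stimulus = s))
}

chain_rhs <- function(t, y, p) {
  n <- p$n
  rE <- y[seq_len(n)]
  rI <- y[n + seq_len(n)]
  m <- p$m
  nb <- function(r) c(r[-1], 0) + c(0, r[-n])  # absorbing chain ends
  jt <- if (p$omega == 0) p$j else p$j * cos(p$omega * t)
  CE <- m$w_EE * rE + m$wt_EE * nb(rE) - (m$w_EI * rI + m$wt_EI * nb(rI)) +
    m$alpha * jt
  CI <- m$w_IE * rE + m$wt_IE * nb(rE) - (m$w_II * rI + m$wt_II * nb(rI)) +
    (1 - m$alpha) * jt
  list(c((-rE + m$act_E(CE)) / m$tau_E, -rI + m$act_I(CI)))
}

#' Simulate the continuum reaction-diffusion system
#'
#' Integrates the two-population continuum equations
#' \deqn{\tau_E \partial_t r_E = -r_E + W_{EE} r_E + D_{EE} r_E''
#'   - W_{EI} r_I - D_{EI} r_I'' + \alpha j
#'   - \gamma_E (\tau_E \partial_t r_E + r_E)^3}
#' (and the analogous inhibitory equation) by the method of lines.  The cubic
#' damping is handled exactly: with `y = tau_E dr_E/dt + r_E` the equation
#' reads `y + gamma_E y^3 = C_E`, a scalar cubic with a unique real root
#' solved in closed form at every node and step.
#'
#' @param p An `nw_continuum_params` object.
#' @param s An `nw_stimulus1d`.
#' @param domain Length-2 interval.  Should extend well beyond the stimulus;
#'   with absorbing boundaries, pad by several decay lengths `1/lambda`.
#' @param nx Number of grid nodes (>= 64).
#' @param t_end,dt Integration time and fixed Runge-Kutta step.
#' @param boundary `"absorbing"` (zero-value ghost nodes, the default) or
#'   `"periodic"`.
#' @param steady_tol,validate_dt,dt_check_tol,save_times As in
#'   [simulate_chain()].
#' @return An `nw_response_field` on the uniform grid over `domain`.
#' @export
simulate_pde <- function(p, s, domain, nx = 256, t_end = 100, dt = 0.02,
                         boundary = c("absorbing", "periodic"),
                         steady_tol = 1e-8, validate_dt = FALSE,
                         dt_check_tol = 1e-4, save_times = NULL) {
  stopifnot(inherits(p, "nw_continuum_params"), inherits(s, "nw_stimulus1d"))
  boundary <- match.arg(boundary)
  if (nx < 64) stop("nx must be >= 64")
  x <- seq(domain[1], domain[2], length.out = nx)
  dx <- x[2] - x[1]
  j <- stimulus_on_grid(s, x)
  parms <- list(p = p, j = j, omega = s$omega, n = nx, dx2 = dx^2,
                boundary = boundary)
  run <- function(dt) {
    times <- if (is.null(save_times)) c(0, t_end) else
      sort(unique(c(0, save_times, t_end)))
    out <- deSolve::ode(y = numeric(2 * nx), times = times, func = pde_rhs,
                        parms = parms, method = "rk4", hini = dt)
    if (any(!is.finite(out)))
      stop(sprintf(paste0("PDE integration diverged (dt = %g, dx = %g); the ",
                          "explicit step is likely unstable"), dt, dx))
    out
  }
  out <- run(dt)
  final <- out[nrow(out), -1]
  if (validate_dt) {
    final2 <- run(dt / 2)[nrow(out), -1]
    if (max(abs(final - final2)) > dt_check_tol)
      stop(sprintf("step-halving check failed at dt = %g (delta = %.3g)",
                   dt, max(abs(final - final2))))
  }
  drdt <- pde_rhs(t_end, final, parms)[[1]]
  steady <- max(abs(drdt)) < steady_tol
  if (!steady && s$omega == 0)
    warning(sprintf("steady state not reached within t_end = %g (max |dr/dt| = %.3g)",
                    t_end, max(abs(drdt))))
  sel <- function(M, cols) if (is.null(save_times)) M[nrow(M), cols] else
    M[, cols, drop = FALSE]
  new_response_field(x, sel(out, 1 + seq_len(nx)),
                     sel(out, 1 + nx + seq_len(nx)),
    meta = list(model = "pde", steady_state = steady,
                max_drdt = max(abs(drdt)), dt = dt, dx = dx, t_end = t_end,
                boundary = boundary,
                times = if (is.null(save_times)) t_end else out[, 1],
                params = p, stimulus = s))
}

second_diff <- function(r, dx2, boundary) {
  n <- length(r)
  if (boundary == "periodic")
    (c(r[-1], r[1]) - 2 * r + c(r[n], r[-n])) / dx2
  else
    (c(r[-1], 0) - 2 * r + c(0, r[-n])) / dx2
}

pde_rhs <- function(t, y, parms) {
  n <- parms$n
  p <- parms$p
  rE <- y[seq_len(n)]
  rI <- y[n + seq_len(n)]
  d2E <- second_diff(rE, parms$dx2, parms$boundary)
  d2I <- second_diff(rI, parms$dx2, parms$boundary)
  jt <- if (parms$omega == 0) parms$j else parms$j * cos(parms$omega * t)
  CE <- p$W_EE * rE + p$D_EE * d2E - p$W_EI * rI - p$D_EI * d2I + p$alpha * jt
  CI <- p$W_IE * rE + p$D_IE * d2E - p$W_II * rI - p$D_II * d2I +
    (1 - p$alpha) * jt
  yE <- solve_gain_cubic(CE, p$gamma_E)
  yI <- solve_gain_cubic(CI, p$gamma_I)
  list(c((yE - rE) / p$tau_E, yI - rI))
}
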