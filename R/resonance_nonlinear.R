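# Contrast-dependent resonance: harmonic-balance solution for spatially
# periodic stimuli j = j0 cos(kx).  Substituting rE = E cos(kx),
# rI = I cos(kx) into the static continuum equations and discarding the
# third harmonic (cos 3kx) leaves a 2x2 nonlinear algebraic system whose
# matrix depends on the amplitudes themselves.

#' Nonlinear wave-interaction matrix
#'
#' The 2x2 matrix coupling the excitatory and inhibitory wave amplitudes
#' `(E, I)` of the static grating response.  The diagonal entries carry the
#' amplitude-dependent self terms `-(3/4) gamma_E E^2` and
#' `-(3/4) gamma_I I^2` produced by the cubic nonlinearity under harmonic
#' balance; with `gamma_E = gamma_I = 0` the matrix reduces to the static
#' (omega = 0) 2x2 block of the linear wave-component system.
#'
#' @param E,I Current wave amplitudes.
#' @param k Stimulus spatial frequency.
#' @param p An `nw_continuum_params` object.
#' @return A 2x2 numeric matrix.
#' @export
wave_interaction_matrix <- function(E, I, k, p) {
  stopifnot(inherits(p, "nw_continuum_params"))
  co <- static_abcd(p, k^2)
  matrix(c(co$a - 0.75 * p$gamma_E * E^2, co$b,
           co$c,                          co$d - 0.75 * p$gamma_I * I^2),
         nrow = 2, byrow = TRUE, dimnames = list(c("E", "I"), c("E", "I")))
}

#' Constants of the explicit nonlinear iteration
#'
#' Derives the coefficients of the explicit harmonic-balance fixed-point map
#' in its structural form
#' \deqn{E_{n+1} = j_0 \frac{\Psi_E + \Phi_E k^2 + \eta_I I_n^2}
#'   {(k^2 - k_n^2 + \lambda^2 + \xi_I I_n^2 - \xi_E E_n^2)^2
#'    + 4\lambda^2 k_n^2 + \sigma_I I_n^2 - \sigma_E E_n^2}}
#' (and the analogous map for `I`).  The constants are obtained by expanding
#' the exact 2x2 determinant to first order in the cubic coefficients and
#' matching: `eta`, `xi`, `sigma` are proportional to `gamma_E`, `gamma_I`
#' and vanish in the linear limit, while `Psi`, `Phi` are the linear-gain
#' constants.  The sign of `xi_I - xi_E` alone sets the direction of the
#' contrast-induced resonance shift.
#'
#' @param p An `nw_continuum_params` object in the oscillatory regime.
#' @return An object of class `nw_nonlinear_coefficients`: list with
#'   `Psi_E`, `Phi_E`, `Psi_I`, `Phi_I`, `eta_E`, `eta_I`, `xi_E`, `xi_I`,
#'   `sigma_E`, `sigma_I`, `k_n`, `lam`, and `a_c` (the determinant scale).
#' @export
nonlinear_coefficients <- function(p) {
  stopifnot(inherits(p, "nw_continuum_params"))
  w <- wave_params(p)
  cp <- char_poly_coef(p)
  a_c <- cp$a_c
  v0 <- w$k_n^2 - w$lam^2
  xi_E <- -0.375 * p$gamma_E * p$D_II / a_c
  xi_I <- -0.375 * p$gamma_I * p$D_EE / a_c
  structure(list(
    Psi_E = (-p$alpha * (p$W_II + 1) + (1 - p$alpha) * p$W_EI) / a_c,
    Phi_E = (p$alpha * p$D_II - (1 - p$alpha) * p$D_EI) / a_c,
    Psi_I = ((1 - p$alpha) * (p$W_EE - 1) - p$alpha * p$W_IE) / a_c,
    Phi_I = (-(1 - p$alpha) * p$D_EE + p$alpha * p$D_IE) / a_c,
    eta_I = -0.75 * p$alpha * p$gamma_I / a_c,
    eta_E = -0.75 * (1 - p$alpha) * p$gamma_E / a_c,
    xi_E = xi_E, xi_I = xi_I,
    sigma_E = 0.75 * p$gamma_E * (p$W_II + 1) / a_c + 2 * v0 * xi_E,
    sigma_I = 0.75 * p$gamma_I * (p$W_EE - 1) / a_c + 2 * v0 * xi_I,
    k_n = w$k_n, lam = w$lam, a_c = a_c,
    meta = list(params = p)),
    class = "nw_nonlinear_coefficients")
}

#' Iterative solution of the nonlinear amplitude equations
#'
#' Solves the harmonic-balance system `M(Y) Y = J0` for the grating-response
#' amplitudes `Y = (E, I)` by fixed-point iteration
#' `Y_{n+1} = M(Y_n)^{-1} J0`, starting from the linear solution.  Optional
#' under-relaxation (automatically engaged when the raw iteration
#' oscillates) stabilizes the map at high contrast.  On convergence the
#' independent defect `||M(Y) Y - J0||` is checked against `tol`.
#'
#' @param j0 Stimulus amplitude (contrast proxy), nonnegative.
#' @param k Stimulus spatial frequency.
#' @param p An `nw_continuum_params` object.
#' @param tol Convergence tolerance on successive amplitude change.
#' @param max_iter Maximum iterations.
#' @param relax Under-relaxation factor in (0, 1]; `NULL` (default) starts
#'   at 1 and drops to 0.5 if the iteration oscillates.
#' @return An object of class `nw_nonlinear_state`: list with `E`, `I`,
#'   `k`, `j0`, `iterations`, `converged`, `residual` (last update norm)
#'   and `defect` (the algebraic residual of the solved system).
#' @export
iterate_amplitudes <- function(j0, k, p, tol = 1e-12, max_iter = 500,
                               relax = NULL) {
  stopifnot(inherits(p, "nw_continuum_params"), j0 >= 0, tol > 0)
  J0 <- -j0 * c(p$alpha, 1 - p$alpha)
  M_lin <- wave_interaction_matrix(0, 0, k, p)
  if (abs(det(M_lin)) < 1e-14)
    stop("singular linear interaction matrix at k = ", k)
  Y <- unname(solve(M_lin, J0))
  r <- if (is.null(relax)) 1 else relax
  prev_step <- NULL
  res <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M <- wave_interaction_matrix(Y[1], Y[2], k, p)
    if (abs(det(M)) < 1e-14)
      stop("singular wave-interaction matrix during iteration at k = ", k)
    Y_new <- unname(solve(M, J0))
    step <- Y_new - Y
    if (is.null(relax) && !is.null(prev_step) &&
        sum(step * prev_step) < 0 && r == 1) r <- 0.5
    Y <- Y + r * step
    prev_step <- step
    res <- max(abs(r * step))
    if (res < tol) break
  }
  M <- wave_interaction_matrix(Y[1], Y[2], k, p)
  defect <- max(abs(M %*% Y - J0))
  structure(list(E = Y[1], I = Y[2], k = k, j0 = j0, iterations = it,
                 converged = res < tol, residual = res, defect = defect,
                 relax = r),
            class = "nw_nonlinear_state")
}

#' Contrast-response surface and resonance-peak trajectory
#'
#' Sweeps the converged excitatory amplitude over stimulus amplitude
#' (contrast) and spatial frequency, and tracks the per-contrast resonance
#' peak (argmax over `k`, parabolically refined).  At low contrast the peak
#' is contrast-independent; at higher contrast it drifts in the direction
#' set by `sign(xi_E - xi_I)`.
#'
#' @param j0_values,k_values Sorted sweep grids.
#' @param p An `nw_continuum_params` object.
#' @param ... Passed to [iterate_amplitudes()].
#' @return List with `j0`, `k`, `amplitude_E` (matrix, rows = contrasts,
#'   absolute amplitude values), `peak_k` (per-contrast resonance),
#'   `n_masked` (non-converged cells, stored as `NA`).
#' @export
contrast_surface <- function(j0_values, k_values, p, ...) {
  stopifnot(!is.unsorted(j0_values), !is.unsorted(k_values))
  amp <- matrix(NA_real_, length(j0_values), length(k_values))
  n_masked <- 0L
  for (i in seq_along(j0_values)) for (jj in seq_along(k_values)) {
    st <- tryCatch(iterate_amplitudes(j0_values[i], k_values[jj], p, ...),
                   error = function(e) NULL)
    if (!is.null(st) && st$converged) amp[i, jj] <- abs(st$E)
    else n_masked <- n_masked + 1L
  }
  peak_k <- vapply(seq_along(j0_values), function(i)
    parabolic_peak(k_values, amp[i, ]), numeric(1))
  list(j0 = j0_values, k = k_values, amplitude_E = amp, peak_k = peak_k,
       n_masked = n_masked)
}

#' Amplitude-dependent resonance frequency
#'
#' Evaluates the nonlinear spatial-resonance condition
#' \eqn{k_r^2 = (k_n^2 - \lambda^2) - \xi_I I^2 + \xi_E E^2}.  Under the
#' equal-amplitude simplification `E = I = A` this reduces to
#' \eqn{k_r^2 = (k_n^2 - \lambda^2) - A^2 (\xi_I - \xi_E)}: the resonance
#' falls with contrast when `xi_I > xi_E` and rises when `xi_I < xi_E`.
#'
#' @param p An `nw_continuum_params` or `nw_nonlinear_coefficients` object.
#' @param E,I Wave amplitudes (give `E` only for the equal-amplitude form).
#' @return List with `k_r` (NA when suppressed), `k_r2` (the squared value,
#'   possibly negative) and `suppressed` (logical: no real resonance).
#' @export
resonance_shift <- function(p, E, I = E) {
  nc <- if (inherits(p, "nw_nonlinear_coefficients")) p else
    nonlinear_coefficients(p)
  k_r2 <- (nc$k_n^2 - nc$lam^2) - nc$xi_I * I^2 + nc$xi_E * E^2
  list(k_r = ifelse(k_r2 >= 0, sqrt(pmax(k_r2, 0)), NA_real_),
       k_r2 = k_r2, suppressed = k_r2 < 0)
}
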