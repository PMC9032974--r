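# Linear spatiotemporal resonance analysis: response of the continuum system
# to drifting gratings j = j0 cos(kx - wt), written as four wave components
# (cosine/sine x excitatory/inhibitory) coupled by a 4x4 interaction matrix.

#' Wave-component interaction matrix
#'
#' Builds the 4x4 matrix that couples the cosine/sine excitatory and
#' inhibitory wave components of the drifting-grating response, acting on
#' the component vector `Z = (E_C, E_S, I_C, I_S)` with forcing
#' `I0 = -j0 (alpha, 0, 1 - alpha, 0)`.
#'
#' @param k Stimulus spatial frequency (radians per unit length).
#' @param omega Stimulus temporal frequency (radians per unit time).
#' @param p An `nw_continuum_params` object.
#' @return A 4x4 numeric matrix.
#' @export
interaction_matrix <- function(k, omega, p) {
  stopifnot(inherits(p, "nw_continuum_params"))
  co <- static_abcd(p, k^2)
  matrix(c(
    co$a,               p$tau_E * omega,  co$b,   0,
    -p$tau_E * omega,   co$a,             0,      co$b,
    co$c,               0,                co$d,   omega,
    0,                  co$c,             -omega, co$d),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("E_C", "E_S", "I_C", "I_S"), NULL))
}

#' Wave-component amplitudes of the drifting-grating response
#'
#' Solves the linear wave-component system by Cramer's rule: each component
#' is the ratio of a column-substituted determinant to the full determinant.
#' The direct linear solve is used as a cross-check and the two must agree.
#'
#' @inheritParams interaction_matrix
#' @param j0 Stimulus amplitude (contrast proxy).
#' @param det_tol Relative tolerance below which the determinant is treated
#'   as a near-resonance singularity.
#' @return An object of class `nw_wave_components`: named numeric vector
#'   `E_C`, `E_S`, `I_C`, `I_S` with attributes `amplitude_E`, `amplitude_I`
#'   (moduli of the component pairs) and `det` (the determinant).
#' @export
solve_amplitudes <- function(k, omega, j0, p, det_tol = 1e-12) {
  H <- interaction_matrix(k, omega, p)
  I0 <- -j0 * c(p$alpha, 0, 1 - p$alpha, 0)
  dH <- det(H)
  scale <- max(abs(H))^4
  if (abs(dH) < det_tol * max(scale, 1))
    stop(sprintf("near-resonance singularity: |det H| = %.3g at (k = %g, omega = %g)",
                 abs(dH), k, omega))
  z <- vapply(1:4, function(i) {
    Hi <- H; Hi[, i] <- I0; det(Hi) / dH
  }, numeric(1))
  direct <- solve(H, I0)
  if (max(abs(z - direct)) > 1e-8 * max(1, max(abs(z))))
    stop("Cramer solution disagrees with direct linear solve")
  names(z) <- c("E_C", "E_S", "I_C", "I_S")
  structure(z,
            amplitude_E = sqrt(z[["E_C"]]^2 + z[["E_S"]]^2),
            amplitude_I = sqrt(z[["I_C"]]^2 + z[["I_S"]]^2),
            det = dH, class = "nw_wave_components")
}

#' Determinant decomposition of the interaction matrix
#'
#' The determinant `H(k, omega)` of the wave-component interaction matrix
#' separates into three terms:
#' \deqn{H = \mu\big[(k^2 - k_n^2 + \lambda^2)^2 + 4 k_n^2 \lambda^2\big]^2
#'   + \omega^2 (\kappa_4 k^4 - \kappa_2 k^2)
#'   + \omega^2 (\tau_E^2 \omega^2 + \kappa_0),}
#' where the first (purely spatial) term governs spatial selectivity at
#' `omega = 0`, the last (purely temporal) term governs temporal selectivity
#' at `k = 0`, and the middle term couples the two stimulus dimensions.  The
#' weight-dependent constants are extracted in closed form and verified
#' against the numeric determinant on a fixed grid of (k, omega) draws; a
#' mismatch raises an error.
#'
#' @param p An `nw_continuum_params` object in the oscillatory regime.
#' @param check_n Number of verification points.
#' @param check_tol Relative tolerance of the identity check.
#' @return An object of class `nw_det_coefficients`: list with `mu`,
#'   `kappa4`, `kappa2`, `kappa0`, `kappa_asymp = kappa2 / (2 kappa4)`,
#'   `k_n`, `lam`, `tau_E`.
#' @export
det_coefficients <- function(p, check_n = 100, check_tol = 1e-8) {
  stopifnot(inherits(p, "nw_continuum_params"))
  w <- wave_params(p)  # errors in the non-oscillatory regime
  cp <- char_poly_coef(p)
  tE <- p$tau_E
  mu <- cp$a_c^2
  kappa4 <- p$D_EE^2 + tE^2 * p$D_II^2 - 2 * tE * p$D_EI * p$D_IE
  kappa2 <- 2 * ((p$W_EE - 1) * p$D_EE + tE^2 * (p$W_II + 1) * p$D_II -
                   tE * (p$W_EI * p$D_IE + p$W_IE * p$D_EI))
  kappa0 <- (p$W_EE - 1)^2 + tE^2 * (p$W_II + 1)^2 - 2 * tE * p$W_EI * p$W_IE
  dc <- structure(list(mu = mu, kappa4 = kappa4, kappa2 = kappa2,
                       kappa0 = kappa0, kappa_asymp = kappa2 / (2 * kappa4),
                       k_n = w$k_n, lam = w$lam, tau_E = tE,
                       meta = list(params = p)),
                  class = "nw_det_coefficients")
  # identity guard: closed form must reproduce det(H) pointwise
  set.seed_local <- local({
    g <- 12345
    function() { g <<- (1103515245 * g + 12345) %% 2^31; g / 2^31 }
  })
  resid <- 0
  for (i in seq_len(check_n)) {
    k <- 3 * w$k_n * set.seed_local()
    om <- 5 * set.seed_local()
    num <- det(interaction_matrix(k, om, p))
    cf <- det_closed_form(dc, k, om)
    resid <- max(resid, abs(num - cf) / max(abs(num), 1e-12))
  }
  if (resid > check_tol)
    stop(sprintf(paste0("determinant decomposition failed the identity ",
                        "check: max relative residual %.3g"), resid))
  dc
}

#' Closed-form determinant
#'
#' Evaluates the three-term decomposition of `det H` at given `k`, `omega`.
#'
#' @param dc An `nw_det_coefficients` object.
#' @param k,omega Stimulus frequencies (vectorized).
#' @return Numeric vector of determinant values.
#' @export
det_closed_form <- function(dc, k, omega) {
  bracket <- (k^2 - dc$k_n^2 + dc$lam^2)^2 + 4 * dc$k_n^2 * dc$lam^2
  dc$mu * bracket^2 + omega^2 * (dc$kappa4 * k^4 - dc$kappa2 * k^2) +
    omega^2 * (dc$tau_E^2 * omega^2 + dc$kappa0)
}

#' Spatial resonance frequency
#'
#' Solves for the stimulus spatial frequency `k_r(omega)` minimizing the
#' determinant `H(k, omega)` at fixed temporal frequency, the circuit's
#' spatial resonance.  The resonance satisfies
#' \deqn{\omega^2 = \frac{2\mu}{\kappa_4}\,
#'   \frac{[(k_r^2 - k_n^2 + \lambda^2)^2 + 4 k_n^2\lambda^2]
#'         (k_r^2 - k_n^2 + \lambda^2)}{\kappa_{asymp} - k_r^2}.}
#' At `omega = 0`, `k_r = sqrt(k_n^2 - lam^2)`; as `omega` grows `k_r`
#' approaches `sqrt(kappa_asymp)` monotonically: from below when
#' `k_n^2 - lam^2 < kappa_asymp` (regime 1, resonance rises with temporal
#' frequency) and from above otherwise (regime 2).  The root taken is the
#' branch continuous with the `omega = 0` solution.
#'
#' @param omega Temporal frequency (vectorized).
#' @param p An `nw_continuum_params` object, or an `nw_det_coefficients`.
#' @return A data.frame with columns `omega`, `k_r`, `regime` (1, 2 or
#'   `"boundary"`).  `k_r` is `NA` where no real solution exists.
#' @export
spatial_resonance <- function(omega, p) {
  dc <- if (inherits(p, "nw_det_coefficients")) p else det_coefficients(p)
  v0 <- dc$k_n^2 - dc$lam^2
  va <- dc$kappa_asymp
  regime <- if (abs(v0 - va) < 1e-12 * max(abs(v0), abs(va))) "boundary"
            else if (v0 < va) "1" else "2"
  omega_of_v <- function(v) {
    br <- (v - dc$k_n^2 + dc$lam^2)^2 + 4 * dc$k_n^2 * dc$lam^2
    val <- 2 * dc$mu / dc$kappa4 * br * (v - dc$k_n^2 + dc$lam^2) / (va - v)
    val
  }
  k_r <- vapply(omega, function(om) {
    if (om == 0) return(sqrt(max(v0, 0)))
    if (regime == "boundary") return(sqrt(max(v0, 0)))
    target <- om^2
    lo <- min(v0, va); hi <- max(v0, va)
    eps <- (hi - lo) * 1e-12
    f <- function(v) omega_of_v(v) - target
    # omega^2 is 0 at v0 and diverges at the asymptote: bracketed root
    vlo <- if (regime == "1") lo + eps else lo + eps
    vhi <- hi - eps
    flo <- f(if (regime == "1") lo + eps else hi - eps)
    tryCatch({
      root <- stats::uniroot(f, lower = vlo, upper = vhi, tol = 1e-12)$root
      sqrt(root)
    }, error = function(e) NA_real_)
  }, numeric(1))
  data.frame(omega = omega, k_r = k_r, regime = regime,
             asymptote = sqrt(max(va, 0)))
}

#' Temporal resonance frequency
#'
#' Evaluates the temporal frequency minimizing `H(k, omega)` at fixed spatial
#' frequency: \eqn{\omega_r^2 = (\kappa_2 k^2 - \kappa_4 k^4 - \kappa_0) /
#' (2 \tau_E^2)}.  The right-hand side is a downward parabola in `k^2` with
#' vertex at `k^2 = kappa_asymp`, so the temporal resonance is a nonmonotonic
#' function of stimulus spatial frequency, defined only on the band of `k`
#' where the expression is positive.
#'
#' @param k Spatial frequency (vectorized).
#' @param p An `nw_continuum_params` or `nw_det_coefficients` object.
#' @return A data.frame with columns `k`, `omega_r` (`NA` where no temporal
#'   resonance exists), and `resonant` (logical).
#' @export
temporal_resonance <- function(k, p) {
  dc <- if (inherits(p, "nw_det_coefficients")) p else det_coefficients(p)
  rhs <- (dc$kappa2 * k^2 - dc$kappa4 * k^4 - dc$kappa0) / (2 * dc$tau_E^2)
  data.frame(k = k, omega_r = ifelse(rhs >= 0, sqrt(pmax(rhs, 0)), NA_real_),
             resonant = rhs >= 0)
}

#' Response amplitude surface over stimulus frequencies
#'
#' Evaluates the excitatory response amplitude
#' `sqrt(E_C^2 + E_S^2)` of the linear wave-component solution over a grid of
#' stimulus spatial and temporal frequencies, and extracts the resonance
#' ridge (the per-omega argmax over k, refined by parabolic interpolation).
#'
#' @param k_values,omega_values Sorted grids of stimulus frequencies.
#' @param j0 Stimulus amplitude.
#' @param p An `nw_continuum_params` object.
#' @return List with `k`, `omega`, `amplitude` (matrix, rows = omega),
#'   `ridge` (data.frame `omega`, `k_peak`), and the number of masked
#'   singular grid cells in `n_masked`.
#' @export
response_surface <- function(k_values, omega_values, j0, p) {
  stopifnot(!is.unsorted(k_values), !is.unsorted(omega_values))
  amp <- matrix(NA_real_, length(omega_values), length(k_values))
  n_masked <- 0L
  for (i in seq_along(omega_values)) for (jj in seq_along(k_values)) {
    amp[i, jj] <- tryCatch(
      attr(solve_amplitudes(k_values[jj], omega_values[i], j0, p),
           "amplitude_E"),
      error = function(e) { n_masked <<- n_masked + 1L; NA_real_ })
  }
  ridge <- data.frame(
    omega = omega_values,
    k_peak = vapply(seq_along(omega_values), function(i)
      parabolic_peak(k_values, amp[i, ]), numeric(1)))
  list(k = k_values, omega = omega_values, amplitude = amp, ridge = ridge,
       n_masked = n_masked)
}

# Argmax with three-point parabolic refinement; NA-safe.
parabolic_peak <- function(x, y) {
  ok <- is.finite(y)
  if (!any(ok)) return(NA_real_)
  i <- which.max(ifelse(ok, y, -Inf))
  if (i == 1 || i == length(x) || !ok[i - 1] || !ok[i + 1]) return(x[i])
  y1 <- y[i - 1]; y2 <- y[i]; y3 <- y[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(x[i])
  x[i] + 0.5 * (y1 - y3) / denom * (x[i + 1] - x[i])
}
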