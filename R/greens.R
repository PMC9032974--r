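# Static linear-system helpers.  With a plane-wave ansatz exp(i k x) the
# linearized static system has the 2x2 matrix
#   [ a(k2)  b(k2) ]   a = W_EE - 1 - k2 D_EE    b = -(W_EI - k2 D_EI)
#   [ c(k2)  d(k2) ]   c = W_IE - k2 D_IE        d = -(W_II + 1) + k2 D_II
# acting on (rE, rI), equal to -(alpha, 1 - alpha) j0 under forcing.
static_abcd <- function(p, k2) {
  list(a = p$W_EE - 1 - k2 * p$D_EE,
       b = -(p$W_EI - k2 * p$D_EI),
       c = p$W_IE - k2 * p$D_IE,
       d = -(p$W_II + 1) + k2 * p$D_II)
}

# Coefficients of the quartic spatial characteristic polynomial in u = s^2
# (ansatz exp(s x) in the homogeneous static system):
#   P(u) = a_c u^2 + b_c u + c_c.
char_poly_coef <- function(p) {
  list(a_c = p$D_EE * p$D_II - p$D_EI * p$D_IE,
       b_c = p$D_EE * (p$W_II + 1) + p$D_II * (p$W_EE - 1) -
         p$D_EI * p$W_IE - p$D_IE * p$W_EI,
       c_c = (p$W_EE - 1) * (p$W_II + 1) - p$W_EI * p$W_IE)
}

#' Intrinsic wave parameters of the linearized circuit
#'
#' Extracts the descriptors of the standing damped wave evoked by a unit point
#' stimulus: the intrinsic spatial frequency `k_n`, the spatial decay rate
#' `lam`, and the amplitude coefficients `Gamma_E`, `Gamma_I`, `Delta_E`,
#' `Delta_I` of the excitatory and inhibitory components.
#'
#' `k_n` and `lam` come from the complex roots `s = +/- lam +/- i k_n` of the
#' fourth-order spatial characteristic polynomial of the coupled static linear
#' system.  The amplitude coefficients are obtained by contour integration of
#' the Fourier-space solution (residues at the two upper-half-plane poles),
#' which is the delta-input jump-condition matching expressed in closed form.
#' The resulting Green's function integrates to the static gain of the system,
#' which is verified numerically on return.
#'
#' @param p An `nw_continuum_params` object (the cubic coefficients are
#'   ignored; this is a linear analysis).
#' @return An object of class `nw_wave_params` with fields `k_n`, `lam`,
#'   `Gamma_E`, `Gamma_I`, `Delta_E`, `Delta_I` and the originating
#'   parameters in `meta`.
#' @section Errors: If the characteristic roots are purely real the circuit
#'   has no spatial oscillation and a "non-oscillatory regime" error reports
#'   the discriminant.
#' @export
wave_params <- function(p) {
  stopifnot(inherits(p, "nw_continuum_params"))
  cp <- char_poly_coef(p)
  if (abs(cp$a_c) < 1e-14)
    stop("degenerate spread coefficients: D_EE*D_II - D_EI*D_IE is zero; ",
         "the spatial characteristic polynomial is not quartic")
  disc <- cp$b_c^2 - 4 * cp$a_c * cp$c_c
  if (disc >= 0)
    stop(sprintf(paste0("non-oscillatory regime: characteristic roots are ",
                        "real (discriminant = %.4g >= 0); the point response ",
                        "is purely decaying"), disc))
  # complex-conjugate roots of a_c u^2 + b_c u + c_c; u1 = (lam + i k_n)^2
  u1 <- complex(real = -cp$b_c / (2 * cp$a_c),
                imaginary = sqrt(-disc) / (2 * abs(cp$a_c)))
  s <- sqrt(u1)
  if (Re(s) < 0) s <- -s
  lam <- Re(s); k_n <- abs(Im(s))
  if (lam <= 0)
    stop("characteristic roots have no decaying branch (lam <= 0); ",
         "the homogeneous state is spatially unstable")
  u1 <- (complex(real = lam, imaginary = k_n))^2
  u2 <- Conj(u1)
  # Residues: G(x > 0) = e^{-lam x} * 2 Re(c_b e^{i k_n x}) with
  # c_b = i * N(-u2) / (-a_c * 2 k_b * (u1 - u2)), k_b = i sqrt(u2).
  k_b <- 1i * sqrt(u2)
  numer <- function(k2, which) {
    co <- static_abcd(p, k2)
    if (which == "E") -p$alpha * co$d + (1 - p$alpha) * co$b
    else -(1 - p$alpha) * co$a + p$alpha * co$c
  }
  cb_E <- 1i * numer(-u2, "E") / (-cp$a_c * 2 * k_b * (u1 - u2))
  cb_I <- 1i * numer(-u2, "I") / (-cp$a_c * 2 * k_b * (u1 - u2))
  w <- structure(list(k_n = k_n, lam = lam,
                      Gamma_E = 2 * Re(cb_E), Delta_E = 2 * Im(cb_E),
                      Gamma_I = 2 * Re(cb_I), Delta_I = 2 * Im(cb_I),
                      meta = list(params = p, char_coef = cp)),
                 class = "nw_wave_params")
  # closed-form check: integral of G_E must equal the static gain N_E(0)/det(0)
  co0 <- static_abcd(p, 0)
  det0 <- co0$a * co0$d - co0$b * co0$c
  gain <- numer(0, "E") / det0
  area <- greens_area(w, "E")
  if (abs(area - gain) > 1e-8 * max(1, abs(gain)))
    stop(sprintf(paste0("internal error: Green's function area %.6g does ",
                        "not match static gain %.6g"), area, gain))
  w
}

# Closed-form integral of the two-sided damped cosine Green's function.
greens_area <- function(w, component = c("E", "I")) {
  component <- match.arg(component)
  G0 <- if (component == "E") w$Gamma_E else w$Gamma_I
  D0 <- if (component == "E") w$Delta_E else w$Delta_I
  # 2 * Int_0^inf e^{-lam x}(G0 cos - D0 sin) dx
  2 * (G0 * w$lam - D0 * w$k_n) / (w$lam^2 + w$k_n^2)
}

#' @export
print.nw_wave_params <- function(x, ...) {
  cat("<nw_wave_params>\n")
  cat(sprintf("  k_n = %.5g (intrinsic period %.5g), lambda = %.5g (lam/k_n = %.3g)\n",
              x$k_n, 2 * pi / x$k_n, x$lam, x$lam / x$k_n))
  cat(sprintf("  Gamma_E = %.5g  Delta_E = %.5g  Gamma_I = %.5g  Delta_I = %.5g\n",
              x$Gamma_E, x$Delta_E, x$Gamma_I, x$Delta_I))
  invisible(x)
}

#' Standing-wave Green's function
#'
#' Evaluates the damped standing wave evoked by a unit point stimulus,
#' \deqn{G_E(x) = e^{-\lambda |x|}\,(\Gamma_E \cos(k_n x)
#'       - \Delta_E\, \mathrm{sign}(x) \sin(k_n x)),}
#' and the analogous inhibitory component, with `sign(0) = 0`.  Both
#' components are even functions of `x`.
#'
#' @param w An `nw_wave_params` object.
#' @param x Positions at which to evaluate.
#' @return A data.frame with columns `x`, `G_E`, `G_I`.
#' @export
greens_function <- function(w, x) {
  stopifnot(inherits(w, "nw_wave_params"))
  e <- exp(-w$lam * abs(x))
  sg <- sign(x)
  data.frame(
    x = x,
    G_E = e * (w$Gamma_E * cos(w$k_n * x) - w$Delta_E * sg * sin(w$k_n * x)),
    G_I = e * (w$Gamma_I * cos(w$k_n * x) - w$Delta_I * sg * sin(w$k_n * x)))
}

#' Linear superposition response to a stimulus
#'
#' Computes the static linear response as the convolution of the input
#' current with the Green's function,
#' \eqn{r_E(x) = \int j(x') G_E(x - x')\,dx'}.  Point stimuli are summed
#' exactly (no discretization of the delta); distributed stimuli are
#' convolved on the grid.
#'
#' @param s An `nw_stimulus1d` (static: `omega` is ignored here).
#' @param w An `nw_wave_params` object.
#' @param grid Uniform spatial grid.  Must sample the intrinsic period with
#'   at least 8 points.
#' @return An `nw_response_field`.
#' @export
linear_response <- function(s, w, grid) {
  stopifnot(inherits(s, "nw_stimulus1d"), inherits(w, "nw_wave_params"))
  dx <- grid[2] - grid[1]
  if (dx > (2 * pi / w$k_n) / 8)
    stop(sprintf(paste0("grid too coarse: dx = %.4g gives fewer than 8 ",
                        "samples per intrinsic period %.4g"), dx,
                 2 * pi / w$k_n))
  if (s$kind %in% c("point", "point_pair")) {
    rE <- numeric(length(grid)); rI <- numeric(length(grid))
    for (pos in s$positions) {
      G <- greens_function(w, grid - pos)
      rE <- rE + s$j0 * G$G_E
      rI <- rI + s$j0 * G$G_I
    }
  } else {
    j <- stimulus_on_grid(s, grid)
    # pad with the Green's function support so the open convolution is exact
    half <- ceiling(min(20 / w$lam, 2000 * dx) / dx)
    xg <- seq(-half, half) * dx
    G <- greens_function(w, xg)
    conv <- function(g) {
      full <- stats::convolve(j, rev(g), type = "open") * dx
      full[half + seq_along(grid)]
    }
    rE <- conv(G$G_E); rI <- conv(G$G_I)
  }
  new_response_field(grid, rE, rI,
    meta = list(model = "linear_superposition", wave = w, stimulus = s))
}

#' Two-point interference map
#'
#' Evaluates the linear response to two identical unit point stimuli at
#' separations `d_values` and summarizes each row by the total response
#' energy (integral of the squared excitatory response) and by its peak
#' amplitude.  Constructive interference (separations near whole intrinsic
#' periods) raises the energy; destructive interference (near half-periods)
#' lowers it.
#'
#' @param w An `nw_wave_params` object.
#' @param d_values Nonnegative separations between the two point stimuli.
#' @param grid Uniform spatial grid covering the two sources and several
#'   decay lengths beyond them.
#' @return An object of class `nw_interference_map`: list with `distances`,
#'   `field` (matrix, one row per separation), `energy`, `peak`,
#'   `period_estimate` (dominant spatial period of each row, from
#'   zero-crossing spacing).
#' @export
interference_map <- function(w, d_values, grid) {
  stopifnot(all(d_values >= 0))
  field <- matrix(NA_real_, length(d_values), length(grid))
  energy <- peak <- period <- numeric(length(d_values))
  dx <- grid[2] - grid[1]
  for (i in seq_along(d_values)) {
    r <- linear_response(stimulus_point_pair(separation = d_values[i]), w, grid)
    field[i, ] <- r$r_E
    energy[i] <- sum(r$r_E^2) * dx
    peak[i] <- max(abs(r$r_E))
    period[i] <- dominant_period(grid, r$r_E)
  }
  structure(list(distances = d_values, grid = grid, field = field,
                 energy = energy, peak = peak, period_estimate = period,
                 wave = w),
            class = "nw_interference_map")
}

# Dominant spatial period from mean spacing of zero crossings (each crossing
# is half a period), with linear interpolation of crossing positions.
dominant_period <- function(x, r, min_crossings = 4) {
  sgn <- sign(r)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) < min_crossings) return(NA_real_)
  xc <- x[idx] - r[idx] * (x[idx + 1] - x[idx]) / (r[idx + 1] - r[idx])
  2 * mean(diff(xc))
}

#' Dominant spatial frequency of the laterally activated zone
#'
#' Estimates the dominant spatial frequency of the response outside the
#' directly stimulated region (zone 2), where the model predicts the response
#' oscillates at the circuit's intrinsic frequency regardless of the stimulus
#' frequency.  Two estimators are returned: the mean zero-crossing spacing of
#' the lateral segment and the peak of a Hann-windowed periodogram; the
#' crossing-based estimate is the primary one (short damped segments bias the
#' raw periodogram peak).
#'
#' @param r An `nw_response_field`.
#' @param stim_region Length-2 interval of direct stimulation.
#' @param side Which lateral side to analyze (`"right"` or `"left"`).
#' @param skip Distance beyond the stimulus edge to skip before analysis
#'   (defaults to one grid step).
#' @return List with `k_dominant` (radians per unit length, zero-crossing
#'   estimate), `k_spectral` (periodogram peak), `uncertainty` (one spectral
#'   bin width), `n_crossings`, and `wave` (`FALSE` when the segment has no
#'   sign changes, i.e. a pure-decay, non-wave profile).
#' @export
zone2_spectrum <- function(r, stim_region, side = c("right", "left"),
                           skip = NULL) {
  stopifnot(inherits(r, "nw_response_field"))
  side <- match.arg(side)
  x <- r$grid
  dx <- x[2] - x[1]
  if (is.null(skip)) skip <- dx
  seg <- if (side == "right") x > stim_region[2] + skip else
    x < stim_region[1] - skip
  if (sum(seg) < 16) stop("lateral segment too short for spectral analysis")
  xs <- x[seg]; rs <- r$r_E[seg]
  per <- dominant_period(xs, rs, min_crossings = 4)
  n <- length(rs)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  sp <- stats::spec.pgram(stats::ts(rs * win, deltat = dx), plot = FALSE,
                          taper = 0, detrend = TRUE)
  k_spec <- 2 * pi * sp$freq[which.max(sp$spec)]
  bin <- 2 * pi * (sp$freq[2] - sp$freq[1])
  if (is.na(per)) {
    return(list(k_dominant = 0, k_spectral = k_spec, uncertainty = bin,
                n_crossings = 0, wave = FALSE))
  }
  list(k_dominant = 2 * pi / per, k_spectral = k_spec, uncertainty = bin,
       n_crossings = sum(diff(sign(rs)) != 0), wave = TRUE)
}

#' Extremum location of the pure-decay null model
#'
#' Under a null model in which two flanking stimuli merely induce
#' exponentially decaying activity
#' \eqn{r_E(x) = A e^{-\lambda (x + x_0)} + B e^{-\lambda (x_1 - x)}},
#' the activity between the flankers has exactly one extremum, at
#' \deqn{x_{min} = \ln\!\big(A e^{\lambda (x_1 - x_0)} / B\big) / (2\lambda).}
#' A wave-interference profile, in contrast, has multiple minima; the
#' number of interior extrema distinguishes the two accounts.
#'
#' @param A,B Positive edge activations of the two flankers.
#' @param lam Positive decay rate.
#' @param x0,x1 Flanker edges: the stimuli occupy `x < -x0` and `x > x1`.
#' @return The extremum location (scalar).
#' @export
decay_null_xmin <- function(A, B, lam, x0, x1) {
  if (A <= 0 || B <= 0) stop("A and B must be positive")
  if (lam <= 0) stop("lam must be positive")
  log(A * exp(lam * (x1 - x0)) / B) / (2 * lam)
}
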