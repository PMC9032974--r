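#' One-dimensional stimuli
#'
#' Constructors for the parametric input currents `j(x, t)` accepted by the
#' simulators and by [linear_response()].  Point stimuli carry unit-free
#' "mass" `j0` (they are deposited as `j0 / dx` on the nearest grid node, so
#' the integral of the current equals `j0` regardless of resolution).
#' Gratings and custom profiles are densities: `j(x)` is evaluated pointwise.
#'
#' `stimulus_grating()` describes a bounded luminance grating
#' `j(x, t) = j0 * cos(k * x - omega * t)` restricted to `region` (a
#' half-open interval `[x0, x1)`), the canonical stimulus of the direct/
#' lateral activation analysis.
#'
#' @param j0 Input amplitude (contrast proxy), nonnegative.
#' @param positions Point-source locations.
#' @param k Spatial frequency in radians per unit length (0 for unmodulated).
#' @param omega Temporal frequency in radians per unit time (0 for static).
#' @param region Numeric length-2 vector, the stimulated interval.
#' @param phase Phase of the grating at `x = 0` (radians).
#' @param profile For `stimulus_custom()`: a function of `x` returning the
#'   current density.
#' @return An object of class `nw_stimulus1d` with fields `kind`, `j0`, `k`,
#'   `omega`, `region`, `positions`.
#' @name stimulus1d
NULL

new_stimulus1d <- function(kind, j0, k = 0, omega = 0,
                           region = c(-Inf, Inf), positions = numeric(),
                           phase = 0, profile = NULL) {
  if (!is.numeric(j0) || length(j0) != 1L || j0 < 0 || !is.finite(j0))
    stop("j0 must be a finite nonnegative scalar")
  if (length(region) != 2L || !(region[1] < region[2]))
    stop("region must be an increasing length-2 interval")
  structure(list(kind = kind, j0 = j0, k = k, omega = omega,
                 region = region, positions = positions,
                 phase = phase, profile = profile),
            class = "nw_stimulus1d")
}

#' @rdname stimulus1d
#' @export
stimulus_point <- function(j0 = 1, positions = 0)
  new_stimulus1d("point", j0, positions = positions[1])

#' @rdname stimulus1d
#' @export
stimulus_point_pair <- function(j0 = 1, separation, center = 0) {
  stopifnot(is.numeric(separation), separation >= 0)
  new_stimulus1d("point_pair", j0,
                 positions = center + c(-separation / 2, separation / 2))
}

#' @rdname stimulus1d
#' @export
stimulus_grating <- function(j0 = 1, k, omega = 0, region, phase = 0)
  new_stimulus1d("bounded_grating", j0, k = k, omega = omega,
                 region = region, phase = phase)

#' @rdname stimulus1d
#' @export
stimulus_custom <- function(profile, j0 = 1, region = c(-Inf, Inf)) {
  stopifnot(is.function(profile))
  new_stimulus1d("custom_profile", j0, region = region, profile = profile)
}

# Current density of a non-point stimulus on a grid (points return NULL;
# they are handled by delta deposition / exact superposition).
stimulus_density <- function(s, x, t = 0) {
  switch(s$kind,
    bounded_grating = {
      inside <- x >= s$region[1] & x < s$region[2]
      s$j0 * cos(s$k * x - s$omega * t + s$phase) * inside
    },
    custom_profile = {
      inside <- x >= s$region[1] & x < s$region[2]
      s$j0 * s$profile(x) * inside
    },
    point = ,
    point_pair = NULL,
    stop("unknown stimulus kind: ", s$kind))
}

# Full current vector on a grid, with point masses deposited as j0/dx on the
# nearest node.  Returns the density j(x) (time-independent part; the omega
# modulation is applied by the integrators).
stimulus_on_grid <- function(s, x) {
  dx <- x[2] - x[1]
  if (s$kind %in% c("point", "point_pair")) {
    j <- numeric(length(x))
    for (p in s$positions) {
      i <- which.min(abs(x - p))
      if (abs(x[i] - p) > dx / 2 + 1e-9)
        stop("point position ", p, " does not lie on the simulation grid")
      j[i] <- j[i] + s$j0 / dx
    }
    j
  } else {
    stimulus_density(s, x)
  }
}

#' Two-dimensional stimuli
#'
#' Stimulus masks for the two-dimensional lattice.  `stimulus2d_point()`
#' places mass `j0` at `center`; `stimulus2d_ring()` builds an elliptical
#' annulus with semi-axes `a` (horizontal) and `b` (vertical) and radial
#' `width`, the stimulus used to demonstrate wave focusing at the ellipse's
#' geometric foci.
#'
#' @param j0 Input amplitude, nonnegative.
#' @param center Length-2 center coordinates.
#' @param a,b Semi-axes of the elliptical ring (`a >= b > 0`).
#' @param width Full radial width of the annulus (in the normalized radius;
#'   the mask is 1 where `|sqrt((x/a)^2 + (y/b)^2) - 1| < width/2`).
#' @return An object of class `nw_stimulus2d`.
#' @name stimulus2d
NULL

#' @rdname stimulus2d
#' @export
stimulus2d_point <- function(j0 = 1, center = c(0, 0)) {
  structure(list(kind = "point", j0 = j0, center = center),
            class = "nw_stimulus2d")
}

#' @rdname stimulus2d
#' @export
stimulus2d_ring <- function(j0 = 1, a, b, width = 0.1, center = c(0, 0)) {
  stopifnot(a > 0, b > 0, width > 0, j0 >= 0)
  structure(list(kind = "elliptical_ring", j0 = j0, a = a, b = b,
                 width = width, center = center),
            class = "nw_stimulus2d")
}

#' @rdname stimulus2d
#' @param mask Numeric matrix of input amplitudes (for `stimulus2d_mask()`),
#'   finite and nonnegative, with `dim(mask) == c(nx, ny)` of the target
#'   lattice.
#' @export
stimulus2d_mask <- function(mask) {
  stopifnot(is.matrix(mask), all(is.finite(mask)), all(mask >= 0))
  structure(list(kind = "mask", j0 = max(mask), mask = mask),
            class = "nw_stimulus2d")
}

# Evaluate a 2D stimulus on lattice coordinates xs (length nx), ys (length ny).
stimulus2d_on_grid <- function(s, xs, ys) {
  nx <- length(xs); ny <- length(ys)
  if (s$kind == "mask") {
    if (!all(dim(s$mask) == c(nx, ny)))
      stop("mask dimensions do not match the lattice")
    return(s$mask)
  }
  j <- matrix(0, nx, ny)
  if (s$kind == "point") {
    ix <- which.min(abs(xs - s$center[1]))
    iy <- which.min(abs(ys - s$center[2]))
    dx <- xs[2] - xs[1]; dy <- ys[2] - ys[1]
    j[ix, iy] <- s$j0 / (dx * dy)
  } else if (s$kind == "elliptical_ring") {
    xr <- (xs - s$center[1]) / s$a
    yr <- (ys - s$center[2]) / s$b
    rr <- sqrt(outer(xr^2, yr^2, `+`))
    j[abs(rr - 1) < s$width / 2] <- s$j0
  } else stop("unknown 2D stimulus kind: ", s$kind)
  j
}
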