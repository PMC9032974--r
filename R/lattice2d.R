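#' Simulate the two-dimensional lattice
#'
#' Steady-state activity of the isotropic two-dimensional generalization of
#' the continuum circuit: the spatial spread acts through the same `D`
#' coefficients along both lattice axes (five-point second differences), and
#' coupling is identical at every node.  For the linear system
#' (`gamma_E = gamma_I = 0`, the default regime of the interference maps)
#' the steady state solves a sparse block linear system directly; with a
#' cubic nonlinearity the equations are integrated in time to steady state.
#'
#' @param p An `nw_continuum_params` object.
#' @param s An `nw_stimulus2d`.
#' @param nx,ny Lattice size.
#' @param dx Lattice spacing (default 1: one motif spacing).
#' @param t_end,dt Integration horizon and step (integration path only).
#' @param method `"direct"` (sparse solve; linear systems only) or
#'   `"integrate"`.  Default picks `"direct"` when the system is linear.
#' @param steady_tol Steady-state tolerance for the integration path.
#' @return An object of class `nw_field2d`: list with `x`, `y`, `r_E`,
#'   `r_I` (nx x ny matrices), `stimulus`, and solver metadata in `meta`.
#' @export
simulate_lattice2d <- function(p, s, nx = 101, ny = 101, dx = 1,
                               t_end = 200, dt = 0.05,
                               method = NULL, steady_tol = 1e-8) {
  stopifnot(inherits(p, "nw_continuum_params"), inherits(s, "nw_stimulus2d"))
  linear <- p$gamma_E == 0 && p$gamma_I == 0
  if (is.null(method)) method <- if (linear) "direct" else "integrate"
  if (method == "direct" && !linear)
    stop("direct steady-state solve requires gamma_E = gamma_I = 0")
  xs <- (seq_len(nx) - (nx + 1) / 2) * dx
  ys <- (seq_len(ny) - (ny + 1) / 2) * dx
  j <- stimulus2d_on_grid(s, xs, ys)
  n <- nx * ny
  if (method == "direct") {
    L <- lattice_laplacian(nx, ny) / dx^2
    Id <- Matrix::Diagonal(n)
    A <- rbind(
      cbind((p$W_EE - 1) * Id + p$D_EE * L, -(p$W_EI * Id + p$D_EI * L)),
      cbind(p$W_IE * Id + p$D_IE * L, -((p$W_II + 1) * Id + p$D_II * L)))
    rhs <- c(-p$alpha * as.vector(j), -(1 - p$alpha) * as.vector(j))
    sol <- as.numeric(Matrix::solve(A, rhs))
    rE <- matrix(sol[seq_len(n)], nx, ny)
    rI <- matrix(sol[n + seq_len(n)], nx, ny)
    meta <- list(method = "direct", dx = dx, steady_state = TRUE)
  } else {
    parms <- list(p = p, j = as.vector(j), nx = nx, ny = ny, dx2 = dx^2)
    out <- deSolve::ode(y = numeric(2 * n), times = c(0, t_end),
                        func = lattice_rhs, parms = parms,
                        method = "rk4", hini = dt)
    if (any(!is.finite(out)))
      stop("2D integration diverged; reduce dt or check parameters")
    y <- out[nrow(out), -1]
    drdt <- lattice_rhs(t_end, y, parms)[[1]]
    steady <- max(abs(drdt)) < steady_tol
    if (!steady)
      warning(sprintf("2D steady state not reached (max |dr/dt| = %.3g)",
                      max(abs(drdt))))
    rE <- matrix(y[seq_len(n)], nx, ny)
    rI <- matrix(y[n + seq_len(n)], nx, ny)
    meta <- list(method = "integrate", dx = dx, dt = dt, t_end = t_end,
                 steady_state = steady, max_drdt = max(abs(drdt)))
  }
  if (any(!is.finite(rE)) || any(!is.finite(rI)))
    stop("non-finite 2D field")
  structure(list(x = xs, y = ys, r_E = rE, r_I = rI, stimulus = s,
                 params = p, meta = meta),
            class = "nw_field2d")
}

# Sparse five-point Laplacian with absorbing (zero-value) boundaries on an
# nx x ny lattice, column-major vectorization.
lattice_laplacian <- function(nx, ny) {
  Tx <- Matrix::bandSparse(nx, k = c(-1, 0, 1),
                           diagonals = list(rep(1, nx - 1), rep(-2, nx),
                                            rep(1, nx - 1)))
  Ty <- Matrix::bandSparse(ny, k = c(-1, 0, 1),
                           diagonals = list(rep(1, ny - 1), rep(-2, ny),
                                            rep(1, ny - 1)))
  Matrix::kronecker(Matrix::Diagonal(ny), Tx) +
    Matrix::kronecker(Ty, Matrix::Diagonal(nx))
}

lattice_rhs <- function(t, y, parms) {
  p <- parms$p
  nx <- parms$nx; ny <- parms$ny
  n <- nx * ny
  rE <- matrix(y[seq_len(n)], nx, ny)
  rI <- matrix(y[n + seq_len(n)], nx, ny)
  lap <- function(m) {
    up <- rbind(m[-1, , drop = FALSE], 0)
    dn <- rbind(0, m[-nx, , drop = FALSE])
    lf <- cbind(m[, -1, drop = FALSE], 0)
    rt <- cbind(0, m[, -ny, drop = FALSE])
    (up + dn + lf + rt - 4 * m) / parms$dx2
  }
  d2E <- lap(rE); d2I <- lap(rI)
  j <- matrix(parms$j, nx, ny)
  CE <- p$W_EE * rE + p$D_EE * d2E - p$W_EI * rI - p$D_EI * d2I + p$alpha * j
  CI <- p$W_IE * rE + p$D_IE * d2E - p$W_II * rI - p$D_II * d2I +
    (1 - p$alpha) * j
  yE <- solve_gain_cubic(CE, p$gamma_E)
  yI <- solve_gain_cubic(CI, p$gamma_I)
  list(c(as.vector((yE - rE) / p$tau_E), as.vector(yI - rI)))
}

#' Interior activation foci of a ring response
#'
#' Finds the dominant interior peaks of positive excitatory activation
#' inside an elliptical-ring stimulus and compares them to the ring's
#' geometric foci at `(+/- sqrt(a^2 - b^2), 0)`.  Wave interference inside
#' an eccentric ring concentrates activation near the foci.
#'
#' @param f An `nw_field2d` from an elliptical-ring run.
#' @param s The `nw_stimulus2d` ring (defaults to the one stored in `f`).
#' @param n_peaks Number of dominant peaks to report (default 2).
#' @param interior_margin Fraction of the normalized ring radius excluded at
#'   the ring itself (peaks are sought where `rho < 1 - width/2 - margin`).
#' @return A data.frame of peak coordinates and values, sorted by value,
#'   with attributes `geometric_foci` (2 x 2 matrix) and `displacement`
#'   (mean distance from each reported peak to its nearest focus).  Zero
#'   rows when no interior positive peak exists.
#' @export
detect_foci <- function(f, s = f$stimulus, n_peaks = 2,
                        interior_margin = 0.05) {
  stopifnot(inherits(f, "nw_field2d"))
  if (s$kind != "elliptical_ring")
    stop("detect_foci expects an elliptical-ring stimulus")
  xr <- outer((f$x - s$center[1]) / s$a, rep(1, length(f$y)))
  yr <- outer(rep(1, length(f$x)), (f$y - s$center[2]) / s$b)
  rho <- sqrt(xr^2 + yr^2)
  interior <- rho < 1 - s$width / 2 - interior_margin
  pk <- local_maxima_2d(f$r_E)
  ok <- pk & interior & f$r_E > 0
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- data.frame(x = numeric(), y = numeric(), value = numeric())
  } else {
    ord <- order(f$r_E[cbind(idx[, 1], idx[, 2])], decreasing = TRUE)
    out <- data.frame(x = f$x[idx[ord, 1]], y = f$y[idx[ord, 2]],
                      value = f$r_E[cbind(idx[ord, 1], idx[ord, 2])])
    out <- out[seq_len(min(n_peaks, nrow(out))), , drop = FALSE]
  }
  cfoc <- sqrt(max(s$a^2 - s$b^2, 0))
  foci <- rbind(c(s$center[1] - cfoc, s$center[2]),
                c(s$center[1] + cfoc, s$center[2]))
  disp <- if (nrow(out) > 0 && cfoc > 0) {
    mean(apply(as.matrix(out[, c("x", "y")]), 1, function(pt)
      min(sqrt(colSums((t(foci) - pt)^2)))))
  } else NA_real_
  structure(out, geometric_foci = foci, displacement = disp)
}

# Strict 8-neighbor local maxima (interior nodes only).
local_maxima_2d <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  pk <- matrix(FALSE, nx, ny)
  i <- 2:(nx - 1); j <- 2:(ny - 1)
  core <- m[i, j]
  pk[i, j] <- core > m[i - 1, j] & core > m[i + 1, j] &
    core > m[i, j - 1] & core > m[i, j + 1] &
    core > m[i - 1, j - 1] & core > m[i - 1, j + 1] &
    core > m[i + 1, j - 1] & core > m[i + 1, j + 1]
  pk
}

#' Supra-threshold activation regions
#'
#' Thresholds the excitatory field at level `theta` and labels the connected
#' components (4-connectivity) of the supra-threshold set.  For an
#' eccentric-ring response, raising the threshold splits the activation into
#' two islands around the foci: the component count is a nondecreasing
#' step function of `theta` over the relevant range, and components at a
#' higher threshold are nested inside those at a lower one.
#'
#' @param f An `nw_field2d`.
#' @param theta Nonnegative threshold.
#' @return List with `mask` (logical matrix `r_E > theta`), `labels`
#'   (integer component labels, 0 = background), `n_components`.
#' @export
threshold_region <- function(f, theta) {
  stopifnot(inherits(f, "nw_field2d"), theta >= 0)
  mask <- f$r_E > theta
  labels <- label_components(mask)
  list(mask = mask, labels = labels, n_components = max(labels))
}

# Two-pass style BFS labeling, 4-connectivity, base R.
label_components <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  cur <- 0L
  for (start in which(mask & lab == 0L)) {
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- ((v - 1L) %% nx) + 1L
      j <- ((v - 1L) %/% nx) + 1L
      nb <- c(if (i > 1) v - 1L, if (i < nx) v + 1L,
              if (j > 1) v - nx, if (j < ny) v + nx)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}
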