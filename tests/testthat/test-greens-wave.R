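test_that("wave parameters come from the characteristic polynomial roots", {
  expect_lte(wave_low$lam / wave_low$k_n, 0.05)  # low damping by construction
  expect_equal(2 * pi / wave_low$k_n, 20, tolerance = 1e-3)

  # cross-check root extraction against base::polyroot on the quartic in s
  cp <- neuralwave:::char_poly_coef(ref_mod)
  roots <- polyroot(c(cp$c_c, 0, cp$b_c, 0, cp$a_c))
  dec <- roots[Re(roots) > 0 & Im(roots) > 0][1]
  expect_equal(Re(dec), wave_mod$lam, tolerance = 1e-8)
  expect_equal(Im(dec), wave_mod$k_n, tolerance = 1e-8)
})

test_that("wave-parameter extraction is consistent under coefficient scaling", {
  # scaling all W - identity offsets and D by one factor scales the
  # characteristic polynomial coefficients predictably; roots recomputed
  # from the scaled polynomial must match wave_params on the scaled system
  s <- 1.7
  p <- ref_mod
  ps <- continuum_params(1 + s * (p$W_EE - 1), s * p$W_EI, s * p$W_IE,
                         s * (p$W_II + 1) - 1,
                         s * p$D_EE, s * p$D_EI, s * p$D_IE, s * p$D_II,
                         p$tau_E, p$alpha)
  cp <- neuralwave:::char_poly_coef(ps)
  cp0 <- neuralwave:::char_poly_coef(p)
  expect_equal(cp$a_c, s^2 * cp0$a_c, tolerance = 1e-12)
  expect_equal(cp$b_c, s^2 * cp0$b_c, tolerance = 1e-12)
  expect_equal(cp$c_c, s^2 * cp0$c_c, tolerance = 1e-12)
  ws <- wave_params(ps)
  expect_equal(ws$k_n, wave_mod$k_n, tolerance = 1e-10)  # roots unchanged
  expect_equal(ws$lam, wave_mod$lam, tolerance = 1e-10)
})

test_that("decoupled populations are flagged as non-oscillatory", {
  p <- continuum_params(W_EE = 0.5, W_EI = 0, W_IE = 0, W_II = 0.5,
                        D_EE = 0.2, D_EI = 0, D_IE = 0, D_II = 0.1)
  expect_error(wave_params(p), "non-oscillatory")
})

test_that("Green's function evaluates the damped standing wave exactly", {
  g0 <- greens_function(wave_low, 0)
  expect_equal(g0$G_E, wave_low$Gamma_E)  # cos(0)=1, sign(0)=0
  expect_equal(g0$G_I, wave_low$Gamma_I)

  x <- seq(0.1, 50, by = 0.7)
  g <- greens_function(wave_low, c(-x, x))
  expect_equal(g$G_E[seq_along(x)], g$G_E[length(x) + seq_along(x)])  # even

  # zeros spaced by pi/k_n for small damping
  xx <- seq(5, 80, by = 0.001)
  gg <- greens_function(wave_low, xx)$G_E
  cross <- xx[which(diff(sign(gg)) != 0)]
  expect_equal(mean(diff(cross)), pi / wave_low$k_n, tolerance = 0.01)

  # closed-form area equals the static gain of the linear system
  co <- neuralwave:::static_abcd(ref_low, 0)
  gain <- (-ref_low$alpha * co$d + (1 - ref_low$alpha) * co$b) /
    (co$a * co$d - co$b * co$c)
  expect_equal(neuralwave:::greens_area(wave_low, "E"), gain,
               tolerance = 1e-10)
})

test_that("linear response reduces to the Green's function for a delta", {
  grid <- wave_grid(wave_low, half = 200)
  r <- linear_response(stimulus_point(j0 = 1), wave_low, grid)
  g <- greens_function(wave_low, grid)
  expect_equal(r$r_E, g$G_E)
  expect_equal(r$r_I, g$G_I)

  # two coincident points give exactly twice the single-point response
  r2 <- linear_response(stimulus_point_pair(j0 = 1, separation = 0),
                        wave_low, grid)
  expect_equal(r2$r_E, 2 * g$G_E)
})

test_that("linear response rejects grids that undersample the wave", {
  coarse <- seq(-100, 100, by = 2 * pi / wave_low$k_n / 4)
  expect_error(linear_response(stimulus_point(), wave_low, coarse),
               "too coarse")
})

test_that("two-point interference energy is extremal at half-period multiples", {
  grid <- wave_grid(wave_low, half = 450)
  d <- seq(0.05, 2, by = 0.01) * period_low
  im <- interference_map(wave_low, d, grid)
  dper <- im$distances / period_low

  # first local minimum near 0.5 periods, local maximum near 1.0
  i_min <- which(diff(sign(diff(im$energy))) == 2)[1] + 1
  expect_equal(dper[i_min], 0.5, tolerance = 0.05)
  in_band <- dper > 0.5 & dper <= 1.5
  i_max <- which(in_band)[which.max(im$energy[in_band])]
  expect_equal(dper[i_max], 1.0, tolerance = 0.05)

  # d = 0 row equals twice the single-point response
  im0 <- interference_map(wave_low, 0, grid)
  expect_equal(as.vector(im0$field),
               2 * greens_function(wave_low, grid)$G_E)
})

test_that("interference-map period is the intrinsic period, independent of d", {
  grid <- wave_grid(wave_low, half = 450)
  im <- interference_map(wave_low, c(0.4, 0.9, 1.3, 1.8) * period_low, grid)
  expect_true(all(abs(im$period_estimate - period_low) / period_low < 0.05))
})

test_that("zone-2 frequency equals the intrinsic frequency for any stimulus SF", {
  grid <- wave_grid(wave_low, half = 500)
  for (mult in c(0.5, 1, 2)) {
    stim <- stimulus_grating(j0 = 1, k = mult * wave_low$k_n,
                             region = c(-400, 0))
    r <- linear_response(stim, wave_low, grid)
    z <- zone2_spectrum(r, c(-400, 0))
    expect_true(z$wave)
    expect_equal(z$k_dominant, wave_low$k_n, tolerance = 0.05)
    expect_lt(abs(z$k_spectral - wave_low$k_n), 2 * z$uncertainty)
  }
})

test_that("zone-2 amplitude decays away from the stimulated region", {
  grid <- wave_grid(wave_low, half = 500)
  stim <- stimulus_grating(j0 = 1, k = wave_low$k_n, region = c(-400, 0))
  r <- linear_response(stim, wave_low, grid)
  seg1 <- abs(r$r_E[r$grid > 20 & r$grid < 120])
  seg2 <- abs(r$r_E[r$grid > 220 & r$grid < 320])
  expect_lt(max(seg2), max(seg1))
})

test_that("a pure-decay profile is flagged as non-wave", {
  grid <- seq(-50, 200, by = 0.5)
  r <- neuralwave:::new_response_field(
    grid, exp(-0.05 * pmax(grid, 0)) * (grid >= 0) + (grid < 0),
    numeric(length(grid)), list())
  z <- zone2_spectrum(r, c(-50, 0))
  expect_false(z$wave)
  expect_equal(z$k_dominant, 0)
})

test_that("pure-decay null model has a single extremum at the printed location", {
  expect_equal(decay_null_xmin(1, 1, 0.3, 5, 5), 0)  # symmetric case
  lam <- 0.7
  expect_equal(decay_null_xmin(exp(2 * lam), 1, lam, 3, 3), 1)

  # grid-search oracle
  A <- 2.3; B <- 0.9; lam <- 0.21; x0 <- 4; x1 <- 9
  f <- function(x) A * exp(-lam * (x + x0)) + B * exp(-lam * (x1 - x))
  xs <- seq(-x0, x1, by = 1e-5)
  brute <- xs[which.min(f(xs))]
  expect_lt(abs(decay_null_xmin(A, B, lam, x0, x1) - brute), 1e-4)

  # derivative changes sign exactly once
  dv <- diff(f(seq(-x0, x1, by = 0.001)))
  expect_equal(sum(diff(sign(dv)) != 0), 1)

  expect_error(decay_null_xmin(-1, 1, 0.3, 1, 1), "positive")
  expect_error(decay_null_xmin(1, 1, 0, 1, 1), "positive")
})
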