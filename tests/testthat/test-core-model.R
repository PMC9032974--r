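test_that("continuum parameters derive from motif weights as W = w + 2*wt, D = wt", {
  m <- motif_weights(w_EE = 1, w_EI = 0.3, w_IE = 1, w_II = 0,
                     wt_EE = 0.5, wt_EI = 0.1, wt_IE = 0.2, wt_II = 0.05,
                     tau_E = 1.3, alpha = 0.7)
  p <- continuum_from_motif(m)
  expect_equal(p$W_EE, 2.0)
  expect_equal(p$D_EE, 0.5)
  expect_equal(p$W_EI, 0.5)
  expect_equal(p$D_EI, 0.1)
  expect_equal(p$tau_E, 1.3)
  expect_equal(p$alpha, 0.7)

  # zero coupling: W = w, D = 0
  m0 <- motif_weights(w_EE = 1.1, w_EI = 0.4, w_IE = 0.9, w_II = 0.2)
  p0 <- continuum_from_motif(m0)
  expect_equal(p0$W_EE, 1.1)
  expect_equal(c(p0$D_EE, p0$D_EI, p0$D_IE, p0$D_II), rep(0, 4))

  # round trip through the inverse map
  p2 <- continuum_from_motif(motif_from_continuum(p))
  expect_equal(p2[1:10], p[1:10])
})

test_that("parameter invariants are enforced", {
  expect_error(motif_weights(1, 1, 1, 1, alpha = 1.5), "alpha")
  expect_error(motif_weights(1, 1, 1, 1, tau_E = -1), "tau_E")
  expect_error(motif_weights(Inf, 1, 1, 1), "finite")
  expect_error(continuum_params(1, 1, 1, 1, 0.1, 0.1, 0.1, 0.1,
                                gamma_E = -1), "gamma")
})

test_that("quiescent state is a fixed point of the chain", {
  m <- nw_node_config("node_excitatory")
  m <- motif_weights(m$w_EE, m$w_EI, m$w_IE, m$w_II, wt_EE = 0.2,
                     wt_EI = 0.05, wt_IE = 0.05, wt_II = 0.02,
                     act_E = logistic_activation(3),
                     act_I = logistic_activation(3))
  r <- simulate_chain(m, stimulus_point(j0 = 0), n_motifs = 21,
                      t_end = 20, dt = 0.05)
  expect_true(all(r$r_E == 0))
  expect_true(all(r$r_I == 0))
  expect_true(r$meta$steady_state)
})

test_that("chain steady state matches the analytic Green's function", {
  m <- motif_from_continuum(ref_mod)
  r <- simulate_chain(m, stimulus_point(j0 = 0.01), n_motifs = 201,
                      t_end = 1500, dt = 0.05, steady_tol = 1e-7)
  g <- greens_function(wave_mod, r$grid)
  expect_lt(max(abs(r$r_E - 0.01 * g$G_E)) / max(abs(0.01 * g$G_E)), 0.03)
  expect_lt(max(abs(r$r_I - 0.01 * g$G_I)) / max(abs(0.01 * g$G_I)), 0.04)
})

test_that("discrete chain approaches the continuum solution as the wave is refined", {
  # lengthening the intrinsic period relative to the motif spacing must
  # shrink the chain-vs-continuum discrepancy monotonically
  errs <- vapply(c(1, 2), function(s) {
    p <- continuum_params(ref_mod$W_EE, ref_mod$W_EI, ref_mod$W_IE,
                          ref_mod$W_II, ref_mod$D_EE * s^2,
                          ref_mod$D_EI * s^2, ref_mod$D_IE * s^2,
                          ref_mod$D_II * s^2, ref_mod$tau_E, ref_mod$alpha)
    w <- wave_params(p)
    m <- motif_from_continuum(p)
    r <- simulate_chain(m, stimulus_point(j0 = 0.01),
                        n_motifs = round(200 * s) + 1,
                        t_end = 1500, dt = 0.05, steady_tol = 1e-6)
    g <- greens_function(w, r$grid)
    max(abs(r$r_E - 0.01 * g$G_E)) / max(abs(0.01 * g$G_E))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("linear-regime responses superpose and scale", {
  m <- motif_from_continuum(ref_mod)
  base <- function(s) simulate_chain(m, s, n_motifs = 121, t_end = 300,
                                     dt = 0.05, steady_tol = Inf)
  r1 <- base(stimulus_point(j0 = 0.005, positions = -10))
  r2 <- base(stimulus_point(j0 = 0.005, positions = 10))
  r12 <- base(stimulus_point_pair(j0 = 0.005, separation = 20))
  expect_lt(max(abs(r12$r_E - (r1$r_E + r2$r_E))) / max(abs(r12$r_E)), 0.01)

  rd <- base(stimulus_point(j0 = 0.01, positions = -10))
  expect_lt(max(abs(rd$r_E - 2 * r1$r_E)) / max(abs(rd$r_E)), 0.01)
})

test_that("step-halving leaves the steady state unchanged", {
  m <- motif_from_continuum(ref_mod)
  s <- stimulus_point(j0 = 0.01)
  r <- simulate_chain(m, s, n_motifs = 61, t_end = 200, dt = 0.1,
                      steady_tol = Inf, validate_dt = TRUE,
                      dt_check_tol = 1e-6)
  expect_s3_class(r, "nw_response_field")
})

test_that("chain integration errors on divergence", {
  m <- motif_weights(w_EE = 30, w_EI = 0.1, w_IE = 0.1, w_II = 0,
                     wt_EE = 1)  # runaway excitation, linear activation
  expect_error(simulate_chain(m, stimulus_point(j0 = 1), n_motifs = 21,
                              t_end = 50, dt = 0.5),
               "diverged")
})

test_that("PDE steady state matches the analytic superposition solution", {
  stim <- gaussian_stimulus()
  r <- simulate_pde(ref_mod, stim, domain = c(-100, 100), nx = 512,
                    t_end = 1200, dt = 0.04, steady_tol = 1e-6)
  lr <- linear_response(stim, wave_mod, r$grid)
  cen <- abs(r$grid) < 80
  expect_lt(max(abs(r$r_E[cen] - lr$r_E[cen])) / max(abs(lr$r_E[cen])), 0.02)
})

test_that("PDE response to a symmetric stimulus is even in x", {
  stim <- gaussian_stimulus(j0 = 0.02, sigma = 3)
  r <- simulate_pde(ref_mod, stim, domain = c(-60, 60), nx = 128,
                    t_end = 300, dt = 0.05, steady_tol = Inf)
  expect_equal(r$r_E, rev(r$r_E), tolerance = 1e-8)
  expect_equal(r$r_I, rev(r$r_I), tolerance = 1e-8)
})

test_that("zone-1 response oscillates at the stimulus spatial frequency", {
  k_stim <- 0.7 * wave_mod$k_n
  stim <- stimulus_grating(j0 = 0.01, k = k_stim, region = c(-120, 0))
  r <- simulate_pde(ref_mod, stim, domain = c(-160, 60), nx = 512,
                    t_end = 800, dt = 0.04, steady_tol = Inf)
  interior <- r$grid > -100 & r$grid < -30  # deep zone 1
  per <- neuralwave:::dominant_period(r$grid[interior], r$r_E[interior])
  expect_equal(2 * pi / per, k_stim, tolerance = 0.05)
})

test_that("cubic gain solver inverts y + gamma*y^3 = C", {
  C <- seq(-5, 5, length.out = 41)
  for (g in c(0, 0.3, 2)) {
    y <- neuralwave:::solve_gain_cubic(C, g)
    expect_equal(y + g * y^3, C, tolerance = 1e-10)
  }
})
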