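test_that("2D point response is symmetric under lattice rotations and reflections", {
  f <- simulate_lattice2d(ref_2d, stimulus2d_point(j0 = 1), nx = 61, ny = 61)
  rE <- f$r_E
  expect_equal(rE, t(rE), tolerance = 1e-8)            # 90-degree rotation
  expect_equal(rE, rE[61:1, ], tolerance = 1e-8)       # reflection
  expect_equal(rE, rE[, 61:1], tolerance = 1e-8)
  # radially damped oscillation: sign alternates along a radius
  mid <- 31
  profile <- rE[mid:61, mid]
  expect_gt(sum(diff(sign(profile)) != 0), 2)
})

test_that("a 1D slice through a line stimulus reproduces the 1D profile", {
  # moderate damping so absorbing boundaries are invisible at the center
  p <- nw_config("reference_moderate")
  p2 <- continuum_params(p$W_EE, p$W_EI, p$W_IE, p$W_II, p$D_EE / 4,
                         p$D_EI / 4, p$D_IE / 4, p$D_II / 4,
                         p$tau_E, p$alpha)
  n <- 101
  mask <- matrix(0, n, n)
  mask[(n + 1) / 2, ] <- 1
  f <- simulate_lattice2d(p2, stimulus2d_mask(mask), nx = n, ny = n)
  # the exact dimensional reduction: the same discrete operator in 1D
  m <- motif_from_continuum(p2)
  r1 <- simulate_chain(m, stimulus_point(j0 = 1), n_motifs = n,
                       t_end = 2500, dt = 0.05, steady_tol = 1e-6)
  mid_col <- f$r_E[, (n + 1) / 2]
  cen <- abs(f$x) < 35
  expect_lt(max(abs(mid_col[cen] - r1$r_E[cen])) / max(abs(r1$r_E[cen])),
            0.005)
  # and the continuum Green's function within discretization error
  g <- greens_function(wave_params(p2), f$x)
  expect_lt(max(abs(mid_col[cen] - g$G_E[cen])) / max(abs(g$G_E[cen])), 0.1)
})

test_that("an eccentric ring concentrates activation at two interior foci", {
  ring <- stimulus2d_ring(j0 = 1, a = 44, b = 22, width = 0.1)
  f <- simulate_lattice2d(ref_2d, ring, nx = 115, ny = 115)
  fo <- detect_foci(f)
  expect_equal(nrow(fo), 2)
  expect_equal(fo$x[1], -fo$x[2], tolerance = 1e-6)
  expect_equal(fo$y, c(0, 0), tolerance = 1e-6)
  # within half an intrinsic wavelength of the geometric foci
  w <- wave_params(ref_2d)
  expect_lt(attr(fo, "displacement"), pi / w$k_n)
})

test_that("a circular ring yields a rotationally degenerate response, not two foci", {
  ring <- stimulus2d_ring(j0 = 1, a = 30, b = 30, width = 0.1)
  f <- simulate_lattice2d(ref_2d, ring, nx = 91, ny = 91)
  expect_equal(f$r_E, t(f$r_E), tolerance = 1e-8)  # full 4-fold symmetry
  # interior maxima form a symmetric set (count a multiple of 4 or a center)
  pk <- which(neuralwave:::local_maxima_2d(f$r_E) & f$r_E > 0,
              arr.ind = TRUE)
  xs <- f$x[pk[, 1]]; ys <- f$y[pk[, 2]]
  rr <- sort(round(sqrt(xs^2 + ys^2), 6))
  expect_true(all(table(round(rr)) != 2))  # never an isolated axis pair
})

test_that("supra-threshold regions are nested and split with rising threshold", {
  ring <- stimulus2d_ring(j0 = 1, a = 44, b = 22, width = 0.1)
  f <- simulate_lattice2d(ref_2d, ring, nx = 115, ny = 115)
  # restrict to the ring interior (the analysis of interest); the directly
  # stimulated annulus itself always exceeds interior activation
  rho <- sqrt(outer((f$x / 44)^2, (f$y / 22)^2, `+`))
  interior <- rho < 0.85
  fi <- f
  fi$r_E[!interior] <- min(f$r_E)
  peak <- max(fi$r_E)
  regs <- lapply(c(0.2, 0.6, 0.97) * peak,
                 function(th) threshold_region(fi, th))
  # nesting: each higher-threshold mask is contained in the lower one
  expect_true(all(regs[[2]]$mask <= regs[[1]]$mask))
  expect_true(all(regs[[3]]$mask <= regs[[2]]$mask))
  # near the maximum only the two focal islands survive
  expect_equal(regs[[3]]$n_components, 2)
})

test_that("single-node pulses form damped oscillations that interfere", {
  m <- nw_node_config("node_excitatory")
  nat <- node_natural_frequency(m)
  expect_true(nat$oscillatory)
  expect_true(nat$stable)

  tg <- seq(0, 40, by = 0.01)
  one <- node_oscillation(m, 0, 0.5, t_grid = tg)
  # damped oscillation at the natural period
  pk <- which(diff(sign(diff(one$r_E))) == -2) + 1
  pk <- pk[one$r_E[pk] > 1e-5]
  expect_equal(mean(diff(tg[pk])), nat$period, tolerance = 0.05)
  expect_true(all(diff(one$r_E[pk]) < 0))  # decaying peaks

  # constructive at one period, destructive at half a period
  inphase <- node_oscillation(m, c(0, nat$period), 0.5, t_grid = tg)
  anti <- node_oscillation(m, c(0, nat$period / 2), 0.5, t_grid = tg)
  after <- tg > nat$period * 1.1
  expect_gt(max(inphase$r_E[after]), max(one$r_E[after]))
  expect_lt(max(anti$r_E[tg > nat$period * 0.6]), max(one$r_E))
})

test_that("linear-regime pulse trains superpose time-shifted single-pulse responses", {
  m <- motif_weights(w_EE = 1.5, w_EI = 2, w_IE = 2, w_II = 0.5,
                     alpha = 0.9)  # identity activations: exactly linear
  nat <- node_natural_frequency(m)
  tg <- seq(0, 30, by = 0.002)  # fine step: pulse-edge quadrature is O(dt)
  single <- node_oscillation(m, 0, 0.3, t_grid = tg)$r_E
  lagged <- c(rep(0, round(2.5 / 0.002)), single)[seq_along(tg)]
  train <- node_oscillation(m, c(0, 2.5), 0.3, t_grid = tg)$r_E
  expect_lt(max(abs(train - (single + lagged))) / max(abs(train)), 0.01)
})

test_that("overdamped nodes are flagged", {
  m <- motif_weights(w_EE = 0.1, w_EI = 0.1, w_IE = 0.1, w_II = 0.1)
  expect_false(node_natural_frequency(m)$oscillatory)
  expect_error(node_oscillation(m, 0), "overdamped")
})

test_that("duration thresholds respect criterion monotonicity and alpha regimes", {
  m_ex <- nw_node_config("node_excitatory")
  t_low <- duration_threshold(1, m_ex, theta = 0.05)
  t_high <- duration_threshold(1, m_ex, theta = 0.1)
  expect_gte(t_high, t_low)  # stricter criterion never lowers the threshold

  cur <- duration_threshold_curve(c(0.5, 1, 2, 3), m_ex, theta = 0.05)
  expect_true(all(diff(cur$threshold) <= 0))

  # undetectable stimulus
  none <- duration_threshold(0.01, m_ex, theta = 0.5,
                             durations = seq(0.2, 2, by = 0.2))
  expect_true(is.na(none))
  expect_true(attr(none, "never_detected"))
})
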