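test_that("identity kernels reproduce raw condition means", {
  d <- gen_tuning_dataset(seed = 3, contrast_grid = c(5, 10),
                          n_trials = 4)
  out <- sliding_kernel_curves(d, c(sf = 1, tf = 1, contrast = 1),
                               slide = "tf")
  raw <- aggregate(rate ~ tf, data = d[d$sf == min(d$sf) &
                                         d$contrast == 5, ], FUN = mean)
  expect_equal(out$rate, raw$rate[match(round(out$tf, 6),
                                        round(raw$tf, 6))])
  expect_true(all(out$n_cells == 4))
})

test_that("kernel aggregation of a constant field is flat and windows geometric-mean label", {
  d <- gen_tuning_dataset(seed = 4, n_trials = 2)
  d$rate <- 7.5
  out <- sliding_kernel_curves(d, c(sf = 4, tf = 1, contrast = 3),
                               slide = "tf")
  expect_true(all(abs(out$rate - 7.5) < 1e-12))
  gt <- attr(gen_tuning_dataset(seed = 4), "ground_truth")
  expect_equal(out$sf[1], exp(mean(log(gt$sf_grid[1:4]))))
  expect_equal(out$contrast[1], exp(mean(log(gt$contrast_grid[1:3]))))
})

test_that("kernel windows larger than the grid are rejected", {
  d <- gen_tuning_dataset(seed = 5, n_trials = 2)
  expect_error(sliding_kernel_curves(d, c(sf = 99, tf = 1, contrast = 1)),
               "window")
})

test_that("sliding-kernel aggregation recovers a planted tuning peak", {
  d <- gen_tuning_dataset(seed = 6, n_trials = 10, dispersion = 0.2)
  gt <- attr(d, "ground_truth")
  out <- sliding_kernel_curves(d, c(sf = 8, tf = 1, contrast = 3),
                               slide = "tf")
  # peak TF within one grid step of the planted peak
  i <- which.max(out$rate)
  steps <- abs(log(out$tf[i] / gt$peak_tf)) /
    diff(log(gt$tf_grid))[1]
  expect_lte(steps, 1)
})

test_that("bootstrap peak estimation is deterministic and exact in the zero-noise limit", {
  x <- exp(seq(log(0.05), log(1.6), length.out = 8))
  truth <- 0.3
  rate <- 40 * exp(-(log(x / truth))^2 / (2 * 0.8^2))
  trials <- data.frame(x = rep(x, each = 10), rate = rep(rate, each = 10))
  pe <- bootstrap_peak(trials, n_iter = 50, seed = 42)
  expect_equal(pe$sd, 0, tolerance = 1e-12)
  # within half a (log-spaced) grid step of the true maximum
  expect_lt(abs(log(pe$peak / truth)), diff(log(x))[1] / 2)
  expect_false(pe$flagged)

  pe2 <- bootstrap_peak(trials, n_iter = 50, seed = 42)
  expect_identical(pe$samples, pe2$samples)  # bit-identical rerun
})

test_that("flat tuning curves are reported as degenerate", {
  trials <- data.frame(x = rep(c(1, 2, 4, 8), each = 5), rate = 3)
  expect_error(bootstrap_peak(trials, n_iter = 10, seed = 1),
               "no valid")
})

test_that("bootstrap 1-SD intervals cover the planted peak at about the nominal rate", {
  # a calibrated bootstrap 1-SD interval has ~68% nominal coverage
  hits <- 0L
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    d <- gen_tuning_dataset(seed = 400 + r)
    gt <- attr(d, "ground_truth")
    tf_near <- gt$tf_grid[which.min(abs(log(gt$tf_grid / gt$peak_tf)))]
    sub <- d[d$contrast == gt$contrast_grid[2] & d$tf == tf_near, ]
    pe <- bootstrap_peak(data.frame(x = sub$sf, rate = sub$rate),
                         n_iter = 150, seed = r)
    truth <- gt$peak_sf * gt$contrast_shift *
      (tf_near / gt$peak_tf)^gt$regime_strength
    if (abs(pe$peak - truth) <= pe$sd) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.35)  # binomial band around the ~68% nominal
  expect_lte(hits / n_rep, 0.95)
})

test_that("peak comparison classifies separation and equality correctly", {
  set.seed(9)
  a <- rnorm(300, 1, 0.05)
  cmp_same <- compare_peaks(a, a + rnorm(300, 0, 1e-6))
  expect_equal(cmp_same$direction, "none")

  b <- rnorm(300, 1.6, 0.05)
  cmp_up <- compare_peaks(a, b)
  expect_equal(cmp_up$direction, "up")
  expect_lt(cmp_up$p_value, 0.05)
  cmp_dn <- compare_peaks(b, a)
  expect_equal(cmp_dn$direction, "down")
  expect_equal(cmp_up$direction_ci, "up")

  expect_error(compare_peaks(a[1:2], b), "insufficient")
})

test_that("damped-harmonic fits recover generated parameters", {
  d <- gen_sensitivity_profiles(seed = 21, noise_sd = 0.02,
                                O = c(0.3, 0.4, 0.5))
  gt <- attr(d, "ground_truth")
  fs <- vapply(split(d, d$condition), function(dd) {
    dd$sensitivity <- dd$sensitivity - mean(dd$sensitivity)
    fit_damped_harmonic(dd$distance, dd$sensitivity)$f
  }, numeric(1))
  # shared frequency recovered within 10% in every condition
  expect_true(all(abs(fs - gt$f) / gt$f < 0.1))
  # and consistent across conditions despite different amplitudes
  expect_lt(diff(range(fs)) / gt$f, 0.15)
})

test_that("zero-noise profiles fit with near-zero residuals", {
  d <- gen_sensitivity_profiles(seed = 22, noise_sd = 0)
  gt <- attr(d, "ground_truth")
  dd <- d[d$condition == d$condition[1], ]
  ft <- fit_damped_harmonic(dd$distance, dd$sensitivity - gt$pedestal)
  expect_lt(ft$rss, 1e-6)
})

test_that("pure-decay profiles are flagged as unmodulated", {
  d <- gen_sensitivity_profiles(seed = 23, scenario = "decay",
                                noise_sd = 0.005)
  dd <- d[d$condition == d$condition[1], ]
  ft <- fit_damped_harmonic(dd$distance, dd$sensitivity - min(dd$sensitivity))
  # modulation frequency collapses toward zero (no crossing within range)
  expect_lt(ft$f * max(dd$distance), 0.5)
})

test_that("fit refuses underdetermined profiles", {
  expect_error(fit_damped_harmonic(1:4, rnorm(4)), "at least 6")
})

test_that("the staircase protocol follows the printed three-down/one-up rules", {
  # deterministic observer: correct iff contrast >= 20
  obs <- function(contrast) contrast >= 20
  st <- run_staircase(obs)
  expect_equal(nrow(st$trials), 30)
  expect_equal(st$trials$contrast[1], 40)
  # three consecutive corrects step down by 12 before the second reversal
  expect_equal(st$trials$contrast[4], 28)
  expect_equal(st$trials$contrast[7], 16)   # crosses the step
  expect_equal(st$trials$contrast[8], 28)   # one error steps straight up
  # threshold brackets the step location
  expect_gt(st$threshold, 20 - 12)
  expect_lt(st$threshold, 20 + 12)
})

test_that("staircase runs are reproducible under a fixed seed and robust to rare lapses", {
  obs <- gen_observer(seed = 31, threshold = 12, slope = 0.3)
  set.seed(5); log1 <- run_staircase(obs)
  set.seed(5); log2 <- run_staircase(obs)
  expect_identical(log1$trials, log2$trials)

  obs_lapse <- gen_observer(seed = 31, threshold = 12, slope = 0.3,
                            lapse = 0.01)
  set.seed(7)
  t_clean <- mean(replicate(150, run_staircase(obs)$threshold))
  set.seed(7)
  t_lapse <- mean(replicate(150, run_staircase(obs_lapse)$threshold))
  expect_lt(abs(t_clean - t_lapse), 2)
})
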