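# Seeded generators for every input the analysis pipeline consumes, with
# ground truth carried alongside so downstream estimates can be scored.

#' Generate a trial-wise spatiotemporal tuning dataset
#'
#' Emulates single-unit recordings on a spatial-frequency x temporal-
#' frequency x contrast grid with a fixed number of trials per condition.
#' The underlying tuning surface is log-Gaussian in both frequency
#' dimensions; the preferred spatial frequency may shift across contrast
#' and with temporal frequency according to a regime rule:
#' `"regime1"` (peak SF rises with TF), `"regime2"` (falls with TF), or
#' `"flat"`.  Trial rates are drawn from a Gamma family (variance
#' proportional to the mean, nonnegative), mimicking spike-count
#' overdispersion.
#'
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param sf_grid,tf_grid,contrast_grid Stimulus grids (positive, sorted).
#'   Defaults: 8 log-spaced SFs (0.03-2 cycles/deg), 5 log-spaced TFs
#'   (1-24 Hz), contrasts 2, 7, 14 (%).
#' @param n_trials Trials per condition (default 10).
#' @param peak_sf,peak_tf Baseline preferred SF and TF at the lowest
#'   contrast.
#' @param contrast_shift Multiplicative shift of peak SF per contrast step
#'   (> 1: preference rises with contrast).
#' @param regime Regime rule for the TF dependence of peak SF.
#' @param regime_strength Log-slope of the within-contrast peak-SF shift
#'   across TF.
#' @param bandwidth_sf,bandwidth_tf Log-Gaussian tuning widths (octave-like
#'   units, natural log).
#' @param rate_max Mean peak firing rate (spikes/s) at the highest contrast.
#' @param dispersion Gamma noise dispersion: `var = dispersion * mean`.
#' @param baseline Baseline rate added to the tuning surface.
#' @return An object of class `nw_tuning_dataset`: a data.frame with
#'   columns `sf`, `tf`, `contrast`, `trial`, `rate` and a `ground_truth`
#'   attribute (list with the planted peaks per contrast/TF and all
#'   generator parameters, seed included).
#' @export
gen_tuning_dataset <- function(seed = 1,
                               sf_grid = exp(seq(log(0.03), log(2),
                                                 length.out = 8)),
                               tf_grid = exp(seq(log(1), log(24),
                                                 length.out = 5)),
                               contrast_grid = c(2, 7, 14),
                               n_trials = 10,
                               peak_sf = 0.25, peak_tf = 6,
                               contrast_shift = 1.35,
                               regime = c("regime1", "regime2", "flat"),
                               regime_strength = 0.15,
                               bandwidth_sf = 0.9, bandwidth_tf = 0.9,
                               rate_max = 60, dispersion = 1,
                               baseline = 2) {
  regime <- match.arg(regime)
  stopifnot(all(sf_grid > 0), all(tf_grid > 0), all(contrast_grid > 0),
            !is.unsorted(sf_grid), !is.unsorted(tf_grid),
            !is.unsorted(contrast_grid), n_trials >= 1)
  set.seed(seed)
  slope <- switch(regime, regime1 = regime_strength,
                  regime2 = -regime_strength, flat = 0)
  cond <- expand.grid(sf = sf_grid, tf = tf_grid, contrast = contrast_grid,
                      KEEP.OUT.ATTRS = FALSE)
  ci <- match(cond$contrast, contrast_grid)
  # planted peak SF depends on contrast level and (log) TF
  peak_sf_cond <- peak_sf * contrast_shift^(ci - 1) *
    (cond$tf / peak_tf)^slope
  gain <- cond$contrast / max(contrast_grid)
  mean_rate <- baseline + rate_max * gain *
    exp(-(log(cond$sf / peak_sf_cond))^2 / (2 * bandwidth_sf^2)) *
    exp(-(log(cond$tf / peak_tf))^2 / (2 * bandwidth_tf^2))
  d <- cond[rep(seq_len(nrow(cond)), each = n_trials), ]
  d$trial <- rep(seq_len(n_trials), times = nrow(cond))
  mu <- rep(mean_rate, each = n_trials)
  # Gamma with var = dispersion * mean: shape = mean/dispersion
  d$rate <- stats::rgamma(nrow(d), shape = mu / dispersion,
                          scale = dispersion)
  rownames(d) <- NULL
  gt <- list(seed = seed, regime = regime, peak_sf = peak_sf,
             peak_tf = peak_tf, contrast_shift = contrast_shift,
             regime_strength = regime_strength,
             peak_sf_by_contrast = peak_sf * contrast_shift^
               (seq_along(contrast_grid) - 1),
             sf_grid = sf_grid, tf_grid = tf_grid,
             contrast_grid = contrast_grid, n_trials = n_trials,
             bandwidth_sf = bandwidth_sf, bandwidth_tf = bandwidth_tf,
             rate_max = rate_max, dispersion = dispersion,
             baseline = baseline)
  structure(d, ground_truth = gt,
            class = c("nw_tuning_dataset", "data.frame"))
}

#' Generate lateral contrast-sensitivity profiles
#'
#' Draws sensitivity-versus-distance profiles from the damped-harmonic
#' family \eqn{S(d) = O e^{-d^2/(2c^2)} \cos(2\pi f d + \phi)} plus a
#' constant pedestal, one profile per flanker condition.  All conditions
#' share the same modulation frequency `f` (the model prediction that the
#' lateral waveform is intrinsic to the circuit, not inherited from the
#' stimulus); amplitudes may differ.  A `"decay"` scenario generates a
#' pure Gaussian decay instead (the no-wave null).
#'
#' @param seed Integer seed.
#' @param distances Probe distances from the flanker edge (deg).  Default
#'   mirrors probe offsets of 0 to 0.5 deg (11 points).
#' @param conditions Condition labels (e.g. flanker SFs in cycles/deg).
#' @param f Shared modulation frequency (cycles/deg).
#' @param O Amplitudes per condition (recycled).
#' @param c_damp Gaussian envelope scale (deg).
#' @param phi Phase (radians).
#' @param pedestal Constant sensitivity offset (keeps sensitivities
#'   positive).
#' @param noise_sd Additive Gaussian noise SD.
#' @param scenario `"wave"` (damped harmonic) or `"decay"` (pure Gaussian
#'   decay, f = 0).
#' @return An object of class `nw_sensitivity_profiles`: data.frame with
#'   columns `condition`, `distance`, `sensitivity` and a `ground_truth`
#'   attribute.
#' @export
gen_sensitivity_profiles <- function(seed = 1,
                                     distances = seq(0, 0.5,
                                                     length.out = 11),
                                     conditions = c(1, 2, 4),
                                     f = 3, O = 0.35, c_damp = 0.35,
                                     phi = 0, pedestal = 1.5,
                                     noise_sd = 0.03,
                                     scenario = c("wave", "decay")) {
  scenario <- match.arg(scenario)
  stopifnot(all(distances >= 0), !is.unsorted(distances))
  set.seed(seed)
  Ov <- rep_len(O, length(conditions))
  f_true <- if (scenario == "wave") f else 0
  rows <- lapply(seq_along(conditions), function(i) {
    mod <- if (scenario == "wave") cos(2 * pi * f_true * distances + phi)
           else 1
    s <- pedestal + Ov[i] * exp(-distances^2 / (2 * c_damp^2)) * mod +
      stats::rnorm(length(distances), 0, noise_sd)
    data.frame(condition = conditions[i], distance = distances,
               sensitivity = s)
  })
  d <- do.call(rbind, rows)
  if (any(d$sensitivity <= 0))
    d$sensitivity <- pmax(d$sensitivity, 1e-3)
  structure(d,
            ground_truth = list(seed = seed, scenario = scenario,
                                f = f_true, O = Ov, c_damp = c_damp,
                                phi = phi, pedestal = pedestal,
                                noise_sd = noise_sd),
            class = c("nw_sensitivity_profiles", "data.frame"))
}

#' Simulated two-alternative forced-choice observer
#'
#' Builds a trial oracle for the staircase: given a probe contrast it
#' returns `TRUE`/`FALSE` from a cumulative-Gaussian psychometric function
#' on log contrast with a 50% guessing floor and an optional lapse rate,
#' \deqn{P(correct) = \lambda/2 + (1 - \lambda)\,
#'  [0.5 + 0.5\,\Phi((\log c - \log \theta)/\sigma)].}
#'
#' @param seed Integer seed; draws consume the R random stream, so a fixed
#'   seed before a run reproduces the trial sequence.
#' @param threshold Contrast (%) at which detection probability reaches the
#'   midpoint of the psychometric range.
#' @param slope Log-contrast slope parameter `sigma` (smaller = steeper).
#' @param lapse Lapse rate in \[0, 0.1\].
#' @return A function of contrast returning logical, with the generating
#'   parameters in attribute `ground_truth` and the probability function in
#'   attribute `p_correct`.  The convergence point of a three-down/one-up
#'   staircase (79.4% correct) is included as `ground_truth$c794`.
#' @export
gen_observer <- function(seed = 1, threshold = 10, slope = 0.35,
                         lapse = 0) {
  stopifnot(threshold > 0, slope > 0, lapse >= 0, lapse <= 0.1)
  set.seed(seed)
  p_correct <- function(contrast) {
    base <- 0.5 + 0.5 * stats::pnorm((log(pmax(contrast, 1e-9)) -
                                        log(threshold)) / slope)
    lapse / 2 + (1 - lapse) * base
  }
  # 79.4% correct point of the psychometric function (3-down/1-up target)
  target <- 0.5^(1 / 3)
  pr <- (target - lapse / 2) / (1 - lapse)
  c794 <- if (pr >= 1) Inf else
    exp(log(threshold) + slope * stats::qnorm(2 * pr - 1))
  obs <- function(contrast) stats::runif(1) < p_correct(contrast)
  structure(obs,
            p_correct = p_correct,
            ground_truth = list(seed = seed, threshold = threshold,
                                slope = slope, lapse = lapse, c794 = c794))
}
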