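# Shared fixtures: packaged configs and small helpers used across tests.

ref_low <- nw_config("reference_low_damping")
ref_mod <- nw_config("reference_moderate")
ref_2d <- nw_config("reference_2d")

wave_low <- wave_params(ref_low)
wave_mod <- wave_params(ref_mod)

period_low <- 2 * pi / wave_low$k_n

# A narrow Gaussian used as a delta-like input where grid deltas would
# introduce a cusp at the source (sigma well below the intrinsic period).
gaussian_stimulus <- function(j0 = 0.01, sigma = 2)
  stimulus_custom(function(x) exp(-x^2 / (2 * sigma^2)), j0 = j0)

# Grid covering several decay lengths around the origin for a wave object.
wave_grid <- function(w, half = NULL, samples_per_period = 32) {
  if (is.null(half)) half <- 6 / w$lam
  dx <- 2 * pi / w$k_n / samples_per_period
  seq(-half, half, by = dx)
}
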