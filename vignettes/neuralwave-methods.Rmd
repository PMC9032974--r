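---
title: "Neural wave interference: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural wave interference: models, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuralwave)
```

This vignette is the package's own account of its science: the circuit
model and its assumptions, the parameters that matter, the numerical
machinery, and the design choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The circuit model

The building block is a Wilson-Cowan motif: one excitatory (E) and one
inhibitory (I) unit, reciprocally and recurrently connected. Motifs are
repeated along a chain with complete nearest-neighbor connectivity
(`motif_weights()`); the stimulus current `j` is split `alpha` to E and
`1 - alpha` to I. Rates relax with time constant `tau_E` (excitation, in
units of the inhibitory relaxation time) through bounded sigmoids
`g_E`, `g_I`.

When activity varies on scales much longer than the motif spacing and far
from saturation, the chain is equivalent to a two-population
reaction-diffusion system (`continuum_params()`, `simulate_pde()`) with
local weights `W = w + 2*wt`, spread coefficients `D = wt`, and cubic
damping terms `gamma_E (tau_E dr_E/dt + r_E)^3`, `gamma_I (...)^3`
inherited from the third-order Taylor expansion of the sigmoids. One unit
of length is one motif spacing throughout; rates are dimensionless.

**Sigmoid form.** The activation nonlinearity is the symmetric logistic
`g(x) = (4/q)[sigma(q(x - theta)) - sigma(-q theta)]`
(`logistic_activation()`): monotone, bounded, `g(0) = 0` so quiescence is
always a fixed point, unit small-signal slope at `theta = 0`, saturation
`2/q`, and implied cubic coefficient `gamma = q^2 / 12`. This keeps the
chain, the continuum system, and the harmonic-balance analysis mutually
consistent: `continuum_from_motif()` carries `gamma` over automatically.

**Boundary conditions.** Defaults are absorbing (zero-value ghost nodes);
periodic boundaries are available for spectral checks. Domains should pad
the stimulus by several decay lengths `1/lambda`; the tests use 6-10.

## The intrinsic wave

With a plane-wave ansatz, the linearized static system yields a quartic
spatial characteristic polynomial in `s` (`exp(s x)` modes). In the
oscillatory regime its roots are `+/- lambda +/- i k_n`, defining the
intrinsic spatial frequency `k_n` and decay rate `lambda` of the standing
wave evoked by a point input. The amplitude coefficients `Gamma_E/I`,
`Delta_E/I` are obtained by residue calculus on the Fourier-space solution
— the closed-form equivalent of matching delta-input jump conditions — and
`wave_params()` verifies on return that the resulting Green's function
integrates to the static gain of the system (tolerance `1e-8`). Purely
real roots raise a "non-oscillatory regime" error reporting the
discriminant.

Responses to arbitrary static stimuli follow by superposition
(`linear_response()`): exact summation for point sources, discrete
convolution (trapezoid, `O(dx^2)`) for distributed profiles, with a
hard error if the grid samples the intrinsic period with fewer than 8
points.

## Packaged parameter sets

The weights behind the figures in the source literature are not public;
the packaged configurations (`nw_config()`) were therefore designed from
the wave descriptors themselves, by solving the characteristic polynomial
for prescribed `(k_n, lambda)` and checking stability:

* `reference_low_damping` — intrinsic period 20 motif spacings,
  `lambda/k_n = 0.04`. Linearly stable at every spatial mode of both the
  chain and the continuum system. Because damping is low, the resonant
  mode is nearly singular: amplification is ~4000-fold and its relaxation
  time is ~2e4 time units, so this circuit is analyzed analytically, not
  integrated to steady state.
* `reference_moderate` — `lambda/k_n = 0.3`, period 16. Settles in a few
  hundred time units; used for all numeric-vs-analytic oracles
  (chain vs Green's function, PDE vs superposition).
* `reference_2d` — the low-damping weights with `D/4`, halving the period
  to 10 lattice units so rings several wavelengths across fit on a modest
  lattice.
* `regime1`, `regime2` — resonance-analysis circuits on either side of the
  separatrix (see below).
* `contrast_up`, `contrast_down` — the low-damping circuit plus cubic
  coefficients with `gamma_E > gamma_I` (resonance rises with contrast)
  or `gamma_E < gamma_I` (falls).
* `nw_node_config()` — single-motif circuits for temporal interference,
  `alpha = 0.9` (excitation-dominated) and `alpha = 0.05`
  (inhibition-dominated), logistic gain 4.

## Linear resonance analysis

For drifting gratings the response is carried by four wave components
(cosine/sine x E/I) coupled by a 4x4 matrix `H` (`interaction_matrix()`),
solved by Cramer's rule with a direct-solve cross-check
(`solve_amplitudes()`). The determinant decomposes into a purely spatial
term, a purely temporal term, and a coupling term with weight-dependent
constants `mu, kappa_4, kappa_2, kappa_0` (`det_coefficients()`). The
constants are extracted in closed form and guarded by a numerical identity
check against `det(H)` at 100 frequency pairs (relative tolerance `1e-8`);
a mismatch is an error, not a warning. During development this guard
exposed a sign inconsistency in one published closed form for the
separatrix; the package uses the self-consistent extraction
(`kappa_2 = 2[(W_EE-1) D_EE + tau_E^2 (W_II+1) D_II - tau_E (W_EI D_IE + W_IE D_EI)]`),
which is the one that reproduces `det(H)` identically.

Resonance is defined as the minimum of `H` at fixed `omega` (spatial) or
fixed `k` (temporal), following the source analysis; the exact amplitude
argmax is also computed by `response_surface()` and the two coincide
closely at small `omega` but diverge at high `omega`, where the numerator
of the solution matters. `spatial_resonance()` solves the resonance
condition on the branch continuous with `sqrt(k_n^2 - lambda^2)` at
`omega = 0` (physical continuity is the tie-break when several roots
exist) and classifies the regime by `k_n^2 - lambda^2` vs `kappa_asymp`.

**A structural constraint worth knowing.** If the homogeneous state is
linearly stable at *every* spatial mode of the continuum system and the
wave is underdamped, one can show `kappa_2 < 0`, which forbids a positive
separatrix with `kappa_4 > 0` — i.e. the bounded-asymptote regime
structure cannot occur. The regime phenomenology requires inhibition to
spread farther than excitation (`D_II > D_EE / tau_E`), which
destabilizes sufficiently fine spatial modes of the continuum equations
(and of the discrete chain at zigzag scales). The packaged `regime1` and
`regime2` circuits therefore live in that lateral-inhibition regime: their
resonance band lies well inside the stable long-wavelength window the
algebra describes, and they are intended for the resonance analysis, not
for time integration. Chain and PDE simulations use the fully stable
reference circuits.

## Nonlinear (contrast-dependent) resonance

For static gratings, substituting single-harmonic solutions
`E cos(kx)`, `I cos(kx)` into the cubic system and discarding the third
harmonic leaves a 2x2 system whose matrix depends on the amplitudes
(`wave_interaction_matrix()`): the diagonal carries `-(3/4) gamma E^2`
self-terms. `iterate_amplitudes()` solves it by fixed-point iteration from
the linear solution, with under-relaxation 0.5 engaged automatically when
successive steps oppose each other; convergence is a step-size criterion
(default `1e-12`) and every converged state is re-checked against the
independent algebraic defect `||M(Y) Y - J0||`. The explicit regrouped
form of the map (`nonlinear_coefficients()`) is derived by expanding the
2x2 determinant to first order in `gamma`; its constants `eta, xi, sigma`
are proportional to `gamma_E`, `gamma_I` and the direction of the
contrast-induced resonance shift is `sign(xi_E - xi_I)` — with
`xi_E = -(3/8) gamma_E D_II / a_c`, `xi_I = -(3/8) gamma_I D_EE / a_c`,
where `a_c = D_EE D_II - D_EI D_IE`. The input amplitude `j0` is treated
as proportional to luminance contrast; the proportionality constant is
external to the model.

## Two-dimensional lattice and temporal interference

`simulate_lattice2d()` extends the continuum system isotropically
(five-point second differences with the same `D` along both axes). Linear
steady states are solved directly as one sparse block system (Matrix);
nonlinear runs are integrated in time. For an eccentric elliptical ring
stimulus the interior activation concentrates in two on-axis islands
(`detect_foci()`, `threshold_region()`). Geometrically these islands track
the cusps of the ellipse's evolute (the endpoints of its medial axis) at
`+/- (a^2 - b^2)/a`, which approach the classical foci
`+/- sqrt(a^2 - b^2)` as eccentricity grows; the packaged 2:1 ring
(a = 44, b = 22, normalized width 0.1 on the `reference_2d` circuit) puts
the converged peaks within half an intrinsic wavelength of the foci, and
the acceptance test checks that the peak positions are stable under 2x
grid refinement rather than that they hit the geometric foci exactly —
with a finite wavelength they cannot.

A single motif in the damped-oscillatory regime rings at its natural
period after a brief pulse; pulse trains interfere in time
(`node_oscillation()`). `duration_threshold()` reports the shortest
stimulus duration whose evoked excitatory trace satisfies a detection
criterion — by default a peak criterion (`r_E >= theta` at any time,
`theta` in rate units; an integral criterion is available because "just
visible" does not pin one down. The onset response is integrated once and
shared across candidate durations; offsets integrate their own rebound
tails). Under excitation-dominated input the threshold-vs-contrast curve
falls monotonically; under inhibition-dominated input the offset rebound
creates a nonmonotonic curve. The packaged `theta = 0.05` (about 5% of
the node's saturation rate) exhibits both regimes.

## Synthetic data and the empirical pipeline

`gen_tuning_dataset()` emulates the structure of the single-unit
experiments: an SF x TF x contrast grid (defaults: 8 log-spaced SFs from
0.03 to 2 cycles/deg, 5 TFs from 1 to 24 Hz, contrasts 2/7/14%,
10 trials per condition), log-Gaussian tuning surfaces whose preferred SF
shifts across contrast and with TF under a configurable regime rule, and
Gamma-distributed trial rates with variance proportional to the mean
(dispersion 1, Poisson-like spike-count variability). It does *not*
emulate spike timing, adaptation, serial dependence, eye movements, or
cell-to-cell heterogeneity beyond the planted surface — so passing
recovery tests show the pipeline's statistical machinery is correct, not
that real cortical data will be as well behaved.

`gen_sensitivity_profiles()` draws lateral contrast-sensitivity profiles
from the damped-harmonic family with a frequency shared across flanker
conditions (the model's signature) plus a pedestal and Gaussian noise;
probe distances default to 0-0.5 deg. `gen_observer()` provides a 2AFC
trial oracle with a cumulative-Gaussian psychometric function on log
contrast, guessing floor 0.5 and optional lapses; its 79.4%-correct point
(the three-down/one-up convergence level) is carried in the ground truth.

Pipeline choices:

* `sliding_kernel_curves()` averages trial rates in a window over the
  three stimulus dimensions, advancing one grid step along the slide
  dimension and labeling placements by the geometric mean of the included
  stimulus values (natural for log-spaced grids).
* `bootstrap_peak()` resamples 10 trials per condition with replacement,
  fits a local quadratic (loess on log stimulus, span 0.9 — on the 5-8
  point grids of these designs narrower spans are singular, so the
  "cross-validated bandwidth" ideal degenerates to this fixed choice;
  the span is exposed), records the fitted maximum, and repeats 500
  times. Flat fits are counted degenerate (more than 20% flags the
  estimate); maxima at the axis boundary are not tuning peaks and are
  excluded. A note on calibration: the 1-SD interval of a calibrated
  bootstrap covers the planted truth at the nominal ~68% rate, and the
  suite's coverage property test asserts exactly that band — not more.
* `compare_peaks()` applies the two-sided Wilcoxon rank-sum test to the
  resampled peak distributions with a strict `p < 0.05` rule. Testing
  bootstrap replicates inflates nominal significance; a percentile-
  interval classification is returned alongside for reference.
* `fit_damped_harmonic()` multi-starts `minpack.lm::nlsLM` over frequency
  and phase grids (short damped profiles have many local minima), returns
  the best fit plus alternatives within 5% residual, and flags fitted
  frequencies near zero as "no modulation" (the pure-decay null, which
  `decay_null_xmin()` characterizes analytically: a two-sided exponential
  decay has exactly one interior extremum).
* `run_staircase()` implements the printed protocol: start 40%, step down
  after three consecutive correct responses, up after one error, 12%
  steps until the second reversal then 3%, 30 trials, threshold = mean of
  the last five presented contrasts.

## Numerical choices and problem sizes

Time integration is fixed-step classical Runge-Kutta (deSolve) with an
optional step-halving validation; steady state is declared at
`max |dr/dt| < 1e-8` by default (configurable; long-settling runs in the
tests use `1e-6`-`1e-7` with explicit horizons). The cubic damping is
handled exactly by solving the scalar cubic `y + gamma y^3 = C` per node
and step via the hyperbolic closed form. Delta inputs are deposited as
`j0/dx` on the nearest node; analytic-vs-numeric comparisons use a narrow
Gaussian instead because a grid delta's cusp converges only at `O(dx)`.
Dominant lateral frequencies are estimated from zero-crossing spacing
(primary) and a Hann-windowed periodogram (cross-check) because short
damped segments bias raw FFT peaks. The test suite runs chain/PDE oracles
at 100-200 units of domain and 512 grid nodes, 2D runs at 61-229^2
lattices, and the empirical recovery studies at 12-20 replicates with
150-500 bootstrap iterations; `scripts/acceptance.R` sweeps separations
at 0.005 periods on a 32-samples-per-period grid.

## Known limitations

* The analytic machinery is linear or weakly nonlinear (single-harmonic
  balance); strongly saturated regimes are only accessible through the
  simulators.
* The regime-1/regime-2 circuits are meaningful for the long-wavelength
  resonance algebra only; their continuum equations are unstable at fine
  spatial scales (see the structural constraint above).
* Nonlinear forced dynamics at `omega != 0` (drifting gratings beyond the
  linear regime) are out of scope, as are anisotropic or long-range
  couplings and multi-layer architectures.
* Wave focusing inside eccentric rings lands on the medial-axis/evolute
  cusps, near — not at — the geometric foci; statements about "foci" are
  wavelength-limited approximations.
* The synthetic generators are structural emulations with planted ground
  truth, not fits to any recorded dataset.
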