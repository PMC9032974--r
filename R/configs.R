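#' Packaged reference parameter sets
#'
#' Named circuit configurations shipped with the package.  All values were
#' fixed at design time by solving the spatial characteristic polynomial for
#' prescribed wave descriptors; they are not fitted to any data.
#'
#' \describe{
#'   \item{`reference_low_damping`}{The default simulation circuit: intrinsic
#'     spatial period of 20 motif spacings (`k_n = 2*pi/20`) with low damping
#'     (`lam/k_n = 0.04`), linearly stable at every spatial mode of both the
#'     discrete chain and the continuum system.  Used for interference maps,
#'     zone-1/zone-2 analyses and all time integrations.}
#'   \item{`regime1`}{Resonance-analysis circuit in which the spatial
#'     resonance rises with stimulus temporal frequency toward the separatrix
#'     (`k_n^2 - lam^2 < kappa_asymp`).}
#'   \item{`regime2`}{Resonance-analysis circuit in which the spatial
#'     resonance falls with temporal frequency toward the separatrix
#'     (`k_n^2 - lam^2 > kappa_asymp`).}
#'   \item{`contrast_up`}{`reference_low_damping` plus a cubic nonlinearity
#'     dominated by the excitatory population (`xi_E > xi_I`): the resonance
#'     frequency increases with stimulus contrast.}
#'   \item{`contrast_down`}{The converse (`xi_I > xi_E`): the resonance
#'     frequency decreases with contrast.}
#'   \item{`reference_moderate`}{A moderately damped variant
#'     (`lam/k_n = 0.3`, intrinsic period 16) whose near-resonant mode
#'     relaxes quickly enough for time integration to reach steady state in
#'     a few hundred time units; the workhorse for numeric-vs-analytic
#'     cross-checks.  (The low-damping circuit's resonant mode relaxes over
#'     ~2e4 time units, so it is analyzed analytically.)}
#'   \item{`reference_2d`}{`reference_low_damping` with all spread
#'     coefficients divided by 4, halving the intrinsic period to 10 lattice
#'     units so that two-dimensional stimuli several wavelengths across fit
#'     on a modest lattice.  Used for the elliptical-ring focusing runs
#'     (packaged ring: semi-axes 44 x 22, normalized width 0.1).}
#' }
#'
#' The two `regime*` configurations put the circuit in the
#' lateral-inhibition-spread regime (`D_II > D_EE / tau_E`) that the
#' bounded-asymptote resonance structure requires; there the continuum
#' equations are intended for the long-wavelength resonance algebra, and the
#' time-domain simulators should use `reference_low_damping` (see the
#' methods vignette).
#'
#' @param name Configuration name.
#' @return An `nw_continuum_params` object.
#' @examples
#' p <- nw_config("reference_low_damping")
#' wave_params(p)
#' @export
nw_config <- function(name = c("reference_low_damping", "regime1", "regime2",
                               "contrast_up", "contrast_down",
                               "reference_2d", "reference_moderate")) {
  name <- match.arg(name)
  base_low <- list(W_EE = 1.2, W_EI = 0.573684, W_IE = 0.573684, W_II = 0.6,
                   D_EE = 0.6, D_EI = 1.040453, D_IE = 1.040453, D_II = 0.25,
                   tau_E = 1, alpha = 0.5)
  cfg <- switch(name,
    reference_low_damping = base_low,
    regime1 = list(W_EE = 2.27243, W_EI = 1.33830, W_IE = 1.33830,
                   W_II = 0.40501, D_EE = 0.15, D_EI = 0.37283,
                   D_IE = 0.37283, D_II = 0.6, tau_E = 1.2, alpha = 0.5),
    regime2 = list(W_EE = 2.26395, W_EI = 1.24454, W_IE = 1.24454,
                   W_II = 0.21032, D_EE = 0.15, D_EI = 0.40631,
                   D_IE = 0.40631, D_II = 0.6, tau_E = 1.2, alpha = 0.5),
    contrast_up = c(base_low[1:10], list(gamma_E = 1, gamma_I = 0.05)),
    contrast_down = c(base_low[1:10], list(gamma_E = 0.05, gamma_I = 1)),
    reference_2d = utils::modifyList(base_low,
      lapply(base_low[c("D_EE", "D_EI", "D_IE", "D_II")], `/`, 4)),
    reference_moderate = utils::modifyList(base_low,
      list(W_EI = 0.5920358, W_IE = 0.5920358,
           D_EI = 1.108913, D_IE = 1.108913)))
  do.call(continuum_params, cfg)
}

#' Packaged single-node configurations
#'
#' Single Wilson-Cowan motifs used by the temporal-interference analyses.
#' Both are in the damped-oscillatory regime; they differ in the input split
#' `alpha`: `node_excitatory` routes most input to the excitatory cell
#' (duration thresholds decline monotonically with contrast) and
#' `node_inhibitory` routes most input to the inhibitory cell
#' (nonmonotonic duration thresholds).
#'
#' @param name Configuration name.
#' @param gain Logistic gain of both activation sigmoids (saturating; the
#'   default keeps responses bounded under strong input).
#' @return An `nw_motif_weights` object.
#' @export
nw_node_config <- function(name = c("node_excitatory", "node_inhibitory"),
                           gain = 4) {
  name <- match.arg(name)
  alpha <- switch(name, node_excitatory = 0.9, node_inhibitory = 0.05)
  motif_weights(w_EE = 1.5, w_EI = 2, w_IE = 2, w_II = 0.5,
                tau_E = 1, alpha = alpha,
                act_E = logistic_activation(gain = gain),
                act_I = logistic_activation(gain = gain))
}

#' Load circuit parameters from a YAML or JSON config file
#'
#' Reads a parameter file whose keys mirror the fields of
#' [continuum_params()] (`W_EE`, ..., `D_II`, `tau_E`, `alpha`, `gamma_E`,
#' `gamma_I`) or of [motif_weights()] (`w_EE`, ..., `wt_II`, plus optional
#' `gain_E`, `gain_I`, `threshold_E`, `threshold_I` describing logistic
#' activations).  Unknown keys are rejected by name; omitted optional keys
#' take the documented defaults, and the injected defaults are recorded in
#' the returned object's `"defaults_injected"` attribute.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `nw_continuum_params` or `nw_motif_weights` object (decided by
#'   whether the file uses `W_*` or `w_*`/`wt_*` keys).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a mapping of parameter names")
  cont_keys <- c("W_EE", "W_EI", "W_IE", "W_II",
                 "D_EE", "D_EI", "D_IE", "D_II",
                 "tau_E", "alpha", "gamma_E", "gamma_I")
  motif_keys <- c("w_EE", "w_EI", "w_IE", "w_II",
                  "wt_EE", "wt_EI", "wt_IE", "wt_II",
                  "tau_E", "alpha", "gain_E", "gain_I",
                  "threshold_E", "threshold_I")
  is_cont <- any(names(raw) %in% cont_keys[1:8])
  keys <- if (is_cont) cont_keys else motif_keys
  unknown <- setdiff(names(raw), keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  bad <- names(raw)[!vapply(raw, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad))
    stop("config value(s) must be finite scalars: ",
         paste(bad, collapse = ", "))
  if (is_cont) {
    required <- cont_keys[1:8]
    missing <- setdiff(required, names(raw))
    if (length(missing))
      stop("missing required key(s): ", paste(missing, collapse = ", "))
    defaults <- list(tau_E = 1, alpha = 0.5, gamma_E = 0, gamma_I = 0)
    injected <- setdiff(names(defaults), names(raw))
    args <- utils::modifyList(defaults, raw)
    out <- do.call(continuum_params, args)
  } else {
    required <- motif_keys[1:4]
    missing <- setdiff(required, names(raw))
    if (length(missing))
      stop("missing required key(s): ", paste(missing, collapse = ", "))
    defaults <- list(wt_EE = 0, wt_EI = 0, wt_IE = 0, wt_II = 0,
                     tau_E = 1, alpha = 0.5)
    injected <- setdiff(names(defaults), names(raw))
    act <- function(gain, thr) {
      if (is.null(gain)) linear_activation()
      else logistic_activation(gain, if (is.null(thr)) 0 else thr)
    }
    args <- utils::modifyList(defaults, raw)
    args$act_E <- act(args$gain_E, args$threshold_E)
    args$act_I <- act(args$gain_I, args$threshold_I)
    args$gain_E <- args$gain_I <- args$threshold_E <- args$threshold_I <- NULL
    out <- do.call(motif_weights, args)
  }
  attr(out, "defaults_injected") <- injected
  attr(out, "config_path") <- path
  out
}

#' Write circuit parameters to a YAML config file
#'
#' Inverse of [load_config()] for continuum parameters: dumping and
#' reloading a config yields an identical parameter object.
#'
#' @param p An `nw_continuum_params` object.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "nw_continuum_params"))
  yaml::write_yaml(unclass(p)[c("W_EE", "W_EI", "W_IE", "W_II",
                                "D_EE", "D_EI", "D_IE", "D_II",
                                "tau_E", "alpha", "gamma_E", "gamma_I")],
                   path)
  invisible(path)
}
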