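#' Synaptic weights of the discrete motif chain
#'
#' Parameterizes a chain of Wilson-Cowan motifs.  Each motif holds one
#' excitatory (E) and one inhibitory (I) unit; `w_*` are the within-motif
#' weights and `wt_*` the weights of connections to each of the two nearest
#' neighbor motifs.  The stimulus current `j` is split between the two cell
#' types: the excitatory units receive `alpha * j` and the inhibitory units
#' `(1 - alpha) * j`.
#'
#' @param w_EE,w_EI,w_IE,w_II Within-motif weights (all finite; the sign
#'   convention is that inhibitory contributions are subtracted, so weights are
#'   given as nonnegative magnitudes).
#' @param wt_EE,wt_EI,wt_IE,wt_II Nearest-neighbor (between-motif) weights.
#' @param tau_E Relaxation time of excitation, in units of the inhibitory
#'   relaxation time.  Must be positive.
#' @param alpha Fraction of input current delivered to excitatory cells, in
#'   \[0, 1\].
#' @param act_E,act_I Activation functions of the two cell types; see
#'   [logistic_activation()].  Default is the identity (linear chain).
#' @return An object of class `nw_motif_weights`.
#' @seealso [continuum_from_motif()] for the continuum-limit parameters.
#' @export
motif_weights <- function(w_EE, w_EI, w_IE, w_II,
                          wt_EE = 0, wt_EI = 0, wt_IE = 0, wt_II = 0,
                          tau_E = 1, alpha = 0.5,
                          act_E = linear_activation(),
                          act_I = linear_activation()) {
  vals <- c(w_EE = w_EE, w_EI = w_EI, w_IE = w_IE, w_II = w_II,
            wt_EE = wt_EE, wt_EI = wt_EI, wt_IE = wt_IE, wt_II = wt_II)
  if (!all(is.finite(vals)))
    stop("all motif weights must be finite")
  if (!is.numeric(tau_E) || length(tau_E) != 1L || tau_E <= 0)
    stop("tau_E must be a positive scalar")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  stopifnot(inherits(act_E, "nw_activation"), inherits(act_I, "nw_activation"))
  structure(list(w_EE = w_EE, w_EI = w_EI, w_IE = w_IE, w_II = w_II,
                 wt_EE = wt_EE, wt_EI = wt_EI, wt_IE = wt_IE, wt_II = wt_II,
                 tau_E = tau_E, alpha = alpha,
                 act_E = act_E, act_I = act_I),
            class = "nw_motif_weights")
}

#' Continuum-limit parameters of the distributed circuit
#'
#' Parameterizes the two-population reaction-diffusion system obtained in the
#' continuum limit of the motif chain.  The local weights `W_xy` collect the
#' within-motif weight plus both neighbors (`W = w + 2*wt`) and the spread
#' coefficients `D_xy` equal the neighbor weight (`D = wt`), with one motif
#' spacing as the unit of length.  `gamma_E`, `gamma_I` are the cubic Taylor
#' coefficients of the activation sigmoids and control amplitude saturation
#' at high input.
#'
#' @param W_EE,W_EI,W_IE,W_II Local interaction weights.
#' @param D_EE,D_EI,D_IE,D_II Spatial-spread coefficients.
#' @param tau_E Excitatory relaxation time (units of inhibitory relaxation).
#' @param alpha Excitatory share of the input current, in \[0, 1\].
#' @param gamma_E,gamma_I Cubic nonlinearity coefficients (nonnegative; 0
#'   gives the linear system).
#' @return An object of class `nw_continuum_params`.
#' @export
continuum_params <- function(W_EE, W_EI, W_IE, W_II,
                             D_EE, D_EI, D_IE, D_II,
                             tau_E = 1, alpha = 0.5,
                             gamma_E = 0, gamma_I = 0) {
  vals <- c(W_EE = W_EE, W_EI = W_EI, W_IE = W_IE, W_II = W_II,
            D_EE = D_EE, D_EI = D_EI, D_IE = D_IE, D_II = D_II)
  if (!all(is.finite(vals)))
    stop("all continuum coefficients must be finite")
  if (!is.numeric(tau_E) || length(tau_E) != 1L || tau_E <= 0)
    stop("tau_E must be a positive scalar")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (gamma_E < 0 || gamma_I < 0)
    stop("gamma_E and gamma_I must be nonnegative")
  structure(list(W_EE = W_EE, W_EI = W_EI, W_IE = W_IE, W_II = W_II,
                 D_EE = D_EE, D_EI = D_EI, D_IE = D_IE, D_II = D_II,
                 tau_E = tau_E, alpha = alpha,
                 gamma_E = gamma_E, gamma_I = gamma_I),
            class = "nw_continuum_params")
}

#' Continuum parameters from motif weights
#'
#' Maps the discrete chain parameterization to the continuum one:
#' `W_xy = w_xy + 2 * wt_xy` and `D_xy = wt_xy` for all four index pairs,
#' with `tau_E` and `alpha` passed through and the cubic coefficients taken
#' from the activation sigmoids.
#'
#' @param m An `nw_motif_weights` object.
#' @return An `nw_continuum_params` object.
#' @examples
#' m <- motif_weights(w_EE = 1, w_EI = 0.3, w_IE = 1, w_II = 0,
#'                    wt_EE = 0.5, wt_EI = 0.1)
#' p <- continuum_from_motif(m)
#' p$W_EE  # 2.0
#' p$D_EE  # 0.5
#' @export
continuum_from_motif <- function(m) {
  stopifnot(inherits(m, "nw_motif_weights"))
  continuum_params(
    W_EE = m$w_EE + 2 * m$wt_EE, W_EI = m$w_EI + 2 * m$wt_EI,
    W_IE = m$w_IE + 2 * m$wt_IE, W_II = m$w_II + 2 * m$wt_II,
    D_EE = m$wt_EE, D_EI = m$wt_EI, D_IE = m$wt_IE, D_II = m$wt_II,
    tau_E = m$tau_E, alpha = m$alpha,
    gamma_E = activation_gamma(m$act_E), gamma_I = activation_gamma(m$act_I))
}

#' Motif weights from continuum parameters
#'
#' Inverse of [continuum_from_motif()]: recovers the chain weights
#' `wt_xy = D_xy`, `w_xy = W_xy - 2 * D_xy`.  Activation sigmoids are chosen
#' as logistic functions whose cubic coefficients match `gamma_E`, `gamma_I`
#' (identity activations when both are 0).
#'
#' @param p An `nw_continuum_params` object.
#' @return An `nw_motif_weights` object.
#' @export
motif_from_continuum <- function(p) {
  stopifnot(inherits(p, "nw_continuum_params"))
  act <- function(g) if (g > 0) logistic_activation(gain = sqrt(12 * g)) else
    linear_activation()
  motif_weights(
    w_EE = p$W_EE - 2 * p$D_EE, w_EI = p$W_EI - 2 * p$D_EI,
    w_IE = p$W_IE - 2 * p$D_IE, w_II = p$W_II - 2 * p$D_II,
    wt_EE = p$D_EE, wt_EI = p$D_EI, wt_IE = p$D_IE, wt_II = p$D_II,
    tau_E = p$tau_E, alpha = p$alpha,
    act_E = act(p$gamma_E), act_I = act(p$gamma_I))
}

#' @export
print.nw_motif_weights <- function(x, ...) {
  cat("<nw_motif_weights>\n")
  cat(sprintf("  within-motif  w:  EE=%.4g EI=%.4g IE=%.4g II=%.4g\n",
              x$w_EE, x$w_EI, x$w_IE, x$w_II))
  cat(sprintf("  neighbor      wt: EE=%.4g EI=%.4g IE=%.4g II=%.4g\n",
              x$wt_EE, x$wt_EI, x$wt_IE, x$wt_II))
  cat(sprintf("  tau_E=%.4g  alpha=%.4g  gamma_E=%.4g  gamma_I=%.4g\n",
              x$tau_E, x$alpha,
              activation_gamma(x$act_E), activation_gamma(x$act_I)))
  invisible(x)
}

#' @export
print.nw_continuum_params <- function(x, ...) {
  cat("<nw_continuum_params>\n")
  cat(sprintf("  W: EE=%.4g EI=%.4g IE=%.4g II=%.4g\n",
              x$W_EE, x$W_EI, x$W_IE, x$W_II))
  cat(sprintf("  D: EE=%.4g EI=%.4g IE=%.4g II=%.4g\n",
              x$D_EE, x$D_EI, x$D_IE, x$D_II))
  cat(sprintf("  tau_E=%.4g  alpha=%.4g  gamma_E=%.4g  gamma_I=%.4g\n",
              x$tau_E, x$alpha, x$gamma_E, x$gamma_I))
  invisible(x)
}
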