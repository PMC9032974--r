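# Analysis procedures for trial-wise tuning data and lateral-sensitivity
# profiles: sliding-kernel aggregation, bootstrap peak estimation with a
# smooth regression fit, rank-sum peak comparison, damped-harmonic fitting
# of contrast-sensitivity profiles, and the adaptive staircase protocol.

#' Sliding-kernel aggregation of tuning data
#'
#' Averages trial-wise firing rates within a kernel spanning a window of
#' grid values on each stimulus dimension (spatial frequency, temporal
#' frequency, contrast), sliding the kernel one grid step at a time along
#' one dimension.  Each kernel placement is labeled by the geometric mean of
#' the stimulus values it contains, which is the natural center for
#' log-spaced frequency and contrast grids.
#'
#' @param d A tuning data.frame with columns `sf`, `tf`, `contrast`,
#'   `trial`, `rate` (see [gen_tuning_dataset()]).
#' @param window Named integer vector of window sizes in grid steps, e.g.
#'   `c(sf = 4, tf = 1, contrast = 3)`.  Every size must be >= 1 and no
#'   larger than the grid extent of its dimension.
#' @param slide Name of the dimension along which the kernel slides.
#' @return A data.frame with one row per kernel placement: the geometric-
#'   mean center of each dimension, the mean rate over all (condition,
#'   trial) cells in the window, and `n_cells`.
#' @export
sliding_kernel_curves <- function(d, window, slide = "tf") {
  dims <- c("sf", "tf", "contrast")
  stopifnot(all(dims %in% names(d)), "rate" %in% names(d),
            slide %in% dims, all(dims %in% names(window)))
  grids <- lapply(dims, function(v) sort(unique(d[[v]])))
  names(grids) <- dims
  for (v in dims) {
    if (window[[v]] < 1 || window[[v]] > length(grids[[v]]))
      stop(sprintf("window for '%s' must be in [1, %d]", v,
                   length(grids[[v]])))
  }
  # fixed windows on the non-slide dimensions: first `window` values
  fixed <- setdiff(dims, slide)
  sel_fixed <- lapply(fixed, function(v) grids[[v]][seq_len(window[[v]])])
  names(sel_fixed) <- fixed
  n_slide <- length(grids[[slide]]) - window[[slide]] + 1L
  out <- vector("list", n_slide)
  for (i in seq_len(n_slide)) {
    sel_slide <- grids[[slide]][i + seq_len(window[[slide]]) - 1L]
    keep <- d[[slide]] %in% sel_slide
    for (v in fixed) keep <- keep & d[[v]] %in% sel_fixed[[v]]
    if (!any(keep))
      stop(sprintf("empty kernel window at %s placement %d", slide, i))
    row <- list(rate = mean(d$rate[keep]), n_cells = sum(keep))
    row[[slide]] <- exp(mean(log(sel_slide)))
    for (v in fixed) row[[v]] <- exp(mean(log(sel_fixed[[v]])))
    out[[i]] <- as.data.frame(row)
  }
  res <- do.call(rbind, out)
  res[, c(dims, "rate", "n_cells")]
}

# Smooth regression fit across a (log-spaced) stimulus axis and location of
# its maximum on a fine grid.  Local quadratic (loess) when there are
# enough points; global quadratic otherwise.  Axis handled in log units.
fit_tuning_peak <- function(x, y, span = 0.9, n_fine = 201) {
  lx <- log(x)
  if (diff(range(y)) < 1e-12 * max(abs(y), 1))
    return(list(peak = NA_real_, degenerate = TRUE, boundary = FALSE))
  fit <- if (length(x) >= 6) {
    tryCatch(
      stats::loess(y ~ lx, span = span, degree = 2,
                   control = stats::loess.control(surface = "direct")),
      error = function(e) NULL)
  } else NULL
  fine <- seq(min(lx), max(lx), length.out = n_fine)
  pred <- if (!is.null(fit)) stats::predict(fit, data.frame(lx = fine)) else {
    cf <- stats::lm(y ~ lx + I(lx^2))
    stats::predict(cf, data.frame(lx = fine))
  }
  i <- which.max(pred)
  list(peak = exp(fine[i]), degenerate = FALSE,
       boundary = i == 1L || i == n_fine)
}

#' Bootstrap estimation of a tuning peak
#'
#' Estimates the preferred stimulus value and its error by trial resampling:
#' on each iteration the trials of every condition are resampled with
#' replacement (`n_samples` draws), a smooth regression is fitted across the
#' stimulus axis, and the location of the fitted maximum is recorded.  The
#' estimate is the mean peak over iterations and its spread the standard
#' deviation.  Iterations whose fitted curve is flat are counted as
#' degenerate; peaks at the axis boundary are not tuning peaks and are
#' excluded (and counted).
#'
#' @param trials A data.frame with columns `x` (stimulus value, e.g. sf or
#'   tf) and `rate`, several rows (trials) per `x`.
#' @param n_samples Number of resampled trials per condition (default 10).
#' @param n_iter Number of resampling iterations (default 500).
#' @param span Loess span of the smooth fit.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `nw_peak_estimate`: list with `peak` (mean
#'   over valid iterations), `sd`, `samples` (the per-iteration peaks),
#'   `n_iter`, `n_degenerate`, `n_boundary`, and `flagged` (`TRUE` when more
#'   than 20% of iterations were degenerate).
#' @export
bootstrap_peak <- function(trials, n_samples = 10, n_iter = 500,
                           span = 0.9, seed = NULL) {
  stopifnot(all(c("x", "rate") %in% names(trials)))
  if (!is.null(seed)) set.seed(seed)
  xs <- sort(unique(trials$x))
  if (length(xs) < 3) stop("need at least 3 stimulus values")
  by_x <- split(trials$rate, trials$x)
  peaks <- numeric(0)
  n_deg <- 0L; n_bound <- 0L
  for (it in seq_len(n_iter)) {
    means <- vapply(by_x, function(r)
      mean(sample(r, n_samples, replace = TRUE)), numeric(1))
    ft <- fit_tuning_peak(xs, means, span = span)
    if (ft$degenerate) n_deg <- n_deg + 1L
    else if (ft$boundary) n_bound <- n_bound + 1L
    else peaks <- c(peaks, ft$peak)
  }
  if (length(peaks) == 0)
    stop("no valid (non-degenerate, interior) peak in any iteration")
  structure(list(peak = mean(peaks), sd = stats::sd(peaks), samples = peaks,
                 n_iter = n_iter, n_degenerate = n_deg,
                 n_boundary = n_bound,
                 flagged = n_deg > 0.2 * n_iter),
            class = "nw_peak_estimate")
}

#' @export
print.nw_peak_estimate <- function(x, ...) {
  cat(sprintf("<nw_peak_estimate> peak = %.4g (SD %.3g, %d/%d valid iterations%s)\n",
              x$peak, x$sd, length(x$samples), x$n_iter,
              if (x$flagged) ", FLAGGED: >20% degenerate" else ""))
  invisible(x)
}

#' Compare two bootstrap peak distributions
#'
#' Two-sided Wilcoxon rank-sum test on the resampled peak locations of two
#' conditions, classifying the change as increased (`"up"`), decreased
#' (`"down"`), or no change (`"none"`) at the strict `p < alpha` rule.
#' Note that testing bootstrap replicates inflates nominal significance
#' relative to a test on raw trials; a percentile-interval classification is
#' returned alongside as `direction_ci` for reference.
#'
#' @param a,b `nw_peak_estimate` objects (or numeric vectors of resampled
#'   peaks); the comparison is b relative to a.
#' @param alpha Significance level (default 0.05, strict inequality).
#' @return List with `direction` (`"up"`, `"down"`, `"none"`), `p_value`,
#'   `estimate_a`, `estimate_b`, and `direction_ci` (sign of the difference
#'   of 95% percentile intervals).
#' @export
compare_peaks <- function(a, b, alpha = 0.05) {
  sa <- if (inherits(a, "nw_peak_estimate")) a$samples else a
  sb <- if (inherits(b, "nw_peak_estimate")) b$samples else b
  if (length(sa) < 3 || length(sb) < 3)
    stop("insufficient resampled peaks for comparison")
  wt <- stats::wilcox.test(sb, sa, exact = FALSE)
  dir <- if (wt$p.value < alpha) {
    if (stats::median(sb) > stats::median(sa)) "up" else "down"
  } else "none"
  qa <- stats::quantile(sa, c(0.025, 0.975), names = FALSE)
  qb <- stats::quantile(sb, c(0.025, 0.975), names = FALSE)
  dir_ci <- if (qb[1] > qa[2]) "up" else if (qb[2] < qa[1]) "down" else "none"
  list(direction = dir, p_value = wt$p.value,
       estimate_a = mean(sa), estimate_b = mean(sb), direction_ci = dir_ci)
}

#' Fit a damped harmonic to a lateral sensitivity profile
#'
#' Least-squares fit of the damped harmonic
#' \deqn{S(d) = O\, e^{-d^2 / (2 c^2)} \cos(2\pi f d + \phi)}
#' to contrast sensitivity as a function of distance `d` from the stimulus
#' edge.  The fit is multi-started over a grid of frequencies and phases
#' (short, decaying profiles have many local minima) and the best fit is
#' returned along with all alternative starts whose residual sum of squares
#' is within 5% of the best.
#'
#' @param distance,sensitivity Numeric vectors (>= 6 points).
#' @param f_grid Candidate starting frequencies (cycles per unit distance).
#'   Defaults to 12 values spanning 0.25-2 cycles over the profile extent.
#' @param phi_grid Candidate starting phases.
#' @param f_zero_tol Fitted frequencies below this value are flagged
#'   `"no modulation"` (a pure-decay family member).
#' @return An object of class `nw_damped_harmonic_fit`: list with `O`, `c`,
#'   `f`, `phi`, `rss`, `fitted`, `residuals`, `no_modulation`, and
#'   `alternatives` (data.frame of near-equivalent fits).
#' @export
fit_damped_harmonic <- function(distance, sensitivity, f_grid = NULL,
                                phi_grid = c(0, pi / 2, pi, 3 * pi / 2),
                                f_zero_tol = 1e-3) {
  stopifnot(length(distance) == length(sensitivity))
  if (length(distance) < 6)
    stop("need at least 6 distance points for a damped-harmonic fit")
  span <- diff(range(distance))
  if (is.null(f_grid)) f_grid <- seq(0.25, 2, length.out = 12) / span
  dat <- data.frame(d = distance, s = sensitivity)
  best <- NULL
  all_fits <- list()
  for (f0 in f_grid) for (p0 in phi_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        s ~ O * exp(-d^2 / (2 * cc^2)) * cos(2 * pi * f * d + phi),
        data = dat,
        start = list(O = max(abs(sensitivity)), cc = span, f = f0, phi = p0),
        lower = c(O = 0, cc = 1e-4, f = 0, phi = -2 * pi),
        upper = c(O = Inf, cc = Inf, f = max(f_grid) * 4, phi = 2 * pi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    cf <- stats::coef(fit)
    all_fits[[length(all_fits) + 1L]] <-
      data.frame(O = cf[["O"]], c = cf[["cc"]], f = cf[["f"]],
                 phi = cf[["phi"]], rss = rss)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss, cf = cf)
  }
  if (is.null(best))
    stop("damped-harmonic fit failed to converge from every start")
  alt <- do.call(rbind, all_fits)
  alt <- alt[alt$rss <= best$rss * 1.05, , drop = FALSE]
  alt <- alt[!duplicated(round(alt$f, 6)), , drop = FALSE]
  cf <- best$cf
  structure(list(O = cf[["O"]], c = cf[["cc"]], f = cf[["f"]],
                 phi = cf[["phi"]], rss = best$rss,
                 fitted = stats::fitted(best$fit),
                 residuals = stats::residuals(best$fit),
                 no_modulation = cf[["f"]] < f_zero_tol,
                 alternatives = alt),
            class = "nw_damped_harmonic_fit")
}

#' @export
print.nw_damped_harmonic_fit <- function(x, ...) {
  cat(sprintf("<nw_damped_harmonic_fit> O = %.4g, c = %.4g, f = %.4g, phi = %.3g (rss %.3g)%s\n",
              x$O, x$c, x$f, x$phi, x$rss,
              if (x$no_modulation) " [no modulation]" else ""))
  invisible(x)
}

#' Three-down/one-up adaptive staircase
#'
#' Runs the adaptive staircase protocol on a simulated (or real) observer:
#' probe contrast starts at `start`, is reduced after three consecutive
#' correct responses and increased after any incorrect response.  Steps are
#' `step_initial` until the second reversal, then `step_final`.  The run
#' terminates after `n_trials` trials and the threshold is the mean of the
#' last five contrast values selected by the procedure.  The asymptotic
#' convergence point of a three-down/one-up rule is the 79.4%-correct level
#' of the observer's psychometric function.
#'
#' @param observer A function of probe contrast returning `TRUE` (correct)
#'   or `FALSE`; see [gen_observer()].
#' @param start Initial contrast (%).
#' @param step_initial,step_final Step sizes (%) before/after the second
#'   reversal.
#' @param n_trials Number of trials (default 30).
#' @param floor,ceiling Contrast limits; clipping is logged in the trial
#'   log.
#' @return An object of class `nw_staircase`: list with `threshold`,
#'   `trials` (data.frame `trial`, `contrast`, `correct`, `reversal`,
#'   `clipped`), and `n_reversals`.
#' @export
run_staircase <- function(observer, start = 40, step_initial = 12,
                          step_final = 3, n_trials = 30,
                          floor = 0, ceiling = 100) {
  stopifnot(is.function(observer))
  contrast <- start
  n_correct <- 0L
  n_reversals <- 0L
  last_dir <- 0L
  log <- data.frame(trial = integer(), contrast = numeric(),
                    correct = logical(), reversal = logical(),
                    clipped = logical())
  for (tr in seq_len(n_trials)) {
    correct <- isTRUE(observer(contrast))
    move <- 0L
    if (!correct) {
      n_correct <- 0L
      move <- 1L
    } else {
      n_correct <- n_correct + 1L
      if (n_correct == 3L) {
        n_correct <- 0L
        move <- -1L
      }
    }
    reversal <- move != 0L && last_dir != 0L && move != last_dir
    if (reversal) n_reversals <- n_reversals + 1L
    step <- if (n_reversals < 2L) step_initial else step_final
    new_contrast <- contrast + move * step
    clipped <- new_contrast < floor || new_contrast > ceiling
    new_contrast <- min(max(new_contrast, floor), ceiling)
    log <- rbind(log, data.frame(trial = tr, contrast = contrast,
                                 correct = correct, reversal = reversal,
                                 clipped = clipped))
    if (move != 0L) last_dir <- move
    contrast <- new_contrast
  }
  threshold <- mean(utils::tail(log$contrast, 5))
  structure(list(threshold = threshold, trials = log,
                 n_reversals = n_reversals),
            class = "nw_staircase")
}

#' @export
print.nw_staircase <- function(x, ...) {
  cat(sprintf("<nw_staircase> threshold = %.3g%% (%d trials, %d reversals)\n",
              x$threshold, nrow(x$trials), x$n_reversals))
  invisible(x)
}
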