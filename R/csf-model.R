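# Contrast-sensitivity predictions: neuronal sensitivity envelope across SF,
# the signal-detection psychometric surface, and the predicted CSF.

#' Neuronal sensitivity envelope
#'
#' Parameterizes how the best (smallest) contrast semi-saturation constant of
#' the population varies with preferred SF: a bell-shaped envelope whose
#' minimum `c_min` sits at the SF `a * b` (the same three-parameter shape
#' used for behavioural CSFs, inverted).
#'
#' @param c_min Best semi-saturation constant across all SFs (> 0).
#' @param a Shape exponent (> 0).
#' @param b Scale, c/d (> 0).
#' @return Object of class `neuronal_sensitivity`.
#' @export
neuronal_sensitivity <- function(c_min, a, b) {
  stopifnot(c_min > 0, a > 0, b > 0)
  structure(list(c_min = c_min, a = a, b = b),
            class = "neuronal_sensitivity")
}

#' Best semi-saturation constant at a preferred SF
#'
#' `c_k_min(f) = c_min * ((a b)^a e^-a) / (f^a e^(-f/b))`; equals `c_min`
#' exactly at `f = a * b` and diverges toward both SF extremes.
#'
#' @param f_j Preferred SF, c/d (> 0).
#' @param sens A [neuronal_sensitivity()] object.
#' @return Semi-saturation constant, >= `c_min`.
#' @export
ck_min_of_sf <- function(f_j, sens) {
  if (any(f_j <= 0)) stop("f_j must be positive")
  a <- sens$a
  b <- sens$b
  sens$c_min * ((a * b)^a * exp(-a)) / (f_j^a * exp(-f_j / b))
}

#' SF tuning width at a preferred SF
#'
#' Tuning width in octaves decreases with increasing preferred SF:
#' `sigma_SF(f_j) = exp(-(f_j - 2) / 0.2)`, equal to one octave at 2 c/d.
#' The decay is steep, so above a few c/d the width is far below the
#' quarter-octave population sampling; the analytic coupling kernel
#' ([sf_coupling()]) keeps the detection pathway well defined there.
#'
#' @param f_j Preferred SF, c/d (> 0).
#' @return Tuning width in octaves, strictly decreasing in `f_j`.
#' @export
sf_width_of_preferred <- function(f_j) {
  if (any(f_j <= 0)) stop("f_j must be positive")
  exp(-(f_j - 2) / 0.2)
}

# second-layer rate of the decision neuron (preferred SF = stimulus SF,
# smallest semi-saturation at that SF); NA when the channel is pruned.
# Vectorized over (c, f).
decision_rate <- function(c, f, sens, I_inh, fixed, prune_above = 1000) {
  c_k <- ck_min_of_sf(f, sens)
  x <- contrast_response(c, c_k, fixed$n)
  k <- sf_coupling(f, f, sf_width_of_preferred(f))
  g_e <- fixed$I_c * fixed$A * x * k
  g_i <- fixed$n_s * I_inh * fixed$A * x * k
  r <- firing_rate(steady_state_voltage(g_e, g_i, fixed), fixed)
  r[c_k > prune_above] <- NA_real_
  r
}

#' Two-interval detection probability
#'
#' Probability of a correct response in the two-interval detection task at
#' contrast `c` and SF `f`. Detection is based on the neuron with the
#' smallest semi-saturation constant at the stimulus SF; the orientation term
#' collapses to one (the target is always vertical). The decision statistic
#' is the standard pooled-noise d-prime between the signal and no-signal
#' rates, `d' = (R_j - R_0) / sqrt(Var(R_j) + Var(R_0))` with Poisson-like
#' variance `Var(R) = R + r0`, mapped to two-interval percent correct by
#' `P_th = 2 (Phi(d'/sqrt(2)) - 0.5)`, then floored and ceilinged by the
#' guess and lapse rates: `P = gamma + (1 - gamma - lambda) P_th`.
#'
#' @param c Contrast in \[0, 1\].
#' @param f Stimulus SF, c/d.
#' @param sens A [neuronal_sensitivity()] object.
#' @param I_inh Surround inhibitory strength per hypercolumn.
#' @param fixed A [v1_fixed_params()] object.
#' @param gamma Guess rate (floor), typically from the third-key rule.
#' @param lambda Lapse rate (ceiling 1 - lambda).
#' @param r0 Spontaneous variance floor so the zero-signal case is well
#'   defined; see the methods vignette for the choice of default.
#' @param prune_above Semi-saturation pruning bound; channels with
#'   `c_k > prune_above` do not exist and the observer can only guess.
#' @return Probability correct in \[gamma, 1 - lambda\], nondecreasing in `c`.
#' @export
detection_probability <- function(c, f, sens, I_inh,
                                  fixed = v1_fixed_params(),
                                  gamma = 0.5, lambda = 0.01, r0 = 0.01,
                                  prune_above = 1000) {
  stopifnot(gamma >= 0, gamma <= 0.5, lambda >= 0, lambda < 0.5, r0 > 0)
  n <- max(length(c), length(f))
  c <- rep_len(c, n)
  f <- rep_len(f, n)
  r_j <- decision_rate(c, f, sens, I_inh, fixed, prune_above)
  r_0 <- decision_rate(rep(0, n), f, sens, I_inh, fixed, prune_above)
  d <- (r_j - r_0) / sqrt(r_j + r0 + r_0 + r0)
  p <- gamma + (1 - gamma - lambda) * 2 * (stats::pnorm(d / sqrt(2)) - 0.5)
  p[is.na(r_j)] <- gamma   # pruned channel: the observer can only guess
  p
}

#' Predicted contrast sensitivity function
#'
#' For each SF the detection threshold is the contrast at which the
#' psychometric surface crosses its midpoint `(gamma + 1 - lambda) / 2`
#' (i.e. where the signal-detection term reaches one half), found by
#' bisection on log10 contrast; sensitivity is its inverse. Where the
#' midpoint is not reached at full contrast the stimulus is invisible and
#' sensitivity is reported as `NA`. Stronger inhibition or a larger `c_min`
#' lowers the whole curve.
#'
#' @inheritParams detection_probability
#' @param sf SF grid at which to predict, c/d.
#' @param tol Bisection tolerance in log10-contrast units.
#' @return Data frame with columns `sf`, `threshold` (contrast) and
#'   `sensitivity` (1 / threshold; `NA` when not measurable).
#' @export
predict_csf <- function(sens, I_inh, gamma = 0.5, lambda = 0.01,
                        sf = csf_sf_grid(), fixed = v1_fixed_params(),
                        r0 = 0.01, prune_above = 1000, tol = 1e-4) {
  mid <- 0.5
  pth_at <- function(ci, fi) {
    p <- detection_probability(ci, fi, sens, I_inh, fixed, gamma, lambda,
                               r0, prune_above)
    (p - gamma) / (1 - gamma - lambda)
  }
  thr <- vapply(sf, function(fi) {
    if (pth_at(1, fi) < mid) return(NA_real_)
    lo <- -6
    hi <- 0
    while (hi - lo > tol) {
      m <- (lo + hi) / 2
      if (pth_at(10^m, fi) >= mid) hi <- m else lo <- m
    }
    10^((lo + hi) / 2)
  }, numeric(1))
  data.frame(sf = sf, threshold = thr, sensitivity = 1 / thr)
}
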