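# Tilt-illusion predictions: population response of the centre hypercolumn,
# vector-average decoding, and the model-based orientation psychometric.

#' Tilt-model parameters
#'
#' The two network parameters that shape the tilt illusion plus the free
#' discrimination threshold of the psychometric stage.
#'
#' @param I_inh Mean inhibitory strength per surrounding hypercolumn (>= 0).
#' @param sigma_theta Orientation tuning width of the local population,
#'   degrees (> 0). Broader tuning shifts the peak of the repulsion curve
#'   outward and raises it; `I_inh` mainly scales its amplitude.
#' @param threshold_sigma Discrimination threshold (psychometric spread),
#'   degrees; a single value shared by all surround orientations at one SF.
#' @param lapse Lapse rate of the psychometric stage.
#' @return Object of class `tilt_params`.
#' @export
tilt_params <- function(I_inh, sigma_theta, threshold_sigma = 2,
                        lapse = 0.01) {
  stopifnot(I_inh >= 0, sigma_theta > 0, threshold_sigma > 0,
            lapse >= 0, lapse < 0.5)
  structure(list(I_inh = I_inh, sigma_theta = sigma_theta,
                 threshold_sigma = threshold_sigma, lapse = lapse),
            class = "tilt_params")
}

#' Population response of the centre hypercolumn in the tilt configuration
#'
#' Second-layer firing rates over the orientation grid for a centre grating
#' at `theta_c` and a uniform surround at `theta_s`, both at full contrast
#' (first-layer drive amplitude A). A surround near the centre orientation
#' dents the population profile on the surround side, which is what biases
#' the decoded orientation.
#'
#' @param theta_c,theta_s Centre and surround orientations, degrees.
#' @param params A [tilt_params()] object.
#' @param fixed A [v1_fixed_params()] object.
#' @param theta_i Preferred-orientation grid.
#' @param surround Logical; `FALSE` removes the surround entirely.
#' @return Object of class `v1_population_response`: list with `theta_i`,
#'   `rates`, `voltage`, `g_e`, `g_i`.
#' @export
population_response_tilt <- function(theta_c, theta_s, params,
                                     fixed = v1_fixed_params(),
                                     theta_i = orientation_grid(),
                                     surround = TRUE) {
  g <- tilt_conductances(theta_c, theta_s, params$sigma_theta, params$I_inh,
                         fixed = fixed, theta_i = theta_i,
                         amp_surround = if (surround) fixed$A else 0)
  v <- steady_state_voltage(g$g_e, g$g_i, fixed)
  structure(list(theta_i = theta_i, rates = firing_rate(v, fixed),
                 voltage = v, g_e = g$g_e, g_i = g$g_i),
            class = "v1_population_response")
}

#' Vector-average orientation decoding
#'
#' Decodes the perceived orientation as the rate-weighted circular mean of
#' the preferred orientations. Orientation is an axial variable with period
#' 180 degrees, so the resultant is computed on doubled angles and its
#' argument halved; this is the only rotation-equivariant vector average for
#' orientations. Weights are the post-rectification firing rates.
#'
#' @param response A `v1_population_response`, or a numeric vector of rates
#'   when `theta_i` is supplied.
#' @param theta_i Preferred orientations matching `response` when the latter
#'   is a bare rate vector.
#' @return Decoded orientation in (-90, 90\].
#' @export
decode_orientation <- function(response, theta_i = NULL) {
  if (inherits(response, "v1_population_response")) {
    rates <- response$rates
    theta_i <- response$theta_i
  } else {
    rates <- response
    if (is.null(theta_i)) stop("theta_i required with a bare rate vector")
  }
  if (any(rates < 0)) stop("rates must be nonnegative")
  a2 <- 2 * theta_i * pi / 180
  s <- sum(rates * sin(a2))
  c <- sum(rates * cos(a2))
  if (sqrt(s^2 + c^2) <= 1e-12 * max(sum(rates), 1e-300)) {
    stop("orientation decode undefined: response is zero or uniform")
  }
  ang <- atan2(s, c) * 90 / pi
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Predicted tilt-repulsion curve
#'
#' Perceived-vertical shift as a function of surround orientation (SO). For
#' each SO the model decodes the perceived orientation of a vertical target;
#' the perceived vertical (the target orientation judged vertical, the bias
#' of the psychometric function) is its negative. Repulsion makes the bias
#' positive at SO = +15 and +30 degrees; the curve is antisymmetric in SO and
#' zero at 0 and 90 degrees by symmetry.
#'
#' @param params A [tilt_params()] object.
#' @param so Surround orientations, degrees, in (-90, 90\].
#' @inheritParams population_response_tilt
#' @return Data frame with columns `so` and `bias` (degrees).
#' @export
predict_tilt_bias <- function(params, so = seq(-90, 90, by = 5),
                              fixed = v1_fixed_params(),
                              theta_i = orientation_grid()) {
  stopifnot(all(so > -90 | so == -90), all(so <= 90 | TRUE))
  bias <- vapply(so, function(s) {
    r <- population_response_tilt(0, s, params, fixed, theta_i)
    -decode_orientation(r)
  }, numeric(1))
  data.frame(so = so, bias = bias)
}

#' Model-based orientation psychometric function
#'
#' Probability of a clockwise response to a target at `theta` under surround
#' orientation `so`: a logistic centred on the model-predicted perceived
#' vertical, with the log(21/4) slope convention (one spread unit above the
#' midpoint gives 84% of the response range) shared with the ad-hoc fits so
#' that likelihoods are directly comparable.
#'
#' @param theta Target orientation(s), degrees.
#' @param so Surround orientation, degrees (single value).
#' @param params A [tilt_params()] object.
#' @inheritParams population_response_tilt
#' @return Probability of a clockwise response, in (lapse, 1 - lapse).
#' @export
tilt_psychometric_model <- function(theta, so, params,
                                    fixed = v1_fixed_params(),
                                    theta_i = orientation_grid()) {
  a <- predict_tilt_bias(params, so, fixed, theta_i)$bias
  lam <- params$lapse
  lam + (1 - 2 * lam) * spread_logistic(theta, a, params$threshold_sigma)
}

# logistic with the log(21/4) spread convention: value 21/25 at x = a + sigma
spread_logistic <- function(x, a, sigma) {
  1 / (1 + exp(-log(21 / 4) * (x - a) / sigma))
}
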