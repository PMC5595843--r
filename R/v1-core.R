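# First-layer tuning functions, the conductance-based second layer, and the
# closed-form/numeric conductances shared by the tilt and CSF predictions.

#' Wrapped-Gaussian orientation tuning
#'
#' Orientation tuning of first-layer neurons: a Gaussian in orientation
#' wrapped on the 180-degree period (sum over wraps k = -2..2; the truncation
#' error is below 1e-12 for widths up to 40 degrees). Peaks at the preferred
#' orientation with value one (up to the negligible wrap tails).
#'
#' @param theta Stimulus orientation, degrees.
#' @param theta_i Preferred orientation, degrees.
#' @param sigma_theta Tuning width, degrees (> 0).
#' @return Tuning value in (0, 1].
#' @examples
#' orientation_tuning(15, 0, 15)        # one width off-peak, ~ exp(-1/2)
#' orientation_tuning(180, 0, 20)       # periodicity: back at the peak
#' @export
orientation_tuning <- function(theta, theta_i, sigma_theta) {
  if (any(sigma_theta <= 0)) stop("sigma_theta must be positive")
  wrapped_gaussian(theta - theta_i, sigma_theta)
}

# unnormalized wrapped Gaussian, period 180 deg, wraps -2..2
wrapped_gaussian <- function(x, sigma, period = 180, n_wraps = 2) {
  out <- 0
  for (k in -n_wraps:n_wraps) {
    out <- out + exp(-0.5 * ((x + k * period) / sigma)^2)
  }
  out
}

#' Log-Gaussian spatial-frequency tuning
#'
#' Gaussian in log2 spatial frequency, so the width is in octaves and the
#' curve is symmetric about the preferred SF on a log axis.
#'
#' @param f Stimulus SF, c/d (> 0).
#' @param f_j Preferred SF, c/d (> 0).
#' @param sigma_sf Tuning width, octaves (> 0).
#' @return Tuning value in (0, 1], equal to 1 at `f = f_j`.
#' @export
sf_tuning <- function(f, f_j, sigma_sf) {
  if (any(f <= 0) || any(f_j <= 0)) stop("frequencies must be positive")
  if (any(sigma_sf <= 0)) stop("sigma_sf must be positive")
  exp(-0.5 * ((log2(f) - log2(f_j)) / sigma_sf)^2)
}

#' Hyperbolic-ratio contrast response
#'
#' `c^n / (c_k^n + c^n)`, with `c_k` the semi-saturation constant. The
#' normalized form multiplies by `(1 + c_k^n)` so that the response is exactly
#' one at full contrast for every `c_k`.
#'
#' @param c Michelson contrast in \[0, 1\].
#' @param c_k Semi-saturation constant (> 0).
#' @param n Exponent.
#' @param normalized Use the unit-at-full-contrast normalization.
#' @return Response value; monotone nondecreasing in `c`.
#' @export
contrast_response <- function(c, c_k, n = 2, normalized = TRUE) {
  if (any(c < 0) || any(c > 1)) stop("contrast must lie in [0, 1]")
  if (any(c_k <= 0)) stop("c_k must be positive")
  r <- c^n / (c_k^n + c^n)
  if (normalized) r <- r * (1 + c_k^n)
  r
}

#' Half-amplitude contrast of the normalized response
#'
#' For low exponents or large `c_k` the semi-saturation constant no longer
#' marks the contrast of half-maximal response of the normalized function;
#' the half-amplitude contrast solves
#' `c_half^n = c_k^n / (1 + 2 c_k^n)`.
#'
#' @inheritParams contrast_response
#' @return Contrast at which the normalized response equals 1/2.
#' @export
half_amplitude_constant <- function(c_k, n = 2) {
  if (any(c_k <= 0)) stop("c_k must be positive")
  if (n <= 0) stop("n must be positive")
  (c_k^n / (1 + 2 * c_k^n))^(1 / n)
}

#' First-layer firing rate
#'
#' Separable product of the three tunings scaled by the maximum amplitude A:
#' orientation (wrapped Gaussian), SF (log-Gaussian), contrast (hyperbolic
#' ratio, normalized).
#'
#' @param theta,f,c Stimulus orientation (deg), SF (c/d), contrast.
#' @param theta_i,f_j,c_k Preferred orientation, SF and semi-saturation of
#'   the neuron.
#' @param sigma_theta Orientation tuning width, degrees.
#' @param fixed A [v1_fixed_params()] object (supplies A, n, sigma_sf).
#' @return Nonnegative firing rate.
#' @export
first_layer_response <- function(theta, f, c, theta_i, f_j, c_k,
                                 sigma_theta, fixed = v1_fixed_params()) {
  fixed$A *
    orientation_tuning(theta, theta_i, sigma_theta) *
    sf_tuning(f, f_j, fixed$sigma_sf) *
    contrast_response(c, c_k, fixed$n)
}

#' Steady-state membrane voltage
#'
#' Fixed point of the conductance equation
#' `tau dv/dt = -v + (v_e - v) g_e + (v_i - v) g_i`, i.e.
#' `v = (v_e g_e + v_i g_i) / (1 + g_e + g_i)`. The voltage is confined to
#' `[v_i, v_e]` for any nonnegative conductances.
#'
#' @param g_e,g_i Excitatory and inhibitory conductances (>= 0).
#' @param fixed A [v1_fixed_params()] object.
#' @return Steady-state voltage.
#' @export
steady_state_voltage <- function(g_e, g_i, fixed = v1_fixed_params()) {
  if (any(g_e < 0) || any(g_i < 0)) stop("conductances must be nonnegative")
  (fixed$v_e * g_e + fixed$v_i * g_i) / (1 + g_e + g_i)
}

#' Rectified-linear transducer
#'
#' Voltage-to-rate transducer `m * max(0, v - T)`.
#'
#' @param v Membrane voltage.
#' @param fixed A [v1_fixed_params()] object.
#' @return Nonnegative firing rate.
#' @export
firing_rate <- function(v, fixed = v1_fixed_params()) {
  fixed$m * pmax(0, v - fixed$T)
}

#' Centre-neuron conductances in the tilt configuration (closed form)
#'
#' In the tilt experiment both centre and surround gratings are at full
#' contrast, the SF dimension is collapsed, and the first-layer drive is a
#' wrapped Gaussian in orientation. The feed-forward weights are wrapped
#' Gaussians of width `sigma_theta / 2`, area-normalized so the total
#' synaptic drive does not depend on how finely the input population is
#' sampled. The convolution of the two Gaussians then gives, per centre
#' neuron at preferred orientation `theta_i`,
#'
#'   g_e = I_c  A_c (sigma / sqrt(sigma_cs^2 + sigma^2)) W(theta_i - theta_c)
#'   g_i = n_s I_inh A_s (sigma / sqrt(sigma_cs^2 + sigma^2)) W(theta_i - theta_s)
#'
#' with W the wrapped Gaussian of width `sqrt(sigma_cs^2 + sigma^2)`. The
#' total inhibitory strength is `n_s * I_inh` (all surrounding hypercolumns
#' see the same grating).
#'
#' @param theta_c,theta_s Centre and surround orientations, degrees.
#' @param sigma_theta Population orientation tuning width, degrees.
#' @param I_inh Mean inhibitory strength per surrounding hypercolumn (>= 0).
#' @param fixed A [v1_fixed_params()] object.
#' @param theta_i Preferred orientations of the receiving neurons.
#' @param amp_center,amp_surround First-layer drive amplitudes; default is
#'   the full-contrast amplitude A (the normalized contrast response is one
#'   at c = 1 for every semi-saturation). Set `amp_surround = 0` for an
#'   absent surround.
#' @return List with vectors `g_e` and `g_i` over `theta_i`.
#' @seealso [tilt_conductances_numeric()] for the direct grid summation these
#'   expressions reproduce.
#' @export
tilt_conductances <- function(theta_c, theta_s, sigma_theta, I_inh,
                              fixed = v1_fixed_params(),
                              theta_i = orientation_grid(),
                              amp_center = fixed$A,
                              amp_surround = fixed$A) {
  stopifnot(sigma_theta > 0, I_inh >= 0)
  s_cs <- sigma_theta / 2
  s_conv <- sqrt(s_cs^2 + sigma_theta^2)
  gain <- sigma_theta / s_conv
  list(
    g_e = fixed$I_c * amp_center * gain *
      wrapped_gaussian(theta_i - theta_c, s_conv),
    g_i = fixed$n_s * I_inh * amp_surround * gain *
      wrapped_gaussian(theta_i - theta_s, s_conv)
  )
}

#' Centre-neuron conductances in the tilt configuration (grid summation)
#'
#' Direct numerical summation of the feed-forward weighted sum over a
#' discretised first-layer population, the definition the closed form
#' [tilt_conductances()] reproduces. Weights are iso-orientation wrapped
#' Gaussians of width `sigma_theta / 2` peaking at the receiving neuron's
#' preferred orientation, area-normalized on the sampling grid.
#'
#' @inheritParams tilt_conductances
#' @param input_spacing Spacing of the first-layer orientation grid, degrees.
#' @return List with vectors `g_e` and `g_i` over `theta_i`.
#' @export
tilt_conductances_numeric <- function(theta_c, theta_s, sigma_theta, I_inh,
                                      fixed = v1_fixed_params(),
                                      theta_i = orientation_grid(),
                                      input_spacing = 2,
                                      amp_center = fixed$A,
                                      amp_surround = fixed$A) {
  stopifnot(sigma_theta > 0, I_inh >= 0)
  s_cs <- sigma_theta / 2
  theta_m <- seq(-90, 90 - input_spacing, by = input_spacing)
  # receiving x input weight matrix, unit-area normalization on the grid
  w <- outer(theta_i, theta_m,
             function(a, b) wrapped_gaussian(a - b, s_cs)) *
    (input_spacing / (sqrt(2 * pi) * s_cs))
  drive_c <- amp_center * wrapped_gaussian(theta_m - theta_c, sigma_theta)
  drive_s <- amp_surround * wrapped_gaussian(theta_m - theta_s, sigma_theta)
  list(g_e = fixed$I_c * as.vector(w %*% drive_c),
       g_i = fixed$n_s * I_inh * as.vector(w %*% drive_s))
}

#' Spatial-frequency coupling kernel
#'
#' Analytic feed-forward coupling along the SF dimension: the convolution of
#' the log-Gaussian population tuning (width `sigma_sf` octaves) with the
#' area-normalized feed-forward weight (width `sigma_sf_cs`, default half).
#' Evaluated at the matched SF (`f = f_j`) with the half-width entanglement,
#' the kernel equals `1/sqrt(1.25)` regardless of the width itself, which
#' keeps the contrast-detection pathway well defined even where the SF tuning
#' width falls below any reasonable sampling resolution.
#'
#' @param f Stimulus SF, c/d.
#' @param f_j Preferred SF of the receiving neuron, c/d.
#' @param sigma_sf Population SF tuning width, octaves.
#' @param sigma_sf_cs Feed-forward weight width, octaves.
#' @return Kernel value in (0, 1).
#' @export
sf_coupling <- function(f, f_j, sigma_sf, sigma_sf_cs = sigma_sf / 2) {
  stopifnot(all(f > 0), all(f_j > 0), all(sigma_sf > 0),
            all(sigma_sf_cs > 0))
  s2 <- sigma_sf_cs^2 + sigma_sf^2
  (sigma_sf / sqrt(s2)) * exp(-0.5 * (log2(f) - log2(f_j))^2 / s2)
}
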