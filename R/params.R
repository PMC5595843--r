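#' Fixed network parameters
#'
#' The block of parameters of the two-layer hypercolumn model that are never
#' fitted: they follow a normalized conductance-based subtractive-inhibition
#' scheme. Reversal potentials and the firing threshold are in the
#' dimensionless voltage units of the model.
#'
#' @param n_s Effective number of surrounding hypercolumns feeding the centre.
#' @param n Contrast-response (hyperbolic ratio) exponent.
#' @param A Maximum firing amplitude of first-layer neurons.
#' @param m Slope of the voltage-to-rate transducer.
#' @param T Firing threshold voltage.
#' @param I_c Centre (within-hypercolumn) excitatory strength.
#' @param v_e,v_i Excitatory and inhibitory reversal potentials.
#' @param sigma_sf Default first-layer SF tuning width, octaves.
#' @param tau Membrane time constant; only used by dynamical consistency
#'   checks, the steady state is closed form.
#' @return An object of class `v1_fixed_params` (a validated list).
#' @examples
#' fp <- v1_fixed_params()
#' fp$v_e
#' @export
v1_fixed_params <- function(n_s = 6, n = 2, A = 2, m = 1, T = 1, I_c = 1,
                            v_e = 14 / 3, v_i = -2 / 3, sigma_sf = 1,
                            tau = 10) {
  stopifnot(v_i < 0, v_e > 0, T > 0, n_s >= 0, A >= 0, m >= 0, I_c >= 0,
            n > 0, sigma_sf > 0, tau > 0)
  structure(list(n_s = n_s, n = n, A = A, m = m, T = T, I_c = I_c,
                 v_e = v_e, v_i = v_i, sigma_sf = sigma_sf, tau = tau),
            class = "v1_fixed_params")
}

#' @export
print.v1_fixed_params <- function(x, ...) {
  cat("V1 fixed parameters:\n")
  cat(sprintf("  n_s = %g, n = %g, A = %g, m = %g, T = %g, I_c = %g\n",
              x$n_s, x$n, x$A, x$m, x$T, x$I_c))
  cat(sprintf("  v_e = %.4f, v_i = %.4f, sigma_sf = %g oct, tau = %g\n",
              x$v_e, x$v_i, x$sigma_sf, x$tau))
  invisible(x)
}

#' Feature grids of the population
#'
#' `orientation_grid()` returns preferred orientations covering one 180-degree
#' period without duplicates (default -90 to +88 in 2-degree steps);
#' `sf_grid()` returns preferred spatial frequencies log2-equispaced at a
#' quarter octave from 0.5 to 64 c/d; `csf_sf_grid()` returns the eleven
#' stimulus SFs of the contrast-detection session (half-octave spaced,
#' 0.71 to 22.63 c/d).
#'
#' @param spacing Orientation spacing in degrees (must divide 180).
#' @return Numeric vector of grid values.
#' @export
orientation_grid <- function(spacing = 2) {
  stopifnot(spacing > 0, abs(180 / spacing - round(180 / spacing)) < 1e-9)
  seq(-90, 90 - spacing, by = spacing)
}

#' @rdname orientation_grid
#' @param from,to SF range in c/d.
#' @param step_oct Spacing in octaves.
#' @export
sf_grid <- function(from = 0.5, to = 64, step_oct = 0.25) {
  stopifnot(from > 0, to > from, step_oct > 0)
  2^seq(log2(from), log2(to), by = step_oct)
}

#' @rdname orientation_grid
#' @export
csf_sf_grid <- function() {
  c(0.71, 1, 1.41, 2, 2.83, 4, 5.66, 8, 11.31, 16, 22.63)
}

#' Feed-forward connection widths
#'
#' Centre and surround feed-forward tuning widths are entangled with the
#' population widths: both are fixed at half the corresponding population
#' tuning width.
#'
#' @param sigma_theta Population orientation tuning width, degrees.
#' @param sigma_sf Population SF tuning width, octaves.
#' @return List with `sigma_theta_cs` (degrees) and `sigma_sf_cs` (octaves).
#' @export
connection_widths <- function(sigma_theta, sigma_sf = 1) {
  stopifnot(sigma_theta > 0, sigma_sf > 0)
  list(sigma_theta_cs = sigma_theta / 2, sigma_sf_cs = sigma_sf / 2)
}

#' Read a model configuration file
#'
#' Reads a YAML configuration with a `fixed_params` block (mirrored by
#' [v1_fixed_params()]), optional `grids` (orientation spacing, SF range) and
#' optional `r0_floor` (spontaneous variance floor of the detection stage).
#' The package default lives in `inst/extdata/v1_config.yaml`.
#'
#' @param path Path to a YAML file; default is the packaged configuration.
#' @return List with elements `fixed_params` (a `v1_fixed_params`),
#'   `orientation_spacing`, `sf_range`, and `r0_floor`.
#' @export
read_v1_config <- function(path = system.file("extdata", "v1_config.yaml",
                                              package = "tiltcsf")) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read configuration files")
  }
  raw <- yaml::read_yaml(path)
  fp <- do.call(v1_fixed_params, as.list(raw$fixed_params))
  list(fixed_params = fp,
       orientation_spacing = raw$grids$orientation_spacing %||% 2,
       sf_range = raw$grids$sf_range %||% c(0.5, 64),
       r0_floor = raw$r0_floor %||% 0.01)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
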