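# Two-stage model fitting per eye: tilt data first (inhibition strength and
# tuning width), then the contrast data with the inhibition fixed; plus the
# study-level plumbing (SF choice, likelihood comparison, correlations).

#' Choose the two measured SFs from a fitted CSF
#'
#' The low SF is the grid SF nearest the fitted sensitivity peak (at
#' `f = a * b`); the high SF is the largest grid SF whose fitted sensitivity
#' still exceeds a margin above the full-contrast limit (default 2, i.e.
#' threshold contrast at most 50%), so the tilt stimulus remains clearly
#' visible there.
#'
#' @param fit A `csf_fit` from [fit_csf_adhoc()].
#' @param sfs Candidate SF grid, c/d.
#' @param margin Minimum fitted sensitivity at the high SF.
#' @return List with `low_sf`, `high_sf` (`NA` when no SF clears the
#'   margin, flagging the eye) and `high_sf_available`.
#' @export
choose_sfs <- function(fit, sfs = csf_sf_grid(), margin = 2) {
  peak <- fit$a_shape * fit$b_scale
  low_sf <- sfs[which.min(abs(log2(sfs) - log2(peak)))]
  sens <- csf_shape(sfs, fit$M, fit$a_shape, fit$b_scale)
  ok <- sfs > low_sf & sens >= margin
  high_sf <- if (any(ok)) max(sfs[ok]) else NA_real_
  list(low_sf = low_sf, high_sf = high_sf,
       high_sf_available = !is.na(high_sf))
}

#' Fit the V1 tilt model to discrimination trials (stage 1)
#'
#' Maximum-likelihood fit of the network parameters `(I_inh, sigma_theta)`
#' and one shared discrimination threshold to the clockwise/counterclockwise
#' responses at surround orientations of +/-15 and +/-30 degrees (the direct
#' repulsion regime; the model makes no prediction for the indirect effect
#' at +/-75). Not-seen trials are removed first. The psychometric function
#' is a logistic centred on the model-decoded perceived vertical, so the
#' likelihood is directly comparable to the ad-hoc per-SO fits.
#'
#' @param trials Tilt trial data frame (see [simulate_tilt_session()]).
#' @param lambda Fixed lapse rate.
#' @param fixed A [v1_fixed_params()] object.
#' @param bounds List of ranges for `I_inh`, `sigma_theta`,
#'   `threshold_sigma`.
#' @param so_keep Absolute surround orientations entering the fit.
#' @param starts Matrix of starting values (columns `I_inh`, `sigma_theta`);
#'   default a deterministic 3 x 3 grid.
#' @return List of class `tilt_v1_fit`: fitted `params` ([tilt_params()]),
#'   `neg_log_ml`, `n_trials`, `converged`.
#' @export
fit_tilt_v1 <- function(trials, lambda = 0.01, fixed = v1_fixed_params(),
                        bounds = list(I_inh = c(0, 5),
                                      sigma_theta = c(2, 60),
                                      threshold_sigma = c(0.2, 45)),
                        so_keep = c(15, 30), starts = NULL) {
  use <- drop_unforced_trials(trials)
  use <- use[abs(use$so) %in% so_keep, , drop = FALSE]
  if (nrow(use) == 0) stop("no usable trials at the fitted SOs")
  th <- use$target_orientation
  y <- use$response == "cw"
  w <- if ("weight" %in% names(use)) use$weight else rep(1, nrow(use))
  abs_so <- sort(unique(abs(use$so)))
  so_sign <- sign(use$so)
  so_idx <- match(abs(use$so), abs_so)
  grid_th <- orientation_grid()
  nll <- function(par) {
    I <- par[1]
    sg <- par[2]
    sth <- exp(par[3])
    prm <- tilt_params(I, sg, sth, lambda)
    # bias at the positive SOs; antisymmetry gives the negatives exactly.
    # Inhibition strong enough to silence the population leaves the decode
    # undefined: such parameters cannot produce the data, so penalize.
    b_pos <- tryCatch(vapply(abs_so, function(s) {
      -decode_orientation(population_response_tilt(0, s, prm, fixed,
                                                   grid_th))
    }, numeric(1)), error = function(e) NULL)
    if (is.null(b_pos)) return(1e10)
    a <- so_sign * b_pos[so_idx]
    pr <- lambda + (1 - 2 * lambda) * spread_logistic(th, a, sth)
    pr <- clamp(pr, 1e-10, 1 - 1e-10)
    -sum(w * ifelse(y, log(pr), log(1 - pr)))
  }
  if (is.null(starts)) {
    starts <- as.matrix(expand.grid(I_inh = c(0.02, 0.1, 0.5),
                                    sigma_theta = c(10, 20, 35)))
  }
  starts <- cbind(starts, log(3))
  lower <- c(bounds$I_inh[1], bounds$sigma_theta[1],
             log(bounds$threshold_sigma[1]))
  upper <- c(bounds$I_inh[2], bounds$sigma_theta[2],
             log(bounds$threshold_sigma[2]))
  best <- multistart_ml(nll, starts, lower, upper)
  structure(list(params = tilt_params(best$par[1], best$par[2],
                                      exp(best$par[3]), lambda),
                 neg_log_ml = best$value, n_trials = nrow(use),
                 converged = best$convergence == 0),
            class = "tilt_v1_fit")
}

#' Fit the V1 contrast-detection model (stage 2)
#'
#' Maximum-likelihood fit of the neuronal sensitivity envelope
#' `(c_min, a, b)` to a contrast-detection session, with the lateral
#' inhibition strength held fixed at the value extracted from the low-SF
#' tilt fit. The guess rate comes from the session's third-key proportion
#' and is never fitted; undecided trials are excluded from the Bernoulli
#' likelihood.
#'
#' @param trials Detection trial data frame (see
#'   [simulate_csf_session()]).
#' @param I_inh Inhibition strength inherited from stage 1.
#' @param lambda Fixed lapse rate.
#' @param fixed A [v1_fixed_params()] object.
#' @param r0 Detection variance floor.
#' @param bounds List of ranges for `c_min`, `a`, `b`.
#' @return List of class `csf_v1_fit`: `sens` (a
#'   [neuronal_sensitivity()]), inherited `I_inh`, `gamma`, `neg_log_ml`,
#'   `n_trials`, `converged`.
#' @export
fit_csf_v1 <- function(trials, I_inh, lambda = 0.01,
                       fixed = v1_fixed_params(), r0 = 0.01,
                       bounds = list(c_min = c(1e-4, 1), a = c(0.1, 5),
                                     b = c(0.2, 32))) {
  p3 <- mean(trials$response == "undecided")
  gamma <- guess_rate_from_undecided(p3)
  use <- drop_unforced_trials(trials)
  y <- use$correct
  w <- if ("weight" %in% names(use)) use$weight else rep(1, nrow(use))
  nll <- function(lp) {
    p <- exp(lp)
    pr <- detection_probability(use$contrast, use$sf,
                                neuronal_sensitivity(p[1], p[2], p[3]),
                                I_inh, fixed, gamma, lambda, r0)
    pr <- clamp(pr, 1e-10, 1 - 1e-10)
    -sum(w * ifelse(y, log(pr), log(1 - pr)))
  }
  starts <- log(as.matrix(expand.grid(c_min = c(0.002, 0.02),
                                      a = c(0.7, 2), b = c(2, 8))))
  lower <- log(vapply(bounds, `[`, numeric(1), 1))
  upper <- log(vapply(bounds, `[`, numeric(1), 2))
  best <- multistart_ml(nll, starts, lower, upper)
  par <- exp(best$par)
  structure(list(sens = neuronal_sensitivity(par[1], par[2], par[3]),
                 I_inh = I_inh, gamma = gamma, lambda = lambda,
                 neg_log_ml = best$value, n_trials = nrow(use),
                 converged = best$convergence == 0),
            class = "csf_v1_fit")
}

#' Two-stage per-eye model fit
#'
#' Runs the full per-eye analysis: ad-hoc fits of both measures, then
#' stage 1 (tilt model per measured SF) and stage 2 (contrast model with
#' `I_inh` fixed from the low-SF tilt fit), and the model-predicted
#' sensitivity at the low SF.
#'
#' @param csf_trials Detection session trials.
#' @param tilt_low,tilt_high Tilt session trials at the low/high SF.
#' @param low_sf,high_sf The measured SFs, c/d.
#' @param eye_type Label carried into the result.
#' @param lambda Fixed lapse rate.
#' @param fixed A [v1_fixed_params()] object.
#' @param r0 Detection variance floor.
#' @return Object of class `eye_result` with the ad-hoc fits (`csf_adhoc`,
#'   `tilt_adhoc_low`, `tilt_adhoc_high`), the model fits (`tilt_v1_low`,
#'   `tilt_v1_high`, `csf_v1`), the measured SFs and the model-predicted
#'   low-SF sensitivity.
#' @export
fit_eye <- function(csf_trials, tilt_low, tilt_high, low_sf, high_sf,
                    eye_type = "NTE", lambda = 0.01,
                    fixed = v1_fixed_params(), r0 = 0.01) {
  csf_adhoc <- fit_csf_adhoc(csf_trials, lambda)
  tilt_v1_low <- fit_tilt_v1(tilt_low, lambda, fixed)
  tilt_v1_high <- if (!is.null(tilt_high)) {
    fit_tilt_v1(tilt_high, lambda, fixed)
  }
  csf_v1 <- fit_csf_v1(csf_trials, tilt_v1_low$params$I_inh, lambda,
                       fixed, r0)
  pred <- predict_csf(csf_v1$sens, csf_v1$I_inh, csf_v1$gamma, lambda,
                      sf = low_sf, fixed = fixed, r0 = r0)
  structure(list(eye_type = eye_type, low_sf = low_sf, high_sf = high_sf,
                 csf_adhoc = csf_adhoc,
                 tilt_adhoc_low = fit_tilt_adhoc(tilt_low, lambda),
                 tilt_adhoc_high = if (!is.null(tilt_high)) {
                   fit_tilt_adhoc(tilt_high, lambda)
                 },
                 tilt_v1_low = tilt_v1_low, tilt_v1_high = tilt_v1_high,
                 csf_v1 = csf_v1,
                 predicted_low_sf_sensitivity = pred$sensitivity[1]),
            class = "eye_result")
}

#' @export
print.eye_result <- function(x, ...) {
  cat(sprintf("Eye result (%s), SFs %.3g / %.3g c/d\n", x$eye_type,
              x$low_sf, x$high_sf))
  cat(sprintf("  tilt model (low SF): I_inh = %.3g, sigma_theta = %.3g deg\n",
              x$tilt_v1_low$params$I_inh,
              x$tilt_v1_low$params$sigma_theta))
  cat(sprintf("  contrast model: c_min = %.3g (a = %.3g, b = %.3g)\n",
              x$csf_v1$sens$c_min, x$csf_v1$sens$a, x$csf_v1$sens$b))
  cat(sprintf("  predicted low-SF sensitivity: %.3g\n",
              x$predicted_low_sf_sensitivity))
  invisible(x)
}

#' Compare ad-hoc and model fits by likelihood
#'
#' Paired negative log maximum-likelihood values of two fits computed on the
#' identical trial set, and their difference (model minus ad-hoc; positive
#' means the descriptive fit explains the data better). No complexity
#' penalty is applied.
#'
#' @param adhoc,model Fit objects carrying `neg_log_ml` and `n_trials`.
#' @return List with `adhoc`, `model`, `delta`, `n_trials`.
#' @export
compare_fits <- function(adhoc, model) {
  if (adhoc$n_trials != model$n_trials) {
    stop("fits were not computed on identical trial sets")
  }
  list(adhoc = adhoc$neg_log_ml, model = model$neg_log_ml,
       delta = model$neg_log_ml - adhoc$neg_log_ml,
       n_trials = adhoc$n_trials)
}

#' Vector blur of a refraction record
#'
#' Scalar optical summary of spherical (`s`) and cylindrical (`c`)
#' refractive errors, `sqrt(s^2 + s c + c^2) / 2`, in diopters; symmetric in
#' its two arguments.
#'
#' @param s Spherical refractive error, diopters.
#' @param c Cylindrical refractive error, diopters.
#' @return Vector blur, diopters (>= 0).
#' @export
vector_blur <- function(s, c) sqrt(s^2 + s * c + c^2) / 2

#' Spearman correlation between fitted parameters
#'
#' Rank correlation (midranks for ties) with a two-sided p-value, for
#' relating fitted network parameters to sensitivities across a cohort.
#'
#' @param x,y Paired numeric vectors (at least 5 complete pairs).
#' @return List with `rho`, `p`, `n`.
#' @export
correlate_parameters <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 5) stop("need at least 5 paired observations")
  ct <- stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Simulate the full measurement protocol for one observer
#'
#' Mirrors the experimental order: a detection session first, an ad-hoc CSF
#' fit to choose the low and high SFs, then one tilt session at each. Seeds
#' for the three sessions are derived from `seed`.
#'
#' @param observer An [observer_spec()].
#' @param seed Integer seed.
#' @param fixed A [v1_fixed_params()] object.
#' @return List with `csf_trials`, `tilt_low`, `tilt_high`, `low_sf`,
#'   `high_sf`, `sf_choice`.
#' @export
simulate_eye_dataset <- function(observer, seed,
                                 fixed = v1_fixed_params()) {
  csf_trials <- simulate_csf_session(observer, seed, fixed = fixed)
  choice <- choose_sfs(fit_csf_adhoc(csf_trials))
  tilt_low <- simulate_tilt_session(observer, choice$low_sf, "low",
                                    seed + 1000L, fixed = fixed)
  tilt_high <- if (choice$high_sf_available) {
    simulate_tilt_session(observer, choice$high_sf, "high", seed + 2000L,
                          fixed = fixed)
  }
  list(csf_trials = csf_trials, tilt_low = tilt_low,
       tilt_high = tilt_high, low_sf = choice$low_sf,
       high_sf = choice$high_sf, sf_choice = choice)
}

#' Run the pipeline over a synthetic cohort
#'
#' Simulates every observer's sessions and applies the two-stage fit,
#' returning one row per observer with ground truth and recovered
#' parameters, plus the per-observer `eye_result` objects.
#'
#' @param cohort An [make_cohort()] object.
#' @param seed Integer base seed (per-observer seeds are derived from it).
#' @param fixed A [v1_fixed_params()] object.
#' @return List with `summary` (data frame) and `results` (list of
#'   `eye_result`).
#' @export
fit_cohort <- function(cohort, seed = 1, fixed = v1_fixed_params()) {
  n <- length(cohort$observers)
  results <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obs <- cohort$observers[[i]]
    ds <- simulate_eye_dataset(obs, seed + i * 10000L, fixed)
    res <- fit_eye(ds$csf_trials, ds$tilt_low, ds$tilt_high, ds$low_sf,
                   ds$high_sf, obs$eye_type, fixed = fixed, r0 = obs$r0)
    results[[i]] <- res
    rows[[i]] <- data.frame(
      id = i, eye_type = obs$eye_type,
      true_I_inh = obs$I_inh, true_sigma_theta = obs$sigma_theta,
      true_c_min = obs$c_min,
      fit_I_inh = res$tilt_v1_low$params$I_inh,
      fit_sigma_theta = res$tilt_v1_low$params$sigma_theta,
      fit_c_min = res$csf_v1$sens$c_min,
      low_sf = ds$low_sf, high_sf = ds$high_sf,
      low_sf_sensitivity = csf_shape(ds$low_sf, res$csf_adhoc$M,
                                     res$csf_adhoc$a_shape,
                                     res$csf_adhoc$b_scale),
      predicted_low_sf_sensitivity = res$predicted_low_sf_sensitivity)
  }
  list(summary = do.call(rbind, rows), results = results)
}

#' Noise-free virtual tilt trials
#'
#' Expected-data design for self-consistency checks: a ladder of target
#' orientations around the true bias at each surround orientation, with
#' fractional clockwise/counterclockwise counts equal to the generating
#' probabilities (as `weight` columns). Fitting these recovers the
#' generating parameters up to optimizer tolerance.
#'
#' @param params A [tilt_params()] object (the generating truth).
#' @param n_total Total virtual trial weight.
#' @param so_set Surround orientations.
#' @param n_levels Ladder points per SO.
#' @param fixed A [v1_fixed_params()] object.
#' @return Weighted tilt trial data frame.
#' @export
virtual_tilt_trials <- function(params, n_total = 10000,
                                so_set = c(-30, -15, 15, 30),
                                n_levels = 21,
                                fixed = v1_fixed_params()) {
  per_cell <- n_total / (length(so_set) * n_levels)
  out <- list()
  for (s in so_set) {
    a <- predict_tilt_bias(params, s, fixed)$bias
    th <- seq(a - 3 * params$threshold_sigma,
              a + 3 * params$threshold_sigma, length.out = n_levels)
    p <- params$lapse + (1 - 2 * params$lapse) *
      spread_logistic(th, a, params$threshold_sigma)
    out[[length(out) + 1]] <- data.frame(
      measure = "tilt", sf = NA_real_, so = s,
      target_orientation = rep(th, 2),
      response = rep(c("cw", "ccw"), each = n_levels),
      weight = c(per_cell * p, per_cell * (1 - p)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
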