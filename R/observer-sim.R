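# Simulated observers with known ground truth, and the adaptive-staircase
# sessions that generate trial data in the exact format the fitting
# functions consume.

#' Simulated observer specification
#'
#' Ground truth of a synthetic subject. Two generative modes are supported
#' for both measures: `"v1"` draws responses from the network model itself
#' (one shared `I_inh` couples tilt and contrast detection, which is the
#' point of the model), `"adhoc"` draws from the descriptive psychometric
#' shapes. Third-key usage is a contrast-independent propensity `p3_rate`,
#' so the guess-rate calibration `gamma(p3)` holds exactly by construction;
#' not-seen responses in the tilt task follow a suppression profile that
#' peaks at iso-orientation and is stronger at the high SF.
#'
#' @param eye_type `"AE"`, `"NAE"` or `"NTE"`.
#' @param mode `"v1"` or `"adhoc"`.
#' @param I_inh,sigma_theta Network truth (v1 mode), shared across SFs.
#' @param c_min,a,b Neuronal sensitivity envelope (v1 mode) or, with `M`
#'   instead of `c_min`, the descriptive CSF shape (adhoc mode).
#' @param M Sensitivity scale (adhoc mode).
#' @param sigma_spread Detection spread, natural-log contrast (adhoc mode).
#' @param threshold_low,threshold_high Orientation discrimination threshold
#'   (degrees) at the low and high measured SF.
#' @param tilt_bias Named list mapping SO (as character) to bias in degrees
#'   (adhoc mode only); defaults to zero bias.
#' @param s_iso_low,s_iso_high Not-seen probability at iso-orientation for
#'   low/high SF; decays with |SO| on a Gaussian of width `so_width`.
#' @param so_width Suppression decay width over SO, degrees.
#' @param p3_rate Third-key propensity in the detection task.
#' @param lapse Lapse rate.
#' @param r0 Detection variance floor (v1 mode).
#' @return Object of class `observer_spec`.
#' @export
observer_spec <- function(eye_type = c("NTE", "AE", "NAE"),
                          mode = c("v1", "adhoc"),
                          I_inh = 0.04, sigma_theta = 15,
                          c_min = 0.005, a = 1, b = 4, M = 100,
                          sigma_spread = 0.6,
                          threshold_low = 2.5, threshold_high = 4,
                          tilt_bias = NULL,
                          s_iso_low = 0.05, s_iso_high = 0.3,
                          so_width = 25, p3_rate = 0.3, lapse = 0.01,
                          r0 = 0.01) {
  eye_type <- match.arg(eye_type)
  mode <- match.arg(mode)
  stopifnot(p3_rate >= 0, p3_rate <= 1, s_iso_low >= 0, s_iso_low <= 1,
            s_iso_high >= 0, s_iso_high <= 1, threshold_low > 0,
            threshold_high > 0)
  structure(list(eye_type = eye_type, mode = mode, I_inh = I_inh,
                 sigma_theta = sigma_theta, c_min = c_min, a = a, b = b,
                 M = M, sigma_spread = sigma_spread,
                 threshold_low = threshold_low,
                 threshold_high = threshold_high, tilt_bias = tilt_bias,
                 s_iso_low = s_iso_low, s_iso_high = s_iso_high,
                 so_width = so_width, p3_rate = p3_rate, lapse = lapse,
                 r0 = r0),
            class = "observer_spec")
}

# probability correct (keyed trials) in the detection task
observer_p_correct <- function(obs, c, f, fixed = v1_fixed_params()) {
  gamma <- guess_rate_from_undecided(obs$p3_rate)
  if (obs$mode == "v1") {
    detection_probability(c, f, neuronal_sensitivity(obs$c_min, obs$a,
                                                     obs$b),
                          obs$I_inh, fixed, gamma, obs$lapse, obs$r0)
  } else {
    eval_csf_psychometric(c, f, obs$M, obs$a, obs$b, obs$sigma_spread,
                          gamma, obs$lapse)
  }
}

# probability of a clockwise response at target orientation theta
observer_p_cw <- function(obs, theta, so, which = "low",
                          fixed = v1_fixed_params()) {
  sigma <- if (which == "low") obs$threshold_low else obs$threshold_high
  if (obs$mode == "v1") {
    prm <- tilt_params(obs$I_inh, obs$sigma_theta, sigma, obs$lapse)
    tilt_psychometric_model(theta, so, prm, fixed)
  } else {
    bias <- 0
    if (!is.null(obs$tilt_bias)) {
      bias <- obs$tilt_bias[[as.character(so)]] %||% 0
    }
    obs$lapse + (1 - 2 * obs$lapse) *
      spread_logistic(theta, bias, sigma)
  }
}

# not-seen probability as a function of SO and measured-SF level
observer_p_notseen <- function(obs, so, which = "low") {
  s_iso <- if (which == "low") obs$s_iso_low else obs$s_iso_high
  s_iso * exp(-0.5 * (so / obs$so_width)^2)
}

#' Simulate one contrast-detection session
#'
#' One weighted up-down staircase of `n_per_sf` trials per SF (15 trials at
#' each of eleven SFs by default, 165 in total). Steps are multiples of the
#' base 10% contrast in log10 units: down/up 4.5/8 for the odd SFs of the
#' ladder and 1.5/7 for the rest, the down step tripled for the first four
#' trials, with the published per-SF starting contrasts. Undecided presses
#' are stepped as a random correct/incorrect; the recorded response keeps
#' the undecided label for the fitting stage.
#'
#' @param observer An [observer_spec()].
#' @param seed Integer seed; sessions are byte-identical under a fixed seed.
#' @param sfs Stimulus SFs, c/d.
#' @param n_per_sf Trials per SF.
#' @param start_contrasts Staircase starting contrasts, one per SF.
#' @param fixed A [v1_fixed_params()] object (v1-mode observers).
#' @return Data frame of trials: `measure`, `sf`, `trial`, `contrast`,
#'   `response` (`"correct"`, `"incorrect"`, `"undecided"`), `correct`
#'   (logical, `NA` when undecided).
#' @export
simulate_csf_session <- function(observer, seed, sfs = csf_sf_grid(),
                                 n_per_sf = 15,
                                 start_contrasts = c(0.5, 0.005, 0.5,
                                                     0.005, 0.5, 0.005,
                                                     0.5, 0.005, 0.7,
                                                     0.05, 0.8),
                                 fixed = v1_fixed_params()) {
  stopifnot(length(start_contrasts) == length(sfs))
  set.seed(seed)
  u <- log10(1.1)
  out <- vector("list", length(sfs))
  for (i in seq_along(sfs)) {
    f <- sfs[i]
    coarse <- i %% 2 == 1   # 0.71, 1.41, 2.83, 5.66, 11.31, 22.63 ladder
    cfg <- staircase_config(
      up = (if (coarse) 8 else 7) * u,
      down = (if (coarse) 4.5 else 1.5) * u,
      start = log10(start_contrasts[i]), n_trials = n_per_sf,
      min_level = -4, max_level = 0, boost_trials = 4)
    respond <- function(level, trial) {
      ct <- 10^level
      if (stats::runif(1) < observer$p3_rate) {
        list(tracked = stats::runif(1) < 0.5, response = "undecided",
             correct = NA, contrast = ct)
      } else {
        ok <- stats::runif(1) < observer_p_correct(observer, ct, f, fixed)
        list(tracked = ok,
             response = if (ok) "correct" else "incorrect",
             correct = ok, contrast = ct)
      }
    }
    tr <- run_staircase(cfg, respond)
    out[[i]] <- data.frame(measure = "csf", sf = f, trial = tr$trial,
                           contrast = tr$contrast, response = tr$response,
                           correct = tr$correct)
  }
  do.call(rbind, out)
}

#' Simulate one tilt-discrimination session
#'
#' Seven surround orientations (0, +/-15, +/-30, +/-75 degrees), two
#' interleaved weighted up-down staircases per SO with steps up/down 2/5 and
#' 5/2 degrees (convergence near 29% and 71% clockwise), 30 trials each: 420
#' trials per session. Staircases start on the opposite side of their
#' convergence point (true bias +/- `start_offset`). Not-seen responses are
#' emitted from the observer's suppression profile and stepped as a random
#' CW/CCW.
#'
#' @param observer An [observer_spec()].
#' @param sf Stimulus SF, c/d (recorded in the output).
#' @param which `"low"` or `"high"`: which measured-SF regime of the
#'   observer's thresholds and suppression applies.
#' @param seed Integer seed.
#' @param so_set Surround orientations, degrees.
#' @param n_per_staircase Trials per staircase.
#' @param start_offset Starting distance from the true bias, degrees.
#' @param fixed A [v1_fixed_params()] object.
#' @return Data frame of trials: `measure`, `sf`, `so`, `staircase`,
#'   `trial`, `target_orientation`, `response` (`"cw"`, `"ccw"`,
#'   `"not_seen"`).
#' @export
simulate_tilt_session <- function(observer, sf, which = c("low", "high"),
                                  seed = 1,
                                  so_set = c(0, -15, 15, -30, 30, -75, 75),
                                  n_per_staircase = 30, start_offset = 10,
                                  fixed = v1_fixed_params()) {
  which <- match.arg(which)
  set.seed(seed)
  # cache the true bias per SO once (v1 decode is deterministic)
  p_cw <- lapply(so_set, function(s) {
    function(theta) observer_p_cw(observer, theta, s, which, fixed)
  })
  names(p_cw) <- as.character(so_set)
  out <- list()
  for (s in so_set) {
    pfun <- p_cw[[as.character(s)]]
    # approximate true bias for the start levels: midpoint by root search
    bias0 <- tryCatch(
      stats::uniroot(function(t) pfun(t) - 0.5, c(-60, 60))$root,
      error = function(e) 0)
    cfgs <- list(
      staircase_config(up = 2, down = 5, start = bias0 + start_offset,
                       n_trials = n_per_staircase, min_level = -80,
                       max_level = 80),
      staircase_config(up = 5, down = 2, start = bias0 - start_offset,
                       n_trials = n_per_staircase, min_level = -80,
                       max_level = 80))
    p_ns <- observer_p_notseen(observer, s, which)
    sim_one <- function(cfg, sc_id) {
      respond <- function(level, trial) {
        if (stats::runif(1) < p_ns) {
          list(tracked = stats::runif(1) < 0.5, response = "not_seen")
        } else {
          cw <- stats::runif(1) < pfun(level)
          list(tracked = cw, response = if (cw) "cw" else "ccw")
        }
      }
      tr <- run_staircase(cfg, respond)
      data.frame(measure = "tilt", sf = sf, so = s, staircase = sc_id,
                 trial = tr$trial, target_orientation = tr$level,
                 response = tr$response)
    }
    # strict alternation of the two staircases within the SO
    t1 <- sim_one(cfgs[[1]], 1L)
    t2 <- sim_one(cfgs[[2]], 2L)
    inter <- rbind(t1, t2)
    ord <- order(rep(seq_len(n_per_staircase), 2),
                 rep(c(1L, 2L), each = n_per_staircase))
    out[[length(out) + 1]] <- inter[ord, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic cohort of observers
#'
#' Reproducible groups of v1-mode observers patterned on the study's
#' phenomenology: amblyopic eyes (AE) draw broader orientation tuning widths
#' and stronger lateral inhibition than fellow (NAE) and neurotypical (NTE)
#' eyes; the neuronal sensitivity floor `c_min` varies across observers, and
#' because stronger inhibition mechanically lowers the predicted CSF, the
#' generated low-SF sensitivity is negatively coupled to `I_inh` within each
#' group. See the methods vignette for the parameter regimes and why they
#' were chosen.
#'
#' @param n_per_group Observers per eye group.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param regimes Named list of per-group sampling ranges; see default.
#' @return Object of class `observer_cohort`: list with `observers` (list of
#'   [observer_spec()]) and `ground_truth` (one row per observer).
#' @export
make_cohort <- function(n_per_group = 4, seed = 1,
                        regimes = list(
                          AE = list(sigma_theta = c(20, 30),
                                    I_inh = c(0.03, 0.09),
                                    c_min = c(0.004, 0.006),
                                    threshold_low = c(2.5, 5),
                                    s_iso_high = c(0.25, 0.45)),
                          NAE = list(sigma_theta = c(13, 19),
                                     I_inh = c(0.02, 0.06),
                                     c_min = c(0.004, 0.008),
                                     threshold_low = c(1.5, 3),
                                     s_iso_high = c(0.15, 0.35)),
                          NTE = list(sigma_theta = c(12, 18),
                                     I_inh = c(0.01, 0.05),
                                     c_min = c(0.003, 0.008),
                                     threshold_low = c(1.5, 3),
                                     s_iso_high = c(0.1, 0.3)))) {
  set.seed(seed)
  observers <- list()
  rows <- list()
  for (grp in names(regimes)) {
    rg <- regimes[[grp]]
    for (i in seq_len(n_per_group)) {
      draw <- function(nm) stats::runif(1, rg[[nm]][1], rg[[nm]][2])
      obs <- observer_spec(
        eye_type = grp, mode = "v1",
        I_inh = draw("I_inh"), sigma_theta = draw("sigma_theta"),
        c_min = draw("c_min"),
        a = stats::runif(1, 0.8, 1.5), b = stats::runif(1, 2.5, 5),
        threshold_low = draw("threshold_low"),
        threshold_high = draw("threshold_low") * stats::runif(1, 1.3, 2),
        s_iso_low = stats::runif(1, 0.02, 0.1),
        s_iso_high = draw("s_iso_high"),
        p3_rate = stats::runif(1, 0.15, 0.55))
      observers[[length(observers) + 1]] <- obs
      rows[[length(rows) + 1]] <- data.frame(
        id = length(observers), eye_type = grp, I_inh = obs$I_inh,
        sigma_theta = obs$sigma_theta, c_min = obs$c_min, a = obs$a,
        b = obs$b, threshold_low = obs$threshold_low,
        p3_rate = obs$p3_rate)
    }
  }
  structure(list(observers = observers,
                 ground_truth = do.call(rbind, rows), seed = seed),
            class = "observer_cohort")
}

#' @export
print.observer_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort of %d observers (seed %d):\n",
              length(x$observers), x$seed))
  print(table(x$ground_truth$eye_type))
  invisible(x)
}
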