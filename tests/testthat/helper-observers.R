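# Shared fixtures: observers and small generated datasets, built in code.

# a mid-range network-mode observer (moderate illusion, measurable CSF)
test_observer_v1 <- function(...) {
  args <- utils::modifyList(
    list(eye_type = "NTE", mode = "v1", I_inh = 0.05, sigma_theta = 20,
         c_min = 0.005, a = 1.2, b = 3.5, threshold_low = 2.5,
         threshold_high = 4, p3_rate = 0.3, s_iso_low = 0.05,
         s_iso_high = 0.3),
    list(...))
  do.call(observer_spec, args)
}

# a descriptive-mode observer with explicit biases at +/-15 degrees
test_observer_adhoc <- function(bias15 = 3, threshold = 2.5, ...) {
  observer_spec(eye_type = "NTE", mode = "adhoc", M = 150, a = 1, b = 4,
                sigma_spread = 0.5, threshold_low = threshold,
                tilt_bias = list(`15` = bias15, `-15` = -bias15,
                                 `30` = bias15 * 0.8,
                                 `-30` = -bias15 * 0.8,
                                 `0` = 0, `75` = 0, `-75` = 0),
                p3_rate = 0.3, s_iso_low = 0, ...)
}

# Bernoulli trials on a fixed contrast ladder (no staircase), for
# parameter-recovery checks of the ad-hoc surface fit
lattice_csf_trials <- function(observer, n_total, seed,
                               sfs = csf_sf_grid()) {
  set.seed(seed)
  # levels within +/-1.5 spreads of each SF's threshold, where trials are
  # informative about the psychometric location
  steps <- seq(-1.5, 1.5, by = 0.5) * observer$sigma_spread
  n_per <- ceiling(n_total / (length(sfs) * length(steps)))
  grid <- expand.grid(sf = sfs, step = steps)
  s_true <- csf_shape(grid$sf, observer$M, observer$a, observer$b)
  grid$contrast <- pmin(1, pmax(1e-4, (1 / s_true) * exp(grid$step)))
  grid <- grid[rep(seq_len(nrow(grid)), each = n_per), ]
  p3 <- observer$p3_rate
  und <- runif(nrow(grid)) < p3
  p <- observer_p_correct_public(observer, grid$contrast, grid$sf)
  ok <- runif(nrow(grid)) < p
  data.frame(measure = "csf", sf = grid$sf, contrast = grid$contrast,
             response = ifelse(und, "undecided",
                               ifelse(ok, "correct", "incorrect")),
             correct = ifelse(und, NA, ok))
}

# access the internal response model through the exported surface
observer_p_correct_public <- function(observer, c, f) {
  gamma <- guess_rate_from_undecided(observer$p3_rate)
  if (observer$mode == "adhoc") {
    eval_csf_psychometric(c, f, observer$M, observer$a, observer$b,
                          observer$sigma_spread, gamma, observer$lapse)
  } else {
    detection_probability(c, f,
                          neuronal_sensitivity(observer$c_min, observer$a,
                                               observer$b),
                          observer$I_inh, gamma = gamma,
                          lambda = observer$lapse, r0 = observer$r0)
  }
}
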