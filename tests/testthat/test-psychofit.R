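# Three-key preprocessing rules and ad-hoc maximum-likelihood fits.

test_that("guess rate follows the third-key rule", {
  expect_equal(guess_rate_from_undecided(0), 0.5)
  expect_equal(guess_rate_from_undecided(0.7), 0)
  expect_equal(guess_rate_from_undecided(0.35), 0.25)
  expect_equal(guess_rate_from_undecided(0.9), 0)
  expect_error(guess_rate_from_undecided(-0.1), "p3")
  expect_error(guess_rate_from_undecided(1.2), "p3")
})

test_that("detection surface midpoint and spread follow the convention", {
  s <- csf_shape(4, 100, 1, 4)
  gam <- 0.37
  lam <- 0.01
  mid <- eval_csf_psychometric(1 / s, 4, 100, 1, 4, 0.5, gam, lam)
  expect_equal(mid, gam + (1 - gam - lam) / 2, tolerance = 1e-12)
  # one spread unit above the midpoint: exactly 21/25 of the range
  up <- eval_csf_psychometric(exp(log(1 / s) + 0.5), 4, 100, 1, 4, 0.5,
                              gam, lam)
  expect_equal(up, gam + (1 - gam - lam) * 21 / 25, tolerance = 1e-12)
  lo <- eval_csf_psychometric(1e-12, 4, 100, 1, 4, 0.5, gam, lam)
  expect_equal(lo, gam, tolerance = 1e-6)
})

test_that("fits are invariant under trial-order permutation", {
  obs <- test_observer_adhoc()
  cs <- simulate_csf_session(obs, 101)
  f1 <- fit_csf_adhoc(cs)
  set.seed(1)
  f2 <- fit_csf_adhoc(cs[sample(nrow(cs)), ])
  expect_lt(abs(f1$M - f2$M), 1e-6)
  expect_lt(abs(f1$sigma_spread - f2$sigma_spread), 1e-9)
  expect_equal(f1$neg_log_ml, f2$neg_log_ml, tolerance = 1e-9)

  tl <- simulate_tilt_session(obs, 4, "low", 102)
  t1 <- fit_tilt_adhoc(tl)
  t2 <- fit_tilt_adhoc(tl[rev(seq_len(nrow(tl))), ])
  expect_equal(t1$biases$bias, t2$biases$bias, tolerance = 1e-9)
  expect_equal(t1$neg_log_ml, t2$neg_log_ml, tolerance = 1e-9)
})

test_that("detection-surface parameters are recovered from synthetic data", {
  obs <- test_observer_adhoc()
  peak_true <- csf_shape(obs$a * obs$b, obs$M, obs$a, obs$b)
  # dense lattice (5000 trials): peak sensitivity within a few percent
  err5k <- vapply(1:3, function(s) {
    tr <- lattice_csf_trials(obs, 5000, s)
    fit <- fit_csf_adhoc(tr)
    peak_fit <- csf_shape(fit$a_shape * fit$b_scale, fit$M, fit$a_shape,
                          fit$b_scale)
    abs(peak_fit - peak_true) / peak_true
  }, numeric(1))
  expect_lt(median(err5k), 0.03)
  # session-sized staircase data (165 trials): within 15 percent
  err165 <- vapply(1:7, function(s) {
    tr <- simulate_csf_session(obs, 200 + s)
    fit <- fit_csf_adhoc(tr)
    peak_fit <- csf_shape(fit$a_shape * fit$b_scale, fit$M, fit$a_shape,
                          fit$b_scale)
    abs(peak_fit - peak_true) / peak_true
  }, numeric(1))
  expect_lt(median(err165), 0.15)
  # the guess rate is data-derived, never fitted
  tr <- simulate_csf_session(obs, 300)
  fit <- fit_csf_adhoc(tr)
  expect_equal(fit$gamma,
               guess_rate_from_undecided(mean(tr$response == "undecided")))
})

test_that("refitting its own prediction does not beat the optimum", {
  obs <- test_observer_adhoc()
  tr <- lattice_csf_trials(obs, 2000, 5)
  fit <- fit_csf_adhoc(tr)
  gam <- fit$gamma
  nll_at <- function(M, a, b, sg) {
    use <- drop_unforced_trials(tr)
    p <- eval_csf_psychometric(use$contrast, use$sf, M, a, b, sg, gam,
                               fit$lambda)
    p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
    -sum(ifelse(use$correct, log(p), log(1 - p)))
  }
  expect_lte(fit$neg_log_ml,
             nll_at(obs$M, obs$a, obs$b, obs$sigma_spread) + 1e-6)
})

test_that("tilt biases are recovered as half-differences", {
  obs <- test_observer_adhoc(bias15 = 3)
  errs <- vapply(1:5, function(s) {
    tl <- simulate_tilt_session(obs, 4, "low", 400 + s,
                                so_set = c(-15, 15))
    fit <- fit_tilt_adhoc(tl)
    abs(fit$half_diff$bias[fit$half_diff$abs_so == 15] - 3)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
  # zero-bias observer recovers a near-zero half-difference
  obs0 <- test_observer_adhoc(bias15 = 0)
  tl0 <- simulate_tilt_session(obs0, 4, "low", 410, so_set = c(-15, 15))
  fit0 <- fit_tilt_adhoc(tl0)
  expect_lt(abs(fit0$half_diff$bias), 1)
  # thresholds are tied across opposite surrounds by construction
  tl <- simulate_tilt_session(obs, 4, "low", 420)
  fit <- fit_tilt_adhoc(tl)
  expect_equal(nrow(fit$thresholds), length(unique(abs(tl$so))))
  # sparse surrounds are flagged, not fitted
  few <- tl[!(abs(tl$so) == 30 & tl$trial > 2), ]
  fitf <- fit_tilt_adhoc(few)
  expect_true(30 %in% fitf$insufficient)
})

test_that("median bias-recovery error at 60 trials per SO is below 1 degree", {
  obs <- test_observer_adhoc(bias15 = 3)
  errs <- vapply(1:100, function(s) {
    tl <- simulate_tilt_session(obs, 4, "low", 500 + s,
                                so_set = c(-15, 15))
    fit <- fit_tilt_adhoc(tl)
    abs(fit$half_diff$bias[1] - 3)
  }, numeric(1))
  expect_lt(median(errs), 1)
})

test_that("suppression proportions pool opposite surrounds", {
  tr <- data.frame(
    so = rep(c(-15, 15, 30, -30), each = 30),
    sf = 4,
    target_orientation = 0,
    response = c(rep("not_seen", 6), rep("cw", 24),    # -15: 6/30
                 rep("not_seen", 6), rep("ccw", 24),   # +15: 6/30
                 rep("cw", 30),                        # +30: 0
                 rep("not_seen", 30)))                 # -30: all
  sp <- suppression_proportion(tr)
  expect_equal(sp$prop[sp$abs_so == 15], 12 / 60)
  expect_equal(sp$prop[sp$abs_so == 30], 0.5)
  expect_equal(sp$n, c(60L, 60L))
  tr0 <- tr[tr$response != "not_seen", ]
  expect_true(all(suppression_proportion(tr0)$prop == 0))
  # guarded logit substitutes 1/120 for zero proportions
  expect_equal(guarded_logit(0), stats::qlogis(1 / 120))
  expect_equal(guarded_logit(1), stats::qlogis(1 - 1 / 120))
  expect_equal(guarded_logit(0.3), stats::qlogis(0.3))
})
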