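# First-layer tuning, steady-state conductance model, closed-form vs
# numeric conductances.

test_that("tuning functions match their closed forms and symmetries", {
  # wrapped Gaussian: peak, periodicity, one-width falloff (explicit
  # 5-term wrap sum as the oracle)
  wrap5 <- function(x, s) {
    sum(exp(-0.5 * ((x + 180 * (-2:2)) / s)^2))
  }
  expect_equal(orientation_tuning(10, 10, 15), wrap5(0, 15))
  expect_equal(orientation_tuning(10, 10, 15), 1, tolerance = 1e-9)
  expect_equal(orientation_tuning(190, 10, 20),
               orientation_tuning(10, 10, 20))
  expect_equal(orientation_tuning(18, 10, 8), wrap5(8, 8))
  expect_equal(orientation_tuning(18, 10, 8), exp(-0.5),
               tolerance = 1e-9)
  expect_error(orientation_tuning(0, 0, -1), "sigma")

  # log-Gaussian SF tuning: peak, octave width, log symmetry
  expect_equal(sf_tuning(4, 4, 1), 1)
  expect_equal(sf_tuning(8, 4, 1), exp(-0.5))
  expect_equal(sf_tuning(2, 4, 1), sf_tuning(8, 4, 1))
  expect_error(sf_tuning(-1, 4, 1), "positive")

  # hyperbolic-ratio contrast response
  expect_equal(contrast_response(0.3, 0.3, 2, normalized = FALSE), 0.5)
  expect_equal(contrast_response(1, 0.17, 2, normalized = TRUE), 1)
  expect_equal(contrast_response(0, 0.5), 0)
  lad <- seq(0, 1, length.out = 30)
  expect_true(all(diff(contrast_response(lad, 0.2)) >= 0))
})

test_that("half-amplitude constant halves the normalized response", {
  for (ck in c(0.003, 0.05, 0.3, 1, 5, 100)) {
    ch <- half_amplitude_constant(ck, 2)
    expect_equal(contrast_response(ch, ck, 2, normalized = TRUE), 0.5,
                 tolerance = 1e-9)
  }
  expect_equal(half_amplitude_constant(1, 2), sqrt(1 / 3))
  # small-ck limit: c_half -> c_k; large-ck limit: c_half -> sqrt(1/2)
  expect_equal(half_amplitude_constant(1e-5, 2), 1e-5, tolerance = 1e-3)
  expect_equal(half_amplitude_constant(1e6, 2), sqrt(0.5),
               tolerance = 1e-6)
})

test_that("first-layer response is the product of its factor tunings", {
  fp <- v1_fixed_params()
  expect_equal(first_layer_response(10, 4, 1, 10, 4, 0.1, 20), fp$A)
  expect_equal(first_layer_response(10, 4, 0, 10, 4, 0.1, 20), 0)
  r <- first_layer_response(3, 2.5, 0.4, 10, 4, 0.1, 20)
  expect_equal(r, fp$A * orientation_tuning(3, 10, 20) *
                 sf_tuning(2.5, 4, 1) * contrast_response(0.4, 0.1))
})

test_that("steady-state voltage is the fixed point of the membrane equation", {
  fp <- v1_fixed_params()
  expect_equal(steady_state_voltage(0, 0, fp), 0)
  expect_equal(steady_state_voltage(2, 0, fp), fp$v_e * 2 / 3)
  expect_error(steady_state_voltage(-1, 0, fp), "nonnegative")

  set.seed(11)
  for (i in 1:5) {
    ge <- runif(1, 0, 4)
    gi <- runif(1, 0, 4)
    v <- steady_state_voltage(ge, gi, fp)
    expect_gte(v, fp$v_i)
    expect_lte(v, fp$v_e)
    # membrane equation residual vanishes at the fixed point
    expect_equal(-v + (fp$v_e - v) * ge + (fp$v_i - v) * gi, 0,
                 tolerance = 1e-12)
    # forward integration from rest converges to the same value
    sol <- deSolve::ode(
      y = c(v = 0), times = c(0, 200), parms = NULL,
      func = function(t, y, p) {
        list((-y + (fp$v_e - y) * ge + (fp$v_i - y) * gi) / fp$tau)
      }, rtol = 1e-10, atol = 1e-12)
    expect_equal(unname(sol[2, "v"]), v, tolerance = 1e-8)
  }

  expect_equal(firing_rate(fp$T, fp), 0)
  expect_equal(firing_rate(fp$T + 1, fp), 1)
  expect_equal(firing_rate(fp$T - 3, fp), 0)
})

test_that("closed-form tilt conductances equal direct grid summation", {
  set.seed(21)
  worst <- 0
  for (i in 1:50) {
    sg <- runif(1, 8, 35)
    I <- runif(1, 0, 0.3)
    tc <- runif(1, -90, 90)
    ts <- runif(1, -90, 90)
    g1 <- tilt_conductances(tc, ts, sg, I)
    g2 <- tilt_conductances_numeric(tc, ts, sg, I)
    rel <- max(abs(g1$g_e - g2$g_e) / pmax(abs(g1$g_e), 1e-12),
               abs(g1$g_i - g2$g_i) / pmax(abs(g1$g_i), 1e-12))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-6)

  # zero inhibition / absent surround give zero inhibitory conductance
  g <- tilt_conductances(0, 30, 20, 0)
  expect_true(all(g$g_i == 0))
  g <- tilt_conductances(0, 30, 20, 0.1, amp_surround = 0)
  expect_true(all(g$g_i == 0))
  # linearity in I_inh
  g1 <- tilt_conductances(0, 30, 20, 0.05)
  g2 <- tilt_conductances(0, 30, 20, 0.10)
  expect_equal(g2$g_i, 2 * g1$g_i)
  # excitatory profile peaks at, and is symmetric about, the centre
  th <- orientation_grid()
  ge <- tilt_conductances(10, 40, 18, 0.05)$g_e
  expect_equal(th[which.max(ge)], 10)
  expect_equal(ge[match(10 + 20, th)], ge[match(10 - 20, th)])
})

test_that("population rates are nonnegative and 180-degree periodic", {
  prm <- tilt_params(0.06, 18)
  r <- population_response_tilt(5, 20, prm)
  expect_true(all(r$rates >= 0))
  r2 <- population_response_tilt(5 + 180, 20 + 180, prm)
  expect_equal(r$rates, r2$rates)
})

test_that("SF coupling kernel matches dense numeric integration", {
  # moderate widths, where a discretised input layer is meaningful
  for (sg in c(0.5, 1, 2)) {
    f_j <- 4
    scs <- sg / 2
    dl <- 0.001
    lg <- seq(log2(f_j) - 12, log2(f_j) + 12, by = dl)
    for (f in c(2, 4, 6)) {
      num <- sum(exp(-0.5 * ((log2(f_j) - lg) / scs)^2) *
                   exp(-0.5 * ((lg - log2(f)) / sg)^2)) *
        dl / (sqrt(2 * pi) * scs)
      expect_equal(sf_coupling(f, f_j, sg), num, tolerance = 1e-6)
    }
  }
  # matched-SF value under the half-width entanglement is width-free
  expect_equal(sf_coupling(4, 4, 1), 1 / sqrt(1.25))
  expect_equal(sf_coupling(8, 8, 0.001), 1 / sqrt(1.25))
})

test_that("configuration file reproduces the fixed-parameter block", {
  skip_if_not_installed("yaml")
  cfg <- read_v1_config()
  expect_s3_class(cfg$fixed_params, "v1_fixed_params")
  expect_equal(cfg$fixed_params$v_e, 14 / 3, tolerance = 1e-6)
  expect_equal(cfg$fixed_params$n_s, 6)
  expect_equal(cfg$r0_floor, 0.01)
})
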