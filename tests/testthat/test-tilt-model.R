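# Vector-average decoding and the predicted tilt-repulsion curve.

test_that("decoder matches a brute-force resultant oracle", {
  th <- orientation_grid()
  # independent oracle: explicit angle-doubled resultant loop
  oracle <- function(rates, th) {
    s <- 0
    c <- 0
    for (i in seq_along(th)) {
      s <- s + rates[i] * sin(2 * th[i] * pi / 180)
      c <- c + rates[i] * cos(2 * th[i] * pi / 180)
    }
    a <- atan2(s, c) / 2 * 180 / pi
    if (a <= -90) a + 180 else a
  }
  set.seed(31)
  for (i in 1:20) {
    rates <- runif(length(th))^2
    expect_equal(decode_orientation(rates, th), oracle(rates, th),
                 tolerance = 1e-12)
  }
  # delta response decodes to the preferred orientation
  r <- numeric(length(th))
  r[match(34, th)] <- 1
  expect_equal(decode_orientation(r, th), 34)
  # symmetric response about 5 degrees decodes to 5 degrees
  r <- exp(-0.5 * ((th - 5) / 12)^2) + exp(-0.5 * ((th - 5 + 180) / 12)^2) +
    exp(-0.5 * ((th - 5 - 180) / 12)^2)
  expect_equal(decode_orientation(r, th), 5, tolerance = 1e-9)
  # degenerate cases are refused
  expect_error(decode_orientation(rep(0, length(th)), th), "undefined")
  expect_error(decode_orientation(rep(1, length(th)), th), "undefined")
})

test_that("decoder is equivariant under global rotation", {
  prm <- tilt_params(0.06, 18)
  for (rot in c(-30, 14, 52)) {
    d0 <- decode_orientation(population_response_tilt(0, 15, prm))
    d1 <- decode_orientation(population_response_tilt(rot, 15 + rot, prm))
    delta <- (d1 - d0 - rot) %% 180
    expect_lt(min(delta, 180 - delta), 1e-6)
  }
})

test_that("bias curve is antisymmetric with zeros at 0 and 90 degrees", {
  set.seed(32)
  for (i in 1:5) {
    prm <- tilt_params(runif(1, 0.01, 0.12), runif(1, 10, 30))
    sos <- c(5, 15, 30, 50, 75)
    b_pos <- predict_tilt_bias(prm, sos)$bias
    b_neg <- predict_tilt_bias(prm, -sos)$bias
    expect_equal(b_neg, -b_pos, tolerance = 1e-9)
    expect_equal(predict_tilt_bias(prm, 0)$bias, 0, tolerance = 1e-9)
    expect_equal(predict_tilt_bias(prm, 90)$bias, 0, tolerance = 1e-9)
  }
})

test_that("no interaction means no bias", {
  prm <- tilt_params(0, 20)
  b <- predict_tilt_bias(prm, c(-30, -15, 15, 30, 60))$bias
  expect_equal(b, rep(0, 5), tolerance = 1e-9)
  # without inhibition the response peaks at the centre orientation
  r <- population_response_tilt(12, 40, prm)
  expect_equal(r$theta_i[which.max(r$rates)], 12)
  # zero-contrast surround: no inhibitory conductance, no bias
  r0 <- population_response_tilt(0, 15, tilt_params(0.08, 20),
                                 surround = FALSE)
  expect_true(all(r0$g_i == 0))
})

test_that("repulsion regime: positive direct bias peaking at mid SOs", {
  for (sg in c(10, 20, 30)) {
    for (I in c(0.02, 0.08)) {
      prm <- tilt_params(I, sg)
      expect_gt(predict_tilt_bias(prm, 15)$bias, 0)
      curve <- predict_tilt_bias(prm, seq(2, 88, by = 2))
      peak_so <- curve$so[which.max(abs(curve$bias))]
      expect_gt(peak_so, 5)
      expect_lt(peak_so, 45)
    }
  }
  # the surround reduces the maximum firing rate of the population
  with_s <- population_response_tilt(0, 0, tilt_params(0.08, 20))
  no_s <- population_response_tilt(0, 0, tilt_params(0.08, 20),
                                   surround = FALSE)
  expect_lt(max(with_s$rates), max(no_s$rates))
})

test_that("bias amplitude grows with inhibition strength", {
  ladder <- seq(0.01, 0.15, length.out = 10)
  b <- vapply(ladder, function(I) {
    predict_tilt_bias(tilt_params(I, 20), 15)$bias
  }, numeric(1))
  expect_true(all(diff(b) > 0))
})

test_that("model psychometric follows the shared spread convention", {
  prm <- tilt_params(0.05, 20, threshold_sigma = 3)
  a <- predict_tilt_bias(prm, 15)$bias
  expect_equal(tilt_psychometric_model(a, 15, prm), 0.5)
  expect_equal(tilt_psychometric_model(a + 3, 15, prm),
               0.01 + 0.98 * 21 / 25, tolerance = 1e-12)
  expect_equal(tilt_psychometric_model(a + 1000, 15, prm), 0.99,
               tolerance = 1e-6)
  th <- seq(-20, 20, by = 1)
  expect_true(all(diff(tilt_psychometric_model(th, 15, prm)) > 0))
  # reflection symmetry of the response profile
  r1 <- population_response_tilt(10, 25, prm)
  r2 <- population_response_tilt(-10, -25, prm)
  expect_equal(r1$rates, rev(r2$rates)[c(length(r2$rates),
                                         seq_len(length(r2$rates) - 1))],
               tolerance = 1e-12)
})
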