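# In the anchor design theta0 = 0.1, theta1 = 0.2 with h = 0.5 the event
# weight log(2) already exceeds h, so a single event signals from zero and
# the run length is geometric: ARL = 1/rate.

test_that("Markov-chain ARL reproduces the geometric closed form", {
  expect_equal(markov_arl(0.1, 0.2, h = 0.5)$arl, 10, tolerance = 1e-9)
  expect_equal(markov_arl(0.1, 0.2, h = 0.5, regime = "out-of-control")$arl,
               5, tolerance = 1e-9)
})

test_that("Monte-Carlo ARL agrees with the geometric closed form within 3 SE", {
  sp <- calibration_spec(10, risk = 0.1,
                         hypotheses = list(theta0 = 0.1, theta1 = 0.2),
                         nrep = 10000, horizon = 400, seed = 99)
  e0 <- simulate_arl(sp, h = 0.5)
  expect_lt(abs(e0$arl - 10), 3 * e0$se)
  e1 <- simulate_arl(sp, h = 0.5, regime = "out-of-control")
  expect_lt(abs(e1$arl - 5), 3 * e1$se)
})

test_that("identical spec and seed reproduce the estimate exactly", {
  sp <- calibration_spec(10, risk = list(dist = "beta", shape1 = 2,
                                         shape2 = 8),
                         hypotheses = list(R0 = 1, R1 = 2),
                         nrep = 2000, horizon = 400, seed = 31)
  a <- simulate_arl(sp, h = 0.6)
  b <- simulate_arl(sp, h = 0.6)
  expect_identical(a$arl, b$arl)
  expect_identical(a$se, b$se)
})

test_that("ARL grows with the control limit and detection beats false alarm", {
  arls <- vapply(c(0.5, 1, 2, 3),
                 function(h) markov_arl(0.1, 0.2, h)$arl, numeric(1))
  expect_true(all(diff(arls) > 0))
  # at fixed h, a true shift is detected faster than a false alarm occurs
  expect_lt(markov_arl(0.1, 0.2, 2, regime = "out-of-control")$arl,
            markov_arl(0.1, 0.2, 2)$arl)
})

test_that("Markov and Monte-Carlo ARLs agree within 3 SE off the closed form", {
  sp <- calibration_spec(100, risk = 0.1,
                         hypotheses = list(theta0 = 0.1, theta1 = 0.2),
                         nrep = 20000, horizon = 4000, seed = 12)
  mc <- simulate_arl(sp, h = 2)
  mk <- markov_arl(0.1, 0.2, h = 2)
  expect_lt(abs(mc$arl - mk$arl), 3 * mc$se)
  expect_lt(mk$convergence_gap, 1e-2)
})

test_that("an improvement-side chart (theta1 < theta0) calibrates the same way", {
  # odds halved at p = 0.2: alternative rate 1/9 under the null rate 0.2
  th1 <- shifted_rate(0.2, 0.5)
  mk <- markov_arl(0.2, th1, h = 1.5)
  sp <- calibration_spec(50, risk = 0.2,
                         hypotheses = list(theta0 = 0.2, theta1 = th1),
                         nrep = 10000, horizon = 2000, seed = 7)
  mc <- simulate_arl(sp, h = 1.5)
  expect_lt(abs(mc$arl - mk$arl), 3 * mc$se)
})

test_that("a too-small horizon censors replicates and flags the estimate", {
  sp <- calibration_spec(10, risk = 0.1,
                         hypotheses = list(theta0 = 0.1, theta1 = 0.2),
                         nrep = 500, horizon = 120, seed = 3)
  expect_warning(e <- simulate_arl(sp, h = 3), "lower bound")
  expect_gt(e$censored_fraction, 0.05)
  expect_true(e$lower_bound)
})

test_that("the control-limit search solves the geometric toy and is reproducible", {
  sp <- calibration_spec(10, risk = 0.1,
                         hypotheses = list(theta0 = 0.1, theta1 = 0.2),
                         nrep = 4000, horizon = 400, seed = 17)
  cal <- find_control_limit(sp)
  # any h in (0, log 2] has true ARL0 = 10; the search must not overshoot
  expect_lte(cal$h, log(2) + 1e-9)
  expect_lt(abs(cal$arl0 - 10), 4 * cal$se)
  cal2 <- find_control_limit(sp)
  expect_identical(cal$h, cal2$h)
})

test_that("calibration inputs are validated", {
  expect_error(calibration_spec(1, risk = 0.1,
                                hypotheses = list(R0 = 1, R1 = 2)),
               "target_arl0")
  expect_error(calibration_spec(10, risk = 0.1,
                                hypotheses = list(R0 = 1, R1 = 2),
                                horizon = 50), "horizon")
  expect_error(calibration_spec(10, risk = list(dist = "beta", shape1 = 2,
                                                shape2 = 8),
                                hypotheses = list(theta0 = 0.1,
                                                  theta1 = 0.2)),
               "constant risk")
  sp <- calibration_spec(10, risk = 0.1, hypotheses = list(R0 = 1, R1 = 2),
                         nrep = 100, horizon = 200)
  expect_error(find_control_limit(sp), "1000")
  expect_error(simulate_arl(sp, h = -1), "positive")
  expect_error(markov_arl(0.1, 0.2, 1, n_states = 10), "n_states")
})
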