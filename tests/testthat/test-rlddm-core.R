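test_that("delta-rule update and prediction error match hand calculations", {
  expect_equal(q_update(0, 0.5, 1), 0.5)
  expect_equal(q_update(0.7, 0.42, 0.7), 0.7)  # zero-PE fixed point
  expect_equal(q_update(0.7, 0.1, 0), 0.63)
  expect_error(q_update(0, 1.2, 1), "alpha")
  expect_error(q_update(0, 0, 1), "alpha")
  expect_equal(prediction_error(0.7, 1), 0.3)
  expect_equal(prediction_error(0.7, 0), -0.7)
  expect_equal(prediction_error(-0.4, -1), -0.6)
})

test_that("Q values converge to the reinforcement rate and stay bounded", {
  set.seed(7)
  for (alpha in c(0.05, 0.3, 0.8)) {
    q <- 0
    qs <- numeric(1e4)
    for (i in seq_len(1e4)) {
      q <- q_update(q, alpha, rbinom(1, 1, 0.7))
      qs[i] <- q
    }
    expect_true(all(qs >= -1 & qs <= 1))
    expect_lt(abs(mean(qs[2000:1e4]) - 0.7), 0.05)
  }
  # boundary cases of the update formula itself
  expect_equal(0.3 + 0 * (1 - 0.3), 0.3)      # alpha -> 0: constant
  expect_equal(0.3 + 1 * (1 - 0.3), 1)        # alpha -> 1: last outcome
})

test_that("drift rate follows the variant definitions", {
  base <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1.5, t_nd = .3)
  expect_equal(drift_rate(0.7, 0.3, base, t = 1), 0.8)
  expect_equal(drift_rate(NA, NA, base, neutral = TRUE), 0.4 * 2)
  bs <- subject_params("RLDDM_bspow", alpha = .3, nu = 2, bb = 1.2,
                       bp = -.2, t_nd = .3)
  expect_equal(drift_rate(0.7, 0.3, bs, t = 37), 0.8)  # nu-scaled, t-free
  dr <- subject_params("RLDDM_drpow", alpha = .3, a = 1.5, p = 0.7,
                       t_nd = .3)
  # at t = 10 the power term is 1 regardless of p
  expect_equal(drift_rate(0.7, 0.3, dr, t = 10), 0.4)
  expect_equal(drift_rate(0.7, 0.3, dr, t = 40), 0.4 * 4^0.7)
  # the printed drift-power form drops nu; the toggle reinstates it
  drnu <- subject_params("RLDDM_drpow", alpha = .3, nu = 3, a = 1.5,
                         p = 0.7, t_nd = .3, include_nu = TRUE)
  expect_equal(drift_rate(0.7, 0.3, drnu, t = 10), 1.2)
})

test_that("boundary separation follows the variant definitions", {
  bs <- subject_params("RLDDM_bspow", alpha = .3, nu = 2, bb = 2, bp = 1,
                       t_nd = .3)
  expect_equal(boundary_separation(bs, t = 20), 4)
  expect_equal(boundary_separation(bs, t = 10), 2)     # anchor
  bs0 <- subject_params("RLDDM_bspow", alpha = .3, nu = 2, bb = 2, bp = 0,
                        t_nd = .3)
  for (t in c(1, 10, 60)) expect_equal(boundary_separation(bs0, t), 2)
  base <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1.5, t_nd = .3)
  expect_equal(boundary_separation(base, t = 55), 1.5)
})

test_that("parameter validation enforces supports and variant fields", {
  expect_error(subject_params("RLDDM", alpha = 1.1, nu = 2, a = 1,
                              t_nd = .3), "alpha")
  expect_error(subject_params("RLDDM", alpha = .3, nu = -2, a = 1,
                              t_nd = .3), "positive")
  expect_error(subject_params("RLDDM_bspow", alpha = .3, nu = 2,
                              t_nd = .3), "bb")
  p <- subject_params("RLDDM", alpha = .3, nu = 2, a = 1, t_nd = .3)
  expect_equal(p$z, 0.5)
})
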