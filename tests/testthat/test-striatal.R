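test_that("gain functions reproduce their sigmoid forms", {
  lp <- gain_params("learning")
  expect_equal(gain("D1", 0, lp), 0)
  expect_equal(gain("D1", 0.1, lp), 0.986614298151431, tolerance = 1e-12)
  # D1R-D2R gain is the sum of the two half-height sigmoids
  expect_equal(gain("D1D2", 0, lp), 0.0499875000002604, tolerance = 1e-12)
  expect_equal(gain("D1D2", 0.3, lp),
               gain("hD1", 0.3, lp) + gain("hD2", 0.3, lp))
  expect_error(gain("D5", 0, lp), "unknown")
})

test_that("D1 gain increases and D2 gain decreases in the dopamine signal", {
  lp <- gain_params("learning")
  grid <- seq(-2, 2, by = 0.05)
  # monotone over the full range (the sigmoids saturate to exactly +/-1 in
  # double precision beyond |delta| ~ 1), strictly so in the responsive part
  expect_true(all(diff(gain("D1", grid, lp)) >= 0))
  expect_true(all(diff(gain("D2", grid, lp)) <= 0))
  expect_true(all(diff(gain("D1", seq(-0.3, 0.3, by = 0.01), lp)) > 0))
  expect_true(all(diff(gain("D2", seq(0.7, 1.3, by = 0.01), lp)) < 0))
  # U-shape of the co-expressing pool: extremes respond at least as much
  # as the midpoint
  mid <- gain("D1D2", 0, lp)
  expect_true(all(gain("D1D2", c(-2, -1.5, -1, 1, 1.5, 2), lp) >= mid))
})

test_that("MSN responses read out the one-hot weight entries", {
  w <- striatal_weights()
  w$w_d1[3, 2] <- 0.7
  w$w_d1d2[1, 1] <- -0.2
  expect_equal(msn_response(w, 3, 2),
               c(y_d1 = 0.7, y_d2 = 0, y_d1d2 = 0))
  expect_equal(msn_response(w, 1, 1)[["y_d1d2"]], -0.2)
  expect_equal(unname(msn_response(striatal_weights(), 2, 1)), c(0, 0, 0))
  expect_error(msn_response(w, 5, 1), "out of range")
})

test_that("TD error and utility arithmetic", {
  expect_equal(td_error(1, 0), 1)
  expect_equal(td_error(0, 0.4), -0.4)
  expect_equal(td_error(-1, -1), 0)
  # risk-averse for gains, risk-seeking for losses, neutral at alpha = 0
  expect_equal(compute_utility(0.5, 0.2, 1), 0.3)
  expect_equal(compute_utility(-0.5, 0.2, 1), -0.3)
  expect_equal(compute_utility(0.4, 0.3, 0), 0.4)
  expect_equal(compute_utility(0, 5, 1), 0)   # sign(0) carries no risk
  # alpha = 0 reduces utility to value for any inputs
  set.seed(1)
  Q <- rnorm(50); h <- rnorm(50)
  expect_equal(compute_utility(Q, h, 0), Q)
  # sqrt transform applies sign-preserving square root to the risk
  expect_equal(compute_utility(1, 0.25, 1, risk_transform = "sqrt"), 0.5)
})

test_that("utility difference is zero on the first trial", {
  expect_equal(utility_difference(0.3, 0.1), 0.2)
  expect_equal(utility_difference(0.7, NA_real_), 0)
  expect_equal(utility_difference(0.4, 0.4), 0)
})

test_that("group dopamine conditions clamp and medicate the TD error", {
  hc <- subject_condition("HC")
  off <- subject_condition("PD-OFF")
  on <- subject_condition("PD-ON-ICD")
  expect_equal(apply_da_condition(0.5, hc), 0.5)
  expect_equal(apply_da_condition(0.5, off), 0.001)
  expect_equal(apply_da_condition(0.5, on), 0.061)
  expect_equal(apply_da_condition(-0.5, off), -0.5)  # clamp is one-sided
  # bound properties over a grid of TD errors
  grid <- seq(-2, 2, by = 0.01)
  expect_true(all(apply_da_condition(grid, off) <= off$delta_lim))
  expect_true(all(apply_da_condition(grid, on) <= on$delta_lim + on$delta_med))
  expect_error(make_condition(delta_med = 0.06), "delta_lim")
})

test_that("group parameter sets load exactly", {
  tab <- list("HC" = c(1, 0.185, 0.997, NA, NA),
              "PD-OFF" = c(1, 0.991, 0.033, 0.001, NA),
              "PD-ON-ICD" = c(1, 0.046, 0.001, 0.001, 0.06),
              "PD-ON-nonICD" = c(1, 0.916, 0.160, 0.001, 0.06))
  for (g in names(tab)) {
    cond <- subject_condition(g)
    expect_equal(c(cond$alpha_d1, cond$alpha_d2, cond$alpha_d1d2,
                   cond$delta_lim, cond$delta_med), tab[[g]],
                 info = g)
  }
  expect_equal(subject_condition("HC")$eta_d1, 0.01)
  expect_equal(subject_condition("HC")$eta_d2, 0.1)
  # packaged config file stays in sync with the built-ins
  from_yaml <- read_group_conditions()
  for (g in names(tab))
    expect_equal(from_yaml[[g]][c("alpha_d1", "alpha_d2", "alpha_d1d2",
                                  "delta_lim", "delta_med")],
                 subject_condition(g)[c("alpha_d1", "alpha_d2", "alpha_d1d2",
                                        "delta_lim", "delta_med")],
                 info = g)
})

test_that("weight updates are local and gain-scaled", {
  w <- striatal_weights()
  cond <- subject_condition("HC")
  w2 <- update_weights(w, 2, 1, 0.1, cond)
  expect_equal(w2$w_d1[2, 1], 0.00986614298151431, tolerance = 1e-12)
  expect_equal(w2$w_d2[2, 1], 0.1 * gain("D2", 0.1, gain_params("learning")))
  # all other entries bit-identical
  expect_identical(w2$w_d1[-2, ], w$w_d1[-2, ])
  expect_identical(w2$w_d1[2, 2], w$w_d1[2, 2])
  # zero TD error leaves the D1 weight exactly unchanged
  w3 <- update_weights(w, 1, 1, 0, cond)
  expect_identical(w3$w_d1[1, 1], 0)
  expect_error(update_weights(w, 9, 1, 0.1, cond), "out of range")
})

test_that("repeated updates drive the value toward the reward mean", {
  # 80% r = +1 / 20% r = 0 schedule on one (state, action): Q must rise
  # toward the high-reward regime, with the drift sign following the
  # prediction error
  cond <- subject_condition("HC")
  w <- striatal_weights()
  set.seed(99)
  for (i in 1:1000) {
    r <- ifelse(runif(1) < 0.8, 1, 0)
    delta <- td_error(r, w$w_d1[1, 1])
    w <- update_weights(w, 1, 1, apply_da_condition(delta, cond), cond)
  }
  expect_gt(w$w_d1[1, 1], 0.5)
  # at the settled value, expected TD error is near zero
  expect_lt(abs(0.8 * (1 - w$w_d1[1, 1]) + 0.2 * (0 - w$w_d1[1, 1])), 0.25)
})
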