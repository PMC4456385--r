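test_that("the origin is a fixed point and activity stays bounded", {
  p <- circuit_params()
  st <- circuit_state(p, init = "zero")
  st2 <- step_stn_gpe(st, c(0, 0), p)
  expect_identical(st2$x_stn, c(0, 0))
  expect_identical(st2$x_gpe, c(0, 0))
  # small perturbation: sustained, bounded, non-constant activity
  st$x_stn[1] <- 1e-3
  st$y_stn <- tanh(p$lambda_stn * st$x_stn)
  xs <- numeric(5000)
  for (i in 1:5000) {
    st <- step_stn_gpe(st, c(0, 0), p)
    xs[i] <- st$x_stn[1]
  }
  expect_lt(max(abs(xs)), 10)
  expect_gt(stats::sd(tail(xs, 2000)), 1e-6)
  expect_true(all(abs(tanh(p$lambda_stn * xs)) <= 1))
})

test_that("zero STN slope decouples the loop", {
  p <- circuit_params(eps_s = 0, lambda_stn = 0)
  st <- circuit_state(p, init = "zero")
  st$x_stn <- c(0.5, -0.3)
  traj <- matrix(NA_real_, 50, 2)
  for (i in 1:50) {
    st <- step_stn_gpe(st, c(0, 0), p)
    traj[i, ] <- st$x_stn
  }
  expect_true(all(st$y_stn == 0))
  # with silent GPe the STN states decay geometrically
  expect_true(all(diff(abs(traj[, 1])) < 0))
  expect_equal(traj[50, 1], 0.5 * 0.9^50, tolerance = 1e-10)
})

test_that("leaky thalamic integration crosses at the closed-form iteration", {
  p <- circuit_params(lambda_stn = 0, leak = 1)
  # constant x_thal = 2.0: y_k = 2 (1 - 0.9^k) crosses 1.815 at k = 23
  res <- select_action(c(2, 0), c(0, 0),
                       p, init = circuit_state(p, init = "zero"))
  expect_equal(res$action, 1L)
  expect_equal(res$rt_iters, 23L)
  expect_true(res$crossed)
  # 20 random supra-threshold drives match the closed form
  set.seed(7)
  for (x in runif(20, 1.9, 6)) {
    res <- select_action(c(x, 0), c(0, 0), p,
                         init = circuit_state(p, init = "zero"))
    k <- ceiling(log(1 - p$threshold / x) / log(1 - p$dt_thal))
    expect_equal(res$rt_iters, k, info = paste("x =", x))
  }
  # sub-threshold constant drive never crosses (asymptote below threshold)
  res <- select_action(c(1.5, 0), c(0, 0), p,
                       init = circuit_state(p, init = "zero"))
  expect_false(res$crossed)
  expect_equal(res$rt_iters, p$max_iters)
})

test_that("accumulator crossing times follow the non-leaky closed form", {
  p <- circuit_params(lambda_stn = 0)  # leak = 0 default
  set.seed(8)
  for (x in runif(20, 0.05, 3)) {
    res <- select_action(c(x, 0), c(0, 0), p,
                         init = circuit_state(p, init = "zero"))
    k <- ceiling(p$threshold / (p$dt_thal * x))
    if (k <= p$max_iters) {
      expect_true(res$crossed)
      expect_equal(res$rt_iters, k, info = paste("x =", x))
    } else {
      expect_false(res$crossed)
    }
  }
})

test_that("pure decay and tie-breaking behave as documented", {
  p <- circuit_params(lambda_stn = 0, leak = 1)
  # zero drive: thalamic units stay at zero, argmax tie resolves to the
  # lowest index deterministically
  res <- select_action(c(0, 0), c(0, 0), p,
                       init = circuit_state(p, init = "zero"))
  expect_false(res$crossed)
  expect_equal(res$action, 1L)
  # exactly symmetric supra-threshold inputs cross together; the stated
  # max-then-lowest-index rule picks action 1, deterministically
  res <- select_action(c(2, 2), c(0, 0), p,
                       init = circuit_state(p, init = "zero"))
  expect_true(res$crossed)
  expect_equal(res$action, 1L)
  expect_identical(res, select_action(c(2, 2), c(0, 0), p,
                                      init = circuit_state(p, init = "zero")))
})

test_that("stronger common drive never slows the race", {
  p <- quick_circuit()
  set.seed(21)
  for (i in 1:100) {
    x_dp <- runif(2, -0.2, 0.6)
    x_ip <- runif(2, -0.3, 0.3)
    init <- circuit_state(p, seed = i)
    r1 <- select_action(x_dp, x_ip, p, init = init)
    r2 <- select_action(x_dp + 0.2, x_ip, p, init = init)
    expect_lte(r2$rt_iters, r1$rt_iters)
  }
})

test_that("compiled and reference race implementations agree exactly", {
  p <- quick_circuit()
  set.seed(5)
  for (i in 1:25) {
    x_dp <- runif(2, -0.3, 0.8)
    x_ip <- runif(2, -0.5, 0.5)
    init <- circuit_state(p, seed = 1000 + i)
    a <- select_action(x_dp, x_ip, p, init = init, use_compiled = TRUE)
    b <- select_action(x_dp, x_ip, p, init = init, use_compiled = FALSE)
    expect_equal(a$action, b$action)
    expect_equal(a$rt_iters, b$rt_iters)
    expect_equal(a$crossed, b$crossed)
    expect_equal(a$y_thal, b$y_thal, tolerance = 1e-12)
    expect_equal(a$x_stn, b$x_stn, tolerance = 1e-12)
  }
  # recorded trajectories agree too
  init <- circuit_state(p, seed = 3)
  a <- select_action(c(0.4, 0.1), c(0, 0), p, init = init, record = TRUE)
  b <- select_action(c(0.4, 0.1), c(0, 0), p, init = init, record = TRUE,
                     use_compiled = FALSE)
  expect_equal(a$trajectories, b$trajectories, tolerance = 1e-12)
})

test_that("dimension and parameter validation", {
  p <- circuit_params()
  expect_error(select_action(c(1, 2, 3), c(0, 0), p), "length")
  expect_error(select_action(c(1, NA), c(0, 0), p), "finite")
  expect_error(circuit_params(max_iters = 0), "max_iters")
  expect_equal(gpi_output(circuit_state(p, init = "zero"), c(0.5, 0), p),
               c(-0.5, 0))
})
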