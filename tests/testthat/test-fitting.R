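# cheap analytic costs keep the optimizer tests fast; the simulation-backed
# cost is exercised in the acceptance suite
quad_cost <- function(p, spec) (p[["alpha_d2"]] - 0.3)^2
sphere_cost <- function(p, spec) sum(p^2)

test_that("fit specifications validate their parameter partition", {
  expect_error(fit_spec(free = c("alpha_d2"), fixed = c(alpha_d2 = 1),
                        target = c(reward_optimality = 0.5,
                                   punishment_optimality = 0.5)),
               "both free and fixed")
  expect_error(fit_spec(free = c("alpha_d2"),
                        fixed = c(alpha_d1 = 1),
                        target = c(reward_optimality = 0.5,
                                   punishment_optimality = 0.5)),
               "cover")
  expect_error(fit_spec(free = "alpha_d2",
                        fixed = c(alpha_d1 = 1, alpha_d1d2 = 0,
                                  delta_lim = NA, delta_med = NA),
                        target = c(reward_optimality = 0.5,
                                   punishment_optimality = 0.5),
                        bounds = list(alpha_d2 = c(1, Inf))),
               "infeasible")
})

make_spec <- function(free = "alpha_d2", bounds = NULL, ...) {
  fixed_names <- setdiff(c("alpha_d1", "alpha_d2", "alpha_d1d2",
                           "delta_lim", "delta_med"), free)
  fixed <- stats::setNames(c(alpha_d1 = 1, alpha_d2 = 1, alpha_d1d2 = 0,
                             delta_lim = NA_real_,
                             delta_med = NA_real_)[fixed_names], fixed_names)
  fit_spec(free = free, fixed = fixed,
           target = c(reward_optimality = 0.5, punishment_optimality = 0.5),
           bounds = bounds, ...)
}

test_that("grid search finds the minimizer of a convex 1-D cost", {
  spec <- make_spec(bounds = list(alpha_d2 = c(0, 1)), grid_points = 11L)
  g <- grid_search(spec, cost = quad_cost)
  expect_equal(g$alpha_d2[1], 0.3)
  expect_equal(g$cost, sort(g$cost))
  # deterministic cost: stable ranking across calls
  expect_identical(g, grid_search(spec, cost = quad_cost))
  expect_error(grid_search(make_spec(grid_points = 1L), cost = quad_cost),
               "resolution")
})

test_that("the genetic algorithm minimizes a sphere within bounds", {
  spec <- make_spec(free = c("alpha_d1", "alpha_d2"),
                    bounds = list(alpha_d1 = c(-1, 1), alpha_d2 = c(-1, 1)),
                    pop_size = 40L, generations = 40L, seed = 3)
  ga <- ga_optimize(spec, cost = sphere_cost)
  expect_lt(ga$best_cost, 1e-3)
  expect_true(all(abs(ga$best) <= 1))
  # elitism: best-so-far cost is non-increasing across generations
  expect_true(all(diff(ga$trace) <= 0))
  # fixed seed, identical result
  ga2 <- ga_optimize(spec, cost = sphere_cost)
  expect_identical(ga$best, ga2$best)
})

test_that("two-step fitting ranks step-1 survivors by the RT criterion", {
  # analytic stand-in: step 1 leaves several near-ties, step 2 must pick
  # the survivor with the better RT agreement
  spec <- make_spec(bounds = list(alpha_d2 = c(0, 1)), grid_points = 5L,
                    pop_size = 6L, generations = 2L, seed = 2,
                    n_instances = 2L)
  # degenerate free set returns the fixed parameters with their costs
  spec0 <- fit_spec(free = character(0),
                    fixed = c(alpha_d1 = 1, alpha_d2 = 0.2, alpha_d1d2 = 0.5,
                              delta_lim = NA_real_, delta_med = NA_real_),
                    target = c(reward_optimality = 0.5,
                               punishment_optimality = 0.6),
                    n_instances = 2L, seed = 5)
  f0 <- two_step_fit(spec0)
  expect_equal(f0$best_params$alpha_d2, 0.2)
  expect_gte(f0$step1_cost, 0)
})

test_that("optimality cost is non-negative and zero on self-targets", {
  cond <- subject_condition("PD-ON-ICD")
  g <- run_group(cond, n_instances = 2, base_seed = 31)
  spec <- fit_spec(free = c("alpha_d2", "alpha_d1d2"),
                   fixed = c(alpha_d1 = 1, delta_lim = 0.001,
                             delta_med = 0.06),
                   target = c(reward_optimality = g$reward_optimality[["mean"]],
                              punishment_optimality =
                                g$punishment_optimality[["mean"]]),
                   n_instances = 2L, seed = 31)
  self <- c(alpha_d2 = cond$alpha_d2, alpha_d1d2 = cond$alpha_d1d2)
  expect_equal(optimality_cost(self, spec), 0)
  expect_gte(optimality_cost(c(alpha_d2 = 1.2, alpha_d1d2 = 1.2), spec), 0)
})

test_that("a random-choice model scores chance-level cost on a perfect target", {
  # alpha = 0 silences both pathways: choices ride on circuit noise alone,
  # so optimality sits at 1/2 and the squared error to a perfect (1, 1)
  # target approaches 2 * 0.25
  spec <- fit_spec(free = "alpha_d2",
                   fixed = c(alpha_d1 = 0, alpha_d1d2 = 0,
                             delta_lim = NA_real_, delta_med = NA_real_),
                   target = c(reward_optimality = 1,
                              punishment_optimality = 1),
                   n_instances = 8L, seed = 17)
  cost <- optimality_cost(c(alpha_d2 = 0), spec)
  expect_gt(cost, 0.35)
  expect_lt(cost, 0.65)
})
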