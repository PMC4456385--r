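#' Specification of a model-fitting problem
#'
#' Declares which of the five condition parameters (`alpha_d1`, `alpha_d2`,
#' `alpha_d1d2`, `delta_lim`, `delta_med`) are free (with box bounds) and
#' which are fixed, the behavioral targets, and the search budget.  The
#' default bounds cover all fitted group parameter sets: alphas in
#' \[0, 1.2\], `delta_lim` in \[1e-4, 1\], `delta_med` in \[0, 0.5\].
#'
#' @param free Character vector of free parameter names.
#' @param fixed Named numeric vector of the remaining parameters (use `NA`
#'   to disable `delta_lim`/`delta_med`).
#' @param target Named numeric vector with `reward_optimality` and
#'   `punishment_optimality` (and optionally `mean_rt_ms` for step 2).
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   defaults supplied.
#' @param n_instances Model instances per cost evaluation.
#' @param grid_points Grid resolution per free parameter (step 1 seeding).
#' @param pop_size,generations GA budget.
#' @param seed Integer seed; cost evaluations use common random numbers
#'   derived from it so candidate rankings are stable.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(free, fixed, target, bounds = NULL,
                     n_instances = 8L, grid_points = 3L,
                     pop_size = 20L, generations = 10L, seed = 1L) {
  all_par <- c("alpha_d1", "alpha_d2", "alpha_d1d2", "delta_lim", "delta_med")
  stopifnot(all(free %in% all_par))
  if (length(intersect(free, names(fixed))))
    stop("parameters cannot be both free and fixed: ",
         paste(intersect(free, names(fixed)), collapse = ", "), call. = FALSE)
  if (!setequal(c(free, names(fixed)), all_par))
    stop("free + fixed must cover exactly: ",
         paste(all_par, collapse = ", "), call. = FALSE)
  default_bounds <- list(alpha_d1 = c(0, 1.2), alpha_d2 = c(0, 1.2),
                         alpha_d1d2 = c(0, 1.2), delta_lim = c(1e-4, 1),
                         delta_med = c(0, 0.5))
  b <- default_bounds[free]
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  if (any(!vapply(b, function(z) all(is.finite(z)) && z[1] <= z[2], TRUE)))
    stop("infeasible bounds", call. = FALSE)
  spec <- list(free = free, fixed = fixed, target = target, bounds = b,
               n_instances = as.integer(n_instances),
               grid_points = as.integer(grid_points),
               pop_size = as.integer(pop_size),
               generations = as.integer(generations),
               seed = as.integer(seed))
  class(spec) <- "fit_spec"
  spec
}

params_to_condition <- function(spec, p) {
  full <- c(as.list(p), as.list(spec$fixed))
  make_condition(group = "fit",
                 alpha_d1 = full$alpha_d1, alpha_d2 = full$alpha_d2,
                 alpha_d1d2 = full$alpha_d1d2,
                 delta_lim = if (is.null(full$delta_lim)) NA_real_ else full$delta_lim,
                 delta_med = if (is.null(full$delta_med)) NA_real_ else full$delta_med)
}

#' Behavioral-optimality cost of a parameter set
#'
#' Simulates a cohort under the candidate parameters and returns the
#' squared error between its mean reward/punishment optimality and the
#' target proportions.  Uses common random numbers: the same `seed` across
#' candidates, so rankings are not dominated by simulation noise.
#'
#' @param p Named numeric vector of the free parameters.
#' @param spec A [fit_spec()].
#' @param seed Base seed for the simulated instances (defaults to
#'   `spec$seed`).
#' @return Non-negative scalar cost.
#' @export
optimality_cost <- function(p, spec, seed = spec$seed) {
  cond <- params_to_condition(spec, p)
  g <- run_group(cond, n_instances = spec$n_instances, base_seed = seed)
  (g$reward_optimality[["mean"]] - spec$target[["reward_optimality"]])^2 +
    (g$punishment_optimality[["mean"]] - spec$target[["punishment_optimality"]])^2
}

# RT cost on min-max normalized scale so the unidentified iteration-to-ms
# factor cancels; with a scalar target, plain squared error of means.
rt_cost <- function(p, spec, rt_target, seed = spec$seed) {
  cond <- params_to_condition(spec, p)
  g <- run_group(cond, n_instances = spec$n_instances, base_seed = seed)
  (g$mean_rt_ms[["mean"]] - rt_target)^2
}

#' Exhaustive grid search over the free parameters
#'
#' Evaluates `cost` on the Cartesian product of equally spaced grids
#' (`spec$grid_points` per free parameter, spanning each parameter's
#' bounds) and returns all candidates ranked by cost.
#'
#' @param spec A [fit_spec()].
#' @param cost Function `(p, spec) -> scalar`; defaults to
#'   [optimality_cost()].
#' @return Data frame of candidates (one column per free parameter plus
#'   `cost`), sorted ascending by cost.
#' @export
grid_search <- function(spec, cost = optimality_cost) {
  stopifnot(inherits(spec, "fit_spec"))
  if (length(spec$free) == 0L)
    stop("no free parameters: empty grid", call. = FALSE)
  if (spec$grid_points < 2L)
    stop("grid resolution must be at least 2 per free parameter",
         call. = FALSE)
  axes <- lapply(spec$bounds, function(b)
    seq(b[1], b[2], length.out = spec$grid_points))
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  grid$cost <- vapply(seq_len(nrow(grid)), function(i) {
    p <- unlist(grid[i, spec$free, drop = FALSE])
    cost(p, spec)
  }, 1)
  grid[order(grid$cost), , drop = FALSE]
}

#' Real-coded genetic algorithm over the free parameters
#'
#' Tournament selection, blend (BLX-alpha) crossover, per-gene Gaussian
#' mutation, and single-elite preservation, on box-bounded real vectors.
#' Fixed seed gives a reproducible trace; the elite guarantees the
#' best-so-far cost is non-increasing across generations.
#'
#' @param spec A [fit_spec()].
#' @param cost Function `(p, spec) -> scalar`.
#' @param init_population Optional matrix (rows = individuals, columns =
#'   free parameters) seeding the population, e.g. top grid candidates.
#' @param crossover_prob,mutation_prob,mutation_sd,tournament_k GA
#'   operators: blend-crossover probability per mating (0.9), per-gene
#'   mutation probability (0.1), mutation sd as a fraction of the box
#'   width (0.1), tournament size (3).
#' @return List with `best` (named parameter vector), `best_cost`, and
#'   `trace` (best cost per generation).
#' @export
ga_optimize <- function(spec, cost = optimality_cost, init_population = NULL,
                        crossover_prob = 0.9, mutation_prob = 0.1,
                        mutation_sd = 0.1, tournament_k = 3L) {
  stopifnot(inherits(spec, "fit_spec"))
  d <- length(spec$free)
  if (d == 0L) stop("no free parameters to optimize", call. = FALSE)
  lo <- vapply(spec$bounds, `[`, 1, 1L)
  hi <- vapply(spec$bounds, `[`, 1, 2L)
  n <- spec$pop_size
  with_local_seed(spec$seed, {
    pop <- matrix(stats::runif(n * d, rep(lo, each = n), rep(hi, each = n)),
                  nrow = n, dimnames = list(NULL, spec$free))
    if (!is.null(init_population)) {
      init_population <- as.matrix(init_population)[, spec$free, drop = FALSE]
      k <- min(nrow(init_population), n)
      pop[seq_len(k), ] <- init_population[seq_len(k), , drop = FALSE]
    }
    evaluate <- function(P) vapply(seq_len(nrow(P)), function(i)
      cost(P[i, ], spec), 1)
    fit <- evaluate(pop)
    trace <- numeric(spec$generations)
    for (gen in seq_len(spec$generations)) {
      elite_i <- which.min(fit)
      newpop <- matrix(NA_real_, n, d, dimnames = list(NULL, spec$free))
      newpop[1, ] <- pop[elite_i, ]
      for (i in seq(2L, n)) {
        pick <- function() {
          cand <- sample.int(n, min(tournament_k, n))
          cand[which.min(fit[cand])]
        }
        p1 <- pop[pick(), ]
        p2 <- pop[pick(), ]
        child <- if (stats::runif(1) < crossover_prob) {
          u <- stats::runif(d, -0.5, 1.5)   # BLX-0.5 blend
          p1 + u * (p2 - p1)
        } else p1
        mut <- stats::runif(d) < mutation_prob
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, mutation_sd * (hi - lo)[mut])
        newpop[i, ] <- pmin(pmax(child, lo), hi)
      }
      newfit <- c(fit[elite_i], evaluate(newpop[-1, , drop = FALSE]))
      pop <- newpop
      fit <- newfit
      trace[gen] <- min(fit)
    }
    best_i <- which.min(fit)
    list(best = pop[best_i, ], best_cost = fit[best_i], trace = trace)
  })
}

#' Two-step behavioral fit: optimality, then reaction time
#'
#' Step 1 seeds a genetic algorithm from the best grid-search candidates
#' and minimizes the reward/punishment optimality cost; all evaluated
#' candidates within `survivor_tol` (relative) of the best step-1 cost
#' survive.  Step 2 re-ranks the survivors by squared error against the
#' target mean reaction time and returns the minimizer.  With no RT
#' target, the step-1 best is returned.
#'
#' @param spec A [fit_spec()].
#' @param rt_target Target mean RT (same units as the simulator's
#'   `ms_per_iter` scale), or `NULL` to skip step 2.
#' @param survivor_tol Relative tolerance defining step-1 survivors
#'   (default 0.1, i.e. within 10% of the best step-1 cost).
#' @param survivor_abs Absolute tolerance floor on the survivor band
#'   (default 0.02, roughly the squared sampling error of the simulated
#'   optimality means); without it a near-zero best cost would shrink the
#'   band below simulation noise and starve step 2 of candidates.
#' @param rt_instances Model instances per step-2 RT evaluation (default
#'   three times the step-1 budget: the survivor set is small, so the RT
#'   ranking can afford tighter estimates).
#' @return An object of class `fit_result`: list with `best_params` (a
#'   [subject_condition()]), `best_free`, `step1_cost`, `step2_cost`,
#'   `candidates` (step-1 survivor table), `ga_trace`, `spec`.
#' @export
two_step_fit <- function(spec, rt_target = NULL, survivor_tol = 0.1,
                         survivor_abs = 0.02,
                         rt_instances = 3L * spec$n_instances) {
  stopifnot(inherits(spec, "fit_spec"))
  if (length(spec$free) == 0L) {
    p <- stats::setNames(numeric(0), character(0))
    cond <- params_to_condition(spec, p)
    g <- run_group(cond, n_instances = spec$n_instances,
                   base_seed = spec$seed)
    c1 <- (g$reward_optimality[["mean"]] -
             spec$target[["reward_optimality"]])^2 +
      (g$punishment_optimality[["mean"]] -
         spec$target[["punishment_optimality"]])^2
    out <- list(best_params = cond, best_free = p, step1_cost = c1,
                step2_cost = if (is.null(rt_target)) NA_real_ else
                  (g$mean_rt_ms[["mean"]] - rt_target)^2,
                candidates = NULL, ga_trace = NULL, spec = spec)
    class(out) <- "fit_result"
    return(out)
  }

  g <- grid_search(spec)
  n_seed <- min(nrow(g), spec$pop_size)
  ga <- ga_optimize(spec, init_population = g[seq_len(n_seed), spec$free,
                                              drop = FALSE])

  # survivor pool: grid candidates + GA best, within tolerance of the best
  pool <- rbind(g[, c(spec$free, "cost"), drop = FALSE],
                c(as.list(ga$best), list(cost = ga$best_cost)))
  best_cost <- min(pool$cost)
  band <- max(survivor_tol * best_cost, survivor_abs)
  surv <- pool[pool$cost <= best_cost + band, , drop = FALSE]
  if (nrow(surv) == 0L) stop("no step-1 survivors", call. = FALSE)

  if (!is.null(rt_target)) {
    rt_spec <- spec
    rt_spec$n_instances <- as.integer(rt_instances)
    surv$rt_cost <- vapply(seq_len(nrow(surv)), function(i)
      rt_cost(unlist(surv[i, spec$free, drop = FALSE]), rt_spec, rt_target), 1)
    surv <- surv[order(surv$rt_cost, surv$cost), , drop = FALSE]
  } else {
    surv <- surv[order(surv$cost), , drop = FALSE]
  }
  best <- unlist(surv[1, spec$free, drop = FALSE])
  out <- list(best_params = params_to_condition(spec, best),
              best_free = best,
              step1_cost = surv$cost[1],
              step2_cost = if (is.null(rt_target)) NA_real_ else
                surv$rt_cost[1],
              candidates = surv, ga_trace = ga$trace, spec = spec)
  class(out) <- "fit_result"
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Two-step fit result\n")
  if (length(x$best_free))
    cat("  best:", paste(names(x$best_free),
                         signif(x$best_free, 4), sep = " = ",
                         collapse = ", "), "\n")
  cat(sprintf("  step-1 cost: %.4g", x$step1_cost))
  if (!is.na(x$step2_cost)) cat(sprintf("   step-2 cost: %.4g", x$step2_cost))
  cat("\n")
  invisible(x)
}
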