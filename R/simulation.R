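#' Run one trial of the task through the full network model
#'
#' The within-trial pipeline: (1) read out MSN responses for every
#' candidate action of the current stimulus and form value Q, risk h, and
#' utility U; (2) compute the utility-difference dopamine signal against
#' the previous trial's realized utility; (3) gate the direct/indirect
#' pathway drives with the selection-context gains; (4) race the
#' STN-GPe-thalamus circuit to threshold to pick the response and the
#' reaction time; (5) sample the outcome; (6) form the TD error, pass it
#' through the group dopamine condition, and update the weights.
#'
#' @param weights A [striatal_weights()].
#' @param cond A [subject_condition()].
#' @param task A [task_config()].
#' @param cparams A [circuit_params()].
#' @param trace Utility trace list as returned by this function (`U_prev`
#'   element), or `NULL` on the first trial.
#' @param stimulus Stimulus label for this trial.
#' @param sel_params Selection-context [gain_params()].
#' @param learn_params Learning-context [gain_params()].
#' @param du_mode `"max"`: the utility-difference signal anticipates the
#'   best available option (uses the maximum candidate utility);
#'   `"chosen"`: it is computed after selection from the chosen action.
#' @param u_prev_mode How the previous trial's utility term is evaluated:
#'   `"realized"` (default) stores the scalar utility realized at the
#'   previous selection, so the signal mixes valences across consecutive
#'   stimuli; `"state"` re-evaluates the previously executed action in the
#'   current state, making the signal a within-state utility contrast
#'   (non-negative under `du_mode = "max"`).
#' @param risk_transform Passed to [compute_utility()].
#' @return List with `record` (one-row data frame in the trial-record
#'   schema plus `crossed` and `rt_iters`), `weights`, and `trace`.
#' @export
run_trial <- function(weights, cond, task, cparams, trace, stimulus,
                      sel_params = gain_params("selection"),
                      learn_params = gain_params("learning"),
                      du_mode = c("max", "chosen"),
                      u_prev_mode = c("realized", "state"),
                      risk_transform = c("linear", "sqrt")) {
  du_mode <- match.arg(du_mode)
  u_prev_mode <- match.arg(u_prev_mode)
  risk_transform <- match.arg(risk_transform)
  s <- match(stimulus, task$stimuli)
  if (is.na(s)) stop("unknown stimulus: ", stimulus, call. = FALSE)
  n_act <- length(task$responses)
  if (is.null(trace))
    trace <- list(U_prev = NA_real_, a_prev = NA_integer_, delta_U = 0)

  Q <- weights$w_d1[s, ]
  y_d2 <- weights$w_d2[s, ]
  h <- weights$w_d1d2[s, ]
  U <- compute_utility(Q, h, cond$alpha_d1d2, risk_transform)

  # the utility-difference dopamine signal gating the pathway gains:
  # "max" anticipates the best available option this trial; "chosen" uses
  # the signal realized on the previous trial (the gains cannot depend on
  # the not-yet-made choice)
  U_prev <- if (u_prev_mode == "state" && !is.na(trace$a_prev))
    U[trace$a_prev] else trace$U_prev
  dU <- if (du_mode == "max") utility_difference(max(U), U_prev)
        else trace$delta_U
  lam_d1 <- gain("D1", dU, sel_params)
  lam_d2 <- gain("D2", dU, sel_params)
  lam_d1d2 <- gain("D1D2", dU, sel_params)

  x_dp <- cond$alpha_d1 * lam_d1 * Q
  x_ip <- cond$alpha_d2 * lam_d2 * y_d2 +
    cond$alpha_d1d2 * sign(Q) * lam_d1d2 * h

  sel <- select_action(x_dp, x_ip, cparams)
  a <- sel$action

  response <- task$responses[a]
  points <- sample_outcome(task, stimulus, response)
  r <- points_to_reward(points)
  delta <- td_error(r, Q[a])
  delta_c <- apply_da_condition(delta, cond)
  weights <- update_weights(weights, s, a, delta_c, cond, learn_params)

  trace$delta_U <- utility_difference(U[a], U_prev)
  trace$U_prev <- U[a]
  trace$a_prev <- a
  trace$delta <- delta_c
  trace$delta_U_gate <- dU

  record <- data.frame(
    stimulus = stimulus, response = response,
    optimal = identical(response, unname(task$optimal_map[[stimulus]])),
    points = points,
    rt_iters = sel$rt_iters, crossed = sel$crossed,
    stringsAsFactors = FALSE)
  list(record = record, weights = weights, trace = trace)
}

#' Simulate one subject's 160-trial session
#'
#' Generates a balanced pseudorandom stimulus sequence and runs the trials
#' sequentially, carrying the cortico-striatal weights and the utility
#' trace.  All randomness (sequence, circuit initialization noise, outcome
#' draws) is controlled by `seed`, so identical seeds give identical
#' sessions.
#'
#' @inheritParams run_trial
#' @param seed Integer seed.
#' @param subject_id Identifier stamped into the records.
#' @param rt_policy How no-crossing trials enter the reaction-time column:
#'   `"censor"` (default) records them at the iteration cap (a response at
#'   the deadline, analogous to an experimental response cutoff);
#'   `"exclude"` records `NA` so they drop out of RT averages.  Either
#'   way the `crossed` flag marks them.
#' @param ... Passed to [run_trial()] (`du_mode`, `u_prev_mode`,
#'   `risk_transform`).
#' @return An object of class `session_result`: list with `records` (data
#'   frame: subject_id, group, trial_index, stimulus, response, optimal,
#'   points, rt_ms, crossed), `final_weights`, `seed`, `condition`.
#'   `rt_ms` is `rt_iters * ms_per_iter`.
#' @export
run_session <- function(cond, task = task_config(), cparams = circuit_params(),
                        seed = 1L, subject_id = paste0("sim-", seed),
                        rt_policy = c("censor", "exclude"), ...) {
  rt_policy <- match.arg(rt_policy)
  validate_task_config(task)
  with_local_seed(seed, {
    stims <- generate_trial_sequence(task, seed)
    weights <- striatal_weights(length(task$stimuli), length(task$responses))
    trace <- NULL
    rows <- vector("list", length(stims))
    for (i in seq_along(stims)) {
      step <- run_trial(weights, cond, task, cparams, trace, stims[i], ...)
      weights <- step$weights
      trace <- step$trace
      rows[[i]] <- step$record
    }
    records <- if (length(rows)) do.call(rbind, rows) else
      data.frame(stimulus = character(), response = character(),
                 optimal = logical(), points = integer(),
                 rt_iters = integer(), crossed = logical())
    records <- cbind(
      data.frame(subject_id = rep(subject_id, nrow(records)),
                 group = rep(cond$group, nrow(records)),
                 trial_index = seq_len(nrow(records)) - 1L),
      records)
    records$rt_ms <- records$rt_iters * cparams$ms_per_iter
    if (rt_policy == "exclude")
      records$rt_ms[!records$crossed] <- NA_real_
    out <- list(records = records, final_weights = weights, seed = seed,
                condition = cond)
    class(out) <- "session_result"
    out
  })
}

reward_stimuli <- c("I1", "I2")
punish_stimuli <- c("I3", "I4")

session_summary <- function(records) {
  rew <- records$stimulus %in% reward_stimuli
  pun <- records$stimulus %in% punish_stimuli
  c(reward_optimality = if (any(rew)) mean(records$optimal[rew]) else NA_real_,
    punishment_optimality = if (any(pun)) mean(records$optimal[pun]) else NA_real_,
    mean_rt_ms = if (any(!is.na(records$rt_ms)))
      mean(records$rt_ms, na.rm = TRUE) else NA_real_)
}

#' Simulate a cohort of independent model instances
#'
#' Runs `n_instances` sessions with seeds `base_seed .. base_seed +
#' n_instances - 1` (each instance re-samples its own stimulus sequence)
#' and aggregates per-instance reward/punishment optimality and mean
#' reaction time.  No-crossing trials always contribute choices; their RT
#' treatment follows `rt_policy`.
#'
#' @inheritParams run_session
#' @param n_instances Number of independent model instances (default 100).
#' @param base_seed First seed.
#' @return An object of class `group_summary`: list with `group`,
#'   `n_instances`, `per_instance` (data frame of per-instance summaries),
#'   `reward_optimality`, `punishment_optimality`, `mean_rt_ms` (each a
#'   `c(mean, sd)` vector), `rt_by_trial` (per-trial mean RT across
#'   instances), and `records` (all trial records).
#' @export
run_group <- function(cond, task = task_config(), cparams = circuit_params(),
                      n_instances = 100L, base_seed = 1L, ...) {
  stopifnot(n_instances >= 1L)
  seeds <- base_seed + seq_len(n_instances) - 1L
  sessions <- lapply(seeds, function(sd)
    run_session(cond, task, cparams, seed = sd,
                subject_id = paste0(cond$group, "-", sd), ...))
  per <- as.data.frame(t(vapply(sessions, function(s)
    session_summary(s$records), numeric(3))))
  per$seed <- seeds
  records <- do.call(rbind, lapply(sessions, `[[`, "records"))
  rt_by_trial <- tapply(records$rt_ms, records$trial_index,
                        mean, na.rm = TRUE)
  msd <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x))
  out <- list(group = cond$group, n_instances = n_instances,
              per_instance = per,
              reward_optimality = msd(per$reward_optimality),
              punishment_optimality = msd(per$punishment_optimality),
              mean_rt_ms = msd(per$mean_rt_ms),
              rt_by_trial = as.numeric(rt_by_trial),
              records = records)
  class(out) <- "group_summary"
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group", x$group, "-", x$n_instances, "instances\n")
  cat(sprintf("  reward optimality:     %.3f (sd %.3f)\n",
              x$reward_optimality[["mean"]], x$reward_optimality[["sd"]]))
  cat(sprintf("  punishment optimality: %.3f (sd %.3f)\n",
              x$punishment_optimality[["mean"]], x$punishment_optimality[["sd"]]))
  cat(sprintf("  mean RT:               %.1f ms (sd %.1f)\n",
              x$mean_rt_ms[["mean"]], x$mean_rt_ms[["sd"]]))
  invisible(x)
}

#' Simulate all four study cohorts
#'
#' Convenience wrapper running [run_group()] for healthy controls, PD-OFF,
#' PD-ON-ICD and PD-ON-nonICD with their fitted parameter sets.
#'
#' @inheritParams run_group
#' @param groups Character vector of group labels.
#' @return Named list of `group_summary` objects.
#' @export
run_cohorts <- function(groups = c("HC", "PD-OFF", "PD-ON-ICD", "PD-ON-nonICD"),
                        task = task_config(), cparams = circuit_params(),
                        n_instances = 100L, base_seed = 1L, ...) {
  out <- lapply(groups, function(g)
    run_group(subject_condition(g), task, cparams, n_instances, base_seed, ...))
  names(out) <- groups
  out
}
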