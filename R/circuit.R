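#' STN-GPe-GPi-thalamus circuit parameters
#'
#' Constants of the subcortical action-selection circuit.  STN and GPe each
#' have one neuron per candidate action, coupled one-to-one; both layers
#' are fully laterally connected, excitatory within STN (`eps_s`, with
#' `1 + eps_s` self-connections) and inhibitory within GPe (`eps_g =
#' -eps_s`).  The excitatory-inhibitory loop sustains oscillations that
#' implement exploration.  GPi combines the direct-pathway drive with the
#' STN signal; the thalamus leakily integrates the sign-inverted GPi output
#' until one unit crosses `threshold`, which selects the action and sets
#' the reaction time (iterations to crossing).
#'
#' @param n Number of candidate actions (default 2).
#' @param eps_s STN lateral strength (default 0.12); GPe lateral strength
#'   is its negation.
#' @param inv_tau_s,inv_tau_g Per-iteration integration coefficients of STN
#'   (0.1) and GPe (0.033).
#' @param lambda_stn Slope of the STN tanh output nonlinearity (3).
#' @param w_stn_gpi STN-to-GPi weight, common to all GPi neurons (1).
#' @param threshold Thalamic decision threshold (1.815).
#' @param dt_thal Thalamic integration step (0.1).
#' @param leak Leak coefficient of the thalamic integrator:
#'   `y <- y + dt_thal * (-leak * y + x)`.  `leak = 0` (default) is a
#'   non-leaky race accumulator, the regime in which the decision threshold
#'   is reachable from the bounded circuit signals and reaction times vary
#'   with drive; `leak = 1` is the strictly leaky integrator, whose
#'   crossing times for constant supra-threshold drive have a closed form.
#' @param max_iters Iteration cap per trial (1000); trials that never cross
#'   are flagged and excluded from reaction-time averages.
#' @param ms_per_iter Linear scale from iterations to milliseconds (1).
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(n = 2L, eps_s = 0.12, inv_tau_s = 0.1,
                           inv_tau_g = 0.033, lambda_stn = 3,
                           w_stn_gpi = 1, threshold = 1.815,
                           dt_thal = 0.1, leak = 0, max_iters = 1000L,
                           ms_per_iter = 1) {
  stopifnot(n >= 1L, threshold > 0, max_iters > 0L, dt_thal > 0, leak >= 0)
  p <- list(n = as.integer(n), eps_s = eps_s, eps_g = -eps_s,
            inv_tau_s = inv_tau_s, inv_tau_g = inv_tau_g,
            lambda_stn = lambda_stn, w_stn_gpi = w_stn_gpi,
            threshold = threshold, dt_thal = dt_thal, leak = leak,
            max_iters = as.integer(max_iters), ms_per_iter = ms_per_iter)
  class(p) <- "circuit_params"
  p
}

#' Circuit state
#'
#' The within-trial state: STN membrane states and outputs, GPe states, and
#' the thalamic integrators.  Each trial starts with small uniform noise on
#' the STN/GPe states (the oscillator needs symmetry breaking) and zeroed
#' thalamic integrators.
#'
#' @param params A [circuit_params()].
#' @param init `"noise"` (uniform in `noise_range`) or `"zero"`.
#' @param noise_range Half-width of the initialization noise (0.01).
#' @param seed Optional integer seed for the initialization draw.
#' @return An object of class `circuit_state` with fields `x_stn`, `y_stn`,
#'   `x_gpe`, `y_thal`, `iter`.
#' @export
circuit_state <- function(params, init = c("noise", "zero"),
                          noise_range = 0.01, seed = NULL) {
  init <- match.arg(init)
  n <- params$n
  if (init == "zero") {
    x_stn <- x_gpe <- numeric(n)
  } else {
    draw <- function() stats::runif(2L * n, -noise_range, noise_range)
    v <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
    x_stn <- v[seq_len(n)]
    x_gpe <- v[n + seq_len(n)]
  }
  st <- list(x_stn = x_stn, y_stn = tanh(params$lambda_stn * x_stn),
             x_gpe = x_gpe, y_thal = numeric(n), iter = 0L)
  class(st) <- "circuit_state"
  st
}

check_len <- function(x, n, what) {
  if (length(x) != n)
    stop(what, " must have length ", n, ", got ", length(x), call. = FALSE)
  if (any(!is.finite(x))) stop(what, " must be finite", call. = FALSE)
}

#' One Euler step of the STN-GPe loop
#'
#' Updates the STN states from the recurrent drive and GPe inhibition,
#' recomputes the STN outputs, then updates the GPe states from lateral
#' inhibition, the fresh STN input, and the (inhibitory) striatal
#' indirect-pathway drive.
#'
#' @param state A [circuit_state()].
#' @param x_ip Indirect-pathway drive, length `params$n`.
#' @param params A [circuit_params()].
#' @return The advanced `circuit_state`.
#' @export
step_stn_gpe <- function(state, x_ip, params) {
  n <- params$n
  check_len(x_ip, n, "x_ip")
  check_len(state$x_stn, n, "x_stn")
  w_stn_drive <- params$eps_s * sum(state$y_stn) + state$y_stn
  x_stn <- state$x_stn +
    params$inv_tau_s * (-state$x_stn + w_stn_drive - state$x_gpe)
  y_stn <- tanh(params$lambda_stn * x_stn)
  x_gpe <- state$x_gpe +
    params$inv_tau_g * (-state$x_gpe + params$eps_g * sum(state$x_gpe) +
                        y_stn - x_ip)
  state$x_stn <- x_stn
  state$y_stn <- y_stn
  state$x_gpe <- x_gpe
  state
}

#' GPi output for inspection
#'
#' GPi is not separately integrated: its output is the algebraic
#' combination of the direct-pathway drive (inhibitory onto GPi) and the
#' STN drive (excitatory).  The thalamus receives its negation.
#'
#' @inheritParams step_thalamus
#' @return Length-n numeric vector of GPi outputs.
#' @export
gpi_output <- function(state, x_dp, params) {
  check_len(x_dp, params$n, "x_dp")
  -x_dp + params$w_stn_gpi * state$y_stn
}

#' One step of the thalamic integrators
#'
#' The thalamic afferent is the sign-inverted GPi output,
#' `x_thal = x_dp - w_stn_gpi * y_stn`; each thalamic unit integrates it
#' with step `dt_thal` and leak coefficient `params$leak` (0 = race
#' accumulator, 1 = leaky integrator).
#'
#' @param state A [circuit_state()].
#' @param x_dp Direct-pathway drive, length `params$n`.
#' @param params A [circuit_params()].
#' @return The advanced `circuit_state` (also increments `iter`).
#' @export
step_thalamus <- function(state, x_dp, params) {
  check_len(x_dp, params$n, "x_dp")
  x_thal <- x_dp - params$w_stn_gpi * state$y_stn
  state$y_thal <- state$y_thal +
    params$dt_thal * (-params$leak * state$y_thal + x_thal)
  state$iter <- state$iter + 1L
  state
}

#' Run the race to threshold and select an action
#'
#' Jointly iterates the STN-GPe loop and the thalamic integrators until one
#' thalamic unit crosses the decision threshold, or `max_iters` is reached.
#' The first crosser is the selected action; simultaneous crossers are
#' broken by the larger thalamic activity, then by the lower index.  If no
#' unit crosses, `crossed` is `FALSE` and the action is the argmax of the
#' thalamic activity at the cap (such trials count for choice but are
#' excluded from reaction-time averages).
#'
#' @param x_dp,x_ip Direct- and indirect-pathway drives, length `params$n`.
#' @param params A [circuit_params()].
#' @param init A [circuit_state()], or `NULL` for a fresh noise-initialized
#'   state (pass `seed` to make it reproducible).
#' @param seed Optional seed for the default initialization.
#' @param record If `TRUE`, keep the per-iteration thalamic trajectories.
#' @param use_compiled Use the compiled inner loop (default) or the pure-R
#'   reference path; both produce identical results.
#' @return An object of class `selection_result`: list with `action`
#'   (1-based), `rt_iters`, `crossed`, `y_thal`, and optionally
#'   `trajectories` (matrix iter x n).
#' @export
select_action <- function(x_dp, x_ip, params, init = NULL, seed = NULL,
                          record = FALSE, use_compiled = TRUE) {
  n <- params$n
  check_len(x_dp, n, "x_dp")
  check_len(x_ip, n, "x_ip")
  if (params$max_iters <= 0L) stop("max_iters must be positive", call. = FALSE)
  if (is.null(init)) init <- circuit_state(params, seed = seed)
  res <- if (use_compiled) {
    .race_cpp(x_dp, x_ip, init$x_stn, init$x_gpe,
              params$eps_s, params$inv_tau_s, params$inv_tau_g,
              params$lambda_stn, params$w_stn_gpi, params$threshold,
              params$dt_thal, params$leak, params$max_iters, record)
  } else {
    race_r(x_dp, x_ip, init, params, record)
  }
  class(res) <- "selection_result"
  res
}

# Pure-R reference implementation of the race; semantics-defining twin of
# the compiled loop.
race_r <- function(x_dp, x_ip, state, params, record = FALSE) {
  state$y_thal <- numeric(params$n)
  traj <- if (record) matrix(NA_real_, params$max_iters, params$n)
  action <- NA_integer_
  crossed <- FALSE
  rt <- params$max_iters
  for (it in seq_len(params$max_iters)) {
    state <- step_stn_gpe(state, x_ip, params)
    state <- step_thalamus(state, x_dp, params)
    if (record) traj[it, ] <- state$y_thal
    over <- which(state$y_thal >= params$threshold)
    if (length(over)) {
      action <- over[which.max(state$y_thal[over])]
      crossed <- TRUE
      rt <- it
      break
    }
  }
  if (!crossed) action <- which.max(state$y_thal)
  out <- list(action = action, rt_iters = rt, crossed = crossed,
              y_thal = state$y_thal, x_stn = state$x_stn,
              x_gpe = state$x_gpe)
  if (record) out$trajectories <- traj[seq_len(rt), , drop = FALSE]
  out
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Action %d after %d iterations (%s)\n", x$action, x$rt_iters,
              if (x$crossed) "threshold crossed" else "no crossing; argmax"))
  invisible(x)
}
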