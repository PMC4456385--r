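#' Dopamine gain-function constants
#'
#' Sigmoid constants (c1, c2, c3) of the receptor-specific gain functions,
#' one set per context.  The `"learning"` context parameterizes the gains
#' used in the cortico-striatal weight updates; the `"selection"` context
#' parameterizes the gains that gate the direct/indirect pathway drives
#' during action selection.  The two contexts differ only in the c3 offsets
#' of the D1/D2 gains.
#'
#' @param context `"learning"` or `"selection"`.
#' @return An object of class `gain_params`: a named list of c(c1, c2, c3)
#'   vectors for `D1`, `D2`, `hD1`, `hD2`, plus the context label.
#' @export
gain_params <- function(context = c("learning", "selection")) {
  context <- match.arg(context)
  p <- switch(context,
    learning = list(
      D1  = c(c1 = 1,    c2 = -50,  c3 = 0),
      D2  = c(c1 = 1,    c2 = 50,   c3 = -1),
      hD1 = c(c1 = 0.05, c2 = -0.01, c3 = -0.05),
      hD2 = c(c1 = 0.05, c2 = 0.01,  c3 = 0.05)),
    selection = list(
      D1  = c(c1 = 1,    c2 = -50,  c3 = 0.01),
      D2  = c(c1 = 1,    c2 = 50,   c3 = 0.01),
      hD1 = c(c1 = 0.05, c2 = -0.01, c3 = -0.05),
      hD2 = c(c1 = 0.05, c2 = 0.01,  c3 = 0.05)))
  p$context <- context
  class(p) <- "gain_params"
  p
}

#' Receptor-specific dopamine gain function
#'
#' Sigmoidal gains translating a dopamine signal (a TD error or a utility
#' difference) into multiplicative modulation of each striatal MSN pool.
#' The full-range form \eqn{2 c_1 / (1 + e^{c_2 (\delta + c_3)}) - 1} is
#' used for the D1 and D2 pools (increasing resp. decreasing in
#' \eqn{\delta}); the half-height form \eqn{c_1 / (1 + e^{c_2 (\delta +
#' c_3)})} for the two components whose sum, `D1D2`, forms the U-shaped
#' gain of the D1R-D2R co-expressing (risk-coding) pool.
#'
#' @param kind One of `"D1"`, `"D2"`, `"hD1"`, `"hD2"`, `"D1D2"`.
#' @param delta Dopamine signal (numeric vector allowed).
#' @param params A [gain_params()] object.
#' @return Numeric vector of gains.
#' @examples
#' gain("D1", 0.1, gain_params("learning"))   # ~0.9866
#' gain("D1D2", 0, gain_params("learning"))   # ~0.05
#' @export
gain <- function(kind, delta, params) {
  stopifnot(inherits(params, "gain_params"))
  half <- function(cc, d) cc[["c1"]] / (1 + exp(cc[["c2"]] * (d + cc[["c3"]])))
  switch(kind,
    D1   = 2 * half(params$D1, delta) - 1,
    D2   = 2 * half(params$D2, delta) - 1,
    hD1  = half(params$hD1, delta),
    hD2  = half(params$hD2, delta),
    D1D2 = half(params$hD1, delta) + half(params$hD2, delta),
    stop("unknown gain kind: ", kind, call. = FALSE))
}

#' Temporal-difference error for the immediate-reward task
#'
#' @param r Reward on the unit scale (-1, 0, +1).
#' @param Q Current value estimate of the taken (state, action).
#' @return The reward prediction error r minus Q (the model correlate of
#'   phasic dopamine).
#' @export
td_error <- function(r, Q) r - Q

#' Subject condition: serotonin coefficients and dopamine availability
#'
#' Bundles the group-level parameters of the model: the serotonergic
#' modulation coefficients on the three MSN pools (`alpha_d1`, `alpha_d2`,
#' `alpha_d1d2`), the dopamine-availability clamp `delta_lim` (upper bound
#' on the TD error, modeling nigral cell loss; PD groups only) and the
#' medication constant `delta_med` (added after clamping; ON-medication
#' groups only), plus the per-pool learning rates.
#'
#' `subject_condition(group)` returns the fitted parameter set of one of
#' the four study cohorts; `make_condition()` builds a custom condition.
#'
#' @param group One of `"HC"`, `"PD-OFF"`, `"PD-ON-ICD"`, `"PD-ON-nonICD"`.
#' @return An object of class `subject_condition`.
#' @examples
#' subject_condition("PD-ON-ICD")
#' @export
subject_condition <- function(group = c("HC", "PD-OFF", "PD-ON-ICD", "PD-ON-nonICD")) {
  group <- match.arg(group)
  p <- switch(group,
    "HC"           = list(alpha_d1 = 1, alpha_d2 = 0.185, alpha_d1d2 = 0.997,
                          delta_lim = NA_real_, delta_med = NA_real_),
    "PD-OFF"       = list(alpha_d1 = 1, alpha_d2 = 0.991, alpha_d1d2 = 0.033,
                          delta_lim = 0.001, delta_med = NA_real_),
    "PD-ON-ICD"    = list(alpha_d1 = 1, alpha_d2 = 0.046, alpha_d1d2 = 0.001,
                          delta_lim = 0.001, delta_med = 0.06),
    "PD-ON-nonICD" = list(alpha_d1 = 1, alpha_d2 = 0.916, alpha_d1d2 = 0.160,
                          delta_lim = 0.001, delta_med = 0.06))
  make_condition(group = group, alpha_d1 = p$alpha_d1, alpha_d2 = p$alpha_d2,
                 alpha_d1d2 = p$alpha_d1d2, delta_lim = p$delta_lim,
                 delta_med = p$delta_med)
}

#' @rdname subject_condition
#' @param alpha_d1,alpha_d2,alpha_d1d2 Non-negative serotonin coefficients.
#' @param delta_lim Upper clamp on the TD error (`NA` = no clamp).
#' @param delta_med Medication constant added after clamping (`NA` = none);
#'   requires `delta_lim`.
#' @param eta_d1,eta_d2,eta_d1d2 Learning rates of the three weight
#'   matrices.
#' @export
make_condition <- function(group = "custom", alpha_d1 = 1, alpha_d2 = 1,
                           alpha_d1d2 = 0, delta_lim = NA_real_,
                           delta_med = NA_real_,
                           eta_d1 = 0.01, eta_d2 = 0.1, eta_d1d2 = 0.1) {
  if (!is.na(delta_med) && is.na(delta_lim))
    stop("delta_med requires delta_lim (medication adds to the clamped TD error)",
         call. = FALSE)
  stopifnot(alpha_d1 >= 0, alpha_d2 >= 0, alpha_d1d2 >= 0)
  cond <- list(group = group, alpha_d1 = alpha_d1, alpha_d2 = alpha_d2,
               alpha_d1d2 = alpha_d1d2, delta_lim = delta_lim,
               delta_med = delta_med, eta_d1 = eta_d1, eta_d2 = eta_d2,
               eta_d1d2 = eta_d1d2)
  class(cond) <- "subject_condition"
  cond
}

#' @export
print.subject_condition <- function(x, ...) {
  cat("Subject condition:", x$group, "\n")
  cat(sprintf("  alpha_D1 = %g, alpha_D2 = %g, alpha_D1D2 = %g\n",
              x$alpha_d1, x$alpha_d2, x$alpha_d1d2))
  cat(sprintf("  delta_lim = %s, delta_med = %s\n",
              ifelse(is.na(x$delta_lim), "-", format(x$delta_lim)),
              ifelse(is.na(x$delta_med), "-", format(x$delta_med))))
  invisible(x)
}

#' Apply the group dopamine-availability condition to a TD error
#'
#' Healthy controls pass the TD error through unchanged.  PD-OFF clamps it
#' from above at `delta_lim` (reduced dopamine availability).  PD-ON
#' additionally adds the medication constant `delta_med` after clamping
#' (elevated tonic dopamine under medication).
#'
#' @param delta Raw TD error (vectorized).
#' @param cond A [subject_condition()].
#' @return The conditioned TD error.
#' @export
apply_da_condition <- function(delta, cond) {
  stopifnot(inherits(cond, "subject_condition"))
  if (is.na(cond$delta_lim)) return(delta)
  out <- pmin(delta, cond$delta_lim)
  if (!is.na(cond$delta_med)) out <- out + cond$delta_med
  out
}

#' Cortico-striatal weight matrices
#'
#' One weight matrix per MSN pool (D1, D2, D1R-D2R co-expressing), indexed
#' by (state, action).  Weights start at zero, so initial values, risks and
#' utilities are zero and first choices are unbiased.
#'
#' @param n_states Number of cortical states (stimuli); default 4.
#' @param n_actions Number of actions; default 2.
#' @return An object of class `striatal_weights`: list of matrices `w_d1`,
#'   `w_d2`, `w_d1d2`.
#' @export
striatal_weights <- function(n_states = 4L, n_actions = 2L) {
  m <- matrix(0, n_states, n_actions)
  w <- list(w_d1 = m, w_d2 = m, w_d1d2 = m,
            n_states = as.integer(n_states), n_actions = as.integer(n_actions))
  class(w) <- "striatal_weights"
  w
}

check_sa <- function(w, state, action) {
  if (state < 1L || state > w$n_states || action < 1L || action > w$n_actions)
    stop("state/action index out of range: (", state, ", ", action, ")",
         call. = FALSE)
}

#' MSN responses for a (state, action) pair
#'
#' The cortical input is one-hot on the current state, so each pool's
#' response equals its weight for that (state, action): y = w.  Returns the
#' D1 (value), D2, and D1R-D2R (risk) responses.
#'
#' @param weights A [striatal_weights()] object.
#' @param state,action 1-based indices.
#' @return Named numeric vector `c(y_d1, y_d2, y_d1d2)`.
#' @export
msn_response <- function(weights, state, action) {
  check_sa(weights, state, action)
  c(y_d1 = weights$w_d1[state, action],
    y_d2 = weights$w_d2[state, action],
    y_d1d2 = weights$w_d1d2[state, action])
}

#' Risk-sensitive utility of a (state, action)
#'
#' Utility combines the learned value Q with the learned risk h:
#' \deqn{U = Q - \alpha_{D1D2}\, \mathrm{sign}(Q)\, h}
#' The sign(Q) term makes the same positive risk penalize gains (risk
#' aversion) and inflate losses toward zero (risk seeking), the
#' outcome-valence asymmetry the model is built around.  `sign(0)` is 0,
#' so zero-value states carry no risk adjustment.
#'
#' @param Q Value estimate (from the D1 pool).
#' @param h Risk estimate (from the D1R-D2R pool).
#' @param alpha_d1d2 Serotonin coefficient on the risk pool.
#' @param risk_transform `"linear"` uses h as is; `"sqrt"` uses
#'   `sign(h) * sqrt(|h|)` (the convention of a precursor lumped model).
#' @return Utility (vectorized over Q, h).
#' @export
compute_utility <- function(Q, h, alpha_d1d2, risk_transform = c("linear", "sqrt")) {
  risk_transform <- match.arg(risk_transform)
  hh <- if (risk_transform == "sqrt") sign(h) * sqrt(abs(h)) else h
  Q - alpha_d1d2 * sign(Q) * hh
}

#' Trial-to-trial utility difference
#'
#' The second dopamine correlate of the model: the difference between the
#' current trial's utility and the utility realized on the previous trial.
#' It gates the pathway gains during action selection.  On the first trial
#' of a session (no previous utility) it is 0.
#'
#' @param U_now Current utility.
#' @param U_prev Previous trial's utility, or `NA` on the first trial.
#' @return `U_now - U_prev`, or 0 when `U_prev` is `NA`.
#' @export
utility_difference <- function(U_now, U_prev) {
  if (is.na(U_prev)) return(0)
  U_now - U_prev
}

#' Update cortico-striatal weights after an outcome
#'
#' Applies the receptor-specific learning rule at the visited (state,
#' action) only: each pool's weight moves by its learning rate times its
#' gain evaluated at the (already conditioned) TD error.  All other entries
#' are untouched.
#'
#' @param weights A [striatal_weights()] object.
#' @param state,action 1-based indices of the visited pair.
#' @param delta TD error after [apply_da_condition()].
#' @param cond A [subject_condition()] (supplies the learning rates).
#' @param params Learning-context [gain_params()]; defaults to
#'   `gain_params("learning")`.
#' @return The updated `striatal_weights` object.
#' @export
update_weights <- function(weights, state, action, delta, cond,
                           params = gain_params("learning")) {
  check_sa(weights, state, action)
  stopifnot(identical(params$context, "learning"))
  weights$w_d1[state, action] <- weights$w_d1[state, action] +
    cond$eta_d1 * gain("D1", delta, params)
  weights$w_d2[state, action] <- weights$w_d2[state, action] +
    cond$eta_d2 * gain("D2", delta, params)
  weights$w_d1d2[state, action] <- weights$w_d1d2[state, action] +
    cond$eta_d1d2 * gain("D1D2", delta, params)
  weights
}
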