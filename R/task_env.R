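#' Probabilistic reward/punishment categorization task
#'
#' Builds the configuration of the 160-trial two-alternative categorization
#' task.  Four stimuli are presented in pseudorandom order: two "reward"
#' stimuli (I1, I2) where the optimal response wins +25 points 80% of the
#' time (0 otherwise) and the non-optimal response wins +25 only 20% of the
#' time, and two "punishment" stimuli (I3, I4) where the optimal response
#' loses -25 points 20% of the time (0 otherwise) and the non-optimal
#' response loses 80% of the time.
#'
#' @param n_trials Total number of trials; must be divisible by the number
#'   of stimuli so each stimulus is tested equally often.  Default 160.
#' @return An object of class `task_config`: a list with elements
#'   `stimuli`, `responses`, `optimal_map` (named character vector),
#'   `schedule` (data frame with columns `stimulus`, `response`, `points`,
#'   `prob`), and `n_trials`.
#' @examples
#' task <- task_config()
#' task$optimal_map
#' subset(task$schedule, stimulus == "I1")
#' @export
task_config <- function(n_trials = 160L) {
  n_trials <- as.integer(n_trials)
  stimuli <- c("I1", "I2", "I3", "I4")
  responses <- c("A", "B")
  optimal_map <- c(I1 = "A", I2 = "B", I3 = "A", I4 = "B")
  sched <- list()
  for (s in stimuli) {
    opt <- optimal_map[[s]]
    non <- setdiff(responses, opt)
    if (s %in% c("I1", "I2")) {
      # reward stimuli: outcomes in {0, +25}
      sched[[length(sched) + 1L]] <- data.frame(
        stimulus = s, response = opt,
        points = c(25L, 0L), prob = c(0.8, 0.2))
      sched[[length(sched) + 1L]] <- data.frame(
        stimulus = s, response = non,
        points = c(25L, 0L), prob = c(0.2, 0.8))
    } else {
      # punishment stimuli: outcomes in {-25, 0}
      sched[[length(sched) + 1L]] <- data.frame(
        stimulus = s, response = opt,
        points = c(0L, -25L), prob = c(0.8, 0.2))
      sched[[length(sched) + 1L]] <- data.frame(
        stimulus = s, response = non,
        points = c(0L, -25L), prob = c(0.2, 0.8))
    }
  }
  cfg <- list(stimuli = stimuli, responses = responses,
              optimal_map = optimal_map,
              schedule = do.call(rbind, sched),
              n_trials = n_trials)
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("Probabilistic reward/punishment task\n")
  cat("  stimuli:  ", paste(x$stimuli, collapse = ", "), "\n")
  cat("  responses:", paste(x$responses, collapse = ", "), "\n")
  cat("  trials:   ", x$n_trials, "\n")
  invisible(x)
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$n_trials %% length(cfg$stimuli) != 0L)
    stop("n_trials (", cfg$n_trials, ") must be divisible by the number of stimuli (",
         length(cfg$stimuli), ")", call. = FALSE)
  if (!all(cfg$schedule$points %in% c(-25L, 0L, 25L)))
    stop("outcome points must be in {-25, 0, +25}", call. = FALSE)
  agg <- stats::aggregate(prob ~ stimulus + response, cfg$schedule, sum)
  if (any(abs(agg$prob - 1) > 1e-12))
    stop("outcome probabilities must sum to 1 for every (stimulus, response)",
         call. = FALSE)
  invisible(cfg)
}

#' Generate a balanced pseudorandom stimulus sequence
#'
#' Each stimulus appears exactly `n_trials / n_stimuli` times; the order is
#' a seeded permutation, so the same seed always yields the same sequence.
#'
#' @param config A [task_config()].
#' @param seed Integer seed controlling the permutation.
#' @return Character vector of stimulus labels, length `config$n_trials`.
#' @export
generate_trial_sequence <- function(config, seed) {
  validate_task_config(config)
  per <- config$n_trials %/% length(config$stimuli)
  base <- rep(config$stimuli, each = per)
  if (config$n_trials == 0L) return(character(0))
  with_local_seed(seed, sample(base))
}

#' Draw one outcome for a (stimulus, response) pair
#'
#' Samples points from the task's outcome schedule.  Uses the current R
#' random-number stream; seed it with [set.seed()] or wrap in a seeded
#' context for reproducibility.
#'
#' @param config A [task_config()].
#' @param stimulus,response Labels present in the config.
#' @return Integer points, one of -25, 0, +25.
#' @export
sample_outcome <- function(config, stimulus, response) {
  rows <- config$schedule[config$schedule$stimulus == stimulus &
                          config$schedule$response == response, ]
  if (nrow(rows) == 0L)
    stop("unknown (stimulus, response) pair: (", stimulus, ", ", response, ")",
         call. = FALSE)
  if (nrow(rows) == 1L) return(rows$points)
  rows$points[sample.int(nrow(rows), 1L, prob = rows$prob)]
}

#' Map task points to model reward
#'
#' The network model consumes rewards on the unit scale: +25 points maps to
#' r = +1, -25 to r = -1, and 0 to r = 0.  Empirical and simulated records
#' share the points scale; the model sees `r`.
#'
#' @param points Integer vector of outcome points.
#' @return Numeric vector of rewards in \{-1, 0, +1\}.
#' @export
points_to_reward <- function(points) {
  bad <- !points %in% c(-25L, 0L, 25L)
  if (any(bad)) stop("points must be in {-25, 0, +25}; got ",
                     paste(unique(points[bad]), collapse = ", "), call. = FALSE)
  points / 25
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
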