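#' Per-subject behavioral summary
#'
#' Reduces one subject's trial records to the three behavioral measures:
#' the proportion of optimal responses on reward stimuli (I1, I2), the
#' proportion on punishment stimuli (I3, I4), and the mean reaction time
#' over trials with an RT.
#'
#' @param records Trial records (data frame with at least `subject_id`,
#'   `stimulus`, `optimal`; optionally `rt_ms`) from a single subject.
#' @return One-row data frame: `subject_id`, `group` (if present),
#'   `reward_optimality`, `punishment_optimality`, `mean_rt_ms` (`NA` when
#'   no RTs are present).
#' @export
summarize_subject <- function(records) {
  ids <- unique(records$subject_id)
  if (length(ids) != 1L)
    stop("records must come from a single subject; got ",
         length(ids), " subject ids", call. = FALSE)
  rew <- records$stimulus %in% reward_stimuli
  pun <- records$stimulus %in% punish_stimuli
  rt <- if ("rt_ms" %in% names(records)) records$rt_ms else NA_real_
  data.frame(
    subject_id = ids,
    group = if ("group" %in% names(records)) records$group[1] else NA_character_,
    reward_optimality = if (any(rew)) mean(records$optimal[rew]) else NA_real_,
    punishment_optimality = if (any(pun)) mean(records$optimal[pun]) else NA_real_,
    mean_rt_ms = if (any(!is.na(rt))) mean(rt, na.rm = TRUE) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Per-subject summaries for a whole cohort
#'
#' @param records Trial records for any number of subjects.
#' @return Data frame with one row per subject (see [summarize_subject()]).
#' @export
summarize_subjects <- function(records) {
  parts <- split(records, records$subject_id)
  out <- do.call(rbind, lapply(parts, summarize_subject))
  rownames(out) <- NULL
  out
}

# Two-sided Grubbs critical value for the maximum studentized deviation
# at significance alpha and sample size n.
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative Grubbs outlier screening
#'
#' Repeatedly applies the two-sided Grubbs test (maximum studentized
#' deviation G = max|x - mean| / sd against the critical value at `alpha`)
#' and removes the most extreme point while it is significant.  Stops when
#' no point is significant or fewer than 3 values remain.  A zero standard
#' deviation (constant data) removes nothing.
#'
#' @param values Numeric vector.
#' @param alpha Significance level per iteration (default 0.05).
#' @return List with `retained`, `removed` (in removal order), and
#'   `n_removed`.  Inputs of fewer than 3 values are returned unchanged
#'   with a warning.
#' @export
grubbs_iterative <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values))
  removed <- numeric(0)
  x <- values[!is.na(values)]
  if (length(x) < 3L) {
    warning("fewer than 3 values; Grubbs screening not applied")
    return(list(retained = x, removed = removed, n_removed = 0L))
  }
  repeat {
    n <- length(x)
    if (n < 3L) break
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    if (G > grubbs_critical(n, alpha)) {
      removed <- c(removed, x[i])
      x <- x[-i]
    } else break
  }
  list(retained = x, removed = removed, n_removed = length(removed))
}

#' One-way fixed-effects analysis of variance
#'
#' Computes the full one-way ANOVA decomposition in the layout of a
#' standard ANOVA summary table: sums of squares between/within/total,
#' degrees of freedom, mean squares, the F statistic, its p-value, and the
#' F critical value at `alpha`.  The sums of squares are computed directly
#' from their definitions so every printed column can be reproduced and
#' cross-checked.
#'
#' @param groups List of numeric vectors, one per group (k >= 2, each
#'   non-empty).
#' @param alpha Level for the F critical value (default 0.05).
#' @return An object of class `anova_result` with fields `ss_between`,
#'   `ss_within`, `ss_total`, `df_between`, `df_within`, `df_total`,
#'   `ms_between`, `ms_within`, `F`, `p`, `f_crit`.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 1L))
    stop("every group must contain at least one value", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (any(is.na(x))) stop("missing values in groups", call. = FALSE)
  k <- length(groups)
  N <- length(x)
  if (N - k < 1L) stop("no residual degrees of freedom", call. = FALSE)
  gm <- mean(x)
  means <- vapply(groups, mean, 1)
  ns <- vapply(groups, length, 1L)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  dfb <- k - 1L
  dfw <- N - k
  msb <- ssb / dfb
  msw <- ssw / dfw
  Fv <- msb / msw
  out <- list(ss_between = ssb, ss_within = ssw, ss_total = ssb + ssw,
              df_between = dfb, df_within = dfw, df_total = N - 1L,
              ms_between = msb, ms_within = msw, F = Fv,
              p = stats::pf(Fv, dfb, dfw, lower.tail = FALSE),
              f_crit = stats::qf(1 - alpha, dfb, dfw))
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  tab <- data.frame(
    `Source` = c("Between Groups", "Within Groups", "Total"),
    SS = c(x$ss_between, x$ss_within, x$ss_total),
    df = c(x$df_between, x$df_within, x$df_total),
    MS = c(x$ms_between, x$ms_within, NA),
    F = c(x$F, NA, NA),
    `P-value` = c(x$p, NA, NA),
    `F crit` = c(x$f_crit, NA, NA), check.names = FALSE)
  print(tab, row.names = FALSE, digits = 6, na.print = "")
  invisible(x)
}

#' @export
as.data.frame.anova_result <- function(x, ...) {
  data.frame(ss_between = x$ss_between, ss_within = x$ss_within,
             ss_total = x$ss_total, df_between = x$df_between,
             df_within = x$df_within, df_total = x$df_total,
             ms_between = x$ms_between, ms_within = x$ms_within,
             F = x$F, p = x$p, f_crit = x$f_crit)
}

#' Pairwise post-hoc two-tailed t-tests
#'
#' Two-sample t-tests for every pair of groups, two-tailed, pooled
#' variance by default (switch to Welch with `var_equal = FALSE`).  No
#' multiple-comparison correction is applied.
#'
#' @param groups Named list of numeric vectors (each of length >= 2).
#' @param var_equal Pooled-variance Student test (default) or Welch.
#' @return Data frame with columns `group1`, `group2`, `t`, `df`, `p`.
#'   Pairs where both groups have zero variance get `NA` statistics and a
#'   warning.
#' @export
posthoc_ttests <- function(groups, var_equal = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (any(vapply(groups, length, 1L) < 2L))
    stop("every group needs at least 2 values", call. = FALSE)
  pairs <- utils::combn(names(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- groups[[pairs[1, j]]]
    b <- groups[[pairs[2, j]]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b)))) {
        # identical constant groups: no evidence of difference
        return(data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
                          t = 0, df = length(a) + length(b) - 2L, p = 1))
      }
      warning("degenerate zero variance in both groups for pair ",
              pairs[1, j], " vs ", pairs[2, j])
      return(data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
                        t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(a, b, var.equal = var_equal,
                        alternative = "two.sided")
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-comparison pipeline for one behavioral measure
#'
#' Applies the full analysis used for the published group comparisons to a
#' set of trial records: per-subject summaries, optional iterative Grubbs
#' screening of per-subject values within each group (applied to reaction
#' times), one-way ANOVA across groups, and pairwise post-hoc t-tests.
#'
#' @param records Trial records for several subjects and groups.
#' @param measure `"reward"`, `"punishment"`, or `"rt"`.
#' @param grubbs Screen per-subject values within each group with
#'   [grubbs_iterative()] before testing (default: only for `"rt"`).
#' @param alpha Level for the Grubbs screening and F critical value.
#' @return List with `measure`, `groups` (named list of screened
#'   per-subject values), `n_removed`, `anova` (an `anova_result`), and
#'   `posthoc` (pairwise t-table).
#' @export
analyze_groups <- function(records, measure = c("reward", "punishment", "rt"),
                           grubbs = measure == "rt", alpha = 0.05) {
  measure <- match.arg(measure)
  subj <- summarize_subjects(records)
  col <- switch(measure, reward = "reward_optimality",
                punishment = "punishment_optimality", rt = "mean_rt_ms")
  vals <- split(subj[[col]], subj$group)
  n_removed <- 0L
  if (isTRUE(grubbs)) {
    vals <- lapply(vals, function(v) {
      g <- suppressWarnings(grubbs_iterative(v, alpha))
      n_removed <<- n_removed + g$n_removed
      g$retained
    })
  }
  list(measure = measure, groups = vals, n_removed = n_removed,
       anova = one_way_anova(vals, alpha),
       posthoc = posthoc_ttests(vals))
}
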