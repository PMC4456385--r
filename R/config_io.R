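#' Read and write cohort profiles as YAML
#'
#' The profile file is a list of group blocks, each with the fields of
#' [cohort_profile()] (`n_subjects`, `reward_mean`, `reward_sd`,
#' `punish_mean`, `punish_sd`, `rt_mean`, `rt_sd`, `rt_outlier_rate`).
#'
#' @param path YAML file path.
#' @return A [cohort_profile()].
#' @export
read_cohort_profile <- function(path) {
  y <- yaml::read_yaml(path)
  rows <- lapply(names(y), function(g) {
    as.data.frame(c(list(group = g), y[[g]]), stringsAsFactors = FALSE)
  })
  cohort_profile(do.call(rbind, rows))
}

#' @rdname read_cohort_profile
#' @param profile A [cohort_profile()].
#' @export
write_cohort_profile <- function(profile, path) {
  profile <- as.data.frame(profile)
  y <- lapply(seq_len(nrow(profile)), function(i)
    as.list(profile[i, setdiff(names(profile), "group")]))
  names(y) <- profile$group
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Group parameter sets from a packaged config file
#'
#' Reads the per-group serotonin/dopamine parameter file shipped with the
#' package (`extdata/group_conditions.yaml`), or a user file of the same
#' layout, into [subject_condition()] objects.
#'
#' @param path YAML path; defaults to the packaged file.
#' @return Named list of `subject_condition` objects.
#' @export
read_group_conditions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "group_conditions.yaml",
                        package = "bgicd", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  out <- lapply(names(y), function(g) {
    p <- y[[g]]
    make_condition(group = g,
                   alpha_d1 = p$alpha_d1, alpha_d2 = p$alpha_d2,
                   alpha_d1d2 = p$alpha_d1d2,
                   delta_lim = if (is.null(p$delta_lim)) NA_real_ else p$delta_lim,
                   delta_med = if (is.null(p$delta_med)) NA_real_ else p$delta_med)
  })
  names(out) <- names(y)
  out
}
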