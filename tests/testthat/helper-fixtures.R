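# Shared fixtures: small, fast parameterizations used across test files.

quick_circuit <- function(...) circuit_params(max_iters = 400L, ...)

# a tiny cohort profile for I/O and stats tests
tiny_profile <- function(n = 5L) {
  cohort_profile(data.frame(
    group = c("HC", "PD-OFF", "PD-ON-ICD", "PD-ON-nonICD"),
    n_subjects = n,
    reward_mean = c(0.75, 0.55, 0.82, 0.72), reward_sd = 0.1,
    punish_mean = c(0.74, 0.78, 0.58, 0.70), punish_sd = 0.1,
    rt_mean = c(640, 520, 630, 720), rt_sd = 80,
    rt_outlier_rate = 0, stringsAsFactors = FALSE))
}
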