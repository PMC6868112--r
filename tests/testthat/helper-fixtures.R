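# Shared fixtures: a baseline-consistent average subject and small seeded
# cohorts. Everything is built in code at test time.

avg_subject <- function() {
  p <- cohort_average_params()
  ss <- receptor_steady_state(14.3, p, fixed_kinetics())
  p$V_ii <- hgp_rate(ss$re_bar, p) -
    p$V_id * 10 * 0.9 / (p$K_id + 0.9)
  p
}

noiseless <- function() noise_model(0, 0, 0, 0, 0)

small_cohort <- function(seed = 3, n = 2, noise = noiseless()) {
  generate_paired_cohort(cohort_spec(n_subjects = n, seed = seed),
                         noise = noise)
}

# fast estimator configuration for unit tests
quick_cfg <- function(...) {
  smoothing_config(lambda_schedule = 1e3, outer_maxit = 40,
                   outer_ptol = 1e-8, ...)
}

free_params <- c("V_1", "K1_prime", "V_id", "K_id", "k_in", "V_h")

rel_err <- function(fit, truth, params = free_params) {
  vapply(params, function(nm)
    abs(fit$theta_hat[[nm]] - truth[[nm]]) / truth[[nm]], numeric(1))
}
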