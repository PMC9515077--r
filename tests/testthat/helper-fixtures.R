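# Shared fixtures: everything is generated in code at test time.

# A small polar grid that still resolves the 36-cycle grating.
test_grid <- function() polar_grid(240, 180, 0.1)

# A labeled multi-run trial sequence at the main-experiment timing.
test_sequence <- function(n_runs = 2, seed = 42, p_fill = 0.5) {
  label_filling_in(main_experiment_sequence(n_runs, seed = seed),
                   p_fill = p_fill, seed = seed + 1)
}

# Small simulated cohort member: one ROI, modest size.
test_bold <- function(n_runs = 2, n_voxels = 8, seed = 42, ...) {
  simulate_bold(test_sequence(n_runs, seed), sim_params(n_voxels = n_voxels, ...),
                seed = seed + 2)
}

# Label-independent trial features: balanced labels within run, random x.
chance_features <- function(n_runs = 8, trials_per_run = 10, n_voxels = 20) {
  n <- n_runs * trials_per_run
  structure(list(
    x = matrix(stats::runif(n * n_voxels), n, n_voxels),
    y = factor(unlist(lapply(seq_len(n_runs), function(r)
      sample(rep(c("Fill", "NoFill"), trials_per_run / 2))))),
    run = rep(seq_len(n_runs), each = trials_per_run),
    trial = rep(seq_len(trials_per_run), n_runs)),
    class = "trial_features")
}
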