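# small learned cohort shared across test files (kept deliberately modest so
# the default suite stays fast; the acceptance tests run the full study)
learned_cohort <- run_learning_phase(n_subjects = 2, n_trials = 150,
                                     base_seed = 42)
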