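# Study-scale cohorts for the acceptance checks, built once per run.

# Driver-free cohort for background-model parameter recovery.
recovery_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh))
      coh <<- simulate_cohort(sim_config(n_genes = 15000L, n_drivers = 0L,
                                         seed = 1001L))
    coh
  }
})

# Driver cohort (study conditions) run end-to-end through the pipeline.
driver_cohort_run <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      coh <- simulate_cohort(sim_config(n_genes = 15000L, n_drivers = 20L,
                                        seed = 1002L))
      dir <- file.path(tempdir(), "mutburden_driver_cohort")
      export_cohort(coh, dir)
      run <- suppressMessages(run_pipeline(pipeline_config_from_dir(dir)))
      res <<- list(cohort = coh, dir = dir, run = run)
    }
    res
  }
})
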