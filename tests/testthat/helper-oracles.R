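# Independent oracles and shared fixtures.

# Brute-force substitution-outcome tally: mutate the string base by base,
# translate the affected codon with seqinr (independent genetic-code
# implementation), and compare amino acids.
oracle_site_counts <- function(sequence) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  tally <- c(silent = 0L, missense = 0L, nonsense = 0L, stop_loss = 0L)
  for (i in seq_len(n)) {
    codon_i <- (i - 1L) %/% 3L
    cod <- chars[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
    aa_ref <- seqinr::translate(tolower(cod), numcode = 1)
    for (alt in setdiff(bases, chars[i])) {
      cod_alt <- cod
      cod_alt[i - codon_i * 3L] <- alt
      aa_alt <- seqinr::translate(tolower(cod_alt), numcode = 1)
      cls <- if (aa_ref == aa_alt) "silent"
             else if (aa_alt == "*") "nonsense"
             else if (aa_ref == "*") "stop_loss"
             else "missense"
      tally[cls] <- tally[cls] + 1L
    }
  }
  tally
}

# Random valid CDS (no length/stop constraints beyond frame) for oracle
# comparisons.
random_cds <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3L * n_codons, replace = TRUE),
        collapse = "")
}

# A small cohort shared by model/outlier/pipeline tests; built once per
# test run.
small_cohort <- local({
  coh <- NULL
  function() {
    if (is.null(coh))
      coh <<- simulate_cohort(sim_config(n_genes = 1200L, n_drivers = 6L,
                                         seed = 424242L))
    coh
  }
})

# The same cohort exported to disk (once), with its pipeline run.
small_pipeline_run <- local({
  res <- NULL
  function() {
    if (is.null(res)) {
      dir <- file.path(tempdir(), "mutburden_small_cohort")
      files <- export_cohort(small_cohort(), dir)
      out <- run_pipeline(pipeline_config_from_dir(dir))
      res <<- list(dir = dir, files = files, run = out)
    }
    res
  }
})
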