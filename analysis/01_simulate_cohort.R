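#!/usr/bin/env Rscript
# Stage 1: generate the study cohort.
#
# Simulates 15,610 genes under the default study conditions — log-normal
# CDS lengths (~1.5 kb mean), Dirichlet base composition, copula-linked
# covariates, Poisson counts around linear background rates targeting
# R^2 = 0.88 / 0.40 / 0.23 for missense / nonsense / frameshift, and 20
# driver genes with an 8-residual-SD excess — and exports it in the exact
# file formats the pipeline ingests. Bulky inputs go to scratch/ (they are
# regenerated on demand); everything downstream reads from there.

library(mutburden)

cohort_dir <- "scratch/cohort"
cfg <- sim_config(seed = 20260926L)

cat("Simulating cohort:", cfg$n_genes, "genes,", cfg$n_drivers,
    "drivers, seed", cfg$seed, "\n")
cohort <- simulate_cohort(cfg)

cat("Mean counts per gene:\n")
print(round(colMeans(
  cohort$counts[, .(n_missense, n_nonsense, n_fs, n_silent)]), 2))

files <- export_cohort(cohort, cohort_dir)
cat("Exported", length(files), "files to", cohort_dir, "\n")
cat("Driver genes (truth, withheld from the pipeline):",
    sum(cohort$truth$is_driver), "\n")
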