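#!/usr/bin/env Rscript
# Stage 4: positive-outlier calling and driver recovery.
#
# Reads the pipeline run of stage 3, reports the multiplicity-corrected
# Z cutoff, the flagged genes, how many of them are the cohort's injected
# drivers, and the TS/OG group Z-score comparison.

library(mutburden)
library(data.table)

cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config_from_dir(cohort_dir,
                                             out_dir = "scratch/run"))
truth <- fread(file.path(cohort_dir, "truth_genes.tsv"))

cat(sprintf("Cutoff: Z > %.2f (alpha = 0.05 over %d genes, max of 3)\n",
            res$cutoff, nrow(res$scoring)))

out <- as.data.table(res$outliers)
flagged <- out[n_flags > 0]
drivers <- truth[is_driver == TRUE, gene_id]
cat(sprintf("Flagged %d genes; %d of %d injected drivers recovered, %d false positives\n",
            nrow(flagged), sum(drivers %in% flagged$gene_id),
            length(drivers), sum(!flagged$gene_id %in% drivers)))

fwrite(out[seq_len(min(50L, .N)),
           .(gene_id, z_missense = round(z_missense, 2),
             z_nonsense = round(z_nonsense, 2), z_fs = round(z_fs, 2),
             max_z = round(max_z, 2), flags)],
       "results/outliers_top50.tsv", sep = "\t")

if (!is.null(res$group_summary)) {
  gs <- res$group_summary
  fwrite(gs[, .(group, mut_type, n_genes, mean_z = round(mean_z, 2),
                sem_z = round(sem_z, 3), p_vs_other = signif(p_vs_other, 2))],
         "results/group_zscores.tsv", sep = "\t")
  cat("Group mean Z (vs other genes):\n")
  print(gs)
}
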