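#!/usr/bin/env Rscript
# Stage 3: background-burden regression models.
#
# Runs the full pipeline (feature assembly, stepwise fits per mutation
# type plus the pan-mutation model) on the exported cohort and writes the
# univariate screening tables, the multivariate model reports, and the
# pan-vs-specific R^2 comparison.

library(mutburden)
library(data.table)

cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config_from_dir(cohort_dir,
                                             out_dir = "scratch/run"))

fit_rows <- res$scoring$gene_id %in% res$features$fit_genes
ft <- res$scoring[fit_rows]
cnt <- res$counts[match(ft$gene_id, gene_id)]

for (tp in c("missense", "nonsense", "frameshift")) {
  y <- cnt[[paste0("n_", c(missense = "missense", nonsense = "nonsense",
                           frameshift = "fs")[[tp]])]]
  uni <- univariate_screen(ft, y, candidate_predictors(tp))
  fwrite(uni[, .(predictor, t = round(t, 1), p = signif(p, 2),
                 beta = round(beta, 2))],
         sprintf("results/univariate_%s.tsv", tp), sep = "\t")
}

for (tp in names(res$models)) {
  m <- res$models[[tp]]
  cat(sprintf("%-10s R^2 = %.3f, residual SD = %.2f, predictors: %s\n",
              tp, m$r2, m$residual_sd,
              paste(m$selected_predictors, collapse = ", ")))
  fwrite(m$table[, .(predictor, t = round(t, 2), p = signif(p, 3),
                     beta = round(beta, 3))],
         sprintf("results/model_%s.tsv", tp), sep = "\t")
}

fwrite(res$comparison[, .(outcome, r2_specific = round(r2_specific, 3),
                          r2_pan = round(r2_pan, 3))],
       "results/r2_pan_vs_specific.tsv", sep = "\t")
cat("Pan vs type-specific R^2:\n")
print(res$comparison)
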