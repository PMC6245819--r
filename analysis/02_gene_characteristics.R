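#!/usr/bin/env Rscript
# Stage 2: gene characteristics and their inter-correlations.
#
# Reads the exported cohort, computes every per-gene characteristic from
# the coding sequences and covariate tracks, tabulates mutation counts,
# and writes (a) the pairwise Spearman correlation matrix of the
# characteristics, and (b) moving-average curves of mutation count
# against gene size — the descriptive analyses that motivate modeling
# the three mutation types separately.

library(mutburden)
library(data.table)

cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

seqs <- read_cds_fasta(file.path(cohort_dir, "cds.fasta"))
cov <- fread(file.path(cohort_dir, "covariates.tsv"))
feats <- sequence_features(seqs, setNames(cov$n_orthologs, cov$gene_id))

records <- read_mutation_tsv(file.path(cohort_dir, "mutations.tsv"))
filtered <- filter_records(records)
cat("Filter audit:", nrow(records), "records in,", nrow(filtered),
    "retained,", attr(filtered, "n_dropped_filter"),
    "removed (SNP-flagged or targeted screens)\n")
counts <- count_by_gene(filtered, setNames(feats$cds_length, feats$gene_id))

full <- merge(feats, cov, by = "gene_id")
full[, n_silent_observed := counts[match(full$gene_id, gene_id), n_silent]]

char_cols <- c("pct_a", "pct_g", "pct_c", "pct_t", "nd", "pct_cpg",
               "cds_length", "conservation_index",
               "n_potential_nonsense", "n_potential_missense",
               "mutsig_expr", "mutsig_reptime", "mutsig_hic",
               "n_silent_observed")
sp <- pairwise_spearman(full, char_cols)
rho <- data.table(characteristic = rownames(sp$rho),
                  round(as.data.table(sp$rho), 2))
fwrite(rho, "results/characteristic_correlations.tsv", sep = "\t")
n_sig <- sum(sp$p[upper.tri(sp$p)] < 0.05, na.rm = TRUE)
cat("Significant characteristic pairs (p < 0.05):", n_sig, "of",
    sum(upper.tri(sp$p)), "\n")

# burden vs gene size, smoothed over a 100-gene sliding window (curves
# exported at every 10th window position for compactness)
for (tp in c("missense", "nonsense", "fs")) {
  curve <- moving_average_curve(full$cds_length,
                                counts[match(full$gene_id, gene_id),
                                       get(paste0("n_", tp))],
                                window = 100L, step = 10L)
  fwrite(curve, sprintf("results/curve_size_vs_%s.tsv", tp), sep = "\t")
}
cat("Wrote correlation matrix and size curves to results/\n")
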