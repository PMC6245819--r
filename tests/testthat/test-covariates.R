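# Covariate assembly: track assignment, expression aggregation, feature
# joining, Spearman correlations.

test_that("probe tracks average inside genes and fall back to the nearest probe", {
  genes <- data.table::data.table(
    gene_id = c("gIn", "gOut", "gOne"),
    chrom = "chr1",
    start = c(100L, 500L, 900L),
    end = c(200L, 600L, 1000L))
  probes <- data.table::data.table(
    chrom = "chr1",
    pos = c(120L, 180L, 650L, 950L),
    value = c(-1.0, 3.0, 2.5, 7.0))
  v <- assign_track_to_genes(probes, genes)
  expect_equal(v[["gIn"]], 1.0)    # mean of -1 and 3
  expect_equal(v[["gOut"]], 2.5)   # nearest probe outside
  expect_equal(v[["gOne"]], 7.0)   # singleton mean
  # constant track gives every gene that constant
  const <- data.table::data.table(chrom = "chr1", pos = c(1L, 700L),
                                  value = 4.2)
  expect_true(all(assign_track_to_genes(const, genes) == 4.2))
  # exact distance tie broken toward the lower coordinate
  tie_gene <- data.table::data.table(gene_id = "gTie", chrom = "chr1",
                                     start = 100L, end = 101L)
  tie_probes <- data.table::data.table(chrom = "chr1", pos = c(90L, 110L),
                                       value = c(1, 2))
  expect_equal(unname(assign_track_to_genes(tie_probes, tie_gene)), 1)
  # absent chromosome names the gene
  bad <- data.table::data.table(gene_id = "gX", chrom = "chrZ",
                                start = 0L, end = 10L)
  expect_error(assign_track_to_genes(probes, bad), "gX")
})

test_that("expression aggregation takes row means and log10", {
  m <- rbind(gA = c(100, 100, 100), gB = c(1, NA, 3), gC = c(NA, NA, NA))
  expect_message(agg <- aggregate_expression(m), "excluded")
  expect_equal(agg$gene_id, c("gA", "gB"))
  expect_equal(agg$mean_expression, c(100, 2))
  expect_equal(agg$log_mean_expression[1], 2)
  # brute-force oracle on a random matrix
  set.seed(3)
  rm_ <- matrix(runif(60, 1, 50), 12, 5,
                dimnames = list(paste0("g", 1:12), NULL))
  agg2 <- aggregate_expression(rm_)
  for (i in 1:12)
    expect_equal(agg2$mean_expression[i], sum(rm_[i, ]) / 5)
  # zero mean with pseudocount 0 -> NA log (dropped later as incomplete)
  z <- aggregate_expression(rbind(g0 = c(0, 0)))
  expect_true(is.na(z$log_mean_expression))
  expect_equal(aggregate_expression(rbind(g0 = c(0, 0)),
                                    pseudocount = 1)$log_mean_expression, 0)
})

test_that("snp_density is a scale-invariant ratio", {
  expect_equal(snp_density(0, 1000), 0)
  expect_equal(snp_density(5, 1000), 0.005)
  expect_equal(snp_density(10, 2000), snp_density(5, 1000))
  expect_error(snp_density(-1, 100), "negative")
  expect_error(snp_density(1, 0), "positive")
})

test_that("feature assembly inner-joins sources and keeps excluded genes for scoring", {
  seqs <- Biostrings::DNAStringSet(
    c(g1 = "ATGAAATAA", g2 = "ATGCCCTAA", g3 = "ATGGGGTAA"))
  sf <- sequence_features(seqs, c(g1 = 2L, g2 = 4L, g3 = 6L))
  expr <- data.table::data.table(gene_id = c("g1", "g2"),
                                 mean_expression = c(10, 20),
                                 log_mean_expression = c(1, log10(20)))
  cov <- data.table::data.table(
    gene_id = c("g1", "g2", "g3"), n_unique_snps = c(1L, 2L, 3L),
    chromatin_accessibility = c(1, 1, 1), mutsig_expr = c(5, 5, 5),
    mutsig_hic = c(0, 0, 0), mutsig_reptime = c(500, 500, 500))
  rep_t <- c(g1 = 0.1, g2 = -0.2, g3 = 0.3)
  n_sil <- c(g1 = 4L, g2 = 0L, g3 = 2L)
  asm <- assemble_features(sf, expr, cov, rep_t, n_sil,
                           exclude_fit = "g2")
  # g3 dropped: absent from expression source
  expect_equal(sort(asm$scoring$gene_id), c("g1", "g2"))
  expect_true("g3" %in% asm$drop_log$gene_id)
  # excluded gene still scored, not fitted
  expect_equal(asm$fit_genes, "g1")
  expect_true(all(asm$fit_genes %in% asm$scoring$gene_id))
  # every cell traces to its source
  expect_equal(asm$scoring[gene_id == "g1", n_silent_observed], 4L)
  expect_equal(asm$scoring[gene_id == "g1", snp_density], 1 / 9)
  expect_error(assemble_features(sf, expr[0L], cov, rep_t, n_sil),
               "no genes shared")
})

test_that("pairwise Spearman has unit diagonal and rank invariance", {
  set.seed(9)
  n <- 1000L
  dt <- data.table::data.table(x = rnorm(n))
  dt[, y := exp(x)]          # strictly increasing transform
  dt[, z := rnorm(n)]        # independent
  ps <- pairwise_spearman(dt, c("x", "y", "z"))
  expect_equal(unname(diag(ps$rho)), c(1, 1, 1))
  expect_equal(ps$rho["x", "y"], 1)
  expect_lt(abs(ps$rho["x", "z"]), 0.1)
  expect_true(isSymmetric(ps$rho))
  # under the null, p-values are roughly uniform: significance near alpha
  set.seed(10)
  m <- data.table::as.data.table(matrix(rnorm(1000 * 12), 1000, 12))
  psn <- pairwise_spearman(m, names(m))
  off <- psn$p[upper.tri(psn$p)]
  expect_lt(mean(off < 0.05), 0.15)
  # constant column flagged
  dt[, const := 1]
  expect_warning(pc <- pairwise_spearman(dt, c("x", "const")), "constant")
  expect_true(is.na(pc$rho["x", "const"]))
})
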