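# Synthetic cohort generator: sequences, copula covariates, counts,
# export round-trip.

test_that("generated coding sequences start with ATG, end with a stop, no internal stops", {
  cds <- generate_cds(2L, c(0.25, 0.25, 0.25, 0.25), 1L)
  expect_equal(cds$length_nt, 6L)
  expect_equal(substr(cds$sequence, 1, 3), "ATG")
  expect_true(substr(cds$sequence, 4, 6) %in% c("TAA", "TAG", "TGA"))
  set.seed(7)
  for (i in 1:20) {
    n_cod <- sample(3:80, 1)
    cds <- generate_cds(n_cod, c(0.3, 0.2, 0.2, 0.3), 100L + i)
    expect_equal(cds$length_nt, 3L * n_cod)
    codons <- substring(cds$sequence, seq(1, cds$length_nt - 3, 3),
                        seq(3, cds$length_nt - 3, 3))
    expect_false(any(codons[-1][-length(codons[-1])] %in%
                       c("TAA", "TAG", "TGA")))
  }
})

test_that("realized base composition tracks the stop-rejection-adjusted target", {
  target <- c(0.25, 0.25, 0.25, 0.25)
  cds <- generate_cds(10000L, target, 9L)
  # oracle: expected base fractions of internal codons are the mean
  # per-position base usage of the 61 non-stop codons under the target
  # product distribution (stop rejection slightly depletes T, A and G)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0,
                  collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  expected <- colSums(vapply(bases, function(b)
    vapply(strsplit(sense, ""), function(cc) sum(cc == b), numeric(1)),
    numeric(length(sense)))) / (3 * length(sense))
  internal <- substr(cds$sequence, 4, cds$length_nt - 3)
  st <- composition_stats(internal)
  got <- c(A = st$p_a, C = st$p_c, G = st$p_g, T = st$p_t)
  expect_true(all(abs(got - expected) < 0.01))
})

test_that("generation is deterministic per seed", {
  c1 <- simulate_cohort(sim_config(n_genes = 60L, n_drivers = 2L,
                                   seed = 5L))
  c2 <- simulate_cohort(sim_config(n_genes = 60L, n_drivers = 2L,
                                   seed = 5L))
  expect_identical(as.character(c1$seqs), as.character(c2$seqs))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(sim_config(n_genes = 60L, n_drivers = 2L,
                                   seed = 6L))
  expect_false(identical(c1$counts, c3$counts))
})

test_that("copula covariates reproduce their configured length correlation", {
  cfg <- sim_config(n_genes = 5000L, n_drivers = 0L, seed = 88L,
                    cor_with_length = c(expression = -0.3,
                                        replication_time = 0,
                                        chromatin_accessibility = 0,
                                        snp = 0, orthologs = 0,
                                        mutsig_expr = -0.2,
                                        mutsig_hic = 0,
                                        mutsig_reptime = 0))
  ch <- generate_characteristics(cfg)
  ft <- ch$features
  rho_expr <- cor(log(ft$cds_length), ft$log_mean_expression,
                  method = "spearman")
  expect_lt(abs(rho_expr - (-0.3)), 0.05)
  rho_null <- cor(log(ft$cds_length), ft$replication_time,
                  method = "spearman")
  expect_lt(abs(rho_null), 0.05)
})

test_that("count means and driver injection behave as configured", {
  cfg <- sim_config(n_genes = 5000L, n_drivers = 0L, seed = 13L)
  coh <- simulate_cohort(cfg)
  mc <- cfg$mean_count
  got <- colMeans(coh$counts[, .(n_missense, n_nonsense, n_fs, n_silent)])
  expect_lt(abs(got[["n_missense"]] - mc[["missense"]]), 0.03 * mc[["missense"]])
  expect_lt(abs(got[["n_silent"]] - mc[["silent"]]), 0.03 * mc[["silent"]])
  # no drivers: labels carry no signal
  expect_true(all(!coh$truth$is_driver))

  cfg2 <- sim_config(n_genes = 2000L, n_drivers = 10L, seed = 14L)
  coh2 <- simulate_cohort(cfg2)
  tr <- coh2$truth
  expect_equal(sum(tr$is_driver), 10L)
  # OG-like drivers are missense-only: nonsense/FS deltas zero
  og <- tr[tr$driver_class == "OG", ]
  expect_true(all(og$delta_missense > 0))
  expect_true(all(og$delta_nonsense == 0 & og$delta_fs == 0))
  # silent counts never receive driver excess: their mean matches the
  # background rate even on driver genes
  drv <- which(tr$is_driver)
  expect_lt(abs(mean(coh2$counts$n_silent[drv] -
                       tr$lambda_silent[drv])),
            3 * sqrt(mean(tr$lambda_silent[drv]) / length(drv)))
})

test_that("the generating coefficients reproduce the latent rates", {
  coh <- small_cohort()
  ft <- coh$features
  for (tp in c("missense", "nonsense", "fs")) {
    beta <- coh$beta[[tp]]
    terms <- setdiff(names(beta), "(Intercept)")
    lin <- beta[["(Intercept)"]] +
      as.matrix(as.data.frame(ft)[terms]) %*% beta[terms]
    expect_equal(pmax(0, as.vector(lin)),
                 coh$truth[[paste0("lambda_", tp)]], tolerance = 1e-8)
  }
})

test_that("export writes a readable cohort that round-trips", {
  run <- small_pipeline_run()
  d <- run$dir
  expect_true(all(file.exists(run$files)))
  # FASTA round-trip
  seqs <- read_cds_fasta(run$files[["cds"]])
  expect_identical(as.character(seqs), as.character(small_cohort()$seqs))
  # truth files are set apart by naming convention and no pipeline input
  # glob picks them up
  inputs <- setdiff(names(run$files), c("truth_genes", "truth_beta",
                                        "manifest"))
  expect_false(any(grepl("truth", basename(run$files[inputs]))))
  # manifest hash changes iff config changes
  m1 <- jsonlite::read_json(file.path(d, "manifest.json"))
  d2 <- tempfile()
  export_cohort(small_cohort(), d2)
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(m1$config_hash, m2$config_hash)
  coh3 <- simulate_cohort(sim_config(n_genes = 60L, seed = 5L))
  d3 <- tempfile()
  export_cohort(coh3, d3)
  m3 <- jsonlite::read_json(file.path(d3, "manifest.json"))
  expect_false(identical(m1$config_hash, m3$config_hash))
  # exported mutation table reproduces the cohort's counts after filtering
  rec <- read_mutation_tsv(run$files[["mutations"]])
  filt <- filter_records(rec)
  lens <- setNames(small_cohort()$features$cds_length,
                   small_cohort()$features$gene_id)
  tab <- count_by_gene(filt, lens)
  expect_identical(tab$n_missense,
                   small_cohort()$counts[match(tab$gene_id, gene_id),
                                         n_missense])
})
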