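# Genetic-code computations: substitution outcomes, potential sites,
# composition statistics, conservation index.

test_that("single substitutions are classified by their coding outcome", {
  cases <- list(
    list("CGG", 1, "A", "CAG", "missense"),   # Arg -> Gln
    list("CTG", 2, "A", "CTA", "silent"),     # Leu -> Leu
    list("TGG", 1, "A", "TAG", "nonsense"),   # Trp -> stop
    list("TAA", 2, "G", "TAG", "silent"),     # stop retained
    list("TAA", 0, "C", "CAA", "stop_loss"))  # stop -> Gln
  for (cs in cases) {
    out <- classify_substitution(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(out$alt_codon, cs[[4]])
    expect_equal(out$class, cs[[5]])
  }
  # case-insensitive after normalization
  expect_equal(classify_substitution("cgg", 1, "a")$class, "missense")
})

test_that("invalid substitution inputs are rejected", {
  expect_error(classify_substitution("CGN", 1, "A"), "invalid")
  expect_error(classify_substitution("CGG", 1, "G"), "equals the reference")
  expect_error(classify_substitution("CGG", 3, "A"), "within_codon_pos")
  expect_error(coding_sequence("g", "ATGA"), "multiple of 3")
  expect_error(coding_sequence("g", "ATGNNN"), "non-ACGT")
})

test_that("potential-site counts partition 3N and match hand enumeration", {
  # ATG: all 9 substitutions are missense (Met has no synonym, no stop
  # one step away)
  ps <- count_potential_sites("ATG")
  expect_equal(ps$n_total_sns, 9L)
  expect_equal(ps$n_missense, 9L)
  expect_equal(ps$n_nonsense + ps$n_silent + ps$n_stop_loss, 0L)

  ps2 <- count_potential_sites("ATGTGGTAA")
  expect_equal(ps2$n_total_sns, 27L)
  expect_equal(ps2$n_missense + ps2$n_nonsense + ps2$n_silent +
                 ps2$n_stop_loss, 27L)
  expect_equal(unname(oracle_site_counts("ATGTGGTAA")),
               c(ps2$n_silent, ps2$n_missense, ps2$n_nonsense,
                 ps2$n_stop_loss))
})

test_that("potential-site counts agree with a brute-force oracle on random CDSs", {
  set.seed(11)
  for (i in 1:100) {
    seq <- random_cds(sample(1:100, 1))
    ps <- count_potential_sites(seq)
    oracle <- oracle_site_counts(seq)
    expect_equal(ps$n_silent, unname(oracle["silent"]))
    expect_equal(ps$n_missense, unname(oracle["missense"]))
    expect_equal(ps$n_nonsense, unname(oracle["nonsense"]))
    expect_equal(ps$n_stop_loss, unname(oracle["stop_loss"]))
    expect_equal(ps$n_total_sns, 3L * nchar(seq))
  }
})

test_that("21 codons can yield a stop by one substitution", {
  capable <- nonsense_capable_codons()
  expect_length(capable, 21L)
  expect_true(all(c("TGG", "TAC", "TCA") %in% capable))
  expect_false("ATG" %in% capable)
  # stop codons themselves are members (they can mutate to another stop)
  expect_true(all(c("TAA", "TAG", "TGA") %in% capable))
})

test_that("composition statistics follow their definitions", {
  eq <- composition_stats("ACGTACGTACGT")
  expect_equal(eq$nd, 0.75)
  homo <- composition_stats("AAAAAA")
  expect_equal(homo$p_a, 1)
  expect_equal(homo$nd, 0)
  expect_equal(homo$cpg_fraction, 0)
  cg <- composition_stats("CGCGCG")
  expect_equal(cg$cpg_fraction, 0.5)
  expect_equal(cg$nd, 0.5)
  # fractions always sum to 1; nd bounded by [0, 0.75]
  set.seed(5)
  for (i in 1:25) {
    st <- composition_stats(random_cds(sample(2:60, 1)))
    expect_equal(st$p_a + st$p_c + st$p_g + st$p_t, 1, tolerance = 1e-12)
    expect_gte(st$nd, 0)
    expect_lte(st$nd, 0.75)
  }
})

test_that("conservation index bins ortholog counts in pairs", {
  expect_equal(conservation_index(c(0, 1, 2, 3, 20)),
               c(1L, 1L, 2L, 2L, 11L))
  expect_error(conservation_index(-1), "non-negative")
})

test_that("largest transcript per gene is kept, ties broken by record id", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">geneA|tr2", "ATGAAATAA",
               ">geneA|tr1", "ATGTAA",
               ">geneB|trZ", "ATGTAA",
               ">geneB|trA", "ATGTGA"), fa)
  seqs <- read_cds_fasta(fa)
  expect_equal(sort(names(seqs)), c("geneA", "geneB"))
  expect_equal(as.character(seqs[["geneA"]]), "ATGAAATAA")
  # geneB: equal lengths, lexicographically smaller id wins
  expect_equal(as.character(seqs[["geneB"]]), "ATGTGA")
})

test_that("sequence_features matches single-gene computations", {
  seqs <- Biostrings::DNAStringSet(c(g1 = "ATGTGGTAA", g2 = "ATGCGCGCGTAA"))
  ft <- sequence_features(seqs, c(g1 = 4L, g2 = 11L))
  expect_equal(ft$cds_length, c(9L, 12L))
  ps <- count_potential_sites("ATGCGCGCGTAA")
  row2 <- ft[ft$gene_id == "g2", ]
  expect_equal(row2$n_potential_missense, ps$n_missense)
  expect_equal(row2$n_potential_silent, ps$n_silent)
  cs <- composition_stats("ATGCGCGCGTAA")
  expect_equal(row2$nd, cs$nd)
  expect_equal(row2$pct_cpg, cs$cpg_fraction)
  expect_equal(ft$conservation_index, c(3L, 6L))
})
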