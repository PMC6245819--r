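# Synthetic cohort generator: coding sequences, correlated gene
# characteristics, and Poisson mutation counts with a known linear
# background model and injected driver excesses.

# All randomness derives from one integer seed through fixed per-stream
# offsets, so each generation stage is independently reproducible.
stream_seed <- function(seed, stream) {
  offsets <- c(lengths = 1L, composition = 2L, cds = 3L, copula = 4L,
               expression = 5L, snps = 6L, orthologs = 7L, silent = 8L,
               missense = 9L, nonsense = 10L, fs = 11L, drivers = 12L,
               decoys = 13L, probes = 14L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  as.integer((as.numeric(seed) * 97 + offsets[[stream]]) %% 2147483647)
}

#' Simulation configuration for a synthetic cohort
#'
#' Defaults describe the cohort the package's analyses are run on: 15,610
#' genes; log-normal CDS lengths averaging about 1.5 kb; per-gene base
#' composition drawn from a Dirichlet around equal usage; weak correlations
#' between log CDS length and the non-sequence covariates (matching the
#' weak observed inter-characteristic correlations in real cohorts); mean
#' background counts per gene of 143 missense, 10.5 nonsense, 5.5
#' frameshift and 40 silent mutations; background-model R-squared targets
#' of 0.88, 0.40 and 0.23 for missense, nonsense and frameshift; 20 driver
#' genes whose designated mutation types receive a multiplicative excess
#' equal to 8 fitted-residual standard deviations.
#'
#' @param n_genes Number of genes.
#' @param length_meanlog,length_sdlog Log-normal parameters for CDS length
#'   in codons (start and stop codons included).
#' @param min_codons Lower clip for gene length in codons.
#' @param dirichlet_conc Total Dirichlet concentration for per-gene target
#'   base composition (larger = tighter around 25% each).
#' @param cor_with_length Named numeric vector: Gaussian-copula correlation
#'   of each non-sequence covariate with log CDS length.
#' @param n_cell_lines Cell lines in the exported expression matrix.
#' @param mean_count Named numeric: mean background count per gene and
#'   mutation type (`missense`, `nonsense`, `fs`, `silent`).
#' @param target_r2 Named numeric: share of count variance carried by the
#'   linear predictor, per type.
#' @param n_drivers Number of driver genes.
#' @param driver_excess_sd Injected excess per driver gene and type, in
#'   units of the background residual standard deviation (sqrt of the mean
#'   count); the multiplicative delta per gene follows from its own rate.
#' @param decoy_fraction Fraction of extra exported mutation records that
#'   must be removed by the cohort filters (half SNP-flagged, half from
#'   targeted screens).
#' @param seed Integer master seed.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 15610L,
                       length_meanlog = log(450), length_sdlog = 0.55,
                       min_codons = 50L,
                       dirichlet_conc = 100,
                       cor_with_length = c(expression = -0.07,
                                           replication_time = -0.05,
                                           chromatin_accessibility = -0.02,
                                           snp = -0.10,
                                           orthologs = 0.08,
                                           mutsig_expr = -0.07,
                                           mutsig_hic = -0.02,
                                           mutsig_reptime = -0.05),
                       n_cell_lines = 20L,
                       mean_count = c(missense = 143, nonsense = 10.5,
                                      fs = 5.5, silent = 40),
                       target_r2 = c(missense = 0.88, nonsense = 0.40,
                                     fs = 0.23, silent = 0.85),
                       n_drivers = 20L,
                       driver_excess_sd = 8,
                       decoy_fraction = 0.04,
                       seed = 1L) {
  stopifnot(n_genes >= 10L, all(mean_count > 0),
            all(target_r2 > 0 & target_r2 < 1),
            all(abs(cor_with_length) < 1), n_drivers >= 0L,
            driver_excess_sd >= 0)
  structure(list(n_genes = as.integer(n_genes),
                 length_meanlog = length_meanlog,
                 length_sdlog = length_sdlog,
                 min_codons = as.integer(min_codons),
                 dirichlet_conc = dirichlet_conc,
                 cor_with_length = cor_with_length,
                 n_cell_lines = as.integer(n_cell_lines),
                 mean_count = mean_count, target_r2 = target_r2,
                 n_drivers = as.integer(n_drivers),
                 driver_excess_sd = driver_excess_sd,
                 decoy_fraction = decoy_fraction,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate one synthetic coding sequence
#'
#' ATG, then `n_codons - 2` codons sampled base-wise from the target
#' composition with rejection of in-frame stop codons, then one uniformly
#' chosen stop codon. Deterministic per seed.
#'
#' @param n_codons Total codons including start and stop (>= 2).
#' @param composition_target Numeric length-4 vector of A/C/G/T fractions.
#' @param rng_seed Integer seed.
#' @param gene_id Identifier for the resulting record.
#' @return A `CodingSequence`.
#' @export
generate_cds <- function(n_codons, composition_target, rng_seed,
                         gene_id = "synth") {
  stopifnot(n_codons >= 2L)
  seqs <- generate_cds_set(n_codons, rbind(composition_target), rng_seed)
  coding_sequence(gene_id, as.character(seqs[[1L]]))
}

# Vectorized CDS generation for a whole cohort. `composition` is an
# n_genes x 4 matrix of target fractions (columns A,C,G,T).
generate_cds_set <- function(n_codons, composition, seed,
                             gene_ids = paste0("g", seq_along(n_codons))) {
  stopifnot(nrow(composition) == length(n_codons),
            all(abs(rowSums(composition) - 1) < 1e-8),
            all(n_codons >= 2L))
  p_stop <- composition[, 4L] * composition[, 1L] *
    (composition[, 1L] + 2 * composition[, 3L])  # TAA + TAG + TGA
  if (any(1 - p_stop < 1e-6))
    stop("composition makes stop-codon rejection impossible")
  set.seed(seed)
  n_internal <- n_codons - 2L
  gene_idx <- rep.int(seq_along(n_codons), n_internal)
  cum <- composition %*% upper.tri(diag(4), diag = TRUE)
  draw_base <- function(rows) {
    u <- runif(length(rows))
    cc <- cum[rows, , drop = FALSE]
    idx <- 1L + (u > cc[, 1L]) + (u > cc[, 2L]) + (u > cc[, 3L])
    idx
  }
  b1 <- draw_base(gene_idx); b2 <- draw_base(gene_idx)
  b3 <- draw_base(gene_idx)
  codon_of <- function(i1, i2, i3)
    paste0(BASES[i1], BASES[i2], BASES[i3])
  codons <- codon_of(b1, b2, b3)
  repeat {
    bad <- which(codons %in% STOP_CODONS)
    if (!length(bad)) break
    rows <- gene_idx[bad]
    codons[bad] <- codon_of(draw_base(rows), draw_base(rows),
                            draw_base(rows))
  }
  stops <- STOP_CODONS[sample.int(3L, length(n_codons), replace = TRUE)]
  internal <- vapply(split(codons, factor(gene_idx,
                                          levels = seq_along(n_codons))),
                     paste0, character(1L), collapse = "")
  seqs <- Biostrings::DNAStringSet(paste0("ATG", internal, stops))
  names(seqs) <- gene_ids
  seqs
}

# Gaussian copula scores for the non-sequence covariates: each covariate's
# normal score is r * z_len + sqrt(1-r^2) * e, with the MutsigCV analogue
# of a covariate sharing 70% of its idiosyncratic part with it.
copula_scores <- function(z_len, cor_with_length, seed) {
  set.seed(seed)
  n <- length(z_len)
  r <- cor_with_length
  e <- list()
  for (nm in c("expression", "replication_time", "chromatin_accessibility",
               "snp", "orthologs"))
    e[[nm]] <- rnorm(n)
  couple <- function(base_nm) {
    a <- 0.7
    a * e[[base_nm]] + sqrt(1 - a^2) * rnorm(n)
  }
  e$mutsig_expr <- couple("expression")
  e$mutsig_reptime <- couple("replication_time")
  e$mutsig_hic <- couple("chromatin_accessibility")
  z <- lapply(names(r), function(nm)
    r[[nm]] * z_len + sqrt(1 - r[[nm]]^2) * e[[nm]])
  names(z) <- names(r)
  z
}

#' Generate correlated gene characteristics for a synthetic cohort
#'
#' Draws CDS lengths and per-gene target compositions, generates coding
#' sequences, computes all sequence-derived features with the codon engine,
#' and attaches non-sequence covariates (expression over cell lines,
#' replication timing with an exported probe track, chromatin
#' accessibility, SNP counts, ortholog counts, MutsigCV-style covariates)
#' drawn from a Gaussian copula correlated with log CDS length and mapped
#' to realistic marginal scales.
#'
#' @param config A `SimulationConfig`.
#' @return List with `seqs` (`DNAStringSet`), `features` (full
#'   `GeneFeatureRecord` table minus observed silent counts),
#'   `expression_matrix`, `covariates` (the covariate TSV contents),
#'   `gene_intervals`, `probes`.
#' @export
generate_characteristics <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  n <- config$n_genes
  set.seed(stream_seed(config$seed, "lengths"))
  n_codons <- pmax(config$min_codons,
                   as.integer(round(stats::rlnorm(n, config$length_meanlog,
                                                  config$length_sdlog))))
  set.seed(stream_seed(config$seed, "composition"))
  alpha <- config$dirichlet_conc / 4
  g <- matrix(stats::rgamma(n * 4L, shape = alpha), n, 4L)
  composition <- g / rowSums(g)

  gene_ids <- sprintf("g%05d", seq_len(n))
  seqs <- generate_cds_set(n_codons, composition,
                           stream_seed(config$seed, "cds"), gene_ids)

  z_len <- as.vector(scale(log(Biostrings::width(seqs))))
  z <- copula_scores(z_len, config$cor_with_length,
                     stream_seed(config$seed, "copula"))

  # marginal transforms
  mean_expr <- stats::qlnorm(pnorm(z$expression), meanlog = 3, sdlog = 1.2)
  reptime <- z$replication_time                       # signed, ~N(0,1)
  chromatin <- stats::qlnorm(pnorm(z$chromatin_accessibility), 0, 0.5)
  snp_rate <- stats::qlnorm(pnorm(z$snp), log(0.005), 0.5)
  n_orth <- stats::qbinom(pnorm(z$orthologs), 20L, 0.6)
  mutsig_expr <- stats::qlnorm(pnorm(z$mutsig_expr), 3, 1.2)
  mutsig_reptime <- stats::qunif(pnorm(z$mutsig_reptime), 100, 1000)
  mutsig_hic <- stats::qunif(pnorm(z$mutsig_hic), -50, 50)

  set.seed(stream_seed(config$seed, "expression"))
  expr_mat <- matrix(mean_expr, n, config$n_cell_lines) *
    exp(matrix(rnorm(n * config$n_cell_lines, 0, 0.1), n,
               config$n_cell_lines))
  # rescale rows so the cell-line mean reproduces the copula value exactly
  expr_mat <- expr_mat * (mean_expr / rowMeans(expr_mat))
  rownames(expr_mat) <- gene_ids
  colnames(expr_mat) <- sprintf("CL%02d", seq_len(config$n_cell_lines))

  set.seed(stream_seed(config$seed, "snps"))
  n_snps <- rpois(n, snp_rate * Biostrings::width(seqs))

  # toy genome layout: genes laid head-to-tail on one chromosome with 1 kb
  # gaps; most genes carry an internal probe with their exact replication
  # value, every tenth gene exercises the nearest-probe path instead
  w <- Biostrings::width(seqs)
  gap <- 1000L
  start <- cumsum(c(0L, head(w + gap, -1L)))
  gene_intervals <- data.table::data.table(
    gene_id = gene_ids, chrom = "chrS", start = start, end = start + w)
  probeless <- seq_len(n) %% 10L == 0L
  probes <- data.table::data.table(
    chrom = "chrS",
    pos = ifelse(probeless, start - 10L, start + w %/% 2L),
    value = reptime)
  probes <- probes[pos >= 0L]
  data.table::setorder(probes, chrom, pos)

  covariates <- data.table::data.table(
    gene_id = gene_ids,
    n_orthologs = as.integer(n_orth),
    n_unique_snps = as.integer(n_snps),
    chromatin_accessibility = chromatin,
    mutsig_expr = mutsig_expr,
    mutsig_hic = mutsig_hic,
    mutsig_reptime = mutsig_reptime)

  feats <- sequence_features(seqs, setNames(as.integer(n_orth), gene_ids))
  feats[, mean_expression := mean_expr]
  feats[, log_mean_expression := log10(mean_expr)]
  feats[, replication_time := reptime]
  feats[, chromatin_accessibility := chromatin]
  feats[, n_unique_snps := as.integer(n_snps)]
  feats[, snp_density := snp_density(n_unique_snps, cds_length)]
  feats[, mutsig_expr := mutsig_expr]
  feats[, mutsig_hic := mutsig_hic]
  feats[, mutsig_reptime := mutsig_reptime]

  list(seqs = seqs, features = feats, expression_matrix = expr_mat,
       covariates = covariates, gene_intervals = gene_intervals,
       probes = probes)
}

# Standardized direction weights defining the generating linear predictor
# per mutation type. The silent model is pure background; the other types
# lean on the observed silent count plus type-appropriate characteristics.
generating_directions <- function() {
  list(
    silent = c(n_potential_silent = 0.8, replication_time = 0.3,
               log_mean_expression = -0.3, pct_cpg = 0.2),
    missense = c(n_silent_observed = 0.9, n_potential_missense = 0.3,
                 replication_time = -0.15, pct_c = -0.1, nd = -0.1),
    nonsense = c(n_potential_nonsense = 0.8, n_silent_observed = 0.4,
                 pct_g = -0.15),
    fs = c(cds_length = 0.9, n_silent_observed = 0.3, nd = -0.15,
           pct_a = 0.15))
}

# Linear rate lambda = clip0(mean + s * standardized direction), with s set
# so that var(lambda) / (var(lambda) + mean) equals the target R^2 under
# Poisson noise. Returns lambda plus the implied raw-scale coefficients.
linear_rate <- function(features, weights, mean_count, target_r2) {
  x <- as.data.frame(features)[names(weights)]
  xs <- scale(as.matrix(x))
  combo <- as.vector(xs %*% weights)
  combo <- (combo - mean(combo)) / sd(combo)
  s <- sqrt(target_r2 / (1 - target_r2) * mean_count)
  lambda <- pmax(0, mean_count + s * combo)
  sd_x <- attr(xs, "scaled:scale")
  mean_x <- attr(xs, "scaled:center")
  w_unit <- weights / sd(as.vector(scale(as.matrix(x)) %*% weights))
  beta <- s * w_unit / sd_x
  intercept <- mean_count - sum(beta * mean_x)
  list(lambda = lambda, beta = beta, intercept = intercept)
}

#' Simulate per-gene mutation counts with injected drivers
#'
#' Background rates follow a linear model on the gene characteristics,
#' calibrated so the linear predictor carries the configured share of the
#' count variance (the target R-squared) around the configured mean count.
#' Silent counts are generated first — always without driver excess — and
#' then join the features as the observed silent-mutation predictor for
#' the other three types. Driver genes multiply their designated types'
#' rates by `1 + delta`, with `delta` chosen per gene so the injected
#' excess equals `driver_excess_sd` background residual standard
#' deviations. Counts are independent Poisson draws.
#'
#' @param characteristics Output of [generate_characteristics()].
#' @param config The `SimulationConfig`.
#' @return List: `counts` (`data.table` gene_id, n_missense, n_nonsense,
#'   n_fs, n_silent + densities), `features` (characteristics plus
#'   `n_silent_observed`), `truth` (`data.table` of per-gene lambdas,
#'   driver labels and injected deltas), `beta` (list of generating
#'   raw-scale coefficient vectors per type).
#' @export
simulate_counts <- function(characteristics, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  feats <- data.table::copy(characteristics$features)
  dirs <- generating_directions()
  mc <- config$mean_count; r2 <- config$target_r2

  sil <- linear_rate(feats, dirs$silent, mc[["silent"]], r2[["silent"]])
  set.seed(stream_seed(config$seed, "silent"))
  n_silent <- rpois(nrow(feats), sil$lambda)
  feats[, n_silent_observed := n_silent]

  lam <- list(silent = sil)
  for (tp in c("missense", "nonsense", "fs"))
    lam[[tp]] <- linear_rate(feats, dirs[[tp]], mc[[tp]], r2[[tp]])

  # driver injection: TS-like drivers get all three types, OG-like get
  # missense only; excess per type = driver_excess_sd * sqrt(mean count)
  n <- nrow(feats)
  is_driver <- rep(FALSE, n)
  driver_class <- rep("", n)
  delta <- matrix(0, n, 3L,
                  dimnames = list(NULL, c("missense", "nonsense", "fs")))
  if (config$n_drivers > 0L) {
    eligible <- which(lam$missense$lambda > 0 & lam$nonsense$lambda > 0 &
                        lam$fs$lambda > 0)
    set.seed(stream_seed(config$seed, "drivers"))
    chosen <- sample(eligible, config$n_drivers)
    cls <- rep(c("TS", "OG"), length.out = config$n_drivers)
    is_driver[chosen] <- TRUE
    driver_class[chosen] <- cls
    for (i in seq_along(chosen)) {
      g <- chosen[i]
      types <- if (cls[i] == "TS") c("missense", "nonsense", "fs")
               else "missense"
      for (tp in types)
        delta[g, tp] <- config$driver_excess_sd * sqrt(mc[[tp]]) /
          lam[[tp]]$lambda[g]
    }
  }

  draw_counts <- function(tp) {
    set.seed(stream_seed(config$seed, tp))
    rpois(n, lam[[tp]]$lambda * (1 + delta[, tp]))
  }
  counts <- data.table::data.table(
    gene_id = feats$gene_id,
    n_missense = draw_counts("missense"),
    n_nonsense = draw_counts("nonsense"),
    n_fs = draw_counts("fs"),
    n_silent = n_silent)
  len <- feats$cds_length
  counts[, `:=`(density_missense = n_missense / len,
                density_nonsense = n_nonsense / len,
                density_fs = n_fs / len,
                density_silent = n_silent / len)]

  truth <- data.table::data.table(
    gene_id = feats$gene_id,
    lambda_missense = lam$missense$lambda,
    lambda_nonsense = lam$nonsense$lambda,
    lambda_fs = lam$fs$lambda,
    lambda_silent = lam$silent$lambda,
    is_driver = is_driver,
    driver_class = driver_class,
    delta_missense = delta[, "missense"],
    delta_nonsense = delta[, "nonsense"],
    delta_fs = delta[, "fs"])

  beta <- lapply(lam, function(l)
    c("(Intercept)" = l$intercept, l$beta))
  list(counts = counts[], features = feats[], truth = truth[], beta = beta)
}

#' Simulate a complete synthetic cohort
#'
#' @param config A `SimulationConfig`.
#' @return A `SyntheticCohort` list: everything from
#'   [generate_characteristics()] plus `counts`, `features` (with observed
#'   silent counts), `truth`, `beta`, and the `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  ch <- generate_characteristics(config)
  sim <- simulate_counts(ch, config)
  structure(c(ch[c("seqs", "expression_matrix", "covariates",
                   "gene_intervals", "probes")],
              sim, list(config = config)),
            class = "SyntheticCohort")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Export a synthetic cohort as pipeline input files
#'
#' Writes exactly the formats the analysis pipeline reads: a CDS FASTA, a
#' record-level mutation TSV in the COSMIC-style column layout (counts
#' expanded to one row per mutation report, plus filter decoys that the
#' cohort filters must remove), the expression matrix, the covariate
#' table, gene intervals and the replication-timing probe track as BED,
#' and exclusion/annotation gene lists. Ground truth goes to
#' `truth_*.tsv` files that no pipeline stage reads; `manifest.json`
#' records the seed and a hash of the configuration.
#'
#' @param cohort A `SyntheticCohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  cfg <- cohort$config

  Biostrings::writeXStringSet(cohort$seqs, path("cds.fasta"))

  cn <- cohort$counts
  expand <- function(n_col, description) {
    idx <- rep.int(seq_len(nrow(cn)), cn[[n_col]])
    data.table::data.table(gene_id = cn$gene_id[idx],
                           description = description)
  }
  set.seed(stream_seed(cfg$seed, "decoys"))
  fs_idx <- rep.int(seq_len(nrow(cn)), cn$n_fs)
  fs_desc <- sample(c("Insertion - Frameshift", "Deletion - Frameshift"),
                    length(fs_idx), replace = TRUE)
  rec <- data.table::rbindlist(list(
    expand("n_missense", "Substitution - Missense"),
    expand("n_nonsense", "Substitution - Nonsense"),
    expand("n_silent", "Substitution - coding silent"),
    data.table::data.table(gene_id = cn$gene_id[fs_idx],
                           description = fs_desc)))
  rec[, snp := "n"][, screen := "y"]
  n_decoy <- ceiling(nrow(rec) * cfg$decoy_fraction)
  if (n_decoy > 0L) {
    d_idx <- sample.int(nrow(rec), n_decoy, replace = TRUE)
    decoys <- rec[d_idx]
    half <- seq_len(n_decoy) <= n_decoy / 2
    decoys[half, snp := "y"]
    decoys[!half, screen := "n"]
    rec <- data.table::rbindlist(list(rec, decoys))
  }
  rec[, sample_id := sprintf("S%04d",
                             seq_len(.N) %% 1000L + 1L)]
  out_rec <- data.table::data.table(
    "Gene name" = rec$gene_id, "ID_sample" = rec$sample_id,
    "Mutation Description" = rec$description, "SNP" = rec$snp,
    "Genome-wide screen" = rec$screen)
  data.table::fwrite(out_rec, path("mutations.tsv"), sep = "\t")

  expr <- data.table::data.table(gene_id = rownames(cohort$expression_matrix))
  expr <- cbind(expr, data.table::as.data.table(cohort$expression_matrix))
  data.table::fwrite(expr, path("expression.tsv"), sep = "\t")

  data.table::fwrite(cohort$covariates, path("covariates.tsv"), sep = "\t")
  data.table::fwrite(cohort$gene_intervals[, .(chrom, start, end, gene_id)],
                     path("genes.bed"), sep = "\t", col.names = FALSE)
  data.table::fwrite(cohort$probes[, .(chrom, pos, pos + 1L, value)],
                     path("reptime_probes.bed"), sep = "\t",
                     col.names = FALSE)

  writeLines(character(), path("exclude_fit.txt"))
  ts_genes <- cohort$truth[is_driver & driver_class == "TS", gene_id]
  og_genes <- cohort$truth[is_driver & driver_class == "OG", gene_id]
  writeLines(ts_genes, path("annotation_ts.txt"))
  writeLines(og_genes, path("annotation_og.txt"))

  data.table::fwrite(cohort$truth, path("truth_genes.tsv"), sep = "\t")
  beta_dt <- data.table::rbindlist(lapply(names(cohort$beta), function(tp)
    data.table::data.table(outcome = tp,
                           term = names(cohort$beta[[tp]]),
                           value = unname(cohort$beta[[tp]]))))
  data.table::fwrite(beta_dt, path("truth_beta.tsv"), sep = "\t")

  jsonlite::write_json(list(seed = cfg$seed, config_hash = config_hash(cfg),
                            n_genes = cfg$n_genes),
                       path("manifest.json"), auto_unbox = TRUE)
  files <- c(cds = path("cds.fasta"), mutations = path("mutations.tsv"),
             expression = path("expression.tsv"),
             covariates = path("covariates.tsv"),
             genes_bed = path("genes.bed"),
             probes_bed = path("reptime_probes.bed"),
             exclude_fit = path("exclude_fit.txt"),
             annotation_ts = path("annotation_ts.txt"),
             annotation_og = path("annotation_og.txt"),
             truth_genes = path("truth_genes.tsv"),
             truth_beta = path("truth_beta.tsv"),
             manifest = path("manifest.json"))
  invisible(files)
}
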