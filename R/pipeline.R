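# Orchestration: validated configuration and the end-to-end run
# (features -> counts -> four model fits -> outlier report -> summaries).

#' Pipeline configuration
#'
#' Validated bundle of input paths and analysis settings. Unknown keys are
#' rejected so typos never silently fall back to defaults.
#'
#' @param cds_fasta FASTA of coding sequences (one record per gene, or
#'   `gene|transcript` ids from which the largest transcript is kept).
#' @param mutations_tsv Record-level mutation TSV (COSMIC-style profile).
#' @param expression_tsv Gene-by-cell-line expression TSV (first column
#'   `gene_id`).
#' @param covariates_tsv Per-gene covariate TSV (`gene_id`, `n_orthologs`,
#'   `n_unique_snps`, `chromatin_accessibility`, `mutsig_expr`,
#'   `mutsig_hic`, `mutsig_reptime`).
#' @param genes_bed BED of gene intervals (chrom, start, end, gene_id).
#' @param probes_bed BED of replication-timing probes (chrom, start, end,
#'   value).
#' @param exclude_fit_txt Optional gene list (one id per line) withheld
#'   from model fitting but still scored.
#' @param annotation_ts_txt,annotation_og_txt Optional tumor-suppressor /
#'   oncogene lists for the group Z-score summary.
#' @param out_dir Output directory.
#' @param alpha Family-wise error level for the outlier cutoff.
#' @param p_enter,p_remove Stepwise thresholds.
#' @param silent_as Silent-mutation predictor scale, `"count"` or
#'   `"density"`.
#' @param log_pseudocount Pseudocount for log expression.
#' @param seed Integer seed stamped on outputs (the pipeline itself is
#'   deterministic).
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(cds_fasta, mutations_tsv, expression_tsv,
                            covariates_tsv, genes_bed, probes_bed,
                            exclude_fit_txt = NULL,
                            annotation_ts_txt = NULL,
                            annotation_og_txt = NULL,
                            out_dir = "mutburden_out",
                            alpha = 0.05, p_enter = 0.05, p_remove = 0.10,
                            silent_as = c("count", "density"),
                            log_pseudocount = 0, seed = 1L) {
  silent_as <- match.arg(silent_as)
  stopifnot(alpha > 0, alpha < 1, p_enter < p_remove)
  structure(list(cds_fasta = cds_fasta, mutations_tsv = mutations_tsv,
                 expression_tsv = expression_tsv,
                 covariates_tsv = covariates_tsv, genes_bed = genes_bed,
                 probes_bed = probes_bed,
                 exclude_fit_txt = exclude_fit_txt,
                 annotation_ts_txt = annotation_ts_txt,
                 annotation_og_txt = annotation_og_txt,
                 out_dir = out_dir, alpha = alpha, p_enter = p_enter,
                 p_remove = p_remove, silent_as = silent_as,
                 log_pseudocount = log_pseudocount,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Build a pipeline configuration from an exported cohort directory
#'
#' Convenience wrapper mapping the file names written by [export_cohort()]
#' to a [pipeline_config()].
#'
#' @param dir Directory written by [export_cohort()].
#' @param out_dir Output directory (default `file.path(dir, "out")`).
#' @param ... Further arguments passed to [pipeline_config()].
#' @export
pipeline_config_from_dir <- function(dir, out_dir = file.path(dir, "out"),
                                     ...) {
  p <- function(f) file.path(dir, f)
  pipeline_config(cds_fasta = p("cds.fasta"),
                  mutations_tsv = p("mutations.tsv"),
                  expression_tsv = p("expression.tsv"),
                  covariates_tsv = p("covariates.tsv"),
                  genes_bed = p("genes.bed"),
                  probes_bed = p("reptime_probes.bed"),
                  exclude_fit_txt = p("exclude_fit.txt"),
                  annotation_ts_txt = p("annotation_ts.txt"),
                  annotation_og_txt = p("annotation_og.txt"),
                  out_dir = out_dir, ...)
}

#' Validate pipeline inputs without computing anything
#'
#' Checks that every configured file exists, that mapped columns are
#' present, and that the gene-id namespaces of the FASTA and the mutation
#' table overlap. Never modifies inputs.
#'
#' @param config A `PipelineConfig`.
#' @param min_overlap Minimum required number of shared gene ids between
#'   FASTA and mutation table.
#' @return Character vector of failure messages (empty when valid).
#' @export
validate_inputs <- function(config, min_overlap = 1L) {
  stopifnot(inherits(config, "PipelineConfig"))
  fail <- character()
  paths <- c(cds_fasta = config$cds_fasta,
             mutations_tsv = config$mutations_tsv,
             expression_tsv = config$expression_tsv,
             covariates_tsv = config$covariates_tsv,
             genes_bed = config$genes_bed, probes_bed = config$probes_bed)
  opt <- c(exclude_fit_txt = config$exclude_fit_txt,
           annotation_ts_txt = config$annotation_ts_txt,
           annotation_og_txt = config$annotation_og_txt)
  paths <- c(paths, opt)
  missing_files <- paths[!file.exists(paths)]
  for (nm in names(missing_files))
    fail <- c(fail, paste0("missing file (", nm, "): ", missing_files[nm]))
  if (length(fail)) return(fail)

  mut_head <- data.table::fread(config$mutations_tsv, nrows = 0L)
  need <- unname(cosmic_profile()$columns)
  miss <- setdiff(need, names(mut_head))
  for (m in miss)
    fail <- c(fail, paste0("mutation table missing column: ", m))

  cov_head <- data.table::fread(config$covariates_tsv, nrows = 0L)
  cov_need <- c("gene_id", "n_orthologs", "n_unique_snps",
                "chromatin_accessibility", "mutsig_expr", "mutsig_hic",
                "mutsig_reptime")
  for (m in setdiff(cov_need, names(cov_head)))
    fail <- c(fail, paste0("covariate table missing column: ", m))

  if (!length(fail)) {
    fasta_genes <- names(read_cds_fasta(config$cds_fasta))
    mut <- data.table::fread(config$mutations_tsv,
                             select = cosmic_profile()$columns[["gene"]])
    overlap <- length(intersect(fasta_genes, mut[[1L]]))
    if (overlap < min_overlap)
      fail <- c(fail, sprintf(
        "gene-id overlap between FASTA and mutation table is %d (< %d)",
        overlap, min_overlap))
  }
  fail
}

read_gene_list <- function(path) {
  if (is.null(path) || !file.exists(path)) return(character())
  x <- readLines(path, warn = FALSE)
  x[nzchar(x)]
}

#' Run the full background-mutability analysis
#'
#' Executes the whole pipeline: sequence features from the FASTA; mutation
#' filtering and per-gene counting; covariate assembly into a
#' complete-case feature matrix; stepwise model fits for missense,
#' nonsense, frameshift and the pan-mutation sum; residual Z-scores with
#' the multiplicity-corrected cutoff; the outlier report; and (when
#' annotation lists are configured) the TS/OG group Z summary. All outputs
#' are written under `config$out_dir` and stamped with a configuration
#' hash; reruns on identical inputs produce byte-identical files.
#'
#' @param config A `PipelineConfig`.
#' @return Invisibly, a list with `features` (assembly result), `counts`,
#'   `models`, `comparison` (pan vs specific R^2 table), `outliers`,
#'   `cutoff`, `group_summary` (or `NULL`), `paths` of written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  fails <- validate_inputs(config)
  if (length(fails))
    stop("invalid pipeline inputs:\n  ", paste(fails, collapse = "\n  "))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  # stage: sequence features
  seqs <- read_cds_fasta(config$cds_fasta)
  cov <- data.table::fread(config$covariates_tsv)
  seq_feat <- sequence_features(
    seqs, setNames(as.integer(cov$n_orthologs), cov$gene_id))

  # stage: mutation counts
  records <- read_mutation_tsv(config$mutations_tsv)
  filtered <- filter_records(records)
  message(sprintf("mutation filter: %d in, %d retained, %d removed",
                  nrow(records), nrow(filtered),
                  attr(filtered, "n_dropped_filter")))
  cds_len <- setNames(seq_feat$cds_length, seq_feat$gene_id)
  counts <- count_by_gene(filtered, cds_len)

  # stage: covariate assembly
  expr_raw <- data.table::fread(config$expression_tsv)
  expr_mat <- as.matrix(expr_raw[, -1L])
  rownames(expr_mat) <- expr_raw[[1L]]
  expression <- aggregate_expression(expr_mat,
                                     pseudocount = config$log_pseudocount)
  genes_bed <- data.table::fread(
    config$genes_bed, col.names = c("chrom", "start", "end", "gene_id"))
  probes_bed <- data.table::fread(
    config$probes_bed, col.names = c("chrom", "start", "end", "value"))
  reptime <- assign_track_to_genes(
    data.table::data.table(chrom = probes_bed$chrom, pos = probes_bed$start,
                           value = probes_bed$value),
    genes_bed)
  asm <- assemble_features(
    seq_feat, expression, cov, reptime,
    setNames(counts$n_silent, counts$gene_id),
    exclude_fit = read_gene_list(config$exclude_fit_txt))
  scoring <- merge(asm$scoring,
                   counts[, .(gene_id, density_silent)], by = "gene_id")
  fit_rows <- scoring$gene_id %in% asm$fit_genes

  # stage: models (three type-specific + pan) on the fitting rows
  cnt <- counts[match(scoring$gene_id, gene_id)]
  cmp <- compare_pan_vs_specific(scoring[fit_rows], cnt[fit_rows],
                                 p_enter = config$p_enter,
                                 p_remove = config$p_remove)
  models <- cmp$models

  # stage: outliers over the full scoring matrix
  obs <- list(missense = cnt$n_missense, nonsense = cnt$n_nonsense,
              frameshift = cnt$n_fs)
  z <- lapply(names(obs), function(tp)
    residual_zscores(obs[[tp]],
                     predict_expected(models[[tp]], scoring),
                     models[[tp]]$residual_sd))
  names(z) <- names(obs)
  n_tests <- nrow(scoring)
  cutoff <- significance_cutoff(config$alpha, n_tests)
  z_table <- data.table::data.table(gene_id = scoring$gene_id,
                                    z_missense = z$missense,
                                    z_nonsense = z$nonsense,
                                    z_fs = z$frameshift)
  report <- call_outliers(z_table, cutoff, config$alpha, n_tests)

  ts <- read_gene_list(config$annotation_ts_txt)
  og <- read_gene_list(config$annotation_og_txt)
  group_summary <- NULL
  if (length(ts) || length(og)) {
    ann <- c(setNames(rep("TS", length(ts)), ts),
             setNames(rep("OG", length(og)), og))
    group_summary <- group_zscore_summary(z_table, ann)
  }

  # outputs
  paths <- character()
  wr <- function(dt, f) {
    data.table::fwrite(dt, out(f), sep = "\t")
    paths[[f]] <<- out(f)
  }
  wr(scoring, "feature_matrix.tsv")
  wr(asm$drop_log, "drop_log.tsv")
  wr(counts, "gene_counts.tsv")
  for (tp in names(models)) {
    wr(models[[tp]]$table, paste0("model_", tp, ".tsv"))
    write_model_json(models[[tp]], out(paste0("model_", tp, ".json")))
    paths[[paste0("model_", tp, ".json")]] <- out(paste0("model_", tp,
                                                         ".json"))
  }
  wr(cmp$comparison, "r2_comparison.tsv")
  wr(data.table::as.data.table(report), "outliers.tsv")
  if (!is.null(group_summary)) wr(group_summary, "group_zscores.tsv")
  jsonlite::write_json(
    list(config_hash = config_hash_pipeline(config), seed = config$seed,
         n_genes_scored = n_tests, n_genes_fit = sum(fit_rows),
         cutoff = cutoff, alpha = config$alpha),
    out("run_manifest.json"), auto_unbox = TRUE, digits = NA)
  paths[["run_manifest.json"]] <- out("run_manifest.json")

  invisible(list(features = asm, scoring = scoring, counts = counts,
                 models = models, comparison = cmp$comparison,
                 outliers = report, cutoff = cutoff,
                 group_summary = group_summary, paths = paths))
}

config_hash_pipeline <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}
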