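# Joining external per-gene tracks with sequence features into one
# complete-case feature matrix.

#' Assign a probe track to gene intervals
#'
#' Replication-timing (or any positional) probes are averaged over each gene
#' interval; a gene containing no probe receives the value of the nearest
#' probe, measured from the probe position to the closer interval edge, with
#' exact distance ties broken toward the lower coordinate. Intervals are
#' 0-based half-open, BED convention.
#'
#' @param probes `data.frame`/`data.table` with columns `chrom`, `pos`
#'   (0-based), `value`.
#' @param genes `data.frame`/`data.table` with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return Named numeric vector of per-gene values.
#' @export
assign_track_to_genes <- function(probes, genes) {
  probes <- data.table::as.data.table(probes)
  genes <- data.table::as.data.table(genes)
  stopifnot(all(c("chrom", "pos", "value") %in% names(probes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(genes$end > genes$start))
  miss <- setdiff(unique(genes$chrom), unique(probes$chrom))
  if (length(miss)) {
    bad <- genes$gene_id[genes$chrom %in% miss]
    stop("no probes on chromosome(s) ", paste(miss, collapse = ", "),
         " needed by gene(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  data.table::setorder(probes, chrom, pos)
  out <- rep(NA_real_, nrow(genes))
  names(out) <- genes$gene_id
  for (ch in unique(genes$chrom)) {
    p <- probes[chrom == ch]
    g <- genes[chrom == ch]
    for (i in seq_len(nrow(g))) {
      inside <- p$pos >= g$start[i] & p$pos < g$end[i]
      if (any(inside)) {
        out[g$gene_id[i]] <- mean(p$value[inside])
      } else {
        # distance from each probe to the closer interval edge; ties go to
        # the probe at the lower coordinate (p is sorted by pos)
        d <- pmax(g$start[i] - p$pos, p$pos - (g$end[i] - 1L), 0L)
        out[g$gene_id[i]] <- p$value[which.min(d)]
      }
    }
  }
  out
}

#' Average expression across cell lines
#'
#' Row means of a gene-by-cell-line expression matrix plus their log10
#' transform. The log uses a configurable pseudocount, 0 by default; genes
#' whose mean is not positive under pseudocount 0 get `NA` log values and
#' are later dropped as incomplete. Genes with no observed value in any
#' cell line are excluded.
#'
#' @param mat Numeric matrix or data.frame, rows = genes (rownames = gene
#'   ids), columns = cell lines; `NA`s allowed.
#' @param pseudocount Added to the mean before log10.
#' @return `data.table` with `gene_id`, `mean_expression`,
#'   `log_mean_expression`.
#' @export
aggregate_expression <- function(mat, pseudocount = 0) {
  mat <- as.matrix(mat)
  stopifnot(!is.null(rownames(mat)), ncol(mat) >= 1L)
  n_obs <- rowSums(!is.na(mat))
  if (any(n_obs == 0L))
    message(sum(n_obs == 0L), " gene(s) with no expression values excluded")
  keep <- n_obs > 0L
  m <- rowMeans(mat[keep, , drop = FALSE], na.rm = TRUE)
  lm_ <- ifelse(m + pseudocount > 0, log10(m + pseudocount), NA_real_)
  data.table::data.table(gene_id = rownames(mat)[keep],
                         mean_expression = unname(m),
                         log_mean_expression = unname(lm_))
}

#' Germline SNP density of a coding region
#'
#' Unique SNPs per nucleotide of coding sequence.
#'
#' @param n_unique_snps Non-negative integer vector.
#' @param cds_length Positive integer vector (nt).
#' @return Numeric vector of densities per nt.
#' @export
snp_density <- function(n_unique_snps, cds_length) {
  if (any(n_unique_snps < 0)) stop("negative SNP count")
  if (any(cds_length <= 0)) stop("cds_length must be positive")
  n_unique_snps / cds_length
}

#' Assemble the per-gene feature matrix
#'
#' Inner-joins all per-gene sources on gene id, drops genes with any missing
#' value (with a per-reason drop log), and applies the configured exclusion
#' lists. Excluded genes are removed from the *fitting* matrix only: they
#' remain in the scoring matrix so that genes like TP53 are still scored for
#' outlier excess even though they are withheld from model estimation.
#'
#' @param seq_features Sequence feature table from [sequence_features()]
#'   (must include `conservation_index`).
#' @param expression Output of [aggregate_expression()].
#' @param covariates `data.table` with `gene_id`, `n_unique_snps`,
#'   `chromatin_accessibility`, `mutsig_expr`, `mutsig_hic`,
#'   `mutsig_reptime`.
#' @param replication_time Named numeric vector (from
#'   [assign_track_to_genes()]).
#' @param n_silent Named integer vector of observed silent-mutation counts
#'   per gene (from [count_by_gene()]).
#' @param exclude_fit Character vector of gene ids to withhold from fitting
#'   (e.g. olfactory receptors and known extreme outliers).
#' @return List with `scoring` (complete-case feature `data.table`),
#'   `fit_genes` (character vector, subset of `scoring$gene_id`), and
#'   `drop_log` (`data.table` gene_id, reason).
#' @export
assemble_features <- function(seq_features, expression, covariates,
                              replication_time, n_silent,
                              exclude_fit = character()) {
  sf <- data.table::as.data.table(seq_features)
  ex <- data.table::as.data.table(expression)
  cv <- data.table::as.data.table(covariates)
  stopifnot("conservation_index" %in% names(sf))
  drop <- list()
  note_drops <- function(ids, reason) {
    if (length(ids))
      drop[[length(drop) + 1L]] <<-
        data.table::data.table(gene_id = ids, reason = reason)
  }

  common <- Reduce(intersect, list(sf$gene_id, ex$gene_id, cv$gene_id,
                                   names(replication_time),
                                   names(n_silent)))
  if (length(common) == 0L) stop("no genes shared by all feature sources")
  note_drops(setdiff(sf$gene_id, common), "absent_from_some_source")

  m <- sf[gene_id %in% common]
  m <- merge(m, ex, by = "gene_id")
  m <- merge(m, cv, by = "gene_id")
  m[, replication_time := replication_time[gene_id]]
  m[, n_silent_observed := as.integer(n_silent[gene_id])]
  m[, snp_density := snp_density(n_unique_snps, cds_length)]

  complete <- stats::complete.cases(m)
  note_drops(m$gene_id[!complete], "missing_value")
  m <- m[complete]

  fit_genes <- setdiff(m$gene_id, exclude_fit)
  drop_log <- if (length(drop)) data.table::rbindlist(drop)
              else data.table::data.table(gene_id = character(),
                                          reason = character())
  list(scoring = m[], fit_genes = fit_genes, drop_log = drop_log)
}

#' Pairwise Spearman correlations with significance
#'
#' Spearman's rank correlation for every pair of feature columns, with
#' two-sided p-values from [stats::cor.test()] (t approximation under
#' ties). Constant columns give `NA` correlations for their pairs and are
#' flagged with a warning.
#'
#' @param features Feature `data.table`/data.frame.
#' @param columns Character vector of numeric columns to correlate.
#' @return List with matrices `rho` and `p` (diagonal 1 and 0).
#' @export
pairwise_spearman <- function(features, columns) {
  stopifnot(all(columns %in% names(features)), nrow(features) >= 3L)
  x <- as.data.frame(features)[columns]
  const <- vapply(x, function(v) length(unique(v)) == 1L, logical(1L))
  if (any(const))
    warning("constant column(s): ", paste(columns[const], collapse = ", "))
  k <- length(columns)
  rho <- diag(1, k); p <- matrix(0, k, k)
  dimnames(rho) <- dimnames(p) <- list(columns, columns)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (const[i] || const[j]) {
      rho[i, j] <- rho[j, i] <- NA_real_
      p[i, j] <- p[j, i] <- NA_real_
    } else {
      ct <- suppressWarnings(
        cor.test(x[[i]], x[[j]], method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}
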