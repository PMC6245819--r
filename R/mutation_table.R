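# Ingestion and tabulation of somatic mutation records.

MUT_CLASSES <- c("missense", "nonsense", "silent",
                 "frameshift_ins", "frameshift_del", "other")

# Built-in column profile for a COSMIC-style mutation export. `class_map`
# maps lowercase mutation-description patterns to internal classes;
# descriptions that match nothing become "other" (in-frame indels included).
cosmic_profile <- function() {
  list(
    columns = c(gene = "Gene name", sample = "ID_sample",
                description = "Mutation Description", snp = "SNP",
                screen = "Genome-wide screen"),
    class_patterns = c(
      "missense"                              = "missense",
      "nonsense"                              = "nonsense",
      "coding silent|synonymous"              = "silent",
      "insertion - frameshift"                = "frameshift_ins",
      "deletion - frameshift"                 = "frameshift_del"),
    true_values = c("y", "yes", "true", "1")
  )
}

classify_description <- function(description, profile = cosmic_profile()) {
  desc <- tolower(description)
  out <- rep("other", length(desc))
  for (pat in names(profile$class_patterns)) {
    hit <- grepl(pat, desc) & out == "other"
    out[hit] <- profile$class_patterns[[pat]]
  }
  out
}

#' Read a somatic mutation table
#'
#' Reads a TSV of somatic mutation reports and maps it to the internal
#' record schema: gene, sample, mutation class, reported-SNP flag and
#' genome-wide-screen flag. The column mapping and the description-to-class
#' patterns are profile-driven, with a built-in COSMIC-export profile.
#' Duplicate rows are kept: the analysis counts mutation reports, not unique
#' alleles. The reader is gzip-transparent.
#'
#' @param path TSV (optionally .gz) of mutation reports.
#' @param profile Column/classification profile, see [cosmic_profile()].
#' @return `data.table` with columns `gene_id`, `sample_id`, `mut_class`,
#'   `is_reported_snp`, `genome_wide_screen`.
#' @export
read_mutation_tsv <- function(path, profile = cosmic_profile()) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  need <- unname(profile$columns)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("mutation table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  flag <- function(x) tolower(x) %in% profile$true_values
  data.table::data.table(
    gene_id = raw[[profile$columns[["gene"]]]],
    sample_id = raw[[profile$columns[["sample"]]]],
    mut_class = classify_description(raw[[profile$columns[["description"]]]],
                                     profile),
    is_reported_snp = flag(raw[[profile$columns[["snp"]]]]),
    genome_wide_screen = flag(raw[[profile$columns[["screen"]]]]))
}

#' Apply the cohort inclusion filters to mutation records
#'
#' Keeps only mutations detected by genome-wide screens, and drops mutations
#' reported as germline SNPs. Order-preserving.
#'
#' @param records `data.table` of mutation records as from
#'   [read_mutation_tsv()].
#' @return Filtered `data.table` (copy), with attribute `n_dropped_filter`
#'   giving the number of removed records.
#' @export
filter_records <- function(records) {
  stopifnot(all(c("genome_wide_screen", "is_reported_snp") %in%
                  names(records)))
  keep <- records$genome_wide_screen & !records$is_reported_snp
  out <- records[keep, ]
  data.table::setattr(out, "n_dropped_filter", sum(!keep))
  out
}

#' Tabulate mutation counts and densities per gene
#'
#' Counts missense, nonsense, frameshift (insertion + deletion) and silent
#' mutations per gene over a set of known genes, and derives per-nucleotide
#' densities against each gene's CDS length. Genes without records get
#' all-zero rows; records for genes outside the known set are dropped and
#' their number recorded.
#'
#' @param records Filtered mutation records.
#' @param cds_length Named integer vector of CDS lengths (names = gene ids)
#'   defining the gene universe.
#' @return `data.table` keyed by `gene_id` with `n_missense`, `n_nonsense`,
#'   `n_fs`, `n_silent` and per-nt densities `density_missense`,
#'   `density_nonsense`, `density_fs`, `density_silent`; attribute
#'   `n_dropped_unknown_gene` records dropped records.
#' @export
count_by_gene <- function(records, cds_length) {
  stopifnot(!is.null(names(cds_length)), all(cds_length > 0))
  genes <- names(cds_length)
  known <- records$gene_id %in% genes
  n_unknown <- sum(!known)
  if (n_unknown > 0)
    message(n_unknown, " record(s) for unknown genes dropped")
  rec <- records[known, ]
  tab <- function(classes) {
    t <- table(factor(rec$gene_id[rec$mut_class %in% classes],
                      levels = genes))
    as.integer(t)
  }
  out <- data.table::data.table(
    gene_id = genes,
    n_missense = tab("missense"),
    n_nonsense = tab("nonsense"),
    n_fs = tab(c("frameshift_ins", "frameshift_del")),
    n_silent = tab("silent"))
  len <- as.numeric(cds_length[out$gene_id])
  out[, `:=`(density_missense = n_missense / len,
             density_nonsense = n_nonsense / len,
             density_fs = n_fs / len,
             density_silent = n_silent / len)]
  data.table::setkey(out, gene_id)
  data.table::setattr(out, "n_dropped_unknown_gene", n_unknown)
  out[]
}

#' Mean mutation density per gene group
#'
#' Arithmetic mean and standard error of per-gene mutation densities within
#' annotated gene groups, reported per kilobase (the field's customary
#' unit). This is the summary behind statements like "the density of
#' missense mutations in olfactory receptors is twice that of other genes".
#'
#' @param counts Count table from [count_by_gene()].
#' @param group_labels Named character vector mapping gene ids to group
#'   labels; genes absent from the map are ignored.
#' @param mut_type One of `"missense"`, `"nonsense"`, `"fs"`, `"silent"`.
#' @return `data.table` with `group`, `n_genes`, `mean_per_kb`,
#'   `sem_per_kb` (`NA` with a warning for singleton groups).
#' @export
group_density_summary <- function(counts, group_labels,
                                  mut_type = c("missense", "nonsense", "fs",
                                               "silent")) {
  mut_type <- match.arg(mut_type)
  col <- paste0("density_", mut_type)
  dt <- counts[gene_id %in% names(group_labels), ]
  dt[, group := group_labels[gene_id]]
  res <- dt[, {
    d <- .SD[[col]] * 1000
    if (.N < 2L) {
      warning("group of size < 2: SEM undefined", call. = FALSE)
      list(n_genes = .N, mean_per_kb = mean(d), sem_per_kb = NA_real_)
    } else {
      list(n_genes = .N, mean_per_kb = mean(d),
           sem_per_kb = sd(d) / sqrt(.N))
    }
  }, by = group]
  data.table::setorder(res, group)
  res[]
}
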