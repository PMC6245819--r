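#' @importFrom stats coef lm pnorm qnorm sd t.test cor.test reformulate
#'   rnorm rpois runif setNames
#' @importFrom utils head
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# 64 codons in the fixed order Biostrings uses (A,C,G,T fastest-varying last)
all_codons <- function() {
  b <- BASES
  as.vector(vapply(b, function(x)
    vapply(b, function(y) paste0(x, y, b), character(4L)),
    matrix(character(), 4L, 4L)))
}

#' Translate a codon under the standard nuclear genetic code
#'
#' @param codon Character vector of DNA 3-mers.
#' @return Character vector of single-letter amino acids, `"*"` for stop.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- !codon %in% names(Biostrings::GENETIC_CODE)
  if (any(bad))
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "))
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Construct a coding sequence record
#'
#' A `CodingSequence` is a gene identifier plus its coding nucleotide
#' sequence. The sequence is uppercased on ingestion; length must be a
#' positive multiple of 3 and only A/C/G/T are admitted (ambiguity codes are
#' a hard error so that downstream feature values are never computed from
#' partial sequence).
#'
#' @param gene_id Single gene identifier string.
#' @param sequence DNA string over A/C/G/T.
#' @return An object of class `CodingSequence` with fields `gene_id`,
#'   `sequence`, `length_nt`.
#' @export
coding_sequence <- function(gene_id, sequence) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3L || n %% 3L != 0L)
    stop("coding sequence length must be a multiple of 3 and >= 3, got ", n,
         " for ", gene_id)
  if (grepl("[^ACGT]", sequence))
    stop("non-ACGT character in coding sequence of ", gene_id)
  structure(list(gene_id = gene_id, sequence = sequence, length_nt = n),
            class = "CodingSequence")
}

#' @export
print.CodingSequence <- function(x, ...) {
  cat(sprintf("<CodingSequence> %s: %d nt (%d codons)\n",
              x$gene_id, x$length_nt, x$length_nt %/% 3L))
  invisible(x)
}

#' Classify one single-nucleotide substitution
#'
#' Every possible coding change produced by a single-nucleotide substitution
#' (SNS) falls into one of four classes under the standard nuclear code:
#' silent (amino acid unchanged, including stop retained), missense,
#' nonsense (sense codon to stop), or stop-loss (stop codon to sense).
#'
#' @param ref_codon Reference DNA 3-mer.
#' @param within_codon_pos 0-based position (0, 1 or 2) of the substituted
#'   base within the codon.
#' @param alt_base Substituting nucleotide; must differ from the reference
#'   base at that position.
#' @param codon_index Optional 0-based codon index carried through to the
#'   result.
#' @return A list of class `SubstitutionOutcome` with `class` (one of
#'   `"silent"`, `"missense"`, `"nonsense"`, `"stop_loss"`), `ref_codon`,
#'   `alt_codon`, `codon_index`, `within_codon_pos`.
#' @examples
#' classify_substitution("CGG", 1, "A")  # Arg -> Gln, missense
#' classify_substitution("TGG", 1, "A")  # Trp -> stop, nonsense
#' @export
classify_substitution <- function(ref_codon, within_codon_pos, alt_base,
                                  codon_index = 0L) {
  ref_codon <- toupper(ref_codon)
  alt_base <- toupper(alt_base)
  if (!ref_codon %in% names(Biostrings::GENETIC_CODE))
    stop("invalid reference codon: ", ref_codon)
  if (!within_codon_pos %in% 0:2)
    stop("within_codon_pos must be 0, 1 or 2")
  if (!alt_base %in% BASES)
    stop("invalid alternate base: ", alt_base)
  ref_base <- substr(ref_codon, within_codon_pos + 1L, within_codon_pos + 1L)
  if (alt_base == ref_base)
    stop("alternate base equals the reference base (", ref_base, ")")
  alt_codon <- ref_codon
  substr(alt_codon, within_codon_pos + 1L, within_codon_pos + 1L) <- alt_base
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  cls <-
    if (aa_ref == aa_alt) "silent"
    else if (aa_ref != "*" && aa_alt == "*") "nonsense"
    else if (aa_ref == "*" && aa_alt != "*") "stop_loss"
    else "missense"
  structure(list(class = cls, ref_codon = ref_codon, alt_codon = alt_codon,
                 codon_index = as.integer(codon_index),
                 within_codon_pos = as.integer(within_codon_pos)),
            class = "SubstitutionOutcome")
}

# Per-codon tallies of SNS outcomes: a 64 x 4 matrix (rows = codons in
# all_codons() order, columns silent/missense/nonsense/stop_loss), each row
# summing to 9. Computed once at load time by exhaustive enumeration.
codon_sns_matrix <- local({
  m <- NULL
  function() {
    if (!is.null(m)) return(m)
    codons <- all_codons()
    out <- matrix(0L, length(codons), 4L,
                  dimnames = list(codons,
                                  c("silent", "missense", "nonsense",
                                    "stop_loss")))
    for (cod in codons) {
      for (pos in 0:2) {
        ref_base <- substr(cod, pos + 1L, pos + 1L)
        for (alt in setdiff(BASES, ref_base)) {
          cls <- classify_substitution(cod, pos, alt)$class
          out[cod, cls] <- out[cod, cls] + 1L
        }
      }
    }
    m <<- out
    m
  }
})

#' Count potential mutation sites in a coding sequence
#'
#' Enumerates all 3N possible single-nucleotide substitutions of an N-nt
#' coding sequence and tallies them by outcome class. The four class counts
#' partition 3N exactly; stop-loss changes (stop codon to sense codon) are
#' kept as their own class and are not folded into the three
#' substitution-type predictors.
#'
#' @param cds A `CodingSequence` (or a plain DNA string, which is wrapped).
#' @return A list of class `PotentialSiteCounts` with `n_total_sns`,
#'   `n_missense`, `n_nonsense`, `n_silent`, `n_stop_loss`.
#' @export
count_potential_sites <- function(cds) {
  if (is.character(cds)) cds <- coding_sequence("cds", cds)
  stopifnot(inherits(cds, "CodingSequence"))
  counts <- potential_site_matrix(Biostrings::DNAStringSet(cds$sequence))
  structure(list(n_total_sns = 3L * cds$length_nt,
                 n_missense = unname(counts[1L, "missense"]),
                 n_nonsense = unname(counts[1L, "nonsense"]),
                 n_silent = unname(counts[1L, "silent"]),
                 n_stop_loss = unname(counts[1L, "stop_loss"])),
            class = "PotentialSiteCounts")
}

# Vectorized potential-site counting over a DNAStringSet: in-frame codon
# usage (trinucleotideFrequency at step 3) times the per-codon outcome
# tallies. Returns an integer matrix genes x 4.
potential_site_matrix <- function(seqs) {
  stopifnot(methods::is(seqs, "DNAStringSet"))
  codon_use <- Biostrings::trinucleotideFrequency(seqs, step = 3)
  m <- codon_sns_matrix()
  res <- codon_use[, rownames(m), drop = FALSE] %*% m
  storage.mode(res) <- "integer"
  rownames(res) <- names(seqs)
  res
}

#' Codons capable of producing a nonsense mutation
#'
#' Returns every codon from which at least one single-base substitution
#' yields a stop codon (TAA, TAG or TGA). The membership criterion is that
#' the *resulting* codon is a stop codon, so stop codons that can mutate to
#' a different stop codon are themselves members; under the standard code
#' this yields 21 of the 64 codons.
#'
#' @return Character vector of codons, sorted.
#' @export
nonsense_capable_codons <- function() {
  codons <- all_codons()
  capable <- vapply(codons, function(cod) {
    for (pos in 0:2) {
      ref_base <- substr(cod, pos + 1L, pos + 1L)
      for (alt in setdiff(BASES, ref_base)) {
        alt_codon <- cod
        substr(alt_codon, pos + 1L, pos + 1L) <- alt
        if (alt_codon %in% STOP_CODONS) return(TRUE)
      }
    }
    FALSE
  }, logical(1L))
  sort(codons[capable])
}

#' Sequence-composition statistics
#'
#' Base fractions, CpG-dinucleotide fraction and nucleotide diversity of a
#' coding sequence. Nucleotide diversity is the probability that two bases
#' drawn at random from the sequence differ:
#' `nd = 1 - (pA^2 + pC^2 + pG^2 + pT^2)`; it is 0 for a homopolymer and at
#' most 0.75 (equal base usage). The CpG fraction is the number of CG
#' dinucleotides at consecutive positions divided by the sequence length N.
#'
#' @param cds A `CodingSequence` or plain DNA string (need not be a multiple
#'   of 3 for this statistic alone).
#' @return A list of class `CompositionStats` with `p_a`, `p_c`, `p_g`,
#'   `p_t`, `cpg_fraction`, `nd`.
#' @export
composition_stats <- function(cds) {
  seq <- if (inherits(cds, "CodingSequence")) cds$sequence
         else toupper(as.character(cds))
  if (nchar(seq) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", seq)) stop("non-ACGT character in sequence")
  x <- Biostrings::DNAString(seq)
  n <- nchar(seq)
  cnt <- Biostrings::letterFrequency(x, BASES)
  p <- as.numeric(cnt) / n
  names(p) <- BASES
  cpg <- Biostrings::countPattern("CG", x) / n
  nd <- 1 - sum(p^2)
  structure(list(p_a = p[["A"]], p_c = p[["C"]], p_g = p[["G"]],
                 p_t = p[["T"]], cpg_fraction = cpg, nd = nd),
            class = "CompositionStats")
}

#' Conservation index from an ortholog count
#'
#' Bins the number of orthologs detected across the 20 reference species:
#' 0 or 1 orthologs give index 1, 2 or 3 give index 2, and so on
#' (`floor(n/2) + 1`).
#'
#' @param n_orthologs Non-negative integer vector (0..20).
#' @return Integer vector of conservation indices.
#' @export
conservation_index <- function(n_orthologs) {
  if (any(is.na(n_orthologs)) || any(n_orthologs < 0))
    stop("n_orthologs must be non-negative")
  if (any(n_orthologs != floor(n_orthologs)))
    stop("n_orthologs must be integer-valued")
  as.integer(n_orthologs %/% 2L + 1L)
}

#' Read coding sequences from FASTA, keeping the largest transcript per gene
#'
#' Record ids of the form `"geneId|transcriptId"` (delimiter configurable)
#' are split into gene and transcript; plain ids are taken as gene ids. When
#' a gene has several transcripts the longest is kept; exact length ties are
#' broken by the lexicographically smallest record id.
#'
#' @param path FASTA file of coding sequences.
#' @param id_delim Delimiter between gene and transcript id in record names.
#' @return A named `DNAStringSet`, one record per gene, names = gene ids.
#' @export
read_cds_fasta <- function(path, id_delim = "|") {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in ", path)
  ids <- names(seqs)
  gene <- vapply(strsplit(ids, id_delim, fixed = TRUE), `[[`, character(1L), 1L)
  ord <- order(gene, -Biostrings::width(seqs), ids)
  seqs <- seqs[ord]
  gene <- gene[ord]
  keep <- !duplicated(gene)
  out <- seqs[keep]
  names(out) <- gene[keep]
  out
}

#' Per-gene sequence feature table
#'
#' Computes, for every gene in a `DNAStringSet` of coding sequences, the CDS
#' length, potential-site counts per substitution class, base percentages,
#' CpG fraction, nucleotide diversity and (when ortholog counts are given)
#' the conservation index.
#'
#' @param seqs Named `DNAStringSet` of coding sequences (one per gene), e.g.
#'   from [read_cds_fasta()].
#' @param n_orthologs Optional named integer vector of ortholog counts.
#' @return A `data.table` with one row per gene, columns `gene_id`,
#'   `cds_length`, `n_potential_missense`, `n_potential_nonsense`,
#'   `n_potential_silent`, `pct_a` .. `pct_t`, `pct_cpg`, `nd`, and
#'   `conservation_index` if ortholog counts were supplied.
#' @export
sequence_features <- function(seqs, n_orthologs = NULL) {
  stopifnot(methods::is(seqs, "DNAStringSet"), !is.null(names(seqs)))
  w <- Biostrings::width(seqs)
  if (any(w < 3L | w %% 3L != 0L))
    stop("all coding sequences must have length a positive multiple of 3; ",
         "offending gene(s): ",
         paste(head(names(seqs)[w < 3L | w %% 3L != 0L], 5L), collapse = ", "))
  freq <- Biostrings::letterFrequency(seqs, c(BASES, "N"))
  if (any(freq[, "N"] > 0) ||
      any(rowSums(freq[, BASES, drop = FALSE]) != w))
    stop("non-ACGT characters present in input sequences")
  sites <- potential_site_matrix(seqs)
  p <- freq[, BASES, drop = FALSE] / w
  cpg <- Biostrings::vcountPattern("CG", seqs) / w
  nd <- 1 - rowSums(p^2)
  dt <- data.table::data.table(
    gene_id = names(seqs),
    cds_length = as.integer(w),
    n_potential_missense = sites[, "missense"],
    n_potential_nonsense = sites[, "nonsense"],
    n_potential_silent = sites[, "silent"],
    pct_a = p[, "A"], pct_c = p[, "C"], pct_g = p[, "G"], pct_t = p[, "T"],
    pct_cpg = cpg, nd = nd)
  if (!is.null(n_orthologs)) {
    miss <- setdiff(dt$gene_id, names(n_orthologs))
    if (length(miss))
      stop("no ortholog count for gene(s): ",
           paste(head(miss, 5L), collapse = ", "))
    dt[, conservation_index := conservation_index(n_orthologs[dt$gene_id])]
  }
  dt[]
}
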