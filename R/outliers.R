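# Residual Z-scores, the multiplicity-corrected significance cutoff,
# outlier calling and group summaries.

#' Residual Z-scores
#'
#' `(observed - predicted) / residual_sd`, using the fitting-set
#' root-mean-square residual as the scale. A positive Z indicates an excess
#' of mutations over the background expectation, a negative Z a deficit.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param residual_sd Positive scalar residual scale from the fitted model.
#' @return Numeric vector of Z-scores (names preserved from `observed` or
#'   `predicted`).
#' @export
residual_zscores <- function(observed, predicted, residual_sd) {
  if (!is.numeric(residual_sd) || length(residual_sd) != 1L ||
      residual_sd <= 0)
    stop("residual_sd must be a positive scalar")
  stopifnot(length(observed) == length(predicted))
  z <- (observed - predicted) / residual_sd
  if (is.null(names(z))) names(z) <- names(predicted)
  z
}

#' Multiplicity-corrected significance cutoff for residual Z-scores
#'
#' With `n_tests` genes each contributing the maximum of three Z-scores
#' (missense, nonsense, frameshift), the Bonferroni-style family-wise
#' threshold is the standard-normal quantile of the cube root of
#' `1 - alpha/n_tests`. At alpha = 0.05 and n = 15,610 this is 4.74.
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param n_tests Number of genes tested (>= 1).
#' @return Positive scalar cutoff on the Z scale.
#' @export
significance_cutoff <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.numeric(n_tests) || n_tests < 1 || n_tests != floor(n_tests))
    stop("n_tests must be a positive integer")
  if (alpha / n_tests >= 1) stop("alpha/n_tests must be < 1")
  qnorm((1 - alpha / n_tests)^(1 / 3))
}

#' Call positive outlier genes from per-type Z-scores
#'
#' Flags gene/type pairs whose residual Z strictly exceeds the cutoff.
#' Only positive excesses are flagged as candidate driver genes; genes
#' whose Z falls below `-cutoff` (mutation deficits) are reported in a
#' separate column for inspection. The report is sorted by the per-gene
#' maximum Z, descending.
#'
#' @param z_table `data.table`/data.frame with `gene_id`, `z_missense`,
#'   `z_nonsense`, `z_fs`.
#' @param cutoff Positive scalar from [significance_cutoff()].
#' @param alpha,n_tests Stored on the report for provenance (optional).
#' @return Object of class `OutlierReport`: `data.table` with the Z
#'   columns, `max_z`, `flags` (comma-joined subset of
#'   missense/nonsense/frameshift), `n_flags`, `deficit_flags`; attributes
#'   `cutoff`, `alpha`, `n_tests`.
#' @export
call_outliers <- function(z_table, cutoff, alpha = NA_real_,
                          n_tests = NA_integer_) {
  z <- data.table::as.data.table(z_table)
  need <- c("gene_id", "z_missense", "z_nonsense", "z_fs")
  stopifnot(all(need %in% names(z)), cutoff > 0)
  zm <- as.matrix(z[, .(z_missense, z_nonsense, z_fs)])
  type_names <- c("missense", "nonsense", "frameshift")
  pos <- zm > cutoff
  neg <- zm < -cutoff
  join_flags <- function(hit) {
    out <- character(nrow(hit))
    for (j in seq_along(type_names)) {
      h <- hit[, j]
      out[h] <- ifelse(nzchar(out[h]),
                       paste0(out[h], ",", type_names[j]), type_names[j])
    }
    out
  }
  out <- data.table::data.table(
    gene_id = z$gene_id,
    z_missense = zm[, 1L], z_nonsense = zm[, 2L], z_fs = zm[, 3L],
    max_z = pmax(zm[, 1L], zm[, 2L], zm[, 3L]),
    flags = join_flags(pos),
    n_flags = rowSums(pos),
    deficit_flags = join_flags(neg))
  data.table::setorder(out, -max_z)
  data.table::setattr(out, "cutoff", cutoff)
  data.table::setattr(out, "alpha", alpha)
  data.table::setattr(out, "n_tests", n_tests)
  data.table::setattr(out, "class",
                      c("OutlierReport", class(out)))
  out[]
}

#' Mean Z-scores per annotated gene group
#'
#' Mean and SEM of residual Z-scores per (group, mutation type), with a
#' two-sided Welch t-test of each non-reference group against the
#' reference group (annotation value `"other"`). This is the tumor
#' suppressor / oncogene group comparison.
#'
#' @param z_table `data.table` with `gene_id`, `z_missense`, `z_nonsense`,
#'   `z_fs`.
#' @param annotations Named character vector mapping gene ids to group
#'   labels (e.g. `"TS"`, `"OG"`); genes absent from the map are labelled
#'   `"other"`.
#' @return `data.table` with `group`, `mut_type`, `n_genes`, `mean_z`,
#'   `sem_z`, `p_vs_other`.
#' @export
group_zscore_summary <- function(z_table, annotations) {
  z <- data.table::as.data.table(z_table)
  grp <- annotations[z$gene_id]
  grp[is.na(grp)] <- "other"
  cols <- c(missense = "z_missense", nonsense = "z_nonsense",
            frameshift = "z_fs")
  rows <- list()
  for (tp in names(cols)) {
    v <- z[[cols[[tp]]]]
    for (g in sort(unique(grp))) {
      vg <- v[grp == g]
      sem <- if (length(vg) >= 2L) sd(vg) / sqrt(length(vg)) else {
        warning("singleton group ", g, ": SEM undefined", call. = FALSE)
        NA_real_
      }
      ref <- v[grp == "other"]
      p <- if (g == "other" || length(vg) < 2L || length(ref) < 2L)
             NA_real_
           else t.test(vg, ref)$p.value
      rows[[length(rows) + 1L]] <- data.table::data.table(
        group = g, mut_type = tp, n_genes = length(vg),
        mean_z = mean(vg), sem_z = sem, p_vs_other = p)
    }
  }
  data.table::rbindlist(rows)[]
}

#' Moving-average curve over ranked genes
#'
#' Sorts genes ascending by `x`, slides a window of `window` genes with the
#' given step, and returns the window means of `x` and `y`. Used to
#' visualize how mutation burden varies with a gene characteristic while
#' keeping strong single-gene outliers visible.
#'
#' @param x,y Equal-length numeric vectors (predictor and response).
#' @param window Window size in genes (>= 2, <= length(x)).
#' @param step Step size in genes (default 1).
#' @return `data.table` with `mean_x`, `mean_y`; `(n - window)/step + 1`
#'   rows.
#' @export
moving_average_curve <- function(x, y, window = 100L, step = 1L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (window < 2L) stop("window must be >= 2")
  if (window > n) stop("window exceeds number of genes")
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cx <- cumsum(c(0, xs)); cy <- cumsum(c(0, ys))
  starts <- seq(1L, n - window + 1L, by = step)
  data.table::data.table(
    mean_x = (cx[starts + window] - cx[starts]) / window,
    mean_y = (cy[starts + window] - cy[starts]) / window)
}
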