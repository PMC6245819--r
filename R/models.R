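# Univariate screening and stepwise multiple linear regression for expected
# per-gene mutation counts.

#' Default candidate predictor sets per mutation type
#'
#' The per-type candidate lists mirror which gene characteristics are
#' informative for each substitution class (nucleotide composition and
#' potential-site counts matter most for nonsense; size dominates for
#' frameshift), plus the three MutsigCV covariates in every set. For
#' frameshift mutations — which are not substitution outcomes — the total
#' potential-SNS count is three times the CDS length, so only `cds_length`
#' is carried. The pan-mutation set is the union.
#'
#' @param outcome One of `"missense"`, `"nonsense"`, `"frameshift"`,
#'   `"pan"`.
#' @param silent_as Whether the silent-mutation predictor enters as a raw
#'   count (default) or a per-nt density.
#' @return Character vector of feature-column names.
#' @export
candidate_predictors <- function(outcome = c("missense", "nonsense",
                                             "frameshift", "pan"),
                                 silent_as = c("count", "density")) {
  outcome <- match.arg(outcome)
  silent_as <- match.arg(silent_as)
  silent <- if (silent_as == "count") "n_silent_observed"
            else "density_silent"
  mutsig <- c("mutsig_expr", "mutsig_hic", "mutsig_reptime")
  base <- switch(outcome,
    missense = c("snp_density", "conservation_index",
                 "log_mean_expression", "cds_length", "nd",
                 "n_potential_missense", silent, "pct_c", "pct_g", "pct_t",
                 "pct_cpg", "replication_time", "chromatin_accessibility"),
    nonsense = c("conservation_index", "log_mean_expression", "cds_length",
                 "nd", "n_potential_nonsense", silent, "pct_a", "pct_c",
                 "pct_g", "pct_t", "pct_cpg", "replication_time",
                 "chromatin_accessibility"),
    frameshift = c("snp_density", "cds_length", "nd", silent, "pct_a",
                   "pct_g", "pct_cpg"),
    pan = unique(c(candidate_predictors("missense", silent_as),
                   candidate_predictors("nonsense", silent_as),
                   candidate_predictors("frameshift", silent_as))))
  c(base, mutsig[!mutsig %in% base])
}

# One simple linear regression; returns t, p, standardized beta, r2.
simple_fit <- function(x, y) {
  fit <- lm(y ~ x)
  s <- summary(fit)
  ct <- s$coefficients
  beta <- unname(ct["x", "Estimate"]) * sd(x) / sd(y)
  list(t = unname(ct["x", "t value"]), p = unname(ct["x", "Pr(>|t|)"]),
       beta = beta, coefficient = unname(ct["x", "Estimate"]),
       r2 = s$r.squared)
}

#' Univariate predictor screen
#'
#' Regresses the per-gene mutation count on each candidate predictor in
#' turn and reports t statistic, two-sided p-value and standardized beta,
#' sorted by |t| descending (the layout of the univariate results tables).
#' Constant predictors are skipped with a warning.
#'
#' @param features Feature table (fitting rows only).
#' @param outcome Numeric vector of per-gene counts, aligned with
#'   `features` rows.
#' @param predictors Character vector of columns to screen.
#' @return `data.table` with `predictor`, `t`, `p`, `beta`, `r2`.
#' @export
univariate_screen <- function(features, outcome, predictors) {
  stopifnot(nrow(features) >= 3L, length(outcome) == nrow(features))
  if (sd(outcome) == 0) stop("outcome is constant")
  rows <- lapply(predictors, function(nm) {
    x <- features[[nm]]
    if (is.null(x)) stop("predictor column missing: ", nm)
    if (sd(x) == 0) {
      warning("constant predictor skipped: ", nm, call. = FALSE)
      return(NULL)
    }
    f <- simple_fit(x, outcome)
    data.table::data.table(predictor = nm, t = f$t, p = f$p, beta = f$beta,
                           r2 = f$r2)
  })
  out <- data.table::rbindlist(rows)
  out <- out[order(-abs(t))]
  out[]
}

# p-value of dropping/adding one term, from the t-test of its coefficient
# in the given lm fit. Returns named vector over `terms`.
coef_pvalues <- function(fit, terms) {
  ct <- summary(fit)$coefficients
  p <- setNames(rep(NA_real_, length(terms)), terms)
  found <- intersect(terms, rownames(ct))
  p[found] <- ct[found, "Pr(>|t|)"]
  p
}

#' Stepwise multiple linear regression
#'
#' Forward selection with backward elimination on ordinary least squares:
#' at each step the candidate whose addition would be most significant
#' enters if its coefficient p-value is below `p_enter`; after each entry,
#' included predictors whose p-value rises above `p_remove` are removed
#' (worst first). Iteration stops when no candidate can enter and no
#' included predictor must leave. Deterministic: entry ties are broken by
#' smaller p-value, then alphabetical predictor name. Candidates whose
#' addition is numerically degenerate (aliased with the current model) are
#' unavailable at that step.
#'
#' @param features Feature table (fitting rows only).
#' @param outcome Numeric vector of per-gene counts.
#' @param candidates Character vector of candidate predictor columns, e.g.
#'   from [candidate_predictors()].
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must exceed `p_enter`.
#' @param outcome_name Label stored on the fitted model.
#' @return Object of class `mutburden_model`: list with
#'   `selected_predictors`, `coefficients` (named, incl. `(Intercept)`),
#'   `table` (`data.table`: predictor, coefficient, t, p, beta),
#'   `residual_sd` (root-mean-square residual), `r2`, `n_genes_fit`,
#'   `outcome`.
#' @export
stepwise_fit <- function(features, outcome, candidates,
                         p_enter = 0.05, p_remove = 0.10,
                         outcome_name = "count") {
  stopifnot(p_enter < p_remove, length(outcome) == nrow(features))
  dat <- as.data.frame(features)[, candidates, drop = FALSE]
  ok <- vapply(dat, function(x) sd(x) > 0, logical(1L))
  if (any(!ok))
    warning("constant candidate(s) dropped: ",
            paste(candidates[!ok], collapse = ", "), call. = FALSE)
  pool <- sort(candidates[ok])
  dat$.y <- outcome

  included <- character()
  repeat {
    changed <- FALSE
    # forward step
    avail <- setdiff(pool, included)
    if (length(avail)) {
      p_add <- vapply(avail, function(nm) {
        f <- lm(reformulate(c(included, nm), ".y"), data = dat)
        if (anyNA(coef(f))) return(NA_real_)  # aliased
        coef_pvalues(f, nm)
      }, numeric(1L))
      p_add <- p_add[!is.na(p_add)]
      if (length(p_add) && min(p_add) < p_enter) {
        best <- names(p_add)[p_add == min(p_add)]
        included <- c(included, sort(best)[1L])
        changed <- TRUE
      }
    }
    # backward step(s)
    repeat {
      if (!length(included)) break
      f <- lm(reformulate(included, ".y"), data = dat)
      p_cur <- coef_pvalues(f, included)
      worst <- max(p_cur, na.rm = TRUE)
      if (worst > p_remove) {
        drop_nm <- sort(names(p_cur)[which(p_cur == worst)])[1L]
        included <- setdiff(included, drop_nm)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  if (!length(included)) {
    warning("no predictor entered; returning intercept-only model",
            call. = FALSE)
    fit <- lm(.y ~ 1, data = dat)
  } else {
    fit <- lm(reformulate(included, ".y"), data = dat)
  }
  s <- summary(fit)
  cf <- coef(fit)
  resid_sd <- sqrt(mean(fit$residuals^2))
  tab <- if (length(included)) {
    ct <- s$coefficients
    data.table::data.table(
      predictor = included,
      coefficient = unname(cf[included]),
      t = unname(ct[included, "t value"]),
      p = unname(ct[included, "Pr(>|t|)"]),
      beta = vapply(included, function(nm)
        unname(cf[nm]) * sd(dat[[nm]]) / sd(outcome), numeric(1L)))
  } else {
    data.table::data.table(predictor = character(), coefficient = numeric(),
                           t = numeric(), p = numeric(), beta = numeric())
  }
  tab <- tab[order(-abs(t))]
  structure(list(outcome = outcome_name,
                 selected_predictors = included,
                 coefficients = cf,
                 table = tab[],
                 residual_sd = resid_sd,
                 r2 = if (length(included)) s$r.squared else 0,
                 n_genes_fit = nrow(dat)),
            class = "mutburden_model")
}

#' @export
print.mutburden_model <- function(x, ...) {
  cat(sprintf("<mutburden_model> outcome: %s | n = %d | R^2 = %.3f | residual SD = %.3f\n",
              x$outcome, x$n_genes_fit, x$r2, x$residual_sd))
  if (nrow(x$table)) print(x$table) else cat("  (intercept-only)\n")
  invisible(x)
}

#' Expected mutation counts from a fitted model
#'
#' Linear predictor on the raw count scale for every gene in `features`.
#' Predictions are not clipped at zero: residuals must stay centered, and
#' the scoring matrix may include genes that were withheld from fitting.
#'
#' @param model A `mutburden_model`.
#' @param features Feature table containing all selected predictors.
#' @return Named numeric vector (names = `features$gene_id` when present).
#' @export
predict_expected <- function(model, features) {
  stopifnot(inherits(model, "mutburden_model"))
  miss <- setdiff(model$selected_predictors, names(features))
  if (length(miss))
    stop("feature matrix lacks predictor column(s): ",
         paste(miss, collapse = ", "))
  cf <- model$coefficients
  pred <- rep(unname(cf["(Intercept)"]), nrow(features))
  for (nm in model$selected_predictors)
    pred <- pred + cf[[nm]] * features[[nm]]
  if ("gene_id" %in% names(features)) names(pred) <- features$gene_id
  pred
}

#' Coefficient of determination from observed and predicted counts
#'
#' `1 - SS_res / SS_tot`; equals the squared correlation when evaluated on
#' the fitting set of an OLS model.
#'
#' @param observed,predicted Equal-length numeric vectors, n >= 2.
#' @return Single numeric R^2 (can be negative off the fitting set).
#' @export
model_r2 <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  if (sd(observed) == 0) stop("observed vector is constant; R^2 undefined")
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Pan-mutation versus type-specific model comparison
#'
#' Fits a single model to the per-gene sum of missense + nonsense +
#' frameshift counts (the pan-mutation model) and scores it against each
#' mutation type separately, alongside the three type-specific stepwise
#' fits. Because the pan model predicts total counts, its per-type
#' predictions are rescaled by the cohort-level share of that type before
#' computing R^2.
#'
#' @param features Feature table (fitting rows only).
#' @param counts `data.table` with `n_missense`, `n_nonsense`, `n_fs`
#'   aligned with `features`.
#' @param p_enter,p_remove Stepwise thresholds.
#' @return List with `comparison` (`data.table`: outcome, r2_specific,
#'   r2_pan), `models` (named list of the four fits).
#' @export
compare_pan_vs_specific <- function(features, counts,
                                    p_enter = 0.05, p_remove = 0.10) {
  stopifnot(all(c("n_missense", "n_nonsense", "n_fs") %in% names(counts)),
            nrow(counts) == nrow(features))
  y <- list(missense = counts$n_missense, nonsense = counts$n_nonsense,
            frameshift = counts$n_fs)
  pan_y <- counts$n_missense + counts$n_nonsense + counts$n_fs
  models <- lapply(names(y), function(tp)
    stepwise_fit(features, y[[tp]], candidate_predictors(tp),
                 p_enter, p_remove, outcome_name = tp))
  names(models) <- names(y)
  models$pan <- stepwise_fit(features, pan_y, candidate_predictors("pan"),
                             p_enter, p_remove, outcome_name = "pan")
  pan_pred <- predict_expected(models$pan, features)
  shares <- vapply(y, sum, numeric(1L)) / sum(pan_y)
  comparison <- data.table::rbindlist(lapply(names(y), function(tp) {
    data.table::data.table(
      outcome = tp,
      r2_specific = model_r2(y[[tp]], predict_expected(models[[tp]],
                                                       features)),
      r2_pan = model_r2(y[[tp]], pan_pred * shares[[tp]]))
  }))
  list(comparison = comparison[], models = models)
}

#' Serialize a fitted model to JSON
#'
#' Stores selected predictors, coefficients, the per-predictor report table
#' and the residual scale, so the outlier stage can be rerun without
#' refitting.
#'
#' @param model A `mutburden_model`.
#' @param path Output JSON path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "mutburden_model"))
  obj <- list(outcome = model$outcome,
              selected_predictors = model$selected_predictors,
              coefficients = as.list(model$coefficients),
              table = model$table,
              residual_sd = model$residual_sd,
              r2 = model$r2,
              n_genes_fit = model$n_genes_fit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model back
#'
#' @param path JSON produced by [write_model_json()].
#' @return A `mutburden_model`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(outcome = obj$outcome,
                 selected_predictors = as.character(obj$selected_predictors),
                 coefficients = unlist(obj$coefficients),
                 table = data.table::as.data.table(obj$table),
                 residual_sd = obj$residual_sd,
                 r2 = obj$r2,
                 n_genes_fit = obj$n_genes_fit),
            class = "mutburden_model")
}
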