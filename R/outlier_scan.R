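# Residual-based outlier screening: per-year standardized residuals from a
# genotype-fixed fit, robust re-scaling by the rescaled median absolute
# deviation, normal-tail p-values, and Bonferroni-Holm family-wise control.
# One pass: flagged records are removed once, producing the enhanced
# dataset; the scan is not iterated.

#' Standardized residual scores and p-values
#'
#' Standardizes each conditional residual by its year's estimated error SD
#' (\code{studentized = TRUE} additionally divides by sqrt(1 - leverage)),
#' centres the scores on their median, rescales by 1.4826 times the median
#' absolute deviation, and converts to two-sided normal p-values:
#' z = (r - median(r)) / (1.4826 * mad), p = 2 * (1 - Phi(|z|)).
#'
#' When at least half of the residuals coincide the MAD is zero and no score
#' is defined: the degenerate-spread condition is reported via an attribute
#' and an empty score set, which downstream yields zero flags.
#'
#' @param fit a converged genotype-fixed \code{\link{reml_fit}}.
#' @param studentized apply the leverage correction (default \code{FALSE}:
#'   plain per-year standardization).
#' @return data.frame keyed by record (\code{key}, \code{accession_id},
#'   \code{year}, \code{value}, \code{z}, \code{p}); attribute
#'   \code{degenerate} is \code{TRUE} when the MAD was zero.
#' @export
standardized_scores <- function(fit, studentized = FALSE) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$genotype_role != "fixed")
    stop("outlier scores require a genotype-fixed fit")
  if (!fit$converged) stop("fit did not converge; scores not defined")
  sd_year <- sqrt(fit$varcomp$per_year_error)
  r <- fit$residuals / sd_year[as.character(fit$record_years)]
  if (studentized) r <- r / sqrt(1 - fit$leverages)
  m <- stats::median(r)
  madr <- 1.4826 * stats::median(abs(r - m))
  tab <- fit$record_table
  if (madr <= 0) {
    out <- data.frame(key = character(0), accession_id = character(0),
                      year = integer(0), value = numeric(0),
                      z = numeric(0), p = numeric(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (r - m) / madr
  out <- data.frame(key = names(fit$residuals),
                    accession_id = tab$accession_id, year = tab$year,
                    value = tab$value, z = unname(z),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- FALSE
  out
}

#' Holm step-down flags
#'
#' Flags the records whose p-values survive the Bonferroni-Holm step-down at
#' level \code{alpha}: sort ascending, flag while p_(i) <= alpha/(n - i + 1),
#' stop at the first failure. Implemented through
#' \code{stats::p.adjust(method = "holm")}, whose adjusted p <= alpha is
#' exactly that rule. Ties are ordered by record key so output order is
#' deterministic (the flag decision itself is order-independent).
#'
#' @param pvalues named numeric vector of p-values in [0, 1], names = record
#'   keys.
#' @param alpha family-wise error level, default 0.05.
#' @return character vector of flagged keys (possibly empty).
#' @export
holm_flags <- function(pvalues, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(pvalues)) return(character(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  ord <- order(pvalues, names(pvalues))
  p_holm <- stats::p.adjust(pvalues[ord], method = "holm")
  names(p_holm)[p_holm <= alpha]
}

#' Screen, flag and remove outliers for one trait
#'
#' The full single-pass curation of one trait: prune sparse years, fit the
#' genotype-fixed heteroscedastic model, score residuals, apply the Holm
#' step-down at \code{alpha}, and remove the flagged records. Records of
#' other traits are untouched. A fit failure is carried inside the report
#' (\code{fit_ok = FALSE}); no partial dataset is emitted in that case.
#'
#' @param dataset a \code{\link{phenotype_dataset}}.
#' @param trait trait to screen.
#' @param spec a \code{\link{model_spec}} (genotype role is forced to
#'   fixed).
#' @param alpha family-wise error level, default 0.05.
#' @param studentized leverage-corrected scores (see
#'   \code{\link{standardized_scores}}).
#' @return list with \code{dataset} (enhanced: flagged records removed),
#'   \code{report} (an \code{outlier_report}: record/accession counts before
#'   and after pruning, flag count and percentage, corrected size, and the
#'   flagged table sorted by Holm-adjusted p), and \code{fit} (the
#'   genotype-fixed fit the scores came from).
#' @export
correct_outliers <- function(dataset, trait, spec = model_spec(), alpha = 0.05,
                             studentized = FALSE) {
  trait <- match_trait(trait)
  spec$genotype_role <- "fixed"
  n_rec <- n_records(dataset, trait)
  n_acc <- n_accessions(dataset, trait)

  pr <- prune_sparse(dataset, trait, spec)
  pruned <- pr$dataset
  n_rec_p <- n_records(pruned, trait)
  n_acc_p <- n_accessions(pruned, trait)

  fit <- tryCatch(reml_fit(pruned, trait, spec), error = function(e) e)
  if (inherits(fit, "error") || !fit$converged) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit)
           else "REML did not converge"
    report <- structure(list(trait = trait, n_records = n_rec,
                             n_accessions = n_acc,
                             n_records_pruned = n_rec_p,
                             n_accessions_pruned = n_acc_p,
                             fit_ok = FALSE, failure = msg),
                        class = "outlier_report")
    return(list(dataset = NULL, report = report,
                fit = if (inherits(fit, "error")) NULL else fit))
  }

  sc <- standardized_scores(fit, studentized = studentized)
  flagged_keys <- if (nrow(sc))
    holm_flags(stats::setNames(sc$p, sc$key), alpha) else character(0)

  fl <- sc[sc$key %in% flagged_keys, , drop = FALSE]
  if (nrow(fl)) {
    p_all <- stats::setNames(sc$p, sc$key)
    ord <- order(p_all, names(p_all))
    ph <- stats::p.adjust(p_all[ord], method = "holm")
    fl$p_holm <- unname(ph[fl$key])
    fl <- fl[order(fl$p_holm, fl$key), , drop = FALSE]
  } else {
    fl$p_holm <- numeric(0)
  }
  rownames(fl) <- NULL

  enhanced <- pruned
  keys_all <- record_key(pruned$records$accession_id, pruned$records$year,
                         pruned$records$trait)
  enhanced$records <- pruned$records[!keys_all %in% flagged_keys, , drop = FALSE]
  rownames(enhanced$records) <- NULL

  report <- outlier_report(trait = trait, n_records = n_rec,
                           n_accessions = n_acc, n_records_pruned = n_rec_p,
                           n_accessions_pruned = n_acc_p,
                           n_outliers = nrow(fl), flagged = fl,
                           degenerate = isTRUE(attr(sc, "degenerate")))
  list(dataset = enhanced, report = report, fit = fit)
}

#' Assemble an outlier report
#'
#' Bundles the screening counts with their arithmetic identities:
#' corrected size = records after pruning minus flags, and the flag
#' percentage = 100 * flags / records after pruning, rounded half-up to two
#' decimals.
#'
#' @param trait trait name.
#' @param n_records,n_accessions counts before pruning.
#' @param n_records_pruned,n_accessions_pruned counts after pruning.
#' @param n_outliers number of flagged records.
#' @param flagged flagged-record table (may be \code{NULL}).
#' @param degenerate zero-MAD condition flag.
#' @return an \code{outlier_report}.
#' @export
outlier_report <- function(trait, n_records, n_accessions, n_records_pruned,
                           n_accessions_pruned, n_outliers, flagged = NULL,
                           degenerate = FALSE) {
  stopifnot(n_outliers <= n_records_pruned)
  structure(list(trait = trait, n_records = as.integer(n_records),
                 n_accessions = as.integer(n_accessions),
                 n_records_pruned = as.integer(n_records_pruned),
                 n_accessions_pruned = as.integer(n_accessions_pruned),
                 n_outliers = as.integer(n_outliers),
                 outlier_pct = round_half_up(100 * n_outliers / n_records_pruned, 2),
                 corrected_size = as.integer(n_records_pruned - n_outliers),
                 flagged = flagged, degenerate = degenerate, fit_ok = TRUE),
            class = "outlier_report")
}

#' @method print outlier_report
#' @export
print.outlier_report <- function(x, ...) {
  cat("outlier_report: trait ", x$trait, "\n", sep = "")
  if (!isTRUE(x$fit_ok)) {
    cat("  model fit failed: ", x$failure, "\n", sep = "")
    return(invisible(x))
  }
  cat("  records ", x$n_records, " (", x$n_records_pruned, " after pruning), ",
      "accessions ", x$n_accessions, " (", x$n_accessions_pruned, ")\n", sep = "")
  cat("  outliers ", x$n_outliers, " (", format(x$outlier_pct, nsmall = 2),
      "%), corrected size ", x$corrected_size, "\n", sep = "")
  invisible(x)
}
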