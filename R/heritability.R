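# Entry-mean heritability: the repeatability of accession means over the
# average number of regeneration years,
#   h2 = sigma2_G / (sigma2_G + sigma2_e / Year),
# with sigma2_G and the average error variance sigma2_e taken from a
# genotype-random REML fit.

#' Average number of test years per accession
#'
#' Arithmetic mean, over accessions with at least one record for the trait,
#' of the number of distinct years in which that trait was scored.
#'
#' @param dataset a \code{\link{phenotype_dataset}}.
#' @param trait trait name.
#' @return a real >= 1.
#' @export
mean_years <- function(dataset, trait) {
  trait <- match_trait(trait)
  r <- dataset$records[dataset$records$trait == trait, ]
  if (!nrow(r)) stop("no records for trait ", trait)
  ny <- tapply(r$year, r$accession_id, function(y) length(unique(y)))
  mean(ny)
}

#' Entry-mean heritability ratio
#'
#' h2 = sigma2_G / (sigma2_G + sigma2_e_mean / mean_years): strictly
#' increasing in the genetic variance and in the number of test years,
#' decreasing in the error variance.
#'
#' @param sigma2_G genetic variance (>= 0).
#' @param sigma2_e_mean average error variance across regeneration years
#'   (>= 0).
#' @param mean_years average number of distinct test years per accession
#'   (>= 1).
#' @return h2 in [0, 1].
#' @export
entry_mean_h2 <- function(sigma2_G, sigma2_e_mean, mean_years) {
  stopifnot(sigma2_G >= 0, sigma2_e_mean >= 0, mean_years >= 1)
  if (sigma2_G == 0 && sigma2_e_mean == 0)
    stop("heritability undefined: both variance components are zero")
  sigma2_G / (sigma2_G + sigma2_e_mean / mean_years)
}

#' Heritability of a trait from a genotype-random fit
#'
#' Fits the accession-by-year model with both accessions and years random,
#' extracts the genetic variance and the unweighted mean of the per-year
#' error variances, and combines them with the realized mean test years into
#' the entry-mean heritability. A non-converged fit, insufficient data, or a
#' degenerate solution with both variances pinned at the floor is a reported
#' state (\code{fit_ok = FALSE}, no h2), never an error: with historical
#' data some trait/stage combinations genuinely cannot support the model.
#'
#' @param dataset a \code{\link{phenotype_dataset}} (original or enhanced
#'   stage; \code{mean_years} is computed on the same records as the fit).
#' @param trait trait name.
#' @param spec a \code{\link{model_spec}} (genotype role forced to random).
#' @param dataset_stage label stored in the result, \code{"original"} or
#'   \code{"enhanced"}.
#' @param prune prune sparse years before fitting (default \code{TRUE}).
#' @param error_mean how to average the per-year error variances into the
#'   single sigma2_e of the heritability ratio: \code{"unweighted"}
#'   (default, one value per regeneration year) or \code{"weighted"}
#'   (weighted by the number of records in each year).
#' @return a \code{heritability_result}: \code{sigma2_G},
#'   \code{sigma2_e_mean}, \code{mean_years}, \code{h2}, \code{fit_ok},
#'   and \code{diagnosis} when the fit failed.
#' @export
heritability_pipeline <- function(dataset, trait, spec = model_spec("random"),
                                  dataset_stage = c("original", "enhanced"),
                                  prune = TRUE,
                                  error_mean = c("unweighted", "weighted")) {
  trait <- match_trait(trait)
  dataset_stage <- match.arg(dataset_stage)
  error_mean <- match.arg(error_mean)
  spec$genotype_role <- "random"

  fail <- function(msg) structure(
    list(trait = trait, dataset_stage = dataset_stage, sigma2_G = NA_real_,
         sigma2_e_mean = NA_real_, mean_years = NA_real_, h2 = NULL,
         fit_ok = FALSE, diagnosis = msg),
    class = "heritability_result")

  ds <- dataset
  if (prune) {
    pr <- tryCatch(prune_sparse(dataset, trait, spec), error = function(e) e)
    if (inherits(pr, "error")) return(fail(conditionMessage(pr)))
    ds <- pr$dataset
  }
  fit <- tryCatch(reml_fit(ds, trait, spec), error = function(e) e)
  if (inherits(fit, "error")) return(fail(conditionMessage(fit)))
  if (!fit$converged) return(fail("REML did not converge"))
  vc <- fit$varcomp
  if (all(c("sigma2_G") %in% vc$pinned) &&
      any(grepl("^sigma2_e", vc$pinned)))
    return(fail("genetic and error variances pinned at the floor"))
  my <- mean_years(ds, trait)
  s2e <- if (error_mean == "weighted") {
    yr_n <- table(ds$records$year[ds$records$trait == trait])
    sum(vc$per_year_error * as.numeric(yr_n[names(vc$per_year_error)])) /
      sum(yr_n)
  } else {
    vc$sigma2_e_mean
  }
  h2 <- tryCatch(entry_mean_h2(vc$sigma2_G, s2e, my),
                 error = function(e) NULL)
  if (is.null(h2)) return(fail("heritability undefined at the fitted variances"))
  structure(list(trait = trait, dataset_stage = dataset_stage,
                 sigma2_G = vc$sigma2_G, sigma2_year = vc$sigma2_year,
                 sigma2_e_mean = s2e, mean_years = my,
                 h2 = h2, fit_ok = TRUE, fit = fit),
            class = "heritability_result")
}

#' @method print heritability_result
#' @export
print.heritability_result <- function(x, ...) {
  cat("heritability_result: trait ", x$trait, " (", x$dataset_stage,
      " data)\n", sep = "")
  if (!x$fit_ok) {
    cat("  not available: ", x$diagnosis, "\n", sep = "")
    return(invisible(x))
  }
  cat("  sigma2_G = ", format(x$sigma2_G), ", mean sigma2_e = ",
      format(x$sigma2_e_mean), ", mean years = ",
      format(round(x$mean_years, 3)), "\n", sep = "")
  cat("  entry-mean h2 = ", format(round(x$h2, 4)), "\n", sep = "")
  invisible(x)
}
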