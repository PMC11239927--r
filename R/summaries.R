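# Descriptive summaries of a collection: provenance composition, record
# coverage by trait and decade, regeneration-year histograms and the
# year-effect table.

#' Provenance composition of a collection
#'
#' Counts accessions by origin country. Origins holding at least
#' \code{threshold_pct} percent of accessions are listed individually,
#' sorted by count descending; origins strictly below the threshold are
#' grouped under Others. Unknown origin is always its own row, never
#' grouped. Percentages are against the total accession count, rounded
#' half-up to two decimals.
#'
#' @param dataset a \code{\link{phenotype_dataset}} with populated
#'   provenance.
#' @param threshold_pct listing threshold in percent, default 1.
#' @return a \code{provenance_summary}: \code{rows} (origin, n, pct),
#'   \code{others_count}, \code{others_n_countries}, \code{unknown_count},
#'   \code{total}.
#' @export
provenance_table <- function(dataset, threshold_pct = 1.0) {
  prov <- dataset$provenance
  if (!length(prov)) stop("empty dataset: no accessions")
  total <- length(prov)
  cnt <- table(prov)
  unknown_count <- if ("Unknown" %in% names(cnt)) as.integer(cnt[["Unknown"]]) else 0L
  cnt <- cnt[names(cnt) != "Unknown"]
  pct <- 100 * as.numeric(cnt) / total
  listed <- pct >= threshold_pct
  rows <- data.frame(origin = names(cnt)[listed],
                     n = as.integer(cnt[listed]),
                     pct = round_half_up(pct[listed], 2),
                     stringsAsFactors = FALSE)
  rows <- rows[order(-rows$n, rows$origin), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows,
                 others_count = as.integer(sum(cnt[!listed])),
                 others_n_countries = sum(!listed),
                 unknown_count = unknown_count, total = total,
                 threshold_pct = threshold_pct),
            class = "provenance_summary")
}

#' @method print provenance_summary
#' @export
print.provenance_summary <- function(x, ...) {
  cat("provenance_summary: ", x$total, " accessions\n", sep = "")
  print(x$rows, row.names = FALSE)
  cat("  Others (", x$others_n_countries, " countries): ", x$others_count,
      "; Unknown: ", x$unknown_count, "\n", sep = "")
  invisible(x)
}

#' Record and accession counts by trait and decade
#'
#' The decade of a record is floor(year / 10) * 10. Counts non-missing
#' records and distinct accessions per trait per decade, plus a total per
#' trait.
#'
#' @param dataset a \code{\link{phenotype_dataset}}.
#' @return data.frame with columns \code{trait}, \code{decade}
#'   (\code{NA} in the totals rows), \code{n_records},
#'   \code{n_accessions}.
#' @export
records_by_decade <- function(dataset) {
  r <- dataset$records
  if (!nrow(r))
    return(data.frame(trait = character(0), decade = integer(0),
                      n_records = integer(0), n_accessions = integer(0)))
  dec <- (r$year %/% 10L) * 10L
  out <- do.call(rbind, lapply(sort(unique(r$trait)), function(tr) {
    i <- r$trait == tr
    per <- do.call(rbind, lapply(sort(unique(dec[i])), function(d) {
      j <- i & dec == d
      data.frame(trait = tr, decade = d, n_records = sum(j),
                 n_accessions = length(unique(r$accession_id[j])))
    }))
    rbind(per, data.frame(trait = tr, decade = NA_integer_,
                          n_records = sum(i),
                          n_accessions = length(unique(r$accession_id[i]))))
  }))
  rownames(out) <- NULL
  out
}

#' Regeneration-year histogram
#'
#' For one trait, the number of accessions scored in exactly k distinct
#' years, for each realized k. The histogram masses sum to the number of
#' accessions with at least one record for the trait.
#'
#' @param dataset a \code{\link{phenotype_dataset}}.
#' @param trait trait name.
#' @return named integer vector: names are k, values are accession counts.
#' @export
regeneration_distribution <- function(dataset, trait) {
  trait <- match_trait(trait)
  r <- dataset$records[dataset$records$trait == trait, ]
  if (!nrow(r)) return(stats::setNames(integer(0), character(0)))
  ny <- tapply(r$year, r$accession_id, function(y) length(unique(y)))
  tb <- table(factor(ny, levels = sort(unique(ny))))
  stats::setNames(as.integer(tb), names(tb))
}

#' Year-effect table
#'
#' BLUPs of the random year effect from a converged fit, one row per
#' retained year. Being shrunken predictions of a zero-mean effect, they
#' sum to approximately (not exactly) zero under unbalanced designs.
#'
#' @param fit a converged \code{\link{reml_fit}}.
#' @return data.frame with columns \code{year}, \code{effect}.
#' @export
year_effect_table <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged) stop("fit did not converge; year effects not reported")
  ye <- fit$year_effects
  data.frame(year = as.integer(names(ye)), effect = unname(ye))
}
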