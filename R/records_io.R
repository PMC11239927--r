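# Reading, validating and writing tab-delimited phenotype tables.
#
# Input tables are wide (one row per accession-year, one column per trait),
# following the tab-separated study/assay conventions of plant-phenotype
# repositories. Internally everything is long: one record = one
# accession x year x trait observation.

TRAITS <- c("HD", "PH", "TGW")

.default_col_map <- function() {
  list(accession_id = "Accession_ID", year = "Year", origin = "Origin",
       value_type = "Value_type", HD = "HD", PH = "PH", TGW = "TGW")
}

# trait-specific plausibility window; HD is days since Jan 1
.value_ok <- function(trait, value) {
  trait <- rep_len(trait, length(value))
  ifelse(trait == "HD", value > 0 & value <= 366, value > 0)
}

#' Construct a phenotype dataset
#'
#' Bundles long-format phenotype records with growth habit and a
#' per-accession provenance (origin country) map. Records violating the
#' trait plausibility rules (HD in (0, 366], PH > 0, TGW > 0) or falling
#' outside the year window are an error here; \code{\link{read_assay_table}}
#' filters such rows into its parse report instead.
#'
#' @param records data.frame with columns \code{accession_id}, \code{year},
#'   \code{trait}, \code{value} and optionally \code{value_type}.
#' @param growth_habit \code{"spring"} or \code{"winter"}.
#' @param provenance named character vector mapping accession to an ISO3166
#'   alpha-3 code or \code{"Unknown"}; accessions absent from the map are
#'   assigned \code{"Unknown"}.
#' @param year_window length-2 integer vector of admissible calendar years.
#' @return object of class \code{phenotype_dataset}.
#' @export
phenotype_dataset <- function(records, growth_habit = c("spring", "winter"),
                              provenance = NULL,
                              year_window = c(1951L, 2020L)) {
  growth_habit <- match.arg(growth_habit)
  stopifnot(is.data.frame(records))
  need <- c("accession_id", "year", "trait", "value")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  records$accession_id <- as.character(records$accession_id)
  records$year <- as.integer(records$year)
  records$trait <- as.character(records$trait)
  records$value <- as.numeric(records$value)
  if (is.null(records$value_type)) records$value_type <- "single"

  bad_trait <- !records$trait %in% TRAITS
  if (any(bad_trait))
    stop("unknown trait(s): ", paste(unique(records$trait[bad_trait]), collapse = ", "))
  if (anyNA(records$value)) stop("missing trait values are not records; drop them")
  bad_val <- !.value_ok(records$trait, records$value)
  if (any(bad_val))
    stop(sum(bad_val), " record(s) violate trait value rules (first: ",
         records$trait[bad_val][1], " = ", records$value[bad_val][1], ")")
  bad_year <- records$year < year_window[1] | records$year > year_window[2]
  if (any(bad_year))
    stop(sum(bad_year), " record(s) outside year window [",
         year_window[1], ", ", year_window[2], "]")

  key <- record_key(records$accession_id, records$year, records$trait)
  if (anyDuplicated(key)) {
    warning("duplicate (accession, year, trait) rows: keeping first occurrence")
    records <- records[!duplicated(key), , drop = FALSE]
  }

  acc <- sort(unique(records$accession_id))
  prov <- rep("Unknown", length(acc))
  names(prov) <- acc
  if (!is.null(provenance)) {
    provenance[is.na(provenance) | provenance == ""] <- "Unknown"
    hit <- intersect(names(provenance), acc)
    prov[hit] <- provenance[hit]
  }

  rownames(records) <- NULL
  structure(
    list(records = records[, c("accession_id", "year", "trait", "value", "value_type")],
         growth_habit = growth_habit, provenance = prov,
         year_window = as.integer(year_window), parse_report = NULL),
    class = "phenotype_dataset")
}

#' @method print phenotype_dataset
#' @export
print.phenotype_dataset <- function(x, ...) {
  r <- x$records
  cat("phenotype_dataset (", x$growth_habit, " habit)\n", sep = "")
  cat("  ", nrow(r), " records, ", length(unique(r$accession_id)),
      " accessions, years ", min(r$year), "-", max(r$year), "\n", sep = "")
  tb <- table(factor(r$trait, TRAITS))
  cat("  records per trait: ", paste(names(tb), tb, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$parse_report))
    cat("  parse report: ", x$parse_report$rows_read, " rows read, ",
        x$parse_report$rows_rejected, " rejected\n", sep = "")
  invisible(x)
}

#' Number of records
#' @param dataset a \code{phenotype_dataset}
#' @param trait optional trait to restrict to
#' @return integer count
#' @export
n_records <- function(dataset, trait = NULL) {
  r <- dataset$records
  if (!is.null(trait)) r <- r[r$trait == match_trait(trait), ]
  nrow(r)
}

#' Number of distinct accessions
#' @inheritParams n_records
#' @return integer count
#' @export
n_accessions <- function(dataset, trait = NULL) {
  r <- dataset$records
  if (!is.null(trait)) r <- r[r$trait == match_trait(trait), ]
  length(unique(r$accession_id))
}

#' Read a wide assay table into a phenotype dataset
#'
#' Parses a tab-separated assay table (one row per accession-year, one column
#' per trait), unpivots it to long records and attaches a parse report.
#' Empty cells and \code{"NA"} are missing; a missing trait cell simply
#' produces no record. A row is rejected -- recorded in the parse report, not
#' an error -- when its year is unparseable or outside the window, or when a
#' present trait cell is non-numeric or violates the trait's plausibility
#' rule.
#'
#' @param path file path.
#' @param growth_habit \code{"spring"} or \code{"winter"}.
#' @param col_map named list mapping internal names (\code{accession_id},
#'   \code{year}, \code{origin}, \code{value_type}, \code{HD}, \code{PH},
#'   \code{TGW}) to the file's column headers; deposited headers vary, so the
#'   mapping is caller-configurable.
#' @param year_window admissible calendar years, default \code{c(1951, 2020)}.
#' @param na_tokens cell values treated as missing.
#' @return a \code{phenotype_dataset}; its \code{parse_report} lists
#'   \code{rows_read}, \code{rows_with_records}, \code{rows_empty},
#'   \code{rows_rejected}, \code{records_produced} and per-row rejection
#'   reasons. Conservation: rows_read = rows_with_records + rows_empty +
#'   rows_rejected.
#' @export
read_assay_table <- function(path, growth_habit = c("spring", "winter"),
                             col_map = .default_col_map(),
                             year_window = c(1951L, 2020L),
                             na_tokens = c("", "NA")) {
  growth_habit <- match.arg(growth_habit)
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
  cm <- utils::modifyList(.default_col_map(), as.list(col_map))
  for (col in c("accession_id", "year")) {
    if (!cm[[col]] %in% names(raw))
      stop("schema error: mandatory column '", cm[[col]], "' (", col,
           ") absent from ", path)
  }
  traits_present <- TRAITS[vapply(TRAITS, function(tr) cm[[tr]] %in% names(raw),
                                  logical(1))]
  if (!length(traits_present))
    stop("schema error: no trait column among '",
         paste(unlist(cm[TRAITS]), collapse = "', '"), "' in ", path)

  nr <- nrow(raw)
  blank <- function(x) is.na(x) | x %in% na_tokens
  acc <- trimws(raw[[cm$accession_id]])
  year_raw <- trimws(raw[[cm$year]])
  year <- suppressWarnings(as.integer(year_raw))
  origin <- if (cm$origin %in% names(raw)) trimws(raw[[cm$origin]]) else rep(NA, nr)
  vtype <- if (cm$value_type %in% names(raw)) trimws(raw[[cm$value_type]])
           else rep("single", nr)
  vtype[blank(vtype) | !vtype %in% c("single", "average")] <- "single"

  reject_reason <- rep(NA_character_, nr)
  flag <- function(cond, why) {
    new <- cond & is.na(reject_reason)
    reject_reason[new] <<- why
  }
  flag(blank(acc), "missing accession identifier")
  flag(is.na(year), "unparseable year")
  flag(!is.na(year) & (year < year_window[1] | year > year_window[2]),
       "year outside window")

  vals <- matrix(NA_real_, nr, length(traits_present),
                 dimnames = list(NULL, traits_present))
  for (tr in traits_present) {
    cell <- trimws(raw[[cm[[tr]]]])
    present <- !blank(cell)
    v <- suppressWarnings(as.numeric(cell))
    flag(present & is.na(v), paste0("non-numeric ", tr, " cell"))
    bad <- present & !is.na(v) & !.value_ok(tr, v)
    flag(bad, paste0("implausible ", tr, " value"))
    v[!present] <- NA_real_
    vals[, tr] <- v
  }

  rejected <- !is.na(reject_reason)
  has_any <- rowSums(!is.na(vals)) > 0
  empty <- !rejected & !has_any
  keep <- !rejected & has_any

  long <- do.call(rbind, lapply(traits_present, function(tr) {
    i <- which(keep & !is.na(vals[, tr]))
    if (!length(i)) return(NULL)
    data.frame(accession_id = acc[i], year = year[i], trait = tr,
               value = vals[i, tr], value_type = vtype[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(long) || !nrow(long))
    stop("no valid records parsed from ", path)

  prov <- origin
  prov[blank(prov)] <- "Unknown"
  prov_map <- tapply(prov, acc, function(v) v[1])
  prov_map <- stats::setNames(as.character(prov_map), names(prov_map))

  ds <- phenotype_dataset(long, growth_habit, provenance = prov_map,
                          year_window = year_window)
  ds$parse_report <- list(
    rows_read = nr,
    rows_with_records = sum(keep),
    rows_empty = sum(empty),
    rows_rejected = sum(rejected),
    records_produced = nrow(long),
    rejections = if (any(rejected))
      data.frame(row = which(rejected), reason = reject_reason[rejected])
    else NULL)
  ds
}

#' Write a phenotype dataset as a wide assay table
#'
#' Inverse of \code{\link{read_assay_table}}: pivots long records back to one
#' row per accession-year with one column per trait, tab-separated, UTF-8,
#' \code{"."} decimal mark, empty cell for missing. Rows are ordered by
#' accession then year, so identical datasets produce byte-identical files.
#'
#' @param dataset a \code{phenotype_dataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  r <- dataset$records
  cell <- data.frame(accession_id = r$accession_id, year = r$year,
                     value_type = r$value_type, stringsAsFactors = FALSE)
  wide <- unique(cell[order(cell$accession_id, cell$year), c("accession_id", "year")])
  for (tr in TRAITS) {
    sub <- r[r$trait == tr, ]
    i <- match(paste(wide$accession_id, wide$year),
               paste(sub$accession_id, sub$year))
    wide[[tr]] <- sub$value[i]
  }
  vt <- tapply(r$value_type, paste(r$accession_id, r$year), function(v) v[1])
  wide$Value_type <- as.character(vt[paste(wide$accession_id, wide$year)])
  wide$Origin <- unname(dataset$provenance[wide$accession_id])
  out <- data.frame(Accession_ID = wide$accession_id, Year = wide$year,
                    HD = wide$HD, PH = wide$PH, TGW = wide$TGW,
                    Value_type = wide$Value_type, Origin = wide$Origin)
  .write_tsv(out, path)
  invisible(path)
}

# deterministic tab-separated writer shared by all output files
.write_tsv <- function(df, path, comments = character(0)) {
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write file: ", path))
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
}

#' Write the per-trait curation output file set
#'
#' Emits the four tab-separated files of one trait run: per-year variance
#' components (\code{Var.comp.<TRAIT>.txt}, with the model configuration as
#' comment lines), the flagged-outlier list (\code{Outliers.<TRAIT>.txt}),
#' the outlier-corrected data (\code{Data.corrected.<TRAIT>.txt}) and the
#' per-accession BLUEs (\code{BLUEs.<TRAIT>.txt}). Row order is deterministic
#' (accession ascending, then year); re-running on identical inputs gives
#' byte-identical files.
#'
#' @param fit a converged genotype-fixed \code{\link{reml_fit}} result.
#' @param report an \code{outlier_report} from \code{\link{correct_outliers}}.
#' @param blues BLUE table from \code{\link{compute_blues}}.
#' @param corrected the enhanced \code{phenotype_dataset}.
#' @param dir output directory (created if absent).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_outputs <- function(fit, report, blues, corrected, dir) {
  trait <- report$trait
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  if (is.null(blues) || !nrow(blues)) stop("empty BLUE table: upstream fit failed")

  vc <- fit$varcomp
  vdf <- data.frame(year = as.integer(names(vc$per_year_error)),
                    sigma2_error = unname(vc$per_year_error))
  vdf <- vdf[order(vdf$year), ]
  cmts <- c(paste0("trait=", trait),
            paste0("genotype_role=", fit$genotype_role),
            paste0("heteroscedastic=", fit$heteroscedastic),
            paste0("min_records_per_year=", fit$spec$min_records_per_year),
            paste0("rel_tol=", format(fit$spec$rel_tol)),
            paste0("max_iter=", fit$spec$max_iter),
            paste0("sigma2_year=", format(vc$sigma2_year)),
            paste0("sigma2_e_mean=", format(vc$sigma2_e_mean)))
  paths <- c(varcomp = file.path(dir, sprintf("Var.comp.%s.txt", trait)),
             outliers = file.path(dir, sprintf("Outliers.%s.txt", trait)),
             corrected = file.path(dir, sprintf("Data.corrected.%s.txt", trait)),
             blues = file.path(dir, sprintf("BLUEs.%s.txt", trait)))
  .write_tsv(vdf, paths["varcomp"], comments = cmts)

  fl <- report$flagged
  if (is.null(fl))
    fl <- data.frame(accession_id = character(0), year = integer(0),
                     value = numeric(0), z = numeric(0), p = numeric(0),
                     p_holm = numeric(0))
  .write_tsv(fl[, c("accession_id", "year", "value", "z", "p", "p_holm")],
             paths["outliers"])

  cr <- corrected$records[corrected$records$trait == trait, ]
  cr <- cr[order(cr$accession_id, cr$year), c("accession_id", "year", "value")]
  .write_tsv(cr, paths["corrected"])

  bl <- blues[order(blues$accession_id), ]
  .write_tsv(bl, paths["blues"])
  invisible(paths)
}
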