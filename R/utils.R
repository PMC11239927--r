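# shared internal helpers

#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed summary tables here use
#' conventional half-up rounding (20.285 -> 20.29).
#' @param x numeric vector
#' @param digits integer, decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Canonical record key
#'
#' One observation is identified by accession, year and trait; keys are used
#' to align residuals, flags and simulation ground truth.
#' @param accession_id character
#' @param year integer
#' @param trait character
#' @return character vector of keys
#' @export
record_key <- function(accession_id, year, trait) {
  paste(accession_id, year, trait, sep = "|")
}

# single validated trait name
match_trait <- function(trait) {
  match.arg(trait, c("HD", "PH", "TGW"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive sub-seeds from one master seed without exceeding .Machine$integer.max
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
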