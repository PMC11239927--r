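# Generator of non-orthogonal, heteroscedastic multi-year regeneration-trial
# datasets with recorded ground truth, for validating every curation stage.

#' Simulation configuration
#'
#' Parameters of a single-trait multi-year trial simulation. Each accession
#' is observed in k distinct years (k drawn from
#' \code{years_per_accession_pmf}), years assigned uniformly without
#' replacement, and values follow the additive model
#' value = mu + g_i + a_j + e_ij with g ~ N(0, sigma2_G),
#' a ~ N(0, sigma2_year) and e_ij ~ N(0, sigma2_j). Per-year error variances
#' are lognormal, sigma2_j = sigma2_e_mean * exp(tau * z_j - tau^2 / 2), so
#' their expectation is \code{sigma2_e_mean}; tau = 0 gives homoscedastic
#' errors. A Binomial(N, contamination_rate) subset of records is shifted by
#' +/- shift_sd_multiplier * sigma_j (gross errors the outlier screen
#' targets).
#'
#' @param n_accessions number of accessions.
#' @param n_years number of trial years (calendar years ending at
#'   \code{year_end}).
#' @param years_per_accession_pmf probability vector over 1..K distinct
#'   regeneration years per accession; K must not exceed \code{n_years}.
#' @param mu population mean on the trait scale.
#' @param sigma2_G,sigma2_year genetic and year variance components (>= 0).
#' @param sigma2_e_mean mean error variance (> 0).
#' @param tau lognormal dispersion of per-year error variances (>= 0).
#' @param contamination_rate fraction of records receiving a gross shift,
#'   in [0, 1).
#' @param shift_sd_multiplier outlier magnitude in units of that year's
#'   error SD.
#' @param origin_weights named probability vector over origin country codes
#'   (\code{NULL}: all accessions \code{"Unknown"}).
#' @param origins optional explicit origin per accession (length
#'   \code{n_accessions}), overriding \code{origin_weights}; used to keep
#'   provenance consistent across traits.
#' @param trait trait label for the generated records.
#' @param growth_habit habit label for the dataset.
#' @param year_end last calendar year of the design.
#' @param seed integer RNG seed; all draws come from one stream in a fixed
#'   documented order.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_accessions = 500, n_years = 20,
                       years_per_accession_pmf = c(0.02, 0.04, 0.08, 0.12, 0.16,
                                                   0.18, 0.16, 0.12, 0.08, 0.04),
                       mu = 100, sigma2_G = 300, sigma2_year = 50,
                       sigma2_e_mean = 85, tau = 0.3,
                       contamination_rate = 0, shift_sd_multiplier = 8,
                       origin_weights = NULL, origins = NULL,
                       trait = "PH", growth_habit = "winter",
                       year_end = 2020L, seed = 1L) {
  pmf <- years_per_accession_pmf
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-8)
    stop("years_per_accession_pmf must be non-negative and sum to 1")
  if (length(pmf) > n_years)
    stop("years_per_accession_pmf support (", length(pmf),
         ") exceeds n_years (", n_years, ")")
  if (contamination_rate < 0 || contamination_rate >= 1)
    stop("contamination_rate must lie in [0, 1)")
  if (sigma2_G < 0 || sigma2_year < 0 || sigma2_e_mean <= 0 || tau < 0 ||
      shift_sd_multiplier < 0)
    stop("variance-type parameters must be non-negative (sigma2_e_mean > 0)")
  if (!is.null(origins) && length(origins) != n_accessions)
    stop("origins must have length n_accessions")
  structure(list(n_accessions = as.integer(n_accessions),
                 n_years = as.integer(n_years),
                 years_per_accession_pmf = pmf, mu = mu,
                 sigma2_G = sigma2_G, sigma2_year = sigma2_year,
                 sigma2_e_mean = sigma2_e_mean, tau = tau,
                 contamination_rate = contamination_rate,
                 shift_sd_multiplier = shift_sd_multiplier,
                 origin_weights = origin_weights, origins = origins,
                 trait = match_trait(trait), growth_habit = growth_habit,
                 year_end = as.integer(year_end), seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genebank-style trial collection
#'
#' Generates one single-trait dataset under \code{config} together with its
#' ground truth. Fully reproducible: one RNG stream seeded from
#' \code{config$seed}, draws in the order (1) genotype effects, (2) origins,
#' (3) year effects, (4) per-year error variances, (5) years-per-accession
#' counts, (6) year assignments, (7) residuals, (8) contamination subset,
#' signs.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{dataset} (a
#'   \code{\link{phenotype_dataset}}) and \code{truth} (a
#'   \code{truth_record}: genotype and year effects, per-year error
#'   variances, keys of shifted records, realized mean years and
#'   \code{true_h2} = sigma2_G / (sigma2_G + sigma2_e_mean / mean_years)).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)

  acc_ids <- sprintf("ACC%05d", seq_len(cf$n_accessions))
  years <- seq(cf$year_end - cf$n_years + 1L, cf$year_end)

  g <- stats::rnorm(cf$n_accessions, 0, sqrt(cf$sigma2_G))
  names(g) <- acc_ids
  if (!is.null(cf$origins)) {
    origins <- as.character(cf$origins)
  } else if (!is.null(cf$origin_weights)) {
    origins <- sample(names(cf$origin_weights), cf$n_accessions,
                      replace = TRUE, prob = cf$origin_weights)
  } else {
    origins <- rep("Unknown", cf$n_accessions)
  }
  names(origins) <- acc_ids

  a <- stats::rnorm(cf$n_years, 0, sqrt(cf$sigma2_year))
  names(a) <- years
  z <- stats::rnorm(cf$n_years)
  s2j <- cf$sigma2_e_mean * exp(cf$tau * z - cf$tau^2 / 2)
  names(s2j) <- years

  k <- sample.int(length(cf$years_per_accession_pmf), cf$n_accessions,
                  replace = TRUE, prob = cf$years_per_accession_pmf)
  yr_idx <- lapply(k, function(ki) sort(sample.int(cf$n_years, ki)))

  acc_i <- rep(seq_len(cf$n_accessions), k)
  yr_i <- unlist(yr_idx)
  N <- length(acc_i)
  e <- stats::rnorm(N, 0, sqrt(s2j[yr_i]))
  value <- cf$mu + g[acc_i] + a[yr_i] + e
  # a measurement must lie in the trait's admissible range; the vanishingly
  # rare residual draws that leave it are redrawn (truncation mass is
  # negligible at the default scales, so moments are unaffected)
  bad <- !.value_ok(rep(cf$trait, N), value)
  tries <- 0
  while (any(bad) && tries < 100) {
    e[bad] <- stats::rnorm(sum(bad), 0, sqrt(s2j[yr_i[bad]]))
    value[bad] <- cf$mu + g[acc_i[bad]] + a[yr_i[bad]] + e[bad]
    bad <- !.value_ok(rep(cf$trait, N), value)
    tries <- tries + 1
  }
  if (any(bad))
    stop("config places the trait mean too close to its admissible bound")

  n_out <- stats::rbinom(1, N, cf$contamination_rate)
  out_idx <- if (n_out > 0) sort(sample.int(N, n_out)) else integer(0)
  if (n_out > 0) {
    sgn <- sample(c(-1, 1), n_out, replace = TRUE)
    shift <- sgn * cf$shift_sd_multiplier * sqrt(s2j[yr_i[out_idx]])
    shifted <- value[out_idx] + shift
    # a gross error is still a recordable value: when the shift leaves the
    # trait's admissible range, it is applied in the other direction
    invalid <- !.value_ok(rep(cf$trait, length(shifted)), shifted)
    shifted[invalid] <- value[out_idx][invalid] - shift[invalid]
    value[out_idx] <- shifted
  }

  records <- data.frame(accession_id = acc_ids[acc_i],
                        year = years[yr_i], trait = cf$trait,
                        value = as.numeric(value), value_type = "single",
                        stringsAsFactors = FALSE)
  dataset <- phenotype_dataset(records, cf$growth_habit, provenance = origins,
                               year_window = range(years))
  mean_years <- mean(k)
  truth <- structure(list(
    genotype_effects = g, year_effects = a, per_year_error_variance = s2j,
    outlier_indices = record_key(records$accession_id[out_idx],
                                 records$year[out_idx], cf$trait),
    mean_years = mean_years,
    true_h2 = cf$sigma2_G / (cf$sigma2_G + cf$sigma2_e_mean / mean_years),
    config = cf), class = "truth_record")
  list(dataset = dataset, truth = truth)
}

# preset scales: design sizes from the collection descriptions, variance
# components on the scale of the uncorrected per-trait analyses
.historical_profiles <- function() {
  spring_others <- c(AUT = 1, HUN = 1, BGR = 1, ROU = 1, NLD = 1, GBR = 1,
                     DNK = 1, BEL = 1, KAZ = 1, YUG = 1) / 10 * 0.1717
  spring_w <- c(MEX = .2028, RUS = .0789, CSK = .0629, DEU = .0563,
                USA = .0432, JPN = .0404, FRA = .0310, CAN = .0272,
                CZE = .0254, POL = .0225, SYR = .0225, BRA = .0216,
                ITA = .0216, AUS = .0188, SWE = .0188, CHN = .0150,
                IND = .0141, UKR = .0131, ARG = .0122, CHE = .0122,
                TUR = .0122, PRT = .0113, ISR = .0103, Unknown = .0338,
                spring_others)
  winter_others <- c(ESP = 1, PRT = 1, FIN = 1, NOR = 1, IND = 1, JPN = 1,
                     ARG = 1, AUS = 1, CAN = 1, TUR = 1) / 10 * 0.0973
  winter_w <- c(DEU = .1309, FRA = .0856, CSK = .0790, CHE = .0481,
                HUN = .0473, CHN = .0430, CZE = .0427, GBR = .0421,
                UKR = .0421, AUT = .0409, RUS = .0409, POL = .0369,
                BGR = .0340, USA = .0337, ROU = .0239, SWE = .0210,
                ITA = .0187, SVK = .0179, YUG = .0156, NLD = .0150,
                KAZ = .0141, DNK = .0118, BEL = .0104, Unknown = .0075,
                winter_others)
  winter_pmf <- c(0.18, 0.24, 0.22, 0.12, 0.08, 0.05, 0.03, 0.02,
                  rep(0.06 / 20, 20))
  list(
    spring = list(
      n_accessions = 1000L, n_years = 30L,
      pmf = c(0.30, 0.12, 0.25, 0.10, 0.09, 0.06, 0.05, 0.03),
      origin_weights = spring_w / sum(spring_w),
      contamination_rate = 0.20, growth_habit = "spring",
      traits = list(HD = c(mu = 160, G = 17, Y = 51, E = 25),
                    PH = c(mu = 100, G = 192, Y = 75, E = 41),
                    TGW = c(mu = 40, G = 23, Y = 12.5, E = 9.4))),
    winter = list(
      n_accessions = 3400L, n_years = 60L,
      pmf = winter_pmf / sum(winter_pmf),
      origin_weights = winter_w / sum(winter_w),
      contamination_rate = 0.035, growth_habit = "winter",
      traits = list(HD = c(mu = 145, G = 23, Y = 28, E = 10),
                    PH = c(mu = 105, G = 300, Y = 50, E = 87),
                    TGW = c(mu = 42, G = 15, Y = 9.8, E = 9.4))))
}

#' Simulate a collection at historical-collection scale
#'
#' Convenience presets reproducing the scale of the two wheat collections:
#' spring (~1,000 accessions regenerated in 1-8 distinct years, most often 1
#' or 3) and winter (~3,400 accessions, up to ~28 distinct years, 2-3-year
#' cycles prevailing). All three traits (HD, PH, TGW) are generated on a
#' shared accession set with consistent provenance; each trait has its own
#' effects and year coverage, which yields per-trait missingness as in real
#' assay tables. Variance presets follow the uncorrected per-trait analysis
#' scales; contamination defaults to the flag-rate scale of each collection
#' (spring 20\%, winter 3.5\%) at 8 error-SD shifts.
#'
#' @param profile \code{"spring"} or \code{"winter"}.
#' @param seed integer seed; sub-seeds for origins and the three traits are
#'   derived deterministically from it.
#' @return list with \code{dataset} (all three traits) and \code{truth}
#'   (named list of per-trait \code{truth_record}s).
#' @export
simulate_historical <- function(profile = c("spring", "winter"), seed = 1L) {
  profile <- match.arg(profile)
  pf <- .historical_profiles()[[profile]]
  seeds <- derive_seeds(seed, 4)

  set.seed(seeds[1])
  origins <- sample(names(pf$origin_weights), pf$n_accessions,
                    replace = TRUE, prob = pf$origin_weights)

  sims <- lapply(seq_along(pf$traits), function(i) {
    tr <- names(pf$traits)[i]
    pr <- pf$traits[[i]]
    cfg <- sim_config(n_accessions = pf$n_accessions, n_years = pf$n_years,
                      years_per_accession_pmf = pf$pmf,
                      mu = pr[["mu"]], sigma2_G = pr[["G"]],
                      sigma2_year = pr[["Y"]], sigma2_e_mean = pr[["E"]],
                      tau = 0.3, contamination_rate = pf$contamination_rate,
                      shift_sd_multiplier = 8, origins = origins,
                      trait = tr, growth_habit = pf$growth_habit,
                      seed = seeds[1 + i])
    simulate_collection(cfg)
  })
  names(sims) <- names(pf$traits)

  records <- do.call(rbind, lapply(sims, function(s) s$dataset$records))
  prov <- sims[[1]]$dataset$provenance
  dataset <- phenotype_dataset(records, pf$growth_habit, provenance = prov,
                               year_window = c(2020L - pf$n_years + 1L, 2020L))
  list(dataset = dataset, truth = lapply(sims, `[[`, "truth"))
}
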