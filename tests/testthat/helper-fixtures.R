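# Small fixtures built in code, shared across test files.

# long-format records for a fully crossed accession x year grid
grid_records <- function(acc, years, values, trait = "PH") {
  stopifnot(length(values) == length(acc) * length(years))
  data.frame(accession_id = rep(acc, each = length(years)),
             year = rep(years, length(acc)), trait = trait,
             value = values, stringsAsFactors = FALSE)
}

# a modest non-orthogonal simulated dataset reused by several files
small_sim <- function(seed = 11, n_accessions = 120, contamination = 0,
                      tau = 0.3) {
  simulate_collection(sim_config(
    n_accessions = n_accessions, n_years = 10,
    years_per_accession_pmf = c(0.1, 0.2, 0.3, 0.25, 0.15),
    mu = 100, sigma2_G = 300, sigma2_year = 50, sigma2_e_mean = 85,
    tau = tau, contamination_rate = contamination,
    shift_sd_multiplier = 8, seed = seed))
}

# dense-matrix evaluation of -2 * restricted log-likelihood, the
# independent oracle for the sparse MME engine
dense_neg2reml <- function(y, acc, yr, s2G, s2A, s2e_by_year, g_random) {
  facc <- factor(acc); fyr <- factor(yr)
  n <- length(y)
  Zg <- stats::model.matrix(~ facc - 1)
  Za <- stats::model.matrix(~ fyr - 1)
  X <- if (g_random) matrix(1, n, 1) else Zg
  V <- diag(s2e_by_year[as.integer(fyr)], n) + s2A * tcrossprod(Za)
  if (g_random) V <- V + s2G * tcrossprod(Zg)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
  as.numeric((n - ncol(X)) * log(2 * pi) + determinant(V)$modulus +
               determinant(XVX)$modulus + crossprod(y, P %*% y))
}
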