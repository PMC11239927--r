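# Two-way mixed model for non-orthogonal accession x year data:
#
#   y_ij = mu + g_i + a_j + e_ij
#
# with the year effect a_j random and the residual variance specific to each
# year (diagonal heteroscedastic R). The accession effect g_i is fixed for
# outlier screening and BLUEs, or random for variance components and
# heritability. Restricted likelihood is evaluated through the sparse
# Henderson mixed-model equations and maximized numerically over
# log-variances; the sparsity pattern of the coefficient matrix is factored
# once and updated across evaluations.

#' Model specification
#'
#' @param genotype_role \code{"fixed"} (outliers, BLUEs) or \code{"random"}
#'   (variance components, heritability).
#' @param heteroscedastic estimate one residual variance per year
#'   (\code{TRUE}, default) or a single pooled variance.
#' @param min_records_per_year pre-fit pruning threshold: years with fewer
#'   records than this cannot support a year-specific error variance
#'   (default 2).
#' @param max_iter maximum optimizer iterations.
#' @param rel_tol relative convergence tolerance on the restricted
#'   log-likelihood.
#' @return a \code{model_spec} list.
#' @export
model_spec <- function(genotype_role = c("fixed", "random"),
                       heteroscedastic = TRUE, min_records_per_year = 2L,
                       max_iter = 200L, rel_tol = 1e-8) {
  genotype_role <- match.arg(genotype_role)
  stopifnot(rel_tol > 0, rel_tol < 1, min_records_per_year >= 1, max_iter >= 1)
  structure(list(genotype_role = genotype_role,
                 heteroscedastic = isTRUE(heteroscedastic),
                 min_records_per_year = as.integer(min_records_per_year),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol),
            class = "model_spec")
}

#' Remove records from sparsely observed years
#'
#' Drops, for one trait, every record falling in a year with fewer than
#' \code{spec$min_records_per_year} observations of that trait, so that each
#' retained year can support its own error variance. Records of other traits
#' are untouched.
#'
#' @param dataset a \code{\link{phenotype_dataset}}.
#' @param trait trait to prune.
#' @param spec a \code{\link{model_spec}}.
#' @return list with \code{dataset} (pruned) and \code{report} (years
#'   removed, removed records, affected accessions, counts).
#' @export
prune_sparse <- function(dataset, trait, spec = model_spec()) {
  trait <- match_trait(trait)
  r <- dataset$records
  sel <- r$trait == trait
  if (!any(sel)) stop("no records for trait ", trait)
  cnt <- table(r$year[sel])
  bad_years <- as.integer(names(cnt)[cnt < spec$min_records_per_year])
  drop <- sel & r$year %in% bad_years
  if (sum(sel) - sum(drop) == 0)
    stop("empty model: every ", trait, " record pruned at threshold ",
         spec$min_records_per_year)
  out <- dataset
  out$records <- r[!drop, , drop = FALSE]
  rownames(out$records) <- NULL
  out$provenance <- dataset$provenance
  report <- list(trait = trait, years_removed = sort(bad_years),
                 n_removed = sum(drop),
                 removed = r[drop, , drop = FALSE],
                 affected_accessions = sort(unique(r$accession_id[drop])),
                 n_before = sum(sel), n_after = sum(sel) - sum(drop))
  list(dataset = out, report = report)
}

# indicator matrix of a factor, n x nlevels
.ind <- function(f) {
  Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                       dims = c(length(f), nlevels(f)),
                       dimnames = list(NULL, levels(f)))
}

# -2 * restricted log-likelihood via the MME identity
#   log|V| + log|X' V^-1 X| = log|R| + log|G| + log|C|
#   y'Py = y' R^-1 y - rhs' C^-1 rhs
.neg2reml <- function(ltheta, env) {
  th <- exp(ltheta)
  s2 <- .unpack_theta(th, env)
  rinv <- 1 / s2$res_per_obs
  D <- Matrix::Diagonal(x = rinv)
  C <- Matrix::forceSymmetric(Matrix::crossprod(env$W, D %*% env$W) +
                              Matrix::Diagonal(x = s2$ginv_full))
  ch <- tryCatch(Matrix::update(env$chol0, C), error = function(e) NULL)
  if (is.null(ch)) return(1e12)
  logdetC <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  rhs <- Matrix::crossprod(env$W, rinv * env$y)
  sol <- Matrix::solve(ch, rhs)
  yPy <- sum(rinv * env$y^2) - sum(sol * rhs)
  val <- (env$n - env$p) * log(2 * pi) + sum(log(s2$res_per_obs)) +
    s2$logdetG + logdetC + yPy
  if (!is.finite(val)) return(1e12)
  env$last <- list(ch = ch, sol = as.numeric(sol), rinv = rinv, s2 = s2)
  val
}

# theta layout: [sigma2_G?] [sigma2_year?] [residual variances...]
.unpack_theta <- function(th, env) {
  i <- 0
  ginv <- numeric(0); logdetG <- 0
  if (env$g_random) {
    i <- i + 1
    ginv <- c(ginv, rep(1 / th[i], env$n_g))
    logdetG <- logdetG + env$n_g * log(th[i])
  }
  if (env$has_year_re) {
    i <- i + 1
    ginv <- c(ginv, rep(1 / th[i], env$n_yr))
    logdetG <- logdetG + env$n_yr * log(th[i])
  }
  res <- th[(i + 1):length(th)]
  res_per_obs <- if (env$hetero) res[env$yr_int] else rep(res, env$n)
  list(ginv_full = c(rep(0, env$p), ginv), logdetG = logdetG,
       res = res, res_per_obs = res_per_obs,
       sigma2_G = if (env$g_random) th[1] else NA_real_,
       sigma2_year = if (env$has_year_re) th[1 + env$g_random] else NA_real_)
}

#' Fit the accession-by-year mixed model by REML
#'
#' Maximizes the restricted log-likelihood of
#' y = mu + g_i + a_j + e_ij over the variance parameters (year variance,
#' per-year or pooled error variances, and the genetic variance when the
#' genotype is random), then solves the mixed-model equations at the
#' converged variances for effect estimates, BLUPs, conditional residuals
#' and leverages. With the genotype fixed, the design is parameterized by
#' accession cell means, so every reported genotype estimate is the
#' estimable adjusted mean mu + g_i regardless of constraint choice.
#'
#' Non-convergence is reported through \code{converged = FALSE}, never
#' raised. Variance estimates are bounded below by 1e-10 of the total
#' variance; parameters ending on that floor are listed in
#' \code{varcomp$pinned} and are effectively zero. Single-year data with a
#' fixed genotype drop the year effect (its variance is not estimable) and
#' the fit conditions on that year.
#'
#' @param dataset a \code{\link{phenotype_dataset}}, normally pruned by
#'   \code{\link{prune_sparse}}.
#' @param trait trait to fit.
#' @param spec a \code{\link{model_spec}}.
#' @return object of class \code{reml_fit}: \code{mu}, named
#'   \code{genotype_estimates} (adjusted means when fixed, BLUPs when
#'   random), \code{year_effects} (BLUPs), \code{residuals} and
#'   \code{leverages} keyed by record, \code{varcomp} (\code{sigma2_G},
#'   \code{sigma2_year}, \code{per_year_error}, \code{sigma2_e_mean} = their
#'   unweighted mean), \code{log_reml}, \code{converged}, \code{n_iter}.
#' @export
reml_fit <- function(dataset, trait, spec = model_spec()) {
  trait <- match_trait(trait)
  r <- dataset$records[dataset$records$trait == trait, , drop = FALSE]
  if (!nrow(r)) stop("no records for trait ", trait)

  facc <- factor(r$accession_id)
  fyr <- factor(r$year)
  y <- r$value
  n <- length(y)
  n_g <- nlevels(facc)
  n_yr <- nlevels(fyr)
  g_random <- spec$genotype_role == "random"
  has_year_re <- n_yr > 1
  if (!has_year_re && g_random)
    stop("year variance requires >= 2 years when the genotype is random")

  if (spec$heteroscedastic) {
    per_yr <- table(fyr)
    if (any(per_yr < spec$min_records_per_year))
      warning("year(s) with fewer than min_records_per_year records: ",
              "prune_sparse() first for stable per-year variances")
  }

  if (!g_random && n_yr == 1) return(.saturated_fit(r, facc, trait, spec))

  p <- if (g_random) 1L else n_g
  X <- if (g_random) Matrix::Matrix(1, n, 1, sparse = TRUE) else .ind(facc)
  Zs <- list()
  if (g_random) Zs <- c(Zs, list(.ind(facc)))
  if (has_year_re) Zs <- c(Zs, list(.ind(fyr)))
  W <- do.call(cbind, c(list(X), Zs))

  n_res <- if (spec$heteroscedastic) n_yr else 1L
  n_par <- g_random + has_year_re + n_res
  if (n - p < n_par)
    stop("insufficient degrees of freedom: ", n, " records, ", p,
         " fixed effects, ", n_par, " variance parameters")

  vtot <- stats::var(y)
  if (!is.finite(vtot) || vtot <= 0) vtot <- max(mean(y^2), 1)
  floor_v <- 1e-10 * vtot

  env <- new.env(parent = emptyenv())
  env$W <- W; env$y <- y; env$n <- n; env$p <- p
  env$n_g <- n_g; env$n_yr <- n_yr
  env$g_random <- g_random; env$has_year_re <- has_year_re
  env$hetero <- spec$heteroscedastic
  env$yr_int <- as.integer(fyr)
  C0 <- Matrix::forceSymmetric(Matrix::crossprod(W) +
                               Matrix::Diagonal(ncol(W)))
  env$chol0 <- Matrix::Cholesky(C0, LDL = FALSE, perm = TRUE)

  n_random_terms <- g_random + has_year_re
  start <- c(rep(vtot / (n_random_terms + 1), n_random_terms),
             rep(vtot / (n_random_terms + 1), n_res))
  lower <- rep(log(floor_v), n_par)
  upper <- rep(log(1e6 * vtot), n_par)

  obj0 <- .neg2reml(log(start), env)
  opt <- stats::nlminb(log(start), .neg2reml, env = env,
                       lower = lower, upper = upper,
                       control = list(iter.max = spec$max_iter,
                                      eval.max = 50L * spec$max_iter,
                                      rel.tol = spec$rel_tol))
  obj_final <- .neg2reml(opt$par, env)  # refresh env$last at the optimum
  # boundary solutions (a component pinned at the floor) commonly end with
  # nlminb's "false convergence"; only running out of iterations counts as
  # a genuine failure, and the objective must not have degraded
  hit_limit <- grepl("limit", opt$message %||% "", ignore.case = TRUE)
  converged <- !hit_limit && obj_final <= obj0 + 1e-6
  last <- env$last
  th <- exp(opt$par)
  pinned_idx <- which(opt$par <= log(floor_v) + 1e-6)

  beta <- last$sol[seq_len(p)]
  u <- last$sol[-seq_len(p)]
  fitted <- as.numeric(W %*% last$sol)
  resid <- y - fitted
  keys <- record_key(r$accession_id, r$year, trait)
  names(resid) <- keys

  # leverage: diag of the observation-space projection H = W C^-1 W' R^-1
  WCiWt_diag <- Matrix::rowSums(W * Matrix::t(Matrix::solve(last$ch, Matrix::t(W))))
  leverages <- pmin(pmax(as.numeric(WCiWt_diag) * last$rinv, 0), 1 - 1e-12)
  names(leverages) <- keys

  if (env$hetero) {
    per_year_error <- stats::setNames(last$s2$res, levels(fyr))
  } else {
    per_year_error <- stats::setNames(rep(last$s2$res, n_yr), levels(fyr))
  }
  varcomp <- list(sigma2_G = last$s2$sigma2_G,
                  sigma2_year = if (has_year_re) last$s2$sigma2_year else NA_real_,
                  per_year_error = per_year_error,
                  sigma2_e_mean = mean(per_year_error),
                  year_variance_estimable = has_year_re,
                  pinned = names(.theta_names(env))[pinned_idx])

  if (g_random) {
    mu <- beta[1]
    genotype_estimates <- stats::setNames(u[seq_len(n_g)], levels(facc))
    year_effects <- if (has_year_re)
      stats::setNames(u[n_g + seq_len(n_yr)], levels(fyr)) else numeric(0)
    genotype_se <- NULL
  } else {
    genotype_estimates <- stats::setNames(beta, levels(facc))
    mu <- mean(genotype_estimates)
    year_effects <- if (has_year_re)
      stats::setNames(u[seq_len(n_yr)], levels(fyr)) else numeric(0)
    Ep <- Matrix::sparseMatrix(i = seq_len(p), j = seq_len(p), x = 1,
                               dims = c(ncol(W), p))
    S <- Matrix::solve(last$ch, Ep)
    genotype_se <- stats::setNames(sqrt(pmax(S[cbind(seq_len(p), seq_len(p))], 0)),
                                   levels(facc))
  }

  structure(list(mu = mu, genotype_estimates = genotype_estimates,
                 genotype_se = genotype_se, year_effects = year_effects,
                 residuals = resid, leverages = leverages, varcomp = varcomp,
                 log_reml = -0.5 * obj_final, log_reml_start = -0.5 * obj0,
                 converged = converged, n_iter = opt$iterations,
                 genotype_role = spec$genotype_role,
                 heteroscedastic = spec$heteroscedastic,
                 trait = trait, spec = spec, n_records = n,
                 record_years = stats::setNames(r$year, keys),
                 record_table = r),
            class = "reml_fit")
}

# one year, genotype fixed: one record per accession, the model is
# saturated. BLUEs equal the observed values conditional on that year; no
# variance is estimable and no residual information exists.
.saturated_fit <- function(r, facc, trait, spec) {
  y <- r$value
  keys <- record_key(r$accession_id, r$year, trait)
  yr_lab <- as.character(r$year[1])
  est <- stats::setNames(y, as.character(facc))
  varcomp <- list(sigma2_G = NA_real_, sigma2_year = NA_real_,
                  per_year_error = stats::setNames(NA_real_, yr_lab),
                  sigma2_e_mean = NA_real_,
                  year_variance_estimable = FALSE, pinned = character(0))
  structure(list(mu = mean(est), genotype_estimates = est,
                 genotype_se = stats::setNames(rep(NA_real_, length(est)),
                                               names(est)),
                 year_effects = numeric(0),
                 residuals = stats::setNames(rep(0, length(y)), keys),
                 leverages = stats::setNames(rep(1 - 1e-12, length(y)), keys),
                 varcomp = varcomp, log_reml = NA_real_,
                 log_reml_start = NA_real_, converged = TRUE, n_iter = 0L,
                 genotype_role = "fixed",
                 heteroscedastic = spec$heteroscedastic, trait = trait,
                 spec = spec, n_records = length(y),
                 record_years = stats::setNames(r$year, keys),
                 record_table = r, saturated = TRUE),
            class = "reml_fit")
}

.theta_names <- function(env) {
  nm <- character(0)
  if (env$g_random) nm <- c(nm, "sigma2_G")
  if (env$has_year_re) nm <- c(nm, "sigma2_year")
  nm <- c(nm, if (env$hetero) paste0("sigma2_e_", seq_len(env$n_yr))
          else "sigma2_e")
  stats::setNames(seq_along(nm), nm)
}

#' @method print reml_fit
#' @export
print.reml_fit <- function(x, ...) {
  cat("reml_fit: trait ", x$trait, ", genotype ", x$genotype_role,
      ", ", if (x$heteroscedastic) "per-year" else "pooled",
      " residual variance\n", sep = "")
  cat("  ", x$n_records, " records, ", length(x$genotype_estimates),
      " accessions, ", length(x$varcomp$per_year_error), " years\n", sep = "")
  cat("  log restricted likelihood ", format(x$log_reml),
      if (x$converged) " (converged, " else " (NOT converged, ",
      x$n_iter, " iterations)\n", sep = "")
  if (!is.na(x$varcomp$sigma2_G))
    cat("  sigma2_G = ", format(x$varcomp$sigma2_G), "\n", sep = "")
  cat("  sigma2_year = ", format(x$varcomp$sigma2_year),
      ", mean sigma2_e = ", format(x$varcomp$sigma2_e_mean), "\n", sep = "")
  invisible(x)
}

#' Per-accession BLUEs with standard errors
#'
#' Extracts the estimable adjusted mean mu + g_i for every accession in a
#' genotype-fixed fit, with standard errors from the inverse mixed-model
#' coefficient matrix.
#'
#' @param fit a converged genotype-fixed \code{\link{reml_fit}}.
#' @return data.frame with columns \code{accession_id}, \code{blue},
#'   \code{se}, one row per accession.
#' @export
compute_blues <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (fit$genotype_role != "fixed")
    stop("BLUEs require a genotype-fixed fit; a random-genotype fit yields BLUPs")
  if (!fit$converged) stop("fit did not converge; BLUEs not reported")
  data.frame(accession_id = names(fit$genotype_estimates),
             blue = unname(fit$genotype_estimates),
             se = unname(fit$genotype_se),
             stringsAsFactors = FALSE)
}
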