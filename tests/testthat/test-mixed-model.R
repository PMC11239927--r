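test_that("pruning removes exactly the records of under-observed years", {
  rec <- rbind(grid_records(c("A", "B", "C"), 2001:2003, rnorm(9, 100, 5)),
               data.frame(accession_id = "D", year = 2010L, trait = "PH",
                          value = 100))
  ds <- phenotype_dataset(rec, "winter")
  pr <- prune_sparse(ds, "PH", model_spec(min_records_per_year = 2))
  expect_equal(pr$report$n_removed, 1)
  expect_equal(pr$report$years_removed, 2010L)
  expect_equal(pr$report$affected_accessions, "D")
  # threshold 1 is the identity
  pr1 <- prune_sparse(ds, "PH", model_spec(min_records_per_year = 1))
  expect_equal(nrow(pr1$dataset$records), nrow(ds$records))
  # brute-force count on a simulated set
  sim <- small_sim(seed = 13, n_accessions = 40)
  cnt <- table(sim$dataset$records$year)
  expected <- sum(cnt[cnt < 2])
  pr2 <- prune_sparse(sim$dataset, "PH", model_spec(min_records_per_year = 2))
  expect_equal(pr2$report$n_removed, unname(expected))
})

test_that("balanced two-accession design gives the exact mean contrast", {
  rec <- data.frame(accession_id = rep(c("A", "B"), each = 2),
                    year = rep(c(2001L, 2002L), 2), trait = "PH",
                    value = c(10, 12, 14, 16))
  ds <- phenotype_dataset(rec, "winter")
  fit <- reml_fit(ds, "PH", model_spec("fixed", heteroscedastic = FALSE))
  expect_true(fit$converged)
  est <- fit$genotype_estimates
  expect_equal(unname(est["B"] - est["A"]), 4, tolerance = 1e-8)
  blues <- compute_blues(fit)
  expect_equal(blues$blue, unname(est[blues$accession_id]))
})

test_that("shift and scale equivariance hold", {
  sim <- small_sim(seed = 23, n_accessions = 50)
  sp <- model_spec("fixed")
  f0 <- reml_fit(sim$dataset, "PH", sp)

  shifted <- sim$dataset
  shifted$records$value <- shifted$records$value + 50
  f1 <- reml_fit(shifted, "PH", sp)
  expect_equal(f1$genotype_estimates, f0$genotype_estimates + 50,
               tolerance = 1e-4)
  expect_equal(f1$varcomp$per_year_error, f0$varcomp$per_year_error,
               tolerance = 1e-4)

  scaled <- sim$dataset
  scaled$records$value <- scaled$records$value * 3
  f2 <- reml_fit(scaled, "PH", sp)
  expect_equal(f2$varcomp$sigma2_year, 9 * f0$varcomp$sigma2_year,
               tolerance = 1e-3)
  expect_equal(f2$varcomp$per_year_error, 9 * f0$varcomp$per_year_error,
               tolerance = 1e-3)
  z0 <- standardized_scores(f0)
  z2 <- standardized_scores(f2)
  expect_equal(z2$z, z0$z, tolerance = 1e-4)
})

test_that("solver matches a dense grid search of the restricted likelihood", {
  set.seed(42)
  acc <- rep(c("A", "B", "C"), each = 3)[-5]
  yr <- rep(2001:2003, 3)[-5]
  y <- rnorm(8, 50, 5)
  ds <- phenotype_dataset(
    data.frame(accession_id = acc, year = yr, trait = "PH", value = y),
    "winter")
  fit <- reml_fit(ds, "PH", model_spec("random", heteroscedastic = FALSE))
  expect_true(fit$converged)

  # independent dense-V oracle over a 3-D grid, refined once
  grid_opt <- function(centers, widths, m = 11) {
    vals <- expand.grid(
      s2G = exp(seq(log(centers[1] / widths), log(centers[1] * widths), length.out = m)),
      s2A = exp(seq(log(centers[2] / widths), log(centers[2] * widths), length.out = m)),
      s2e = exp(seq(log(centers[3] / widths), log(centers[3] * widths), length.out = m)))
    obj <- apply(vals, 1, function(p)
      dense_neg2reml(y, acc, yr, p[1], p[2], rep(p[3], 3), TRUE))
    unlist(vals[which.min(obj), ])
  }
  v0 <- var(y)
  best <- grid_opt(c(v0, v0, v0) / 3, widths = 1e4, m = 15)
  best <- grid_opt(best, widths = 4, m = 15)
  best <- grid_opt(best, widths = 1.3, m = 15)
  best <- grid_opt(best, widths = 1.05, m = 15)

  got <- c(fit$varcomp$sigma2_G, fit$varcomp$sigma2_year,
           fit$varcomp$sigma2_e_mean)
  # compare on the likelihood scale and, for non-degenerate components,
  # the parameter scale
  o_grid <- dense_neg2reml(y, acc, yr, best[1], best[2], rep(best[3], 3), TRUE)
  o_fit <- -2 * fit$log_reml
  expect_lte(o_fit, o_grid + 1e-3)
  for (i in 1:3) {
    if (got[i] > 1e-3 * v0)
      expect_equal(unname(got[i]), unname(best[i]), tolerance = 1e-2)
  }
})

test_that("engine objective equals the dense restricted likelihood, heteroscedastic", {
  sim <- small_sim(seed = 29, n_accessions = 15)
  fit <- reml_fit(sim$dataset, "PH", model_spec("fixed", heteroscedastic = TRUE))
  r <- sim$dataset$records
  vc <- fit$varcomp
  o <- dense_neg2reml(r$value, r$accession_id, factor(r$year),
                      NA, vc$sigma2_year,
                      unname(vc$per_year_error[levels(factor(r$year))]),
                      g_random = FALSE)
  expect_equal(-2 * fit$log_reml, o, tolerance = 1e-6)
})

test_that("balanced homoscedastic REML matches closed-form ANOVA estimators", {
  set.seed(8)
  acc <- sprintf("G%02d", 1:8)
  years <- 2001:2006
  g <- rnorm(8, 0, 6); a <- rnorm(6, 0, 4)
  rec <- grid_records(acc, years,
                      100 + rep(g, each = 6) + rep(a, 8) + rnorm(48, 0, 2))
  ds <- phenotype_dataset(rec, "winter")
  fit <- reml_fit(ds, "PH", model_spec("random", heteroscedastic = FALSE))

  m <- matrix(rec$value, nrow = 8, byrow = TRUE)
  A <- nrow(m); B <- ncol(m)
  msa <- B * var(rowMeans(m))
  msb <- A * var(colMeans(m))
  res <- m - outer(rowMeans(m), colMeans(m), "+") + mean(m)
  mse <- sum(res^2) / ((A - 1) * (B - 1))
  expect_equal(fit$varcomp$sigma2_G, (msa - mse) / B, tolerance = 1e-4)
  expect_equal(fit$varcomp$sigma2_year, (msb - mse) / A, tolerance = 1e-4)
  expect_equal(fit$varcomp$sigma2_e_mean, mse, tolerance = 1e-4)
  # restricted likelihood never below its starting value
  expect_gte(fit$log_reml, fit$log_reml_start)
})

test_that("heteroscedastic fit agrees with nlme::lme varIdent cross-check", {
  skip_if_not_installed("nlme")
  sim <- small_sim(seed = 37, n_accessions = 40, tau = 0.6)
  fit <- reml_fit(sim$dataset, "PH", model_spec("fixed", heteroscedastic = TRUE))
  r <- sim$dataset$records
  d <- data.frame(y = r$value, acc = factor(r$accession_id),
                  yr = factor(r$year))
  m <- nlme::lme(y ~ acc - 1, random = ~ 1 | yr,
                 weights = nlme::varIdent(form = ~ 1 | yr), data = d,
                 control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                            msMaxIter = 200))
  s2_yr_nlme <- nlme::getVarCov(m)[1, 1]
  expect_equal(fit$varcomp$sigma2_year, s2_yr_nlme, tolerance = 0.02)
  sds <- coef(m$modelStruct$varStruct, uncons = FALSE, allCoef = TRUE)
  s2e_nlme <- (m$sigma * sds[levels(d$yr)])^2
  expect_equal(unname(fit$varcomp$per_year_error[levels(d$yr)]),
               unname(s2e_nlme), tolerance = 0.05)
})

test_that("single-record accession BLUE solves the mixed-model equations", {
  set.seed(55)
  rec <- rbind(grid_records(c("A", "B", "C", "D"), 2001:2004,
                            rnorm(16, 100, 5)),
               data.frame(accession_id = "E", year = 2002L, trait = "PH",
                          value = 130))
  ds <- phenotype_dataset(rec, "winter")
  fit <- reml_fit(ds, "PH", model_spec("fixed", heteroscedastic = FALSE))
  # dense GLS oracle at the converged variances
  r <- ds$records
  facc <- factor(r$accession_id); fyr <- factor(r$year)
  X <- stats::model.matrix(~ facc - 1)
  V <- diag(fit$varcomp$sigma2_e_mean, nrow(r)) +
    fit$varcomp$sigma2_year * tcrossprod(stats::model.matrix(~ fyr - 1))
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, r$value)))
  expect_equal(unname(fit$genotype_estimates), as.numeric(beta),
               tolerance = 1e-6)
  # E's BLUE is its value minus the year-2002 BLUP
  expect_equal(unname(fit$genotype_estimates["E"]),
               130 - unname(fit$year_effects["2002"]), tolerance = 1e-6)
  # standard errors from the dense inverse
  se <- sqrt(diag(solve(crossprod(X, solve(V, X)))))
  expect_equal(unname(fit$genotype_se), unname(se), tolerance = 1e-6)
})

test_that("BLUEs track true genotype values in simulation", {
  sim <- simulate_collection(sim_config(
    n_accessions = 300, n_years = 15,
    years_per_accession_pmf = c(0.1, 0.2, 0.3, 0.25, 0.15),
    sigma2_G = 400, sigma2_year = 50, sigma2_e_mean = 85, tau = 0.3,
    seed = 61))
  fit <- reml_fit(sim$dataset, "PH", model_spec("fixed"))
  blues <- compute_blues(fit)
  g <- sim$truth$genotype_effects[blues$accession_id]
  rho <- cor(blues$blue, g)
  # analytic reliability bound: r2_i ~ s2G / (s2G + s2e / n_i)
  ni <- table(sim$dataset$records$accession_id)[blues$accession_id]
  rel <- 400 / (400 + 85 / as.numeric(ni))
  expect_gt(rho, sqrt(mean(rel)) - 0.1)
  expect_gt(rho, 0.8)
})

test_that("failure paths are contracts, not crashes", {
  rec <- data.frame(accession_id = c("A", "B"), year = c(2001L, 2001L),
                    trait = "PH", value = c(10, 20))
  ds <- phenotype_dataset(rec, "winter")
  expect_error(reml_fit(ds, "PH", model_spec("random")))
  expect_error(compute_blues(reml_fit(small_sim(seed = 3, n_accessions = 30)$dataset,
                                      "PH", model_spec("random"))),
               "BLUP")
  expect_error(prune_sparse(ds, "PH", model_spec(min_records_per_year = 5)),
               "empty model")
})

test_that("single-year data with fixed genotype conditions on the year", {
  rec <- data.frame(accession_id = sprintf("A%d", 1:6), year = 2001L,
                    trait = "PH", value = c(95, 100, 105, 98, 102, 99))
  ds <- phenotype_dataset(rec, "winter")
  fit <- reml_fit(ds, "PH", model_spec("fixed"))
  expect_true(is.na(fit$varcomp$sigma2_year))
  expect_false(fit$varcomp$year_variance_estimable)
  expect_equal(unname(fit$genotype_estimates), rec$value, tolerance = 1e-6)
})
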