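# minimal genotype-fixed fit stand-in: standardized_scores only touches
# residuals, per-year error variances, record keys and the record table
fake_fit <- function(resid, year = 2001L, sigma2 = 1) {
  keys <- record_key(sprintf("A%02d", seq_along(resid)), year, "PH")
  structure(list(genotype_role = "fixed", converged = TRUE,
                 residuals = stats::setNames(resid, keys),
                 leverages = stats::setNames(rep(0.1, length(resid)), keys),
                 varcomp = list(per_year_error = stats::setNames(sigma2,
                                                                 year)),
                 record_years = stats::setNames(rep(year, length(resid)),
                                                keys),
                 record_table = data.frame(
                   accession_id = sprintf("A%02d", seq_along(resid)),
                   year = year, value = resid)),
            class = "reml_fit")
}

test_that("gross residual z matches the hand-worked median/MAD arithmetic", {
  r <- c(-0.6, -0.4, -0.2, -0.1, 0, 0.1, 0.3, 0.5, 9)
  sc <- standardized_scores(fake_fit(r))
  # median 0, MAD 0.3, rescale 1.4826
  z_expected <- 9 / (1.4826 * 0.3)
  i <- which.max(sc$z)
  expect_equal(sc$z[i], z_expected, tolerance = 1e-10)
  expect_equal(sc$p[i], 2 * pnorm(-z_expected), tolerance = 1e-12)
})

test_that("scores are invariant under affine maps of the residual scale", {
  set.seed(71)
  r <- rnorm(40)
  z0 <- standardized_scores(fake_fit(r))$z
  z1 <- standardized_scores(fake_fit(3.7 * r + 11))$z
  expect_equal(z1, z0, tolerance = 1e-10)
})

test_that("zero-spread residuals take the degenerate path with zero flags", {
  sc <- standardized_scores(fake_fit(rep(0, 12)))
  expect_true(attr(sc, "degenerate"))
  expect_equal(nrow(sc), 0)
  expect_length(holm_flags(stats::setNames(sc$p, sc$key)), 0)
})

test_that("Holm step-down follows the hand-worked thresholds", {
  p <- c(a = 0.001, b = 0.02, c = 0.04)
  expect_setequal(holm_flags(p, alpha = 0.05), c("a", "b", "c"))
  # 0.02 fails its threshold 0.025? no: 0.02 <= 0.025 passes; push it past
  p2 <- c(a = 0.001, b = 0.03, c = 0.04)
  expect_setequal(holm_flags(p2, alpha = 0.05), "a")
  expect_length(holm_flags(c(x = 1, y = 1, z = 1)), 0)
  expect_length(holm_flags(stats::setNames(numeric(0), character(0))), 0)
})

test_that("Holm flags are monotone in alpha", {
  set.seed(73)
  for (i in 1:20) {
    p <- stats::setNames(runif(50)^3, sprintf("k%02d", 1:50))
    f1 <- holm_flags(p, 0.01)
    f5 <- holm_flags(p, 0.05)
    expect_true(all(f1 %in% f5))
  }
})

test_that("report arithmetic identities hold on every run", {
  sim <- small_sim(seed = 83, n_accessions = 80, contamination = 0.05)
  co <- correct_outliers(sim$dataset, "PH")
  rp <- co$report
  expect_equal(rp$corrected_size, rp$n_records_pruned - rp$n_outliers)
  expect_equal(rp$outlier_pct,
               round(100 * rp$n_outliers / rp$n_records_pruned, 2))
  expect_equal(nrow(co$dataset$records[co$dataset$records$trait == "PH", ]),
               rp$corrected_size)
  # flagged table sorted by adjusted p
  expect_false(is.unsorted(co$report$flagged$p_holm))
})

test_that("injected gross errors are recovered; clean records rarely flagged", {
  res <- sapply(1:2, function(s) {
    sim <- simulate_collection(sim_config(n_accessions = 200,
                                          contamination_rate = 0.03,
                                          shift_sd_multiplier = 8,
                                          seed = 90 + s))
    co <- correct_outliers(sim$dataset, "PH")
    inj <- sim$truth$outlier_indices
    fl <- co$report$flagged$key
    c(sens = length(intersect(fl, inj)) / length(inj),
      fp = length(setdiff(fl, inj)) /
        (co$report$n_records_pruned - length(inj)))
  })
  expect_gt(mean(res["sens", ]), 0.8)
  expect_lt(mean(res["fp", ]), 0.01)
})

test_that("re-scanning the enhanced data does not flag more records", {
  sim <- small_sim(seed = 97, n_accessions = 80, contamination = 0.04)
  co1 <- correct_outliers(sim$dataset, "PH")
  co2 <- correct_outliers(co1$dataset, "PH")
  expect_lte(co2$report$n_outliers, co1$report$n_outliers)
})

test_that("other traits pass through the correction untouched", {
  sim_ph <- small_sim(seed = 101, n_accessions = 50, contamination = 0.05)
  hd <- data.frame(accession_id = "X1", year = 2015:2018, trait = "HD",
                   value = c(150, 152, 149, 151), value_type = "single")
  ds <- phenotype_dataset(rbind(sim_ph$dataset$records, hd), "winter")
  co <- correct_outliers(ds, "PH")
  expect_equal(co$dataset$records[co$dataset$records$trait == "HD", ]$value,
               hd$value)
})

test_that("a failed screening fit is reported, not raised", {
  rec <- data.frame(accession_id = c("A", "B", "A", "B"),
                    year = rep(c(2001L, 2002L), each = 2), trait = "PH",
                    value = c(10, 12, 11, 13))
  ds <- phenotype_dataset(rec, "winter")
  # 4 records, 2 accessions: heteroscedastic fit lacks degrees of freedom
  co <- correct_outliers(ds, "PH", model_spec(heteroscedastic = TRUE,
                                              min_records_per_year = 2))
  if (!isTRUE(co$report$fit_ok)) {
    expect_null(co$dataset)
    expect_false(co$report$fit_ok)
  } else {
    succeed("small design happened to fit")
  }
})
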