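---
title: "Curating multi-year genebank phenotype trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multi-year genebank phenotype trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genebanks regenerate their seed stocks by growing accessions in field plots
every few years, and score agronomic traits — here heading date (HD, days
since January 1), plant height (PH, cm) and thousand grain weight (TGW,
g) — at each regeneration. Over decades this produces a large but awkward
record: each accession is observed in its own small set of years
(non-orthogonal design), growing conditions shift from year to year, and
measurement quality varies, so raw accession means are biased by year
effects and contaminated by occasional gross errors. phenocurate
implements a curation pipeline for such data: a mixed model that separates
genetic and year signal under year-specific error variances, a robust
residual screen that removes gross errors, per-accession adjusted means
(BLUEs), and entry-mean heritability as the headline quality metric.

## Model

Each observation is modelled as

$$y_{ij} = \mu + g_i + a_j + e_{ij},$$

where $g_i$ is the effect of accession $i$, $a_j \sim N(0, \sigma^2_a)$ a
random year effect, and $e_{ij} \sim N(0, \sigma^2_j)$ a residual whose
variance is specific to year $j$. One observation exists per accession and
year, so no interaction or plot term is identifiable. The model is fitted
in two configurations:

* **genotype fixed** — for outlier screening and BLUEs: every reported
  genotype quantity is the estimable adjusted mean $\mu + g_i$ (the
  internal parameterization is by accession cell means, so no constraint
  choice leaks into output);
* **genotype random** ($g_i \sim N(0, \sigma^2_G)$) — for variance
  components and heritability.

Variance parameters maximize the restricted likelihood. The implementation
evaluates $-2\,\ell_R$ through the sparse Henderson mixed-model equations,
using the identity
$\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C|$
with $C$ the MME coefficient matrix, and maximizes over log-variances with
a bounded quasi-Newton search (`nlminb`). The sparsity pattern of $C$ is
analysed once and its Cholesky factor updated at every evaluation. Effect
estimates, year BLUPs, conditional residuals and observation leverages are
read off the factorization at the converged variances.

### Numerical choices

* Convergence: relative change of the restricted log-likelihood below
  `rel_tol` (default 1e-8), at most `max_iter` = 200 iterations. The
  property "restricted likelihood at the solution at least its value at
  the starting point" is asserted in the test suite.
* Starting values: the total variance split equally across the active
  components; per-year error variances start at the common value.
* Variance floor: $10^{-10}\times$ total variance. A component ending on
  the floor is reported in `varcomp$pinned` and read as effectively zero.
  Boundary solutions commonly terminate with the optimizer's "false
  convergence" message; the fit is accepted whenever the search did not
  exhaust its iteration budget and the objective did not degrade.
* Per-year variances need support: `prune_sparse()` removes records in
  years with fewer than `min_records_per_year` (default 2) observations of
  the trait, so every retained year can carry its own $\sigma^2_j$. The
  pruning rule is this package's choice of how to make the
  heteroscedastic model well-posed.
* Degenerate designs are contracts, not crashes: single-year data with a
  fixed genotype are saturated (BLUE = observed value, conditional on that
  year, no variance estimable — flagged, not raised), and a fit without
  enough residual degrees of freedom errors with a message naming the
  counts.

## Outlier screen

From a converged genotype-fixed fit, each residual is standardized by its
year's error SD, $r_k = e_k/\hat\sigma_{j(k)}$. The scores are centred on
their median and rescaled by $1.4826\times$MAD (the constant that makes
the MAD estimate an SD under normality):

$$z_k = \frac{r_k - \mathrm{med}(r)}{1.4826\,\mathrm{MAD}(r)},\qquad
  p_k = 2\{1 - \Phi(|z_k|)\}.$$

Records surviving the Bonferroni–Holm step-down at $\alpha = 0.05$
(configurable) are flagged and removed in a single pass, producing the
enhanced dataset; the scan is deliberately not iterated, matching the
one-shot removal the deposited workflow describes. Two wordings of the
routine circulate — plain standardization and internal studentization —
so both are implemented: the default divides by the error SD only, and
`studentized = TRUE` additionally divides by $\sqrt{1-h_k}$ with $h_k$
the observation leverage. When at least half the residuals coincide the
MAD is zero; the screen then reports a degenerate-spread condition and
flags nothing.

## Heritability

Entry-mean heritability summarises how repeatable accession means are over
regeneration years:

$$h^2 = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_e / \overline{Y}},$$

with $\sigma^2_e$ the average of the per-year error variances and
$\overline{Y}$ the mean number of distinct test years per accession.
$\sigma^2_e$ is by default the unweighted mean over years — one value per
regeneration year, matching the verbal definition of an average error
variance *across years* — with a record-weighted alternative behind
`error_mean = "weighted"`. $\overline{Y}$ is always computed on the same
records the fit used, so the enhanced-stage $h^2$ uses post-removal year
counts. A non-converged fit, a design without residual degrees of
freedom, or a solution with both variances on the floor yields
`fit_ok = FALSE` with a diagnosis instead of a number — with historical
data some trait/stage combinations genuinely cannot support the model,
and the pipeline treats that as a reportable state.

## The simulator

`simulate_collection()` generates single-trait collections under exactly
the fitted model: accession effects $N(0, \sigma^2_G)$, year effects
$N(0, \sigma^2_a)$, and per-year error variances
$\sigma^2_j = \sigma^2_e \exp(\tau z_j - \tau^2/2)$ — lognormal, strictly
positive, heavy-tailed like real multi-decade trials, with the
$-\tau^2/2$ term pinning the mean at $\sigma^2_e$. Each accession is
observed in $k$ distinct years ($k$ from a configurable distribution),
years assigned uniformly. Gross errors are symmetric location shifts of
$\pm s\,\sigma_j$ on a Binomial subset of records; if a shift would leave
the trait's admissible range the shift is applied in the other direction,
and the vanishingly rare clean draws outside the range are redrawn. All
draws come from one seeded stream in a fixed order, so datasets are fully
reproducible, and every realization is returned together with its ground
truth (effects, per-year variances, shifted-record keys, realized
$h^2$).

### Default validation conditions

The default configuration is the package's reference validation design:
500 accessions tested in 20 years, on average 5.9 distinct years per
accession (about 3,000 records), $\sigma^2_G = 300$, $\sigma^2_a = 50$,
mean $\sigma^2_e = 85$, $\tau = 0.3$ — the variance scale of a winter
plant-height analysis. Under these conditions the test suite and
`scripts/acceptance.R` check that the median relative bias of
$\hat\sigma^2_G$ stays below 10% over 25 replicates, that estimated $h^2$
tracks the realized truth within $\pm 0.05$, that clean data yield
essentially no flags (family-wise control), and that 3% contamination at
8 error-SD shifts is recovered with sensitivity at least 0.9 at a
false-flag fraction below 1%.

`simulate_historical()` adds presets at the scale of the two historical
wheat collections (spring: 1,000 accessions in 1–8 years, most often 1 or
3; winter: 3,400 accessions in up to 28 years, 2–3-year cycles
prevailing), with all three traits on a shared accession set and
per-trait variance scales taken from the uncorrected analyses of those
collections; contamination defaults to each collection's observed flag
scale (spring 20%, winter 3.5%).

### What the simulator does not emulate

Temporal clustering of regeneration years (real campaigns come in waves),
climate or genetic trends across decades, trait–trait genetic
correlations, and within-year spatial structure are all absent. Passing
recovery tests therefore demonstrates correctness of the estimation and
screening machinery under the model's own assumptions, not robustness to
every feature of real historical data.

## Known limitations

* An accession observed once contributes a residual of exactly zero under
  the genotype-fixed fit: a gross error in a single-record accession is
  undetectable by any residual screen of this form. With two records the
  shift splits between the pair. Screen sensitivity is therefore bounded
  by the replication structure; collections dominated by one- and
  two-record accessions should expect materially lower recovery than the
  reference design, and this is a property of the method, not a tuning
  matter.
* Contamination inflates the per-year variance estimates of the
  (non-robust) screening fit itself; the median/MAD rescaling compensates
  globally but not per year.
* The entry-mean $h^2$ has no standard error here, and a single pooled
  $\sigma^2_e$ summary is a convention — per-year variances are the
  primitive quantity.
* The fixed-genotype screening fit estimates one parameter per accession;
  with very few records per accession those estimates are weak, which is
  the usual caveat for BLUEs from unreplicated historical data.

## A worked example

```{r, eval = FALSE}
library(phenocurate)

sim <- simulate_collection(sim_config(contamination_rate = 0.03, seed = 1))
co <- correct_outliers(sim$dataset, "PH")
co$report

h0 <- heritability_pipeline(sim$dataset, "PH")
h1 <- heritability_pipeline(co$dataset, "PH", dataset_stage = "enhanced",
                            prune = FALSE)
c(original = h0$h2, enhanced = h1$h2)
```
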