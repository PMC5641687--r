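# genefactor

Latent genetic factor association models for X-linked SNPs and
longitudinal binary phenotypes.

`genefactor` is for geneticists and psychometricians who want to test a
candidate gene region against noisy questionnaire phenotypes without
throwing away information on either side.  Instead of regressing a sum
score on one SNP at a time, it models

* a **latent genetic factor** `G` measured by several SNPs in high LD
  (X-linked: hemizygous male dosages are binary indicators, diploid
  female dosages 0/1/2 ordinal indicators),
* **latent trait factors** measured by binary items at two ages through a
  liability-threshold (probit) model, with item `i` endorsed when
  `lambda_i * eta + eps_i > tau_i` (theta parameterisation, residuals
  standard normal),
* structural regressions of the wave-1 factor, the wave-2 factor and the
  **latent difference score** `Delta` (defined by
  `eta_26 = eta_16 + Delta`, autoregressive path fixed at 1) on `G`,
  reported as standardised coefficients `beta` with `beta^2` the fraction
  of phenotypic variance explained.

Estimation is two-stage categorical SEM: thresholds and
tetrachoric/polychoric correlations with asymptotic variances first, then
diagonally weighted least squares with full-covariance (influence
function) sandwich standard errors and a mean-and-variance-adjusted
chi-square.  On top of that the package provides genotype/item QC (MAF,
female-only HWE, EM-based D'/r, endorsement tables), the
configural/strong/strict longitudinal measurement-invariance ladder with
Delta-fit-index decision rules, Benjamini-Hochberg FDR over the declared
test family, an extreme-group sensitivity analysis, a synthetic cohort
generator matching the published summary structure, and Monte Carlo power
analysis comparing the latent-variable and single-SNP approaches.

## Worked example

Simulate a male cohort at the study conditions (n = 1160, three SNPs with
MAFs 0.30/0.24/0.30, six binary extraversion items per wave, a genetic
effect of `-0.167` on extraversion at 16 and `0.197` on its change), then
run QC, the invariance ladder and the association models:

```r
library(genefactor)

cfg <- sim_config(sex = "male", n = 1160, traits = "extraversion",
                  beta_cross  = c(extraversion = -0.167, neuroticism = 0),
                  beta_change = c(extraversion = 0.197,  neuroticism = 0),
                  seed = 17)
cohort <- generate_full_study(cfg)

qc_report(cohort$geno)$snps[, c("snp", "sex", "maf", "call_rate")]
#> # A tibble: 3 × 4
#>   snp       sex     maf call_rate
#>   <chr>     <chr> <dbl>     <dbl>
#> 1 rs3788862 male  0.294         1
#> 2 rs5906957 male  0.244         1
#> 3 rs979606  male  0.306         1

inv <- run_invariance(cohort$items)
inv$summary[, c("model", "chi2", "df", "rmsea", "cfi")]
#> # A tibble: 3 × 5
#>   model       chi2    df  rmsea   cfi
#>   <chr>      <dbl> <int>  <dbl> <dbl>
#> 1 configural  68.7    47 0.0199 0.976
#> 2 strong      70.7    51 0.0183 0.978
#> 3 strict      73.1    57 0.0156 0.982
inv$decision
#> [1] "strict"

cs <- fit_cross_sectional(cohort$geno, cohort$items,
                          trait_items = paste0("e", 1:6),
                          snps = cfg$snps$snp)
lc <- fit_latent_change(cohort$geno, cohort$items,
                        trait_items = paste0("e", 1:6),
                        snps = cfg$snps$snp)
dplyr::bind_rows(cs$result, lc$result)
#>             phenotype  sex std_beta     se  ci_low ci_high      p
#> 1  extraversion_age16 male  -0.1359 0.0545 -0.2427 -0.0292 0.0126
#> 2  extraversion_age26 male   0.0262 0.0541 -0.0799  0.1322 0.6287
#> 3 extraversion_change male   0.1932 0.0769  0.0425  0.3438 0.0120
```

The age-16 coefficient recovers the injected `-0.167` within its
confidence interval, the change coefficient recovers `0.197`, and the
cross-sectional and latent-difference fits are the same model in two
parameterisations (identical chi-square).  `fdr_adjust()` turns the raw
p-values into BH-adjusted ones over the 12-test family, and
`run_power()` / `apriori_table()` estimate power, e.g.

```r
run_power(power_scenario("latent", "cross_sectional",
                         effect_variance = 0.028, reps = 250, seed = 1))
#>   approach       phenotype effect_variance power  mc_se ...
#> 1   latent cross_sectional           0.028 0.864 0.0217
```

`run_pipeline(pipeline_config(...))` chains simulate → QC → invariance →
association (FDR) → power and writes TSV reports plus a manifest.

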