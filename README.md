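# radphen

Harmonized radiomic phenotypes for survival analysis.

`radphen` is an end-to-end R pipeline for prognostic modelling with
radiomic feature tables acquired under heterogeneous imaging conditions
(different scanner vendors, contrast protocols, …). Batch effects of that
kind can dominate the biological signal, so the package couples a
harmonization stage to an unsupervised phenotyping stage and then asks
the only question that matters clinically: *does the imaging phenotype
add prognostic value over routine clinical predictors?*

## The model

**Harmonization.** Features are z-scored and batch-corrected with a
parametric empirical-Bayes location/scale model (ComBat): for feature
$v$, batch $b$,

$$x_{iv} = \alpha_v + \gamma_{bv} + \delta_{bv}\,\varepsilon_{iv},$$

with normal/inverse-gamma priors shrinking the per-batch estimates
$\hat\gamma_{bv}, \hat\delta_{bv}$ across features. Several acquisition
variables are harmonized in a *nested* loop ordered by two-sample
Kolmogorov–Smirnov diagnostics (fewest flagged features first).

**Phenotyping.** PCA keeps the fewest components reaching 85% cumulative
variance; consensus clustering (complete linkage on subsamples, minimal
proportion of ambiguous clustering) selects the cluster number; for
$k = 2$ the clusters are oriented into low/high risk by observed event
fraction.

**Evaluation.** Cox proportional-hazards models
$\lambda(t\mid x) = \lambda_0(t)\exp(x^\top\beta)$ are compared by
Harrell's concordance index with bootstrap *t*-approximation confidence
intervals (the reported C-score is the bootstrap average), and the added
value of the phenotype over the clinical baseline (ECOG + age) is tested
by likelihood ratio. Kaplan–Meier curves summarize the phenotype strata.

A built-in generator simulates a study-scale cohort (110 patients, 107
features, imbalanced contrast/vendor batches, a latent two-group
prognostic phenotype with a doubled hazard) so the entire pipeline is
testable without restricted patient data.

## Worked example

```r
library(radphen)

cfg <- pipeline_config(simulation = sim_config(), n_bootstrap = 2000, seed = 1)
res <- run_pipeline(cfg)
res
#> radphen pipeline result
#>   harmonization order: contrast -> vendor
#>   phenotype: 44 PCs, k = 2
#>   multivariate models:
#>                          model c_score ci_low ci_high   lrt_p
#> 1                     baseline   0.622  0.547   0.697      NA
#> 2    phenotype_combat_ecog_age   0.655  0.578   0.732 0.16512
#> 3 phenotype_noncombat_ecog_age   0.658  0.587   0.729 0.81003
#> 4        screened_pcs_ecog_age   0.736  0.667   0.804 0.00897

res$harmonization
#> Nested ComBat harmonization
#>   applied order: contrast -> vendor
#>   KS flag counts (pre -> post):
#>     contrast    69 ->   4
#>     vendor      85 ->   1

head(res$univariate[, c("model", "c_score", "ci_low", "ci_high")], 4)
#>              model c_score ci_low ci_high
#> 1             ecog   0.602  0.530   0.674
#> 2 phenotype_combat   0.598  0.528   0.668
#> 3             race   0.577  0.521   0.632
#> 4              sex   0.572  0.506   0.638
```

At this seed the harmonized phenotype recovers the planted latent
phenotype exactly (adjusted Rand index 1 against the generator's truth),
while phenotyping the *non*-harmonized features fails outright — the
consensus step does not even select two clusters there, and the resulting
labels carry no prognostic signal (LRT p = 0.81 vs the baseline).

Individual stages are exported and composable:

```r
co   <- simulate_cohort(sim_config(), seed = 1)
harm <- nested_combat(co$features, co$batches)        # z-scores internally
ph   <- derive_phenotype(harm$final_features, co$survival, seed = 1)
fit  <- cox_fit(cbind(phen = as.numeric(ph$risk_labels == "high")), co$survival)
concordance_index(drop(fit$design %*% fit$coefficients), co$survival)
```

A thin command-line wrapper with subcommands `simulate`, `harmonize`,
`phenotype`, `evaluate` and `run` lives at `inst/cli/radphen.R`:

```sh
Rscript inst/cli/radphen.R simulate --seed 7 --outdir cohort/
Rscript inst/cli/radphen.R run --config pipeline.yaml   # see ?pipeline_config
```

## Running the tests

```r
testthat::test_dir("tests/testthat", package = "radphen",
                   load_package = "installed")
```

The suite contains unit tests per module (with independent oracles:
brute-force concordance enumeration, numerical score-equation gradients,
closed-form chi-squared, `sva::ComBat`) plus an end-to-end acceptance
file exercising the pipeline at study scale across many seeds.

## Package layout

| path | contents |
|---|---|
| `R/cohort-sim.R` | synthetic cohort generator and clinical table |
| `R/harmonize.R` | z-scoring, EB ComBat, KS diagnostics, nested loop |
| `R/phenotype.R` | PCA truncation, consensus clustering, risk orientation, covariate associations |
| `R/survival-eval.R` | Cox fits, concordance, bootstrap-t CIs, LRT, KM |
| `R/evaluate.R` | univariate / multivariate model comparisons |
| `R/pipeline.R`, `R/io.R` | validation, configuration, orchestration, CSV/JSON artifacts |
| `vignettes/methods.Rmd` | full statistical methods, parameter rationale, limitations |
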