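# dmu: dynamic model updating for regression with missing data

Biomedical and epidemiological tables often arrive with most predictor
cells missing. The two textbook responses — complete-case analysis
(drop every incomplete row) and imputation (fill the holes, e.g. by
predictive mean matching) — either discard almost all the data or
analyse values that were never observed. `dmu` implements a third
strategy for linear regression with a fully observed outcome and
missing-completely-at-random predictors:

1. **Fragment.** Binarise the missingness pattern (0 = missing,
   1 = observed) and hierarchically cluster the rows of that 0/1
   matrix into *k* subgroups. Each subgroup keeps exactly the
   predictors observed in all of its rows, giving row-disjoint,
   fully observed sub-datasets `d₁, …`; a sub-dataset is used only if
   its sample-to-predictor ratio `s/(q+1) ≥ 2`.
2. **Update.** Fit a Bayesian linear regression
   `y = Xβ + ε`, `ε ~ N(0, σ²)`, to each sub-dataset by Gibbs sampling,
   with independent priors `β_j ~ N(0, 100)` and
   `σ⁻² ~ Gamma(5/2, 50/2)` before any data. After each fit the
   moment-matched posterior of every coefficient present in that
   fragment becomes its prior for the next fragment — the model is
   updated dynamically as fragments arrive, and beliefs about absent
   columns are left untouched.
3. **Select k.** The subgroup count is chosen by an integer genetic
   algorithm (or an exhaustive sweep) whose fitness is the pipeline's
   holdout RMSE.

The package also ships the standard comparators (mean imputation,
complete-case OLS, chained-equations predictive mean matching with
Rubin-pooled OLS, and a plug-in interface for external imputers), a
Gaussian-copula simulation generator with per-predictor MCAR
amputation, and a benchmark harness that reports test MSE normalised by
the mean-imputation baseline. See `vignettes/dmu-methods.Rmd` for the
model, the design decisions and their rationale.

## Worked example

Simulate one benchmark replicate (20 predictors, 3150 training rows
with 80% of each predictor missing completely at random plus 50
complete rows, 1000 complete test rows), fragment it, fit the chain,
and compare with the mean-imputation baseline:

```r
library(dmu)
cfg <- scenario_config(p = 20)        # SCR: 3150 amputed + 50 complete rows
sc <- build_scenario(cfg, seed = 1)
sc$train
#> <tabular_dataset> 3200 rows, 20 predictors, 78.5% cells missing
#>   complete rows: 50

bin <- binarize_missingness(sc$train)
frag <- fragment(sc$train, cluster_rows(bin, k = 300))
frag
#> <fragmentation> 129 sub-datasets (1943/3200 rows used, 171 clusters skipped)
#>   s=5 q=1  [x8]
#>   s=5 q=1  [x6]
#>   s=6 q=2  [x4, x8]
#>   ...

model <- dmu_fit(frag, mcmc = mcmc_config(seed = 1))
mean((sc$test$outcome - predict(model, sc$test))^2)
#> 0.314  (mean imputation baseline: 0.259)
```

Letting the genetic algorithm pick the subgroup count (fitness scored
on the test table, the published benchmarking protocol):

```r
sel <- select_k_ga(sc$train, sc$test,
                   ga = ga_config(pop_size = 10, n_generations = 8, seed = 1),
                   mcmc = mcmc_config(3000, 500), seed = 1)
sel
#> <ga_result> ga search: best k = 1001 (RMSE 0.526), 54 evaluations
mean((sc$test$outcome - predict(sel$model, sc$test))^2)
#> 0.277  (ratio to mean imputation: 1.07)
```

The fitted model's belief state is readable directly: posterior means
near `(0.2, 0.3, 0.4)` for `x1..x3` and near zero elsewhere indicate
successful recovery of the generating coefficients; `predict()` uses
the posterior plug-in means. Models serialise to JSON
(`write_model()` / `read_model()`).

A command-line wrapper is installed with the package
(`system.file("cli", "dmu", package = "dmu")`) with subcommands
`simulate`, `fragment`, `fit`, `predict` and `benchmark`, so the same
pipeline can be driven from a shell on any CSV with one complete
outcome column.

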