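# snplasso

Standard and robust Huber-LASSO regression for predicting molecular
phenotypes (protein, metabolite or expression residuals) from individual
SNP genotype dosages.

## The problem

L1-penalized regression is the workhorse for selecting the SNPs
associated with a molecular phenotype and predicting it from genotype:

```
min over (b0, beta):  (1/n) * sum_i rho(y_i - b0 - sum_j beta_j x_ij)
                      + lambda * sum_j |beta_j|
```

With the least-squares loss `rho(e) = e^2/2`, a single individual with an
outlying phenotype — especially in combination with an average or a
divergent multi-SNP genotype — can move the cross-validated penalty, the
selected SNP set and the coefficients. The Huber loss

```
rho_c(e) = e^2 / 2            if |e| <= c
           c*|e| - c^2 / 2    otherwise
```

bounds each observation's influence by the tuning constant `c`
(`c = 1.345` keeps 95% Gaussian efficiency), making the penalized fit
robust to such observations. `snplasso` implements:

* the L1-penalized coordinate-descent solver for squared, Huber and
  (smoothed) quantile losses, with warm-started penalty paths, KKT
  verification and 10-fold cross-validated penalty selection;
* eigenstrat-style genotype PCA and **exact** trivariate halfspace
  (Tukey) depth to identify low-leverage ("average") and high-leverage
  ("divergent") genotypes;
* the outlier-injection subsampling protocol (100 iterations x 500
  individuals, artificial residuals in [-5, 5], single or 1% outliers)
  and its summary statistics: penalty stability, mean pairwise Jaccard
  concordance, false-/true-positive rates, coefficient means with
  empirical confidence intervals, and out-of-sample prediction accuracy
  by the squared Fisher-consistent Kendall correlation `sin(pi*tau/2)`;
* a seeded synthetic genotype/phenotype generator (Hardy-Weinberg or
  Balding-Nichols substructure) emulating a three-SNP additive
  architecture that explains 0.10 of a unit-variance phenotype.

## Worked example

```r
library(snplasso)

# synthetic pool: 3 causal SNPs (MAF 0.082/0.354/0.163, effects
# 0.606/0.241/0.254 -> explained variance 0.0995) + 100 null SNPs
arch <- defb119_architecture(n = 400, n_null = 100, seed = 7)
pool <- simulate_pool(arch)

pr   <- regression_problem(pool$G, pool$y)
cv_h <- cross_validate(pr, loss_spec("huber", c = 1.345), k = 10, seed = 1)
cv_h
#> Cross-validated huber-loss LASSO: lambda_opt = 0.1173 (1 SNPs selected)
selected_variables(cv_h$fit, cv_h$lambda_opt)
#> [1] "rs11845244"

pca    <- genotype_pca(pool$G)
depths <- halfspace_depth(pca$scores)
depths
#> Halfspace depth (exact): n = 400, range 1-130
leverage_extremes(depths)
#> $low_leverage   (the "average genotype": deepest point)
#> [1] 364
#> $high_leverage  (the "divergent genotype": depth-1 point)
#> [1] 22

gaussian_efficiency(c(1.20, 1.345, 1.80))
#> [1] 0.9330473 0.9500003 0.9825439
```

At this small pool size the cross-validated LASSO retains only the
strongest detectable signal — selection power grows with the subsample
size and the experiment protocol quantifies exactly that behaviour over
repeated subsamples. The depth table feeds the outlier-injection
scenarios: `run_experiment()` / `run_scenarios()` re-draw 500-individual
subsamples, replace the phenotype of the leverage-extreme individual
with an artificial residual, and compare loss functions on identical
data and folds.

A command-line interface with `simulate-data`, `fit`, `depth`,
`run-experiment`, `predict-accuracy` and `efficiency` subcommands is
installed under `inst/cli/snplasso.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/snplasso.R", package="snplasso"))')" efficiency --c 1.345
#> c = 1.345 -> Gaussian efficiency 0.9500
```

## Layout

* `R/`, `src/` — losses, solver (Rcpp coordinate descent), depth
  (exact rotating-plane sweep), metrics, synthetic generator, experiment
  orchestration, I/O.
* `vignettes/robust-huber-lasso.Rmd` — model, assumptions, parameter
  choices, what the synthetic world does and does not establish.
* `tests/testthat/` — unit + property tests per module and
  `test-acceptance.R` with the acceptance criteria.
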