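# methnetprog

Rank-based co-methylation networks and hub-based prognostic signatures for
cancer survival analysis.

## What it is for

Prognostic signatures screened directly from expression data are unstable:
rescreen on a different subset of the same cohort and you get a largely
different gene list. DNA methylation behaves better, and network structure
can be used to make the screen more reproducible still. `methnetprog` is
for survival analysts working with methylation beta-value matrices (sites ×
samples, values in [0, 1]) and matched clinical follow-up who want to:

1. build a **co-methylation interaction network** — each CpG site keeps its
   k = 10 most correlated partners by Spearman rank correlation
   ρ = 1 − 6Σdᵢ²/(n³−n), so a network over N sites always has kN selection
   pairs;
2. check **scale-free topology** by a log–log least-squares fit of the
   degree distribution (count ~ degree^γ, with its correlation and R²);
3. select **hubs** (top 10% of sites by degree, ties at the threshold
   included);
4. **screen hubs** with univariate Cox proportional-hazards regression
   (Efron ties, Wald p < 0.05) into a prognostic signature;
5. score patients GGI-style, **PrognosisRisk = Σpᵢ − Σqⱼ** (beta values
   over risk-increasing minus protective signature sites), split at the
   median into bad/good-outcome groups, and evaluate by log-rank test and
   hazard ratio with 95% CI — against a genome-wide **control signature**
   baseline;
6. quantify **split-half stability** of prognostic feature selection with
   the hypergeometric overlap tail
   p = 1 − Σ_{i<x} C(K,i)C(M−K,N−i)/C(M,N) over B random half-splits, and
   compare platforms (methylation vs mRNA vs miRNA) by Wilcoxon rank-sum;
7. test **gene-set over-representation** of hub genes (hypergeometric +
   Benjamini–Hochberg).

A synthetic multi-omics generator (`synth_config()`,
`generate_methylation()`, `generate_survival()`, `generate_platforms()`)
produces cohorts with module structure, planted prognostic driver sites and
ground truth, so the whole pipeline is testable without cohort downloads.

## Worked example

```r
library(methnetprog)

cfg <- synth_config(n_sites = 400, n_samples = 200, n_modules = 8,
                    module_size = 30, n_drivers = 16, seed = 11)
gen <- generate_methylation(cfg)
clinical <- generate_survival(gen$m, gen$truth, cfg)

split <- split_train_test(clinical$sample, seed = 1)
fit <- methnet_fit(gen$m[, split$train], clinical, k = 10)
fit
#> Hub-based prognostic methylation signature fit
#>   training data: 400 sites x 100 samples
#>   network: k = 10, 4000 selection pairs, 2955 unique edges
#>   hubs: 47 sites with degree >= 21 (top 0.1 by degree)
#>   signature: 35 sites at Cox p < 0.05 (35 risk-increasing, 0 protective)

fit$powerlaw
#> Power-law fit of the degree distribution (log10-log10 OLS)
#>   count ~ degree^-3.626   (intercept 5.647, 22 points)
#>   correlation -0.950, R-squared 0.902

evaluate_signature(fit$signature, gen$m[, split$test], clinical, "test")
#> Signature evaluation [test], n = 100
#>   Log-rank test: chi-square 45.058 (1 df), p = 1.91e-11
#>   bad vs good outcome: HR 6.254 (95% CI 3.424-11.425), Wald p = 2.47e-09
```

Reading the output: the 400-site training half yields exactly 4,000
selection pairs (k·N); the degree distribution is heavy-tailed
(R² ≈ 0.90 on the log–log line); 47 hubs survive the 10% degree cut and 35
of them pass the Cox screen. On the held-out 100 samples the signature's
risk score separates survival sharply — bad-outcome patients die at ~6×
the rate of good-outcome patients, log-rank p ≈ 2×10⁻¹¹ — because the
synthetic cohort plants 16 strong drivers inside correlated modules. With
no planted signal the same pipeline returns ~5% screened sites and null
log-rank p-values; see the tests.

`methnet_fit` objects support `print`, `summary`, `coef`, `predict`
(scores or bad/good groups for new samples) and `plot` (degree
distribution with the fitted power law). `run_pipeline()` runs everything
(including optional stability and enrichment stages) and writes TSV/JSON
artifacts plus a manifest to an output directory, byte-reproducibly from
one seed.

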