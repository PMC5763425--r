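---
title: "Co-methylation networks and hub-based prognostic signatures: methods"
author: "methnetprog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-methylation networks and hub-based prognostic signatures: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methnetprog)
```

## The problem

Prognostic gene signatures screened directly from high-throughput expression
data are notoriously unstable: two signatures screened from different
cohorts of the same cancer can share almost no genes. DNA methylation is an
attractive alternative substrate for prognosis — beta values are bounded,
relatively stable measurements, and survival-associated methylation changes
tend to be selected more reproducibly across random subsets of a cohort
than mRNA or miRNA features are.

`methnetprog` implements a network-guided screening strategy on top of that
observation. Instead of screening every CpG site genome-wide, it first
builds a co-methylation interaction network, restricts attention to the
network's hubs, and only then applies survival screening. The hub
restriction acts as a structural prior: sites that are strongly
co-methylated with many partners tend to sit in coordinated regulatory
programs, and prognostic signal carried by such programs generalizes better
than signal found by an unconstrained genome-wide scan, which is free to
pick up cohort-specific noise.

## The model, stage by stage

### Rank-based network construction

For sites $u, v$ with beta values across $n$ patients, association is the
Spearman rank correlation

$$\rho(u,v) = 1 - \frac{6\sum_{i=1}^{n} d_i^2}{n^3 - n},$$

with $d_i$ the per-patient rank difference. Beta values are far from
Gaussian in tumor cohorts, so a rank statistic is the appropriate choice.
Ties are handled by midranks, which makes the statistic the Pearson
correlation of the rank vectors; the formula above is the special case of
all-distinct ranks, and identical orderings give exactly 1.

The network is built by a per-node top-$k$ rule: every site keeps its $k$
(default 10) most relevant partners, where "most relevant" is interpreted
as largest $|\rho|$ — anticorrelated methylation is still coordinated
methylation, and the signed value is kept on the edge. A global correlation
threshold would instead let promiscuously correlated sites dominate while
dropping all edges of weakly coupled modules; the top-$k$ rule gives every
site a voice at whatever correlation scale its module lives on.

Two views of the construction are kept deliberately distinct:

* **selection pairs** — the directed record of who selected whom, exactly
  $k$ per node, so a network over $N$ nodes always has $kN$ selection pairs
  (24,981 nodes at $k=10$ give 249,810);
* **unique edges** — the deduplicated undirected view (a reciprocal
  selection appears once), on which node degrees are counted.

The correlation matrix is processed in row blocks against a rank-transformed
copy of the matrix, so the full $N \times N$ matrix is never held in memory
and genome-scale inputs (tens of thousands of sites) are feasible. Ties in
the top-$k$ ranking are broken by site id so the network is reproducible to
the byte regardless of chunking or site order.

### Scale-free diagnostic

Biological interaction networks typically have heavy-tailed degree
distributions. As a diagnostic, the degree distribution is fitted by
ordinary least squares of $\log_{10}(\text{count})$ on
$\log_{10}(\text{degree})$; the slope is the power-law exponent and the
squared Pearson correlation of the log-log points is the reported $R^2$.
Some network-analysis tools print the correlation of the untransformed
points instead, so that value is also exposed (`raw_correlation`), but the
log-log fit is primary. This is a goodness-of-straight-line diagnostic, not
a formal maximum-likelihood power-law test, which is out of scope.

### Hub selection

Hubs are the top `hub_fraction` (default 10%) of sites by degree. The
degree threshold is the largest degree $d$ such that at least
$\lceil fN \rceil$ sites have degree $\ge d$; every site at or above the
threshold is included, so ties at the cut can push the hub set slightly
above the target fraction — the set is "threshold-closed", which keeps the
rule deterministic and order-free.

### Survival screening and the risk score

Each hub is screened with a univariate Cox proportional-hazards regression
of survival on its beta values. The fitter maximizes the Efron partial
likelihood by Newton iteration with step-halving (tolerance $10^{-9}$ on
the update, at most 50 iterations) on an internally standardized covariate;
Efron's tie correction is the right default for day-resolution survival
times, where tied death times are common. P-values are two-sided Wald
tests. A monotone likelihood (a covariate that perfectly orders the
deaths) is detected by the standardized coefficient diverging and is
flagged, never silently returned. Sites with screening $p < \alpha$
(default 0.05, uncorrected — the screen is a candidate filter, and the
downstream evaluation is on held-out data) form the signature.

Patients are then scored GGI-style:

$$\mathrm{PrognosisRisk} = \sum_i p_i - \sum_j q_j,$$

the sum of beta values over signature sites with positive Cox coefficient
minus the sum over sites with negative coefficient. The top half of scores
(exactly $\lfloor n/2 \rfloor$ patients, score ties broken by sample id) is
the bad-outcome group; the groups are compared by log-rank test and by the
hazard ratio $\exp(\hat\beta)$ with a normal-approximation 95% CI on the
log scale. A coefficient of exactly zero cannot arise from the continuous
fit; if one were ever constructed by hand it would count as positive.

As a baseline, the **control signature** takes the same number of sites
with the smallest Cox p-values genome-wide, ignoring the network. On
training data the control always looks at least as good (it is selected to
minimize exactly the quantity being reported); the comparison of interest
is on the held-out half, where the hub-filtered signature holds up better.
Training-set evaluations are reported but labelled optimistic.

### Split-half stability

The stability experiment asks how reproducibly a platform selects
prognostic features. One replicate: randomly split the cohort in half,
screen every feature in each half at $p<0.05$, and score the overlap of the
two selected sets with the hypergeometric tail

$$p = 1 - \sum_{i=0}^{x-1} \frac{\binom{K}{i}\binom{M-K}{N-i}}{\binom{M}{N}},$$

where $x$ is the overlap, $K$ and $N$ the two selection sizes, and $M$ the
universe size. The universe is the number of features actually screened on
that platform — the natural draw space of both selections. The sum is
evaluated from log-gamma binomial coefficients (never factorials) and as
the complementary upper tail so deep tails survive floating point. $B$
replicates (default 100) give a p-value distribution per platform;
platforms are compared with a two-sided Wilcoxon rank-sum test (exact null
for small tie-free samples, normal approximation with tie and continuity
correction otherwise). Replicate $r$ derives its seed as master seed $+ r$,
so a report is reproducible from one integer.

One caveat worth stating: the overlap statistic is discrete, so its null
p-values live on a lattice and are conservative rather than exactly
uniform. The lattice is fine enough to pass a Kolmogorov–Smirnov
uniformity check once the expected overlap $KN/M \approx \alpha^2 M$ is
roughly 10 — that is why the null-calibration checks screen a few thousand
features, not a few hundred.

### Enrichment

Hub sites are mapped to gene symbols (a probe annotated to two genes
contributes both; duplicates collapse) and gene sets are tested with the
same hypergeometric tail against the universe of genes mappable from the
matrix, followed by Benjamini–Hochberg adjustment across sets. This is an
over-representation test, not a ranked GSEA with permutation FDR; published
FDR values from GSEA-based analyses are therefore not directly comparable.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
with ground truth, so every stage is testable without cohort downloads.

* **Methylation**: sites are partitioned into modules; each module has a
  per-patient latent Gaussian factor, and a member site's latent value is
  $\sqrt{s}\,f + \sqrt{1-s}\,\varepsilon$ with $s$ the
  `correlation_strength` (default 0.8). Beta values are the inverse logit
  of a per-site baseline plus 1.5 times the latent value, which guarantees
  $[0,1]$. Inverse-logit Gaussians were chosen over Beta distributions
  because they give direct control of the correlation structure, which is
  what the network stage consumes. Remaining sites are independent noise.
* **Drivers**: `n_drivers` (default 20) sites spread evenly across modules
  carry survival signal with log-hazard `driver_effect` (default 2.0) per
  unit beta. Because drivers sit inside correlated modules they acquire
  high degree — the structural premise of the hub strategy, and a property
  the tests verify rather than assume.
* **Survival**: event times are exponential with hazard
  $\lambda_0 \exp(\mathrm{lp} - \overline{\mathrm{lp}})$; centering the
  linear predictor makes `baseline_hazard` (default $5 \times 10^{-4}$ per
  day, median survival around 3.8 years) the hazard of an average patient.
  Censoring is independent uniform over a window solved numerically to hit
  the target `censoring_rate` (default 0.4) approximately — exactness is
  not needed, realism of the mix is.
* **Platforms**: for the stability contrast, a shared latent risk drives a
  shared clinical table and, with platform-specific `attenuation` $a$, the
  driver features of each platform: $(aL + \varepsilon)/\sqrt{a^2+1}$.
  Methylation-like platforms use $a = 1$ and are squashed into $[0,1]$;
  mRNA/miRNA-like platforms use smaller $a$ and stay unbounded. Platforms
  with identical profiles are exchangeable by construction, which pins the
  null of the comparison test.

Defaults are fixed at a desk scale of 2,000 sites × 300 samples — large
enough for the network, screening and stability machinery to behave as
they do at genome scale, small enough that the whole pipeline runs in
seconds to minutes. What the generator does **not** emulate: probe-design
artifacts of methylation arrays (type I/II probe chemistry, batch
effects), missingness patterns, non-proportional hazards, or clinical
covariates. Passing tests on synthetic cohorts therefore demonstrate the
statistical machinery, not robustness to array artifacts.

All randomness flows through one documented RNG (Mersenne-Twister with
inversion sampling for normals), pinned explicitly so results do not
depend on the session's RNG settings.

## Numerical and design choices

* **Missing beta values** drop the site (with a count), rather than
  imputing: rank correlations need complete vectors, and imputation would
  manufacture correlation.
* **Matrix orientation** is fixed: sites in rows, samples in columns; all
  ids are case-sensitive.
* **Sign of relevance**: top-$k$ selection ranks by $|\rho|$; the signed
  value is stored. Selecting by signed $\rho$ would discard coordinated
  anticorrelation for no benefit.
* **Efron vs Breslow ties**: Efron, which is more accurate under the heavy
  ties of day-scale data and reduces to the same likelihood without ties.
* **Wald p-values and normal-theory CIs**: the simplest defaults that
  report alongside the SE; score and likelihood-ratio variants agree
  asymptotically (a property the tests check against the log-rank test).
* **Degenerate inputs**: constant covariates, constant rank vectors,
  empty groups, infeasible overlaps and sub-3-point power-law fits all
  raise informative errors rather than returning NA or 0.
* **Determinism**: every stochastic entry point takes an explicit seed;
  split, stability and pipeline runs are byte-reproducible, and the
  pipeline manifest records every parameter and seed needed to rerun.

## Worked example

```{r example}
cfg <- synth_config(n_sites = 400, n_samples = 200, n_modules = 8,
                    module_size = 30, n_drivers = 16, seed = 11)
gen <- generate_methylation(cfg)
clinical <- generate_survival(gen$m, gen$truth, cfg)

split <- split_train_test(clinical$sample, seed = 1)
fit <- methnet_fit(gen$m[, split$train], clinical, k = 10)
fit

evaluate_signature(fit$signature, gen$m[, split$test], clinical, "test")
```

The held-out evaluation is the honest number: the training-half evaluation
is optimistic by construction, and the control signature's held-out
performance is the baseline to beat.

## Known limitations

* The hub premise requires prognostic signal to live inside correlated
  modules; a lone prognostic site with few correlated partners is invisible
  to the method by design.
* The log-log least-squares fit is a diagnostic, not a test of the
  power-law hypothesis; exponents from such fits are known to be biased
  relative to maximum-likelihood estimates.
* The uncorrected screening threshold replicates the method faithfully but
  means signature size scales with cohort size; interpret signature
  membership collectively, not site by site.
* Real-cohort quantities that depend on the original data (specific hazard
  ratios, signature sizes, enrichment tables) are outside what synthetic
  cohorts can reproduce; the package reproduces the method and its
  qualitative behaviour.
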