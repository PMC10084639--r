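---
title: "Mapping pleiotropic QTL: single-trait scans, multivariate scans, and meta-analysis on simulated breeding cohorts"
author: "pleioscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping pleiotropic QTL with pleioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

## The problem

Breeding cohorts are genotyped on medium-density SNP arrays and evaluated on
many traits at once. The phenotypes entering association analyses are usually
not raw records but deregressed estimated breeding values (drEBV):
progeny-derived pseudo-phenotypes with a per-record reliability $r^2$ and a
weight $w$. Genetic correlations between traits suggest that some loci are
pleiotropic, and two families of methods try to exploit that: joint
multivariate mixed-model scans, and meta-analysis of the per-trait summary
statistics. The two differ in a practically important way — the multivariate
model requires every animal to have a record for every trait, while the
meta-analysis happily combines scans run on different (overlapping) subsets
of animals.

`pleioscan` implements the whole comparison as testable, reusable code and
pairs it with a cohort generator with known genetic truth, so every claim
about the methods can be checked on data where the answer is known. The
numbered scripts under `analysis/` run the full study; everything they do is
a call into the package.

## Models

### Single-trait scan (stGWAS)

Per trait, the linear mixed model is

$$ y = W\alpha + x\beta + u + \varepsilon, \qquad
   u \sim N(0, G\sigma^2_a), \quad \varepsilon \sim N(0, I\sigma^2_e), $$

with $W = \mathbf{1}_n$ (an intercept; principal components are deliberately
not included — the GRM carries the structure, and the inflation factors near
1 in the calibration suite justify it), $x$ the allele dosage of the tested
variant, and $G$ the centred genomic relationship matrix
$G = X_c X_c^\top / m$ (`compute_grm_centered()`; missing dosages are
mean-imputed per variant, i.e. centred to zero).

`fit_null()` eigendecomposes $G$ once, estimates the variance ratio
$\lambda = \sigma^2_a/\sigma^2_e$ by profiled REML on the rotated model, and
freezes it. `score_scan()` then tests $H_0\!:\beta = 0$ per variant with the
score-test convention (null variance structure held fixed), which costs
$O(n)$ per variant after one $O(n^2 m)$ rotation. Effect and standard error
are the generalized-least-squares estimates at the null variance parameters,
so $t = \hat\beta/\mathrm{se}$ is exactly the signed statistic the
meta-analysis consumes, and $p = P(\chi^2_1 > t^2)$.

### Multivariate scan (mtGWAS)

For $d$ traits on complete cases, the same model with matrix-valued $y$,
$u$, $\varepsilon$: $\mathrm{vec}(Y) \sim N(\cdot, G \otimes V_g + I \otimes
V_e)$. `estimate_mt_vc()` estimates the $d \times d$ genetic and residual
covariance matrices once under the global null by an EM algorithm on the
eigen-rotated data (each rotated sample contributes an independent
$d \times d$ Gaussian system; every update is projected onto the
positive-semi-definite cone; the intercept is re-estimated by GLS each
iteration). `mv_scan()` then computes the GLS estimate of the $d$-vector
$\beta$ per variant and a Wald $\chi^2_d$. Components are *not* refitted per
variant — the same fixed-null convention as the score test, which keeps the
two scans comparable and the cost linear in $m$.

The scan warns above 10 traits and refuses above 24: multivariate mixed
models over-parametrise long before that, which is also why the pooled
"all-traits" analyses in studies of this design detect few loci.

### Meta-analysis (metaGWAS)

From the per-trait summary statistics, `assemble_t()` builds the
$m \times d$ matrix of signed t-values (effect alleles harmonised to the
first trait's orientation; variants missing from any trait are excluded
rather than zero-filled — a zero fabricates evidence of no effect).
`estimate_v()` estimates $V$, the $d \times d$ correlation of t-values over
markers, and `meta_chi2()` computes per variant

$$ \chi^2 = t_j^\top V^{-1} t_j . $$

Two degrees-of-freedom conventions circulate for this statistic: $d$
(matching the quadratic form) and $d-1$. Both are implemented
(`df_mode`); the package defaults to `d_minus_1` but every calibration
check uses the mode matching the construction (`d`), and reports should
state which was used. `estimate_v()` also offers a null-restricted mode
(only markers with all $|t| < 2$) because strong QTL inflate the
all-marker correlation; with the desk-scale marker counts used here the
difference is small.

Because each trait's scan may use a different sample subset, the t-matrix
records per-cell sample sizes; the empirical $V$ absorbs the induced
correlation, which is what makes the all-available-records configuration
(metaGWAS$^2$) valid and more powerful than the complete-case one
(metaGWAS$^1$).

### QTL calling, LD and variance explained

`call_qtl()` bins significant variants into 1-Mb windows on a fixed genome
grid (windows start at bp 1, $10^6{+}1$, ...; fixed anchoring makes calls
reproducible) and, by default, merges runs of adjacent significant windows —
that is how multi-megabase QTL arise under a 1-Mb-window definition. The
lead variant is the smallest p in the region, ties broken by position then
id. `ld_r2()` is squared Pearson correlation of dosages over pairwise
complete samples. `variance_explained()` reports per lead
$100 \cdot 2p(1-p)\hat\beta^2/\sigma^2$ with $\hat\beta$ from one joint
multiple regression on all leads — joint fitting removes the overlap that
marginal fits double-count when leads are in LD; leads with pairwise
$r^2 > 0.99$ are dropped. `conditional_scan()` refits the null with lead
dosages as fixed covariates and rescans, which should (and in the test
suite does) silence the LD neighbourhood of a true causal variant.

### Heritability

`reml_single()` fits $y = \mu + u + \varepsilon$ with
$\varepsilon \sim N(0, D\sigma^2_e)$, $D = \mathrm{diag}(1/w_i)$. Where the
weights enter a weighted GREML is a genuine modelling choice; this package
puts them in the residual (the standard treatment for deregressed proofs)
and the simulator generates data accordingly. Two normalisations matter and
are easy to get wrong:

* weights are scaled so $\mathrm{mean}(1/w) = 1$, making $\sigma^2_e$ the
  *average* residual variance (and constant weights exactly equivalent to no
  weights);
* the reported $\sigma^2_a$ is the per-unit-$G$ component times
  $\mathrm{mean}(\mathrm{diag}\,G)$ — the centred GRM's diagonal is the mean
  heterozygosity (about 0.33 here), not 1, so without this factor "$h^2$"
  is on the wrong scale.

Standard errors come from the inverse expected information with the
fixed-effect projection handled by rank-one algebra. A GRM whose eigenvalues
are (numerically) constant — unrelated individuals — cannot identify
$\sigma^2_a$; the fit is flagged `identifiable = FALSE` and returns
$h^2 = 0$ rather than noise.

## The cohort generator

`sim_config()` + `simulate_genotypes()` + `simulate_phenotypes()` emulate
the statistical structure of a medium-size pig-breeding cohort. The defaults
are the study conditions and were fixed once:

| parameter | default | why |
|---|---|---|
| `n_samples`, `n_variants` | 1,000 x 10,000 on 5 autosomes | desk-scale stand-in for thousands of animals x tens of thousands of array SNPs |
| `maf_range` | (0.05, 0.5) | the post-QC panel used for scans |
| `n_traits`, `trait_groups` | 6 in reproduction / production / conformation | the grouped-trait design |
| `h2` | 0.07–0.67 | the span of drEBV heritabilities in such cohorts |
| `genetic_corr` | within-group 0.14/0.32/0.17, between 0.10 | the magnitude of mean within-group drEBV correlations |
| `qtl_spec` | 3 pleiotropic QTL, 3–8% per trait | detectable livestock QTL sizes |
| `missing_rate` | per trait, up to 0.37 | "up to 37% missing" record patterns |
| `reliability_range` | (0.3, 0.99) | records surviving the r² > 0.3 eligibility rule |

Genotypes use a founder-haplotype block model rather than a coalescent
simulator: each block of `ld_block_size` consecutive variants carries
`n_founders` (default 20) founder haplotypes, and each animal draws two
founders per block. Founder allele counts are quantised target frequencies
(multiples of $1/k$, clamped so nothing is monomorphic) that follow a
bounded lazy random walk along the block, and founder carrier patterns
evolve by random carrier swaps (`ld_decay` per adjacent variant). The result
is the LD profile fine-mapping needs — high $r^2$ between close variants,
decaying along the block, independence between blocks — at negligible cost
and fully under seed control. Because all animals draw from a small founder
pool, the cohort is *related*, as a breeding population is; that relatedness
is what makes $\sigma^2_a$ identifiable at these sample sizes.

Phenotypes are built per trait as QTL effects (effect sizes set from the
realized dosage variance to hit the target variance fractions, one random
sign per QTL shared across its traits) plus a polygenic term constructed
from the standardized genotypes with per-variant effects correlated across
traits by `genetic_corr`, plus Gaussian residuals scaled so each trait has
unit total variance in expectation. Reliabilities are uniform on
`reliability_range`; weights are $w = r/(1-r)$, a standard deregression
weight form (the exact weight function differs between evaluation systems
and is configurable); and the residual of each record scales with its
normalised inverse weight, so low-reliability records genuinely carry more
noise — without that coupling the weighted analyses would be mis-specified
against the simulator's own truth. Missingness is completely at random per
trait, a simplification: real missingness follows recording schemes and is
not random.

One master seed expands into per-stage substreams (genotypes, polygenics,
reliabilities, residuals, missingness), so identical configurations give
byte-identical cohorts and individual stages are separately reproducible.

### What the generator does not emulate

No pedigree, selection, mutation or recombination model; no genotyping
error; missingness is MCAR; founder blocks have no between-block LD; allele
frequencies are quantised to $1/k$. Consequently, passing tests show that
the *methods* behave as claimed under a controlled genetic architecture —
they do not certify behaviour under ascertainment, selection sweeps,
population admixture, or informative missingness.

## Numerical choices

* REML: 1-D search on $\log\lambda \in [-14, 14]$ via `optimize()`
  (tolerance $10^{-10}$); components truncated at $10^{-8}\,\mathrm{var}(y)$;
  degenerate (flat) likelihoods flagged rather than guessed.
* EM for $(V_g, V_e)$: convergence when the relative log-likelihood change
  is below $10^{-6}$, at most 200 iterations; PSD projection by eigenvalue
  clipping; the likelihood trace is monitored for monotonicity in debug
  mode. A rank-deficient phenotype matrix is flagged `degenerate`.
* `mv_scan` adds a $10^{-10}$-scale ridge before inverting per-sample
  covariances so exactly-boundary components stay usable.
* $V$ in the meta-analysis must have condition number below $10^8$;
  otherwise the estimation fails with advice (prune traits or enable an
  explicit diagonal ridge) instead of silently regularising.
* HWE: exact conditional test with probability ordering and no mid-p,
  computed by the two-sided recurrence anchored at the distribution's mode.
* QC order is fixed and documented: sample call rate, variant call rate,
  imputation DR2 (when present), HWE, MAF; each removal attributed to the
  first failing filter. Coordinates are 1-based throughout; BED export
  converts at the boundary.
* Concordance-ratio ties (imputed dosage exactly 0.5/1.5) round toward the
  heterozygote by default; configurable.
* Lead ties in `call_qtl()` break by position, then id.

## Problem sizes used by the checks

The test suite and the acceptance script scale the study down so a complete
run stays in the minutes range: calibration uses null cohorts of n = 1,000
with m = 5,000 markers (20 seeds in the suite, 12 in the script — the
lambda estimates agree to < 0.01), heritability recovery n = 1,000 with
m = 2,000, QTL-variance recovery n = 2,000 over 20 seeds, oracle
equivalences n <= 60, and the lead-signal comparison two cohorts of
n = 1,200 with six pleiotropic QTL each. The `analysis/` scripts run the
full default cohort (1,000 x 10,000, 6 traits) end-to-end.

## Known limitations

* Variance components are never refitted per variant (score-test
  convention); tools that refit under the alternative will differ slightly
  in strong-signal regions.
* The weighted-REML weight form and its placement (residual) are one
  defensible convention among several; both are configurable at the
  simulator and the estimator.
* No Bayesian fine-mapping, credible sets, colocalisation, heterogeneity
  meta-analysis, or sample-overlap correction beyond what the empirical
  $V$ absorbs.
* Variant-effect annotation is a pass-through hook for an external table;
  nothing is computed in-repo.
* Imputation itself is out of scope: the package provides the masking
  harness (`mask_for_imputation_cv()`) and the accuracy metrics
  (`imputation_accuracy()`) for evaluating an external imputer.
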