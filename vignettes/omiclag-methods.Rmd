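---
title: "omiclag: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{omiclag: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omiclag)
```

This vignette is the package's own account of its statistics: the models and
their assumptions, the tunable parameters with their defaults and units, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. The analysis problem

A paired design samples the same starving *D. discoideum* plates for bulk
RNA-seq (4 replicates at 0, 2, 4, 6, 8, 10 h; 24 libraries) and label-free
proteomics (3 replicates at 0, 2, 4, 8, 10 h; 15 samples, each sharing a
plate with one RNA sample). Three features dominate the statistics:

1. counts are overdispersed relative to Poisson;
2. protein quantification is left-censored — low-abundance proteins drop
   out, a missing-**not**-at-random mechanism;
3. protein levels trail mRNA levels because synthesis and turnover are slow.

## 2. The synthetic world

`generate_paired_dataset()` is first-class, tested code, not a fixture. Its
defaults *are* the stated experimental design; everything else was chosen
once to look like realistic bulk data and is configurable, not revisited.

**Trajectories.** Each gene draws an archetype: exponential ramps
`M(t) = M0 e^{kt}` with `k ~ U(0.10, 0.30) /h` (up) or the negative (down);
a smooth dip-and-recover (log-scale Gaussian well centred mid-course, depth
`U(0.8, 1.6)` log-units); a spike/dip that changes sharply between 0 and 2 h
and relaxes (`x e^{1-x}` pulse with a 1 h time constant); or flat. Baselines
`M0` are log-normal (`sdlog = 1`), giving the heavy-tailed abundance
distribution bulk RNA-seq shows. The default mix
(0.25/0.25/0.15/0.15/0.20) makes most genes developmentally regulated, as
observed in this system.

**Kinetics.** Protein obeys `dP/dt = alpha M(t) - delta P` with
`alpha ~ U(0.5, 2) /h`, `delta ~ U(0.2, 0.5) /h` (default; the lag studies
pin `delta = 1/3 /h`), initialised at steady state `P(0) = alpha M(0)/delta`.
The response time constant is `1/delta`, hence a 2–4 h effective lag for
`delta = 1/3`. Integration is fixed-step RK4 with 0.1 h steps on an mRNA
table sampled every 0.05 h, so half-steps need no interpolation; the
integrator is asserted against the closed-form solution for exponential
inputs at relative tolerance 1e-6.

**Noise.** Counts are NB with `var = mu + phi mu^2`, `phi = 0.05`, library
sizes `U(0.8, 1.2) x 10^6`. Intensities are
`log2(10^6 x P-fraction) + N(0, 0.25^2)`. A per-gene, per-plate Gaussian
effect (log2 s.d. 0.15) is *shared* by the RNA and protein sample from one
plate — the minimal mechanism that makes matched-plate correlations exceed
mismatched ones. Replicate-noise magnitudes are not published for this
design; these defaults were set once to produce the tight replicate
clustering typical of such experiments and must remain configurable.

**Censoring.** Each intensity `x` is missing with probability
`1/(1+exp(slope (x - midpoint)))` (defaults: midpoint 6 on the log2 ppm
scale, slope 1). `mnar_midpoint` may be a vector over protein time points:
a drifting detection limit (harsher late in the course) is the stated
mechanism behind the qualitative 0h-to-10h correlation decay that the
acceptance suite asserts by sign only.

**What the generator does not emulate** — and hence what a green test does
not establish: cell-type heterogeneity, compositional artefacts of
ribosomal/translation shutdown, batch structure beyond plates, peptide-level
measurement error, or the real abundance-dependence of NB dispersion. Tests
against it validate the *statistical machinery*, not biological effect
sizes.

## 3. Transcript differential expression

`nb_lrt()` fits, per gene, an NB GLM with log link and log size-factor
offsets: full model = one mean per time point, reduced = constant. The LRT
statistic `2(l_full - l_red)` is referred to chi-square with T-1 degrees of
freedom; BH adjustment across genes; DE at adjusted p < 0.01 (configurable).
Size factors are the median-of-ratios estimator rescaled to geometric mean 1,
with a total-count fallback (and warning) when no gene is positive
everywhere. Log fold changes versus the earliest time point use the fitted
normalised means with pseudocount 0.5.

**Dispersion.** The spec'd estimator is per-gene method of moments on
normalised counts. At 3–4 replicates per time point that estimate has so few
degrees of freedom that the plug-in chi-square LRT becomes anticonservative
(about 10% rejections at nominal 5% in the package's own null simulation).
We therefore stabilise it: the per-gene moment estimates are shrunk in log
space toward the across-gene pooled moment estimate, with the shrinkage
weight `tau^2/(tau^2+v_s)` obtained by estimating the estimator's pure
sampling variance `v_s` from one parametric null simulation at the pooled
dispersion (fixed internal seed, canonical column order, so results are
deterministic and invariant to reordering replicates). Excess observed
variance beyond `v_s` is attributed to real gene-to-gene dispersion spread
`tau^2`. This is still a moment construction — no Cox–Reid adjustment, no
posterior fold-change machinery — and it restores null uniformity (asserted
by KS in the acceptance suite).

**Fold-change shrinkage.** `shrink_logfc()` is a defined ridge replacement
for posterior shrinkage: per non-baseline time point the coefficient is the
MAP under a `Normal(0, prior_sd^2)` prior (log2 units) with the baseline
fixed at its MLE. Limits are exact: `prior_sd = Inf` returns the input,
`prior_sd = 0` returns zeros; low-information (low-count) genes shrink more.

**Transform.** `log2(normalised count + 4)` stands in for a variance
stabilising transform: monotone, flattening at low counts, trivially
invertible. It feeds PCA, z-scores and clustering only — never the tests.

## 4. Protein differential expression

`select_quantified_proteins()` applies the imputation gate: a protein
qualifies if it is observed in *all* replicates of at least one time point;
proteins observed only patchily are dropped. For qualifying proteins,
`impute_minprob()` draws every missing cell from
`Normal(q-quantile, (sigma_scale x sd)^2)` of that sample's observed values
(defaults `q = 0.01`, `sigma_scale = 1`, per-sample; fewer than 10 observed
values falls back to pooled parameters with a warning). Imputation is
column-wise because the censoring is intensity-driven within a run. Missing
cells in partially observed time points of qualifying genes are also drawn
from the MinProb distribution — the completeness rule gates *which genes*
qualify, not which cells are filled — because the downstream F-test needs a
complete matrix. The imputation seed is recorded on the output.

`moderated_f_test()` is a Smyth-style moderated F: OLS per gene with
time-point indicators, residual variance `s^2` on `d = n - T` df;
hyperparameters `(d0, s0^2)` of the scaled-inverse-chi-square prior by
moment-matching mean and variance of `log s^2` through digamma/trigamma
identities (the trigamma inverse is a Newton iteration); moderated variance
`(d0 s0^2 + d s^2)/(d0 + d)`; F referred to `F(T-1, d0+d)`. If the excess
variance of `log s^2` is non-positive the prior is degenerate (`d0 = Inf`)
and every gene's denominator is `s0^2`. Forcing `d0 = 0` reproduces the
classic per-gene F exactly — the no-moderation limit used in tests.

## 5. Concordance and the lag matrix

All cross-modality comparisons happen on the **fraction-of-total** scale:
each sample divided by its total (intensities de-logged first), so both
modalities sum to 1 and are comparable despite arbitrary units. The gene
universe is genes quantified in both modalities after imputation.

* `across_gene_correlation()` — replicate means per time point, Spearman
  with average ranks (tie handling was unstated; average ranks is the
  conventional choice).
* `lag_matrix()` — the full RNA-time x protein-time Spearman matrix. The
  estimated lag is the protein-minus-RNA offset maximising the mean
  correlation, restricted to offsets represented by at least two time-point
  pairs (a single pair is too noisy to define a lag; one shared time point
  gives lag 0 by convention).
* `rma_regression()` — ranged major axis: scale x and y by their ranges,
  major-axis (orthogonal) slope on the scaled data, back-transform,
  intercept through the means. Model II, symmetric under swapping x and y.
  For abundance regressions the inputs are log10 mean fractions with a
  1e-12 pseudo-fraction guarding zeros.
* `per_gene_correlations()` — Pearson per gene over plate-paired samples
  only; zero-variance genes are flagged undefined rather than silently
  dropped.
* `matched_vs_mismatched()` — permutes protein-to-plate assignment within
  each time point (identity excluded), p = fraction of permuted medians at
  least the matched one; 1000 permutations by default, seed mandatory.

## 6. Ratios and Dunnett contrasts

`ratio_matrix()` divides replicate-averaged protein fractions by mRNA
fractions (pseudo-fraction 1e-12; log2 kept alongside). Classes come from
the mRNA DE result: `up` if DE and FC(10h/0h) > 2, `down` if DE and
FC < 0.5, `other` otherwise. `dunnett_vs_baseline()` pools genes within a
class as independent observations — the published boxplots pool genes the
same way; per-gene pairing across time is a noted simplification, and a
repeated-measures variant is deliberately out of scope. The many-to-one t
statistics use pooled variance; family-wise adjustment comes from
Monte-Carlo draws of the maximum |t| under the contrast correlation
`corr(t_i, t_j) = lambda_i lambda_j`, `lambda_i = sqrt(n_i/(n_i+n_0))`,
using multivariate *t* draws so the two-group case reduces exactly (in the
MC limit) to the pooled t-test. Defaults: `n_mc = 20000`, two-sided,
contrasts reported when adjusted p < 0.1.

## 7. Multi-view factors

`fit_multiview_factors()` replaces probabilistic multi-omics factor
analysis with a deterministic construction: both views restricted to common
genes, replicate-averaged per time point (or aligned per-plate columns — a
flagged choice used when a view would otherwise have too few columns to
separate signal from noise), centred per gene, scaled to equal total
variance so the larger RNA view cannot dominate, stacked gene-wise, and
decomposed by truncated SVD. Variance explained of factor k in view v is
`100 ||d_k u_{k,v} v_k'||^2 / ||Y_v||^2`; per-view sums over all factors
reach exactly 100% at full rank. Signs are fixed by making each factor's
value at the last time point non-negative. Gaussian-process smoothness
priors and automatic relevance determination are *not* reproduced: the
analysis uses the factorisation descriptively (trajectories, variance
split, loadings), and those conclusions are testable under the stand-in.

Loadings are rescaled so the maximum |loading| per factor and view is 1;
the 0.45 both-view threshold of `select_factor_genes()` applies on that
scale. This scaling is declared, not equivalent to other tools'
conventions. `gsea_factor_weights()` tests the mean loading of a set against
same-size random draws from the view's universe, two-sided around the
universe mean (which makes p-values invariant to affine rescaling of
loadings), with the add-one permutation correction.

## 8. Numerical and design choices

* **Rounding** of reported percentages: half *up* to one decimal, matching
  printed-table precision (`round_half_up`).
* **Clustering**: Ward (`ward.D2`) on Euclidean logFC distances — the
  linkage was unstated; Ward gives the compact blocks heatmaps show.
  Clusters are relabelled by descending mean final-time logFC so labels are
  reproducible; clustering is fully deterministic.
* **Enrichment background**: all expressed (RNA) or quantified (protein)
  genes, not the genome; classic per-term Fisher (one-sided hypergeometric
  tail), no term-graph decorrelation; "top terms" = smallest p, ties broken
  by larger fold enrichment.
* **Degenerate inputs**: constant genes get zero LRT (null saturates),
  flagged all-zero z-trajectories, undefined per-gene r; empty matrices
  propagate as empty results; `n_genes = 0` is a valid dataset.
* **Determinism**: every stochastic entry point takes a seed;
  `with_seed()` restores the caller's RNG state. Identical configurations
  give bit-identical datasets.
* **Spec-conflict note**: one published worked example for the Spearman
  rank formula (a 5-vector pair said to give 0.7) is arithmetically 0.8;
  the tests assert the value the rank formula actually yields.

## 9. Known limitations

* The NB LRT relies on a chi-square asymptotic at 3–4 replicates per group;
  calibration is demonstrated at the simulated depths, not guaranteed for
  very low counts.
* Dunnett contrasts treat genes as independent; genes recur across time
  points, so the contrasts are descriptive for real data.
* The SVD factorisation has no smoothness prior: factor trajectories are
  raw values, and loess smoothing is considered plotting convenience.
* Acceptance-scale simulations are deliberately sized for minutes of
  runtime (2000 genes, 20 seeds); headline correlations of the motivating
  dataset are not reproducible at desk scale and are asserted only as
  directions, mechanisms, and arithmetic identities.
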