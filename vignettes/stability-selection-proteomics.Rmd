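---
title: "Stability-selected differential abundance for label-free proteomics"
author: "lfqStability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-selected differential abundance for label-free proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Label-free quantitative (LFQ) proteomics of clinical tissue — here the
motivating setting is visceral adipose tissue from diabetic (DM) versus
non-diabetic (NDM) subjects — produces a proteins × samples intensity matrix
with a characteristic pathology: values are missing not at random. A
protein's chance of being quantified falls as its abundance approaches the
instrument's detection limit, so missingness is left-censored and
concentrates in low-abundance proteins, sometimes wiping out one disease
group entirely. Any differential-abundance analysis has to take a position
on those holes, and any position taken once is fragile: a single random
imputation can flip a borderline protein in or out of the significant list.

`lfqStability` implements a complete, testable version of a pragmatic
answer: normalize, split proteins by how much data they actually have,
repeat the imputation many times, and only believe findings that survive
most repetitions.

# The model and procedure

## Normalization and routing

Sample intensities (log2 scale) are shifted additively so every sample
median equals the median of the original per-sample medians
(`medianNormalize()`). Missing entries are ignored in the medians — filling
them with zeros would drag medians down exactly for the most censored
samples. The additive-on-log2 convention (multiplicative on the raw scale)
preserves within-sample differences, hence fold-change semantics.

Proteins observed in at least `minPerGroup = 4` samples in *both* groups go
to the quantitative path; the rest go to a detection-limit heuristic
(`routeByMissingness()`). The heuristic (`classifyDetectionLimit()`) calls a
protein uniquely expressed in one group when it is observed in at least
`ceiling(0.7 n)` samples of that group and at most `floor(0.1 n)` of the
other (7 and 1 for 10-per-group designs). These thresholds are not forced by
any identity; they encode "clearly present here, essentially absent there"
while tolerating one stray identification, and both are exposed as
arguments. An alternative strict reading (zero detections allowed in the
absent group) is one setting away (`nmaxAbsent = 0`).

## Repeated imputation, moderated regression, stability selection

For each of `M = 50` rounds (`runStabilitySelection()`):

1. **Impute.** Every missing entry of protein $g$ in group $G$ is drawn
   independently from $\mathcal{N}(\hat\mu_{gG}, \hat\sigma_{gG})$, the mean
   and SD of the *observed* $(g, G)$ values (`imputeOnce()`).
2. **Fit.** Per protein, ordinary least squares of log2 intensity on an
   intercept, a disease indicator and reference-coded preparation-batch
   indicators (`fitLinearModels()`). The disease coefficient is the log2
   fold change, DM − NDM. The batch reference is the first level
   lexicographically; the disease coefficient is invariant to that choice.
   A design in which batch is confounded with disease is refused before
   fitting.
3. **Moderate.** An empirical-Bayes prior for the residual variances is
   estimated by moment matching on the log scale (`estimateEBPrior()`):
   under $s_g^2 \sim s_0^2\,(\chi^2_{d}/d)/(\chi^2_{d_0}/d_0)$,
   $\mathrm{Var}[\log s_g^2] = \psi'(d/2) + \psi'(d_0/2)$, so $d_0$ solves
   $\psi'(d_0/2) = \widehat{\mathrm{Var}}[\log s^2] - \psi'(d/2)$
   (Newton inversion of the trigamma function) and $s_0^2$ follows from the
   mean of $\log s^2$. The posterior variance
   $\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ gives the moderated
   statistic $t_g = \hat\beta_g / (u_g \tilde s_g)$ with $d_0 + d$ total
   degrees of freedom (`moderateT()`), where $u_g$ is the unscaled SE
   multiplier from the design.
4. **Adjust.** Per-round q-values, Benjamini–Hochberg by default
   (`computeQvalues()`; Storey's $\hat\pi_0(\lambda = 0.5)$ variant is
   available by flag — the two differ only by the $\hat\pi_0$ factor).
5. **Select.** A protein is called differentially abundant when $q < 0.1$
   in at least $\lceil 0.6 M\rceil$ rounds — 30 of 50 (`stabilityAggregate()`).

Reported per-protein effect sizes and q-values are **medians across
rounds**. Nothing in the procedure forces that summary (a mean or a single
representative round would be defensible); medians were chosen for
robustness against occasional extreme completions, and the per-round table
is retained so any other summary can be recomputed.

Numerical choices worth stating: the prior is re-estimated in every round
(each completed matrix is a full dataset and its variance spectrum shifts
with the imputed values); zero residual variances are excluded from prior
estimation and then moderated normally; when the log-variance moment
equation has no positive solution the variances are pooled completely
($d_0 = \infty$) with $s_0^2$ their arithmetic mean — the unbiased pooled
estimator, which also returns the common value exactly when all variances
are equal; with $d_0 = \infty$ the reference distribution is the normal
limit of the $t$. Round $r$ uses a child seed drawn up front from the master
seed, so rounds are individually replayable and the whole run is
bit-reproducible.

## Category enrichment and redundancy clustering

Set-level analysis (`meanStatEnrichment()`) scores a category by the mean of
its members' moderated t-statistics (median across rounds), compared with
`nPerm = 10000` equally sized random subsets of the universe, drawn without
replacement — a protein-label null. Sample permutation is not an option at
this interface: the enrichment stage consumes one t per protein, not the
sample-level data. Directional p-values use the add-one estimator
$(1 + \#\{\bar t^{\ast} \ge \bar t\})/(B + 1)$, so they are never zero, and
BH control is applied within each direction at a 10% FDR.

Significant categories are then clustered on overlap-coefficient distance,
$1 - |A \cap B| / \min(|A|, |B|)$ (`overlapDistance()`,
`clusterCategories()`). The overlap coefficient — rather than Jaccard — is
deliberate: a GO child term nested inside its parent is at distance 0 and
should read as redundant. Average-linkage trees are cut at height 0.7 and
clusters smaller than `minNodes = 3` are absorbed into their nearest cluster
when the merge height stays within 0.8 — a deterministic, order-invariant
approximation of adaptive tree cutting that reproduces the two behaviours
that matter (near-duplicates collapse; unrelated categories at distance 1
never merge). Clusters of at least 3 categories are flagged for reporting,
represented by their lowest-p member (ties: larger $|\bar t|$, then
lexically first id).

## Transcriptome concordance

The gene layer enters as a finished differential-expression table. DEGs are
genes with $p \le 0.05$ and $|\mathrm{logFC}| \ge 0.5$, both inclusive
(`callDEG()`). `intersectMolecules()` maps called proteins to gene symbols
through a user-supplied offline table (no live database lookups; unmapped
ids are reported, never dropped) and intersects with the DEG list;
`intersectCategories()` intersects significant-category ids between layers.
How the two layers' category significance was harmonized is the caller's
responsibility; the package intersects the lists it is given.

# The synthetic-data generator

`simulateProteome()` generates the structure the analysis assumes:
$y_{gs} = \mu_g + \delta_g\,\mathbb{1}[s \in \mathrm{DM}] + b_{B(s)} +
\varepsilon_{gs}$, $\varepsilon_{gs} \sim \mathcal{N}(0, \sigma_g^2)$,
$\sigma_g^2 \sim s_0^{2\ast} d_0^\ast / \chi^2_{d_0^\ast}$, with probit
left-censoring $P(\text{missing}) = \Phi((m - y)/w)$ and a fraction of
proteins forced fully missing in one group. Batches are assigned round-robin
within each group, so disease and batch are never confounded and both
predictors stay estimable.

Defaults are one fixed set of study conditions, chosen to mirror a
10-vs-10 clinical LFQ comparison: baseline log2 intensities
$\mathcal{N}(25, 2^2)$ (typical LFQ dynamic range), residual variance prior
$d_0^\ast = 6$, $s_0^{2\ast} = 0.16$ (residual log2 SD ≈ 0.4, ≈ 30% CV,
ordinary for between-subject tissue proteomics), batch SD 0.25 (batch
effects real but smaller than biology), two batches (a two-digit cohort
prepared in two sittings), censor width 1 log2 unit and midpoint 23.45,
which yields ≈ 25% missing entries concentrated in low-abundance proteins,
10% of proteins affected at 1 log2 unit (twofold, the magnitude of the
larger effects seen in such studies), and 2% group-unique proteins.

What the generator does **not** emulate: peptide-level structure and shared
peptides, intensity-dependent (heteroscedastic mean-variance) noise,
correlated proteins (complexes, pathways co-regulation beyond the planted
categories), batch×protein interactions, and contaminants. Passing
calibration tests on this generator therefore says the pipeline's inference
behaves as designed under its own assumptions — not that those assumptions
hold in any particular real dataset.

`simulateGeneTable()` and `makeCategoryCollection()` provide the gene layer
and category collections (with optional planted directional signal and a
guaranteed ≥ 90%-overlap duplicate pair) for the concordance and enrichment
stages.

# Problem sizes in the test suite

The shipped tests run the full machinery at reduced but honest sizes:
calibration studies use 2000 proteins × 20 samples with M = 20 rounds over
20 (null) and 10 (planted) replicates; enrichment recovery uses 800 proteins
with 6 rounds over 10 replicates; oracle checks (exhaustive enumeration,
hand OLS, BH by hand, grid-search likelihood for the prior) use deliberately
tiny inputs where the truth is computable exactly.

# Known limitations

* **Single-imputation optimism.** Imputed entries are treated as real
  observations. A protein observed in only $k \approx 4$ of $n = 10$
  samples per group has a true sampling SE proportional to $\sqrt{2/k}$,
  while the completed-data model uses $\sqrt{2/n}$ — null $|t|$ inflated by
  about $\sqrt{n/k}$. Left-censor truncation compounds this by deflating
  the observed SD used both for imputation and in the residual variance.
  Crucially, the distortion is a function of the *fixed observed data*, so
  it recurs in (nearly) every imputation round and the ≥ 60%-of-rounds
  stability rule does not remove it: on null simulations at ≈ 25%
  missingness, false calls concentrate precisely in proteins with 4–6
  observations per group, and the realized false-discovery proportion under
  planted effects runs above the nominal 10% (≈ 0.18 in the shipped
  calibration study). Rubin-style between-imputation variance pooling would
  repair this but is a different procedure from the one implemented here.
  Treat calls on proteins near the 4-per-group floor with caution.
* **Sensitivity is conditional on quantifiability.** Recovery rates are
  reported among proteins on the quantitative path; proteins censored below
  the 4-per-group routing floor are not testable by this (or any) method
  from the same interface.
* The adaptive tree cut is a deterministic approximation, not the published
  dynamic tree cut algorithm; for heavily nested collections the cluster
  boundaries can differ.
* The heuristic's unique-expression thresholds are conventions, not
  estimates; they should be revisited for group sizes far from 10.
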