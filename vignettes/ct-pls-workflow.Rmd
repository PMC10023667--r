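---
title: "Consensus cortical-thickness gene discovery with PLS: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus cortical-thickness gene discovery with PLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ctpls)
```

## The scientific problem

Regional cortical thickness (CT), estimated from structural MRI, varies
systematically across the cortical sheet, and part of that variation tracks
the regional expression of specific genes — myelination, dendrite and spine
genes most prominently.  Given (i) a regional expression atlas (genes
quantified in each of ~100 anatomically defined cortical regions) and (ii)
mean CT per region in several age groups, this package identifies the genes
whose expression profile across regions aligns with the CT profile
*consistently in every age group*, splits them by direction of association
(PLS1+ overexpressed where cortex is thick, PLS1− where it is thin), and
asks which cell types and functional gene panels they are enriched in.

## The inference model

### PLS1 and its closed form

For one age group, let $X$ be the regions × genes matrix with columns
standardised to mean 0 and s.d. 1, and $y$ the centred CT vector.  The first
partial least squares component is the unit vector $w$ maximising
$\mathrm{cov}(Xw, y)$; for a single response this has the closed form

$$ w = X^\top y \, / \, \lVert X^\top y \rVert , $$

with scores $t = Xw$.  `fit_pls1()` uses this closed form; the test suite
verifies it against an independently implemented iterative NIPALS first
component to $10^{-8}$ on random matrices.  The component sign is arbitrary,
so it is fixed by the convention $\mathrm{cor}(t, y) \ge 0$; constant genes
receive weight 0.  Explained variance is reported as
$\mathrm{cor}^2(t, y)$ — the fraction of response variance captured by the
single component — and, separately, as the fraction of predictor variance
carried by $t$ (`explained_var_x`), since either convention appears in the
imaging-transcriptomics literature.

### Permutation test

Significance of the explained variance is assessed by shuffling $y$ over
regions (default 10,000 permutations in the pipeline interface) and
refitting.  The p value uses the add-one estimator
$(1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$, which cannot
return 0 and is exactly valid under exchangeability.  Because only $y$
changes, the permuted statistic is computed from the precomputed Gram matrix
$K = XX^\top$ ($t \propto K y$), making $10^4$ permutations cheap.

One property of this statistic deserves emphasis.  When the number of genes
vastly exceeds the number of regions *and genes are close to independent
noise*, $K y \approx c\,(y - \bar y)$ for any $y$, so
$\mathrm{cor}^2(t, y)$ saturates near 1 under the null; the permutation
test remains exactly calibrated (the test suite verifies the 5% rejection
rate on 200 null atlases), but the statistic has little power against the
kind of sparse planted signal our generator produces, and the observed value
can even fall below the permutation distribution.  Real cortical
transcriptomes are strongly structured (highly correlated gene modules,
low effective rank), which is the regime where this classical statistic is
informative.  The package therefore treats the permutation test as a
calibrated significance machine, and the synthetic validation rests on the
bootstrap/consensus recovery rather than on permutation p values.

### Bootstrap Z-scores

The error of each gene's weight is estimated by resampling regions with
replacement (default 1000 replicates) and refitting.  PLS component signs
are arbitrary, so each replicate's weight vector is aligned to the original
fit by flipping it when its dot product with the original weights is
negative; without this alignment the standard errors are inflated by sign
flips and the Z-scores collapse.  The per-gene standard error is the s.d.
of aligned replicate weights and $Z = w/\mathrm{se}$.  Replicates whose
resampled response is constant, or whose cross-covariance is identically
zero, are discarded and counted (`n_degenerate`); more than 50% degenerate
replicates aborts the run.  A gene with $\mathrm{se} = 0$ and nonzero
weight receives a signed-infinity Z and is treated as selected — a
documented sentinel rather than an error, since it arises only in degenerate
fixtures.

### Selection, persistence, consensus

Per age: PLS1+ genes have $Z > 3$ and PLS1− genes $Z < -3$ (strict).
Independently, each gene's Pearson correlation $r$ with CT is computed with
its two-sided t-transform p value, Benjamini–Hochberg adjusted across all
genes *within that age* (one FDR family per age); the gene is CT-correlated
when $|r| > 0.3$ (strict — a gene at exactly the threshold is excluded) and
$q < 0.05$.  Persistent genes pass the Z threshold with the same sign at
every age; plus and minus persistence are intersected separately, since a
sign flip between ages is not a persistent association.  The consensus
PLS1+/PLS1− lists are the persistent sets intersected with the genes
CT-correlated at every age.  Sign consistency of $r$ across ages is *not*
required — only $|r|$ and $q$ per age — though in practice the Z-persistence
filter makes sign flips in the consensus essentially impossible.  Raising
either threshold can only shrink the consensus (tested as a monotonicity
property).

As a sensitivity interface, `age_model_inputs()` fits per-region OLS of CT
on age and exposes the intercepts (regional CT differences) and slopes
(regional ageing effects) as alternative PLS responses.

## Exact statistics

Enrichment uses a self-contained two-sided Fisher's exact test:
the p value sums the hypergeometric masses of all same-margin tables whose
probability does not exceed the observed one (probability ties resolved at
relative tolerance $10^{-7}$, since exact float equality of hypergeometric
masses is unreliable); the odds ratio is the conditional MLE under the
noncentral hypergeometric model, solved from the conditional mean equation
at root tolerance $10^{-12}$, with the exact conditional 95% CI from
inverting the one-sided tail tests.  Boundary conventions: $a$ at the
support minimum (any table with $a = 0$) gives OR 0; at the maximum (e.g.
$b = 0$ or $c = 0$ with $a > 0$) gives OR $\infty$; a zero margin collapses
the support to a point, giving $p = 1$ and an undefined OR.  The sample
cross-product $ad/bc$ is emitted alongside as `or_sample`.  The test suite
checks the p value and cMLE OR exhaustively against brute-force enumeration
and golden-section oracles for every 2×2 table with $n \le 40$, and against
`stats::fisher.test` as an independent cross-check (at 2%, the accuracy of
that function's default root tolerance).

`bh_adjust()` validates its input and delegates to `stats::p.adjust`; note
that BH is *not* idempotent (the step-up factors reapply), so only
monotonicity and the $q \ge p$ bound are meaningful invariants.

## Preprocessing rules

* **Sample QC.**  Seven metrics; a sample accrues one outlier index per
  violated rule: percent uniquely mapped reads < 50 (absolute), $z > 2$ for
  percent intergenic bases / GC dropout / AT dropout, $z < -2$ for percent
  high-quality aligned reads / percent mRNA bases / median 5′–3′ bias.
  Removal requires more than two indexes (i.e. at least three).  The z
  scores use the sample (n−1) s.d. — the convention matching R's `sd()` —
  configurable to the population denominator.  Z scores are computed once on
  all samples, not recomputed after removing absolute-rule failures.  The
  additional manual outlier screening step sometimes applied in practice
  (PCA/clustering inspection) has no stated rule and is deliberately not
  implemented.
* **Expressed genes.**  Detected means value > 0 (configurable threshold);
  kept when detected in ≥ 10% of samples, boundary inclusive.
* **Low-expression filter.**  Ranks genes by mean expression and drops the
  lowest `floor(0.05 · G)`; ties break by gene id.  Being a fixed-fraction
  rank filter it is *not* idempotent — reapplying it drops further genes —
  whereas the detection filter is.
* **Region aggregation.**  Unweighted arithmetic mean over a region's
  samples, hemispheres pooled; regions under a minimum sample count are
  excluded and reported.
* **CT table.**  Mean CT per region per age; age groups with fewer than 2
  animals are dropped (reproducing the usual exclusion of a singleton oldest
  animal), configurable.
* **Display transform.**  For panel visualisation each gene is shown as
  $2^{x - \mathrm{median}(x)}$, putting all genes on a positive scale with
  per-gene median 1.

## The synthetic generator: what it emulates and what it does not

The generator produces one shared regions × genes expression matrix
(log-scale Gaussian around per-gene baselines, clamped at 0 — truncation is
rare at the default baseline) and a per-age CT table, mirroring the design
in which a single adult expression atlas is regressed against CT at several
ages.

**CT geometry.**  CT is a shared standardised regional profile $z$ plus
per-age deviations: any two ages correlate `age_cor` across regions.  The
profile is standardised in sample and the deviations are orthogonalised
against it, so the profile–CT correlation is exactly
$\sqrt{\texttt{age\_cor}}$ for every age and seed; planted-gene calibration
then fluctuates only through per-gene noise.  The default `age_cor = 0.7`
reflects regional CT rankings that are largely stable across development
while leaving genuine age-specific variation.  A mild linear age trend
(default −0.02 mm/yr) shifts the per-age means without affecting
cross-region correlations.

**Persistent genes.**  A planted gene tracks the shared profile with
coefficient $a = r^* \sigma / \sqrt{\texttt{age\_cor} - r^{*2}}$
($\sigma$ = noise s.d.), which makes its expected correlation with CT equal
the target $r^*$ at *every* age; the familiar single-response calibration
$a = r^*\sigma/(\mathrm{sd}(y)\sqrt{1 - r^{*2}})$ is the `age_cor = 1`
special case.  This also exposes a genuine geometric constraint of the
shared-matrix design: a single expression vector cannot correlate strongly
with several age-specific CT vectors unless those vectors share structure,
hence the requirement $r^{*2} < \texttt{age\_cor}$ enforced at
configuration time.

**Transient genes** (associated at only a strict subset of ages; default
all-but-one, the hardest case for the persistence filter) are built from
the realised standardised CT vectors by solving the realised Gram system
for in-sample covariance `transient_r` (default 0.4) with every active age
and exactly 0 with the inactive age, plus Gaussian noise filling the
variance to 1.  The same geometry dictates that the active-age correlation
of a gene with a sharp dropout cannot reach the persistent genes' 0.6 when
ages correlate 0.7 — the construction errors if the request is infeasible.
Transient genes are therefore plausibly *selected* at their active ages but
reliably fail both the Z and the correlation filter at the inactive age,
which is exactly what the persistence intersection must exploit.

**QC fixtures.**  Clean samples draw each metric from a bounded uniform
spread, so a clean sample cannot reach $|z| > 2$ on its own; each planted
outlier violates the absolute unique-mapping rule plus two directional z
rules, 20 spreads out, with the z-rule pairs rotating round-robin over the
six z-scored metrics so no single metric's mean and s.d. are dragged enough
to mask the outliers.  This makes outlier recovery exact by construction,
provided `n_outliers ≤ floor(n_samples/3)` — beyond that, pooled z scores
provably lose separation (with $k$ outliers on one metric the attainable z
is $\sqrt{(n-k)/k}$), so the generator refuses, including the degenerate
all-outlier case.

**Marker sets** draw a chosen fraction of their members from a designated
planted tail (alternating positive/negative across sets, mimicking neuronal
vs oligodendroglial markers) and the rest from non-planted genes, recording
the realised 2×2 table and its cross-product OR so enrichment recovery is
checkable in closed form.

**What the generator does not emulate:** spatial autocorrelation of
cortical maps (so no spin-test nulls are needed or provided), count-level
sequencing noise (the pipeline operates post-normalisation), correlated
gene modules, batch structure, and hemispheric asymmetry.  Passing the
recovery tests therefore demonstrates the correctness of the selection
machinery under its stated model, not robustness to spatially
autocorrelated or module-structured noise.

## Validation problem sizes

The test suite validates: the PLS1 closed form on 100 random matrices
(20–97 regions × 50–500 genes); permutation calibration on 200 null
atlases of 97 regions × 500 genes at 500 permutations each; planted
recovery on the default study conditions (97 × 2000, 50/40 planted at 0.6,
10 transient, 500 bootstrap replicates) with precision and recall ≥ 0.9 and
zero transient leakage; the Fisher machinery exhaustively for all 2×2
tables with $n \le 40$; BH on 1000 random vectors; QC recovery on 100
random fixtures; the threshold boundary semantics; and the invariance
suite (response scaling, joint region permutation, threshold monotonicity,
enrichment margin sum rule).  `scripts/acceptance.R` re-runs the headline
recovery, calibration, enrichment and QC computations from scratch at a
user-supplied seed.

## Known limitations

* The enrichment universe defaults to the analysed (expressed, filtered)
  genes; annotated-genome universes change the ORs and are the caller's
  choice via `gene_set_collection()`.
* Marker calling uses a Wilcoxon rank-sum test, not a single-cell
  model-based test; it is a fixture-level utility, adequate for the clearly
  separated profiles it is used on here.
* One PLS component only; no deflation or multi-component analysis.
* The bootstrap standard error is the s.d. of aligned replicate weights
  (centred), not the RMS deviation from the original weights.
* Orchestration is exposed as R functions (`run_pipeline()` and the stage
  functions); there is no shell entry point.
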