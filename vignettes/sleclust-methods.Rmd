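---
title: "Methods: integrative subtyping of SLE cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative subtyping of SLE cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sleclust)
```

This vignette is the package's own account of the statistical methods it
implements, the assumptions behind them, and the design decisions taken
where the methodology was genuinely open.

## The analysis in one paragraph

Patients are described by binary ACR classification criteria. Multiple
correspondence analysis (MCA) embeds these profiles in a low-dimensional
Euclidean space; K-means on the retained dimensions yields candidate
partitions, and the number of clusters is selected by bootstrap Jaccard
stability. The clusters — relabelled `M < S1 < S2` by mean severity —
then become the outcome of a chain of covariate-adjusted linear models:
per-CpG ANOVA for differential methylation, additive-dosage regressions
for cis-meQTL, and a four-condition causal inference test (CIT) asking
whether methylation mediates SNP–cluster associations. Enrichment
analyses (gene-set hypergeometric, chromatin-state Fisher, and an
ethnicity label-permutation test) characterize the hit set, and a random
forest transfers the subtype labels to an external cohort for
replication.

## Phenotypic clustering

**MCA.** The binary criteria matrix is expanded to a complete indicator
matrix (absent/present category pair per criterion) and analysed by
correspondence analysis: SVD of the standardized residuals
`(P − rcᵀ)/√(rcᵀ)` of the relative-frequency table. Row coordinates are
returned in principal scale (`F = D_r^{-1/2} U Σ`). For Q complete
binary variables the total inertia is `J/Q − 1 = 1` with `J = 2Q`
categories; this identity and agreement with an independent
correspondence-analysis implementation are asserted in the test suite.
Dimension signs are fixed by the skewness of the category loadings so
results are reproducible across platforms and row orderings.

**Dimension count.** Following the cross-validation idea used by
imputation-based selectors, random cells of the indicator matrix are
held out in k folds, imputed by an iterative *regularized* rank-d SVD
(singular values shrunk by the residual-noise estimate — without the
shrinkage, higher ranks overfit the held-out cells and the curve is
monotone in d), and d is chosen to minimize held-out squared error with
ties broken downward. On the default cohorts this selects 2 dimensions,
and the pipeline enforces a minimum of 2 so K-means always works on a
plane.

**K-means and stability.** K-means uses k-means++ seeding, Lloyd
iterations, and the best of 50 restarts (10 for bootstrap re-clustering;
the re-clustering only needs to find the same local optimum, not polish
it). For each candidate k, every original cluster is matched to its
best-Jaccard counterpart in each of B bootstrap re-clusterings
(computed over the distinct resampled points, the `clusterboot`
convention); the selected k maximizes the *minimum* per-cluster mean
stability — a conservative reading of the rule that every retained
cluster must be stable (flag threshold 0.82). Severity ordering uses a
supplied severity index when available, otherwise mean criterion count,
with ties broken by renal-criterion prevalence and then label order.

**What recovery can and cannot show.** The generator draws criteria as
conditionally independent Bernoulli given the latent cluster, with the
published cluster-specific prevalences. Under this model the three
clusters genuinely overlap: even the Bayes-optimal classifier (known
prevalences and priors) misassigns roughly one patient in eight, which
bounds any clustering method's adjusted Rand index against the *latent*
labels near 0.6–0.7. The test suite therefore checks that the
discovered partition approaches the Bayes partition (computable in
simulation), and the acceptance script reports the measured ARI against
the latent truth without asserting an unreachable threshold. In real
cohorts the criteria are correlated within cluster, and published
subtypes are themselves the output of clustering, so neither number is
directly comparable to this ceiling.

## Adjustment covariates

* **Medication PCs** — centered PCA of the binary
  current-medication matrix; the retained count is chosen by the same
  cell-wise cross-validation (3 folds), capped at 3. Computed on the full
  cohort, since medications enter all models as global confounders.
* **Cell-composition surrogates** — a ReFACTor-style procedure:
  standardize sites, rank sites by distance to their rank-k SVD
  reconstruction, take the t best-reconstructed sites, and use the top k
  PCs of those sites as surrogates. Defaults k = 6, t = 500 (the
  published defaults of the algorithm this emulates); the pipeline uses
  k = 4 on desk-scale cohorts.
* **Ancestry PCs** — PCA of mean-imputed dosages standardized by
  `√(2p(1−p))`; the top 3 scores enter every association model.

A caveat discovered during development and kept on record: on
desk-scale synthetic cohorts the disease axis is an artificially large
share of total methylome variance (hundreds of shifted CpGs among
thousands, versus hundreds among ~800k on a real array), so
reference-free surrogates partially absorb the cluster signal. The
module-level power and mediation analyses therefore adjust for the
generator's *true* cell-factor scores — they test the association
machinery, not the surrogate estimator, which has its own recovery
tests — while the end-to-end pipeline uses the estimated surrogates, as
a real analysis must.

## Differential methylation

Per CpG, an ordinary least-squares fit of the beta value on the cluster
factor plus covariates; the cluster factor is tested by a partial
F-test (k − 1 numerator df) and BH-adjusted across CpGs (FDR 0.1).
Effect sizes are reported as Δβ — differences of covariate-adjusted
cluster means on the beta scale. Two deliberate choices:

* **Beta values, not M-values.** Effects are reported on the beta scale
  throughout; an M-value mode (`use_mvalues = TRUE`) exists because
  which scale entered the original models is not documented. With ~333
  samples the choice is immaterial for calibration (the type-I test in
  the suite runs on betas).
* **No empirical-Bayes moderation.** With n ≈ 333 the residual df is
  large and variance moderation changes little; plain OLS keeps the
  model transparent and exactly matched by the normal-equations oracle
  in the tests.
* **Age stays in the model** (the documented covariate lists are
  ambiguous about it); dropping it is a one-line covariate-table edit.

The "nestedF"-style decomposition is implemented as an overall-F gate at
FDR 0.1 followed by per-pair t-contrasts from the same fitted model,
BH-adjusted within contrast. Zero-variance CpGs are recorded with p = 1
and flagged, never dropped silently. Inflation is summarized by
λ = median(χ²₁ quantile of 1 − p) / qchisq(0.5, 1), which is exactly 1
when all p = 0.5.

## cis-meQTL

QC order is call rate (≥ 95 %) → MAF (strictly > 5 % retained) → HWE
exact test (p ≥ 1e-4 kept; the exact conditional test is enumerated from
first principles and verified against a brute-force oracle for all
totals ≤ 50). LD pruning is windowed greedy (50 SNPs, step 5 — the
conventional defaults; only the r² ≤ 0.8 ceiling is prescribed), keeping
the earlier-positioned SNP. Cis pairs are SNP–CpG pairs on the same
chromosome strictly closer than 1 Mb, with the CpG located at its single
manifest coordinate. Per pair, methylation is regressed on dosage plus
covariates (missing dosages mean-imputed within SNP); estimation uses
Frisch–Waugh residualization, which is algebraically identical to the
full model and is verified against it. By default only
cluster-associated CpGs are scanned (the question the pipeline asks is
which *hits* are under genetic control); `restrict_meqtl_to_hits =
FALSE` scans everything.

## Causal inference test

For a triplet (G, M, Y) with Y the ordinal cluster label (M = 0,
S1 = 1, S2 = 2 — a binary severe-vs-mild recoding is a trivial
preprocessing step), the four component p-values are: (1) F-test of G in
`Y ~ G + W`; (2) F-test of G in `M ~ G + Y + W`; (3) F-test of M in
`Y ~ M + G + W`; (4) a permutation equivalence test of conditional
independence of G and Y given M. Covariates W enter all four components.

Component 4 deserves its own paragraph, since only the max-p convention
is prescribed and the permutation machinery had to be designed.
Residualize G on Y (and W), permute those residuals, and add them back
to the fitted part: the permuted G\* preserves the *marginal* G–Y
association but destroys the mediated (through-M) pathway. Comparing
the observed conditional F statistic of G in `Y ~ M + G + W` against
the permuted F\* distribution, `p4 = (1 + #{F* ≤ F_obs})/(n_perm + 1)`,
gives exactly the behaviour the max-p test needs: under true mediation
the observed F is central while the F\* carry the undestroyed marginal
association, so p4 hits its floor; when conditional dependence remains
(direct effect, reverse causation), F_obs sits among or above the F\*
and p4 is large; under the global null everything is exchangeable and
p4 is uniform, so the four-way maximum is conservative (verified at
1,000 global-null replicates in the suite). n_perm defaults to 1,000
and its floor `1/(n_perm+1)` bounds the smallest achievable CIT p-value.

Screening follows the two-stage design: meQTL SNPs are first tested for
cluster association (same adjusted model, BH FDR 0.05); the CIT runs on
the survivors, and BH is applied across CIT p-values. The
`mediation_effect_profile()` helper fits Y on G with and without M to
show the coefficient shrinking toward zero under mediation.

## Enrichment

* **Gene sets** — upper-tail hypergeometric on gene overlap; GMT input.
* **Chromatin states** — each CpG is assigned the state covering its
  position (BED, 0-based half-open; manifest positions are 1-based and
  converted), one 2×2 Fisher exact test per state and cell type,
  BH across all of them; unassignable CpGs are excluded and counted.
* **Ethnicity permutation** — for the cluster-associated CpG set, count
  CpGs whose ethnicity term (joint partial F over all factor levels —
  per-level testing would make the count depend on the reference level)
  is significant, then recompute that count under label permutations;
  the enrichment statistic is the observed proportion over the null
  mean and the p-value uses the add-one estimator, so its floor is
  `1/(n_perm+1)`. Both a raw-p (default, α = 0.05) and an FDR-based
  counting mode exist because the two appear in different places in the
  source methodology.

## Cohort transfer

The random forest is trained on criteria with the discovered labels,
grid-searched over trees ∈ {250, 500, 1000} and features-per-split
∈ {√p, p/3, p} by out-of-bag error (no grid is documented in the
source; this is the standard one), with the full error curve retained.
External criteria are aligned by column name. Validation re-runs the
cluster ANOVA in the external cohort with its reduced covariate set and
correlates external vs discovery Δβ per contrast. The platform
intersection (e.g. 450k vs EPIC) is an explicit CpG list argument.

## The synthetic cohort generator

`simulate_cohort()` is the package's substitute for restricted patient
data and defines the study conditions for every calibration and
recovery claim. Defaults: n = 333 patients in three clusters of
101/154/78; 18 criteria with the published cluster-specific
prevalences; 20,000 CpGs of which 256 carry cluster shifts of ±0.05
(beta scale); 1,000 SNPs with 50 plain cis-meQTLs (0.05/allele) and 15
mediation triplets (5 causal, 5 reactive, 5 independent); two latent
cell factors (one correlated 0.3 with severity) loading on 2,000 CpGs;
5 ethnicity groups with severity offsets producing the observed
mild-cluster enrichment of White patients, plus 200 CpGs with
non-genetic ethnic shifts (80 % inside the cluster-CpG set); 8
medications, half severity-correlated, driving 20 CpGs; Balding–Nichols
allele-frequency divergence (Fst 0.02) across ethnic groups. Planted
SNPs sit on common variants (MAF 0.2–0.4) so every planted effect is
tested at comparable power; mediation edges default to gm = 0.05
(meQTL R² ≈ 0.5), my = 2 (per-SD propensity weight) — a meQTL so strong
that M has no residual variation cannot be detected as a mediator by
any conditional-independence test, so "strong mediation" requires a
moderate, not maximal, G→M edge.

All methylation is composed on the logit scale and inverse-transformed,
guaranteeing beta ∈ (0, 1) without boundary pile-up. Cluster labels are
a rank-cut of a latent severity propensity (ethnicity offsets + mediator
methylation + direct genetic effects + noise), which yields exact
cluster sizes and a monotone severity interpretation. The biology layer
(coordinates, allele frequencies, base levels, effect signs and
loadings) is seeded by `effect_seed`, the sampling layer by `seed`;
sharing the former across two cohorts emulates a replication study.

What the generator does **not** emulate: array chemistry and detection
failures, linkage disequilibrium beyond what QC fixtures construct,
family structure, criterion correlations within cluster, batch effects,
and cell-type-specific methylation (factors are global additive
surrogate-like terms). Passing tests on this generator therefore show
the estimators do what they claim under their own assumptions — not
that those assumptions hold in any real cohort.

## Numerical choices and problem sizes

Tolerances: oracle-equivalence checks at 1e-8; MCA inertia identities
at 1e-10; sign-indeterminate comparisons always up to per-dimension
sign. Degenerate inputs have defined behaviour (constant criteria →
error; zero-variance CpG → p = 1 + flag; monomorphic SNPs → removed at
the MAF step; empty distance-decay bins → NA). All randomness flows
from one seed through fixed per-component offsets, so any stage can be
reproduced in isolation and the pipeline is bit-identical across reruns.

The calibration and recovery analyses in the tests and the acceptance
script run at deliberately chosen sizes: 10,000 null CpGs for type-I
calibration, 200 meta-replicates for permutation-p validity, 1,000
global-null CIT replicates, 20 cohorts for cluster recovery, and
2,000–4,000-CpG cohorts for the power and mediation runs — large enough
for the binomial error bars the assertions use, small enough that the
entire suite completes in a couple of minutes on one core.

## Known limitations

OLS on beta values is an approximation near the (0,1) boundary; the
CIT's component 4 is a finite-permutation test whose p-value floor
limits how small the combined p can be; the ReFACTor-style surrogates
absorb disease signal when disease CpGs are a non-trivial fraction of
all sites (see above); and the transfer analysis assumes the external
cohort's criteria were dichotomized identically — there is no fuzzy
matching of criterion definitions.
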