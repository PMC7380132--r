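---
title: "Methods: Mes subtype scoring, stromal contrasts, and the synthetic cohort"
author: "mesoscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mes subtype scoring, stromal contrasts, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoscore)
```

## The scientific problem

Transcriptomic profiling clusters primary high-grade serous ovarian carcinoma
(HGSC) into four molecular subtypes — Immunoreactive, Mesenchymal (Mes),
Proliferative and Differentiated. The Mes subtype is distinguished by
elevated myofibroblast/extracellular-matrix gene expression and is associated
with upper-abdominal/omental disease, suboptimal debulking and the worst
survival. Because those signature genes are expressed by cancer-associated
fibroblasts (CAFs) rather than by the epithelial cancer cells, a bulk
sample's Mes status may be a property of its *stroma* — and, if the stroma of
upper-abdominal/omental lesions differs from ovarian stroma, a property of
the *location the sample was collected from*. Under that reading, an ovarian
mass with a Mes profile is a peritoneal metastasis to the ovary, which
predicts that HGSC confined to the pelvis (stage I–II, ovarian-site samples)
should essentially never be Mes.

`mesoscore` implements the quantitative machinery this argument needs:
a binary-threshold classifier on a 15-gene mesenchymal panel, composite
signature z-scores and a signed stromal contrast, agreement and contingency
statistics, score-vs-cell-content correlations, and a simulator that encodes
the location-dependent-stroma model so every claim can be tested against
known ground truth.

## The 15-gene median-threshold classifier

For signature gene $g$, the threshold $t_g$ is the median expression of $g$
over a **reference population**. The reference is always an explicit
parameter — all samples of the data set, or a named subset such as primary
tumors — because both conventions are legitimate and give different
thresholds; the package never infers it. Even-sized references use the
mean of the two central order statistics.

A sample scores $s_g = 1$ when its expression **strictly exceeds** $t_g$ and
$0$ otherwise. "Exceeds" is read strictly: a sample sitting exactly at every
threshold scores 0, and borderline samples whose panel genes are high but do
not cross the thresholds are called non-Mes. The Mes score is the mean of
the $s_g$ over the $k$ genes actually available, so it lives on the lattice
$\{0, 1/k, \dots, 1\}$, and the Mes call requires the score to be exactly 1
(a relaxed cutoff exists behind `mes_cutoff` for sensitivity analysis, off
by default). When panel genes are missing from a platform the score is
renormalized over the available genes, down to a floor of half the panel;
below that the classification is refused as unreliable rather than silently
degraded.

Two consequences are worth noting. First, only the ranking of each gene's
values relative to its median matters, so calls are invariant under any
strictly increasing per-gene transform (log2, affine, cubic — the suite
asserts this). Second, with thresholds at the all-sample medians, at most
half the cohort can be above threshold on any one gene, which makes the
all-genes-above call deliberately conservative.

## Signature z-scores and the stromal contrast

A data set is z-score transformed gene-wise: $z_{gj} = (x_{gj} - \bar x_g)/s_g$
with the sample standard deviation ($n-1$ denominator; the choice of
denominator is a convention — it cancels from all comparisons — and is
documented here once). Zero-variance genes carry no information and are
dropped with a record. Standardization is always within one data set, never
across merged cohorts, since cross-cohort location/scale differences would
otherwise masquerade as biology. Retained rows satisfy
$|\bar z_g| < 10^{-9}$ and $|s_{z_g} - 1| < 10^{-9}$, the tolerance the
suite enforces.

A signature's score for sample $j$ is the unweighted mean of $z_{gj}$ over
its genes present in the matrix. The **stromal contrast** assigns the
omental-metastasis stromal signature a positive sign and the primary-ovarian
stromal signature a negative sign and is computed as the *difference* of the
two signature z-scores. A literal quotient of z-scores is unstable (the
denominator crosses zero) whereas the stated sign convention describes an
additive contrast; a quotient mode is nevertheless available behind a flag
for sensitivity analysis. By linearity, the mean per-sample contrast of a
group equals the contrast of group-mean z-scores, so the two plausible
definitions of a group summary coincide. Both component scores are mean-zero
over the data set, hence so is the contrast.

## Concordance and contingency statistics

Agreement between a classification and the original subtype labels is
summarized by Cohen's kappa on the collapsed two-class (Mes vs non-Mes)
table, as the four-class problem is not what the classifier addresses; the
functions accept $k \times k$ tables for the general case. Kappa is
$(p_o - p_e)/(1 - p_e)$; the degenerate single-category table with perfect
agreement is defined as 1. Per-class accuracy is the per-row diagonal
fraction.

Two-sided Fisher exact tests use the point-probability (minimum-likelihood)
rule — the convention of mainstream statistical software — implemented via
`stats::fisher.test` and cross-checked in the suite against a full
hypergeometric enumeration for all tables with $n \le 60$. Tables with a
zero margin carry no information about association and return $p = 1$.
When several group pairs are tested, raw p-values are primary and a
Benjamini–Hochberg column is reported alongside, never used to gate output.

## Cell-content association

Cell-type content is the percent of one class among the three annotated
classes (fibroblast, epithelial cancer cell, immune) — not of all cells —
making it scale-invariant to whether counts or areas are supplied. The
default correlation is Pearson (continuous z-scores against percentages);
Spearman is available and is the conventional choice for
percent-of-epithelium analyses. P-values are two-sided (the directional
hypotheses are asserted separately on the sign of $r$). Strata with fewer
than three paired samples are reported as untestable rather than erroring,
so stratified tables always enumerate every stratum.

## The synthetic cohort generator

The generator encodes the location-dependent-stroma model as a mixture:

$$x_{gj} = \bigl(f_j \, \mu_g^{S_j} + c_j \, \mu_g^{\mathrm{cancer}} +
 i_j \, \mu_g^{\mathrm{immune}}\bigr)\cdot \varepsilon_{gj},
 \qquad \varepsilon_{gj} \sim \mathrm{LogNormal}(0, \sigma)$$

where $(f_j, c_j, i_j)$ are Dirichlet-distributed fibroblast / cancer /
immune fractions and $S_j$ is the sample's stromal archetype —
primary-ovarian or metastatic (upper-abdominal/omental) stroma.

**Archetypes.** Baseline means are drawn log-uniformly over $2^{[4,10]}$
(linear intensities 16–1024, the scale of normalized array/NanoString data)
and shared across classes; each class receives multiplicative lognormal
jitter (sd 0.1) on non-signature genes, and signature genes receive exact
fold elevations: the Mes 15-gene panel and the omental stromal signature in
the metastatic-stroma archetype, the primary stromal signature in the
primary-stroma archetype. Keeping signature genes jitter-free makes the
elevation ratios exact, so the guarantee "every Mes-panel gene is at least
`fold_mes` above the cancer-epithelium level in metastatic stroma" holds by
construction, setting all folds to 1 yields literally exchangeable
archetypes for the null checks, and increasing a fold at a fixed seed is
exactly monotone. Where a gene belongs to several elevated signatures the
effects combine by maximum.

**Defaults.** Fold elevations default to 10 — stromal ECM genes such as
COL11A1 or POSTN are enriched in CAFs over epithelium by an order of
magnitude or more in microdissection data — and the noise sd to 0.25 on the
natural-log scale, typical of normalized expression intensities. The noise
is multiplicative lognormal because every intended input is a continuous
normalized intensity, not a count; a negative-binomial count mode is out of
scope.

**Cohort design.** The default design (n = 200) mirrors a stage-structured
HGSC cohort: ov-ov I–II 40, ov-ov III–IV 90, ov-per III–IV 30, per-ov III–IV
15, per-per III–IV 25 samples. Stage I–II ovarian-site samples carry only
primary stroma; all peritoneal-route samples carry metastatic stroma; 25% of
late-stage ov-ov samples carry metastatic stroma (re-seeding of the ovary
from upper-abdominal disease). `met_fraction` is implemented as an exact
per-stratum count assigned at random, so the stratum composition is part of
the design, not of sampling noise. Dirichlet concentrations are (4, 5, 1)
for primary-site and (5, 4, 1) for metastatic-site strata — metastatic
lesions modelled as more desmoplastic — giving mean fibroblast fractions of
0.4 and 0.5 with realistic spread.

**Ground truth.** A sample's intended Mes label couples its stromal
archetype with a fibroblast-fraction floor (default 0.2): metastatic stroma
diluted below ~20% fibroblasts is not expected to drive an all-genes-above
call. This is a generator convention reflecting the observation that the
score tracks fibroblast content, not an empirical claim. All randomness
flows from a single integer seed through `withr::with_seed`; no global RNG
state leaks, and fixture bundles written twice from one seed/configuration
are byte-identical (the manifest carries the seed and an md5 of the
canonical configuration).

**What the generator does and does not emulate.** It reproduces the
features the pipeline's inferences rely on: stroma-driven signature
elevation, mixture dilution by cancer/immune content, site- and
stage-structured strata, and archetype-level expression differences. It does
not emulate gene–gene correlation beyond class mixing, platform-specific
mean–variance relationships, batch effects, or copy-number/mutation
structure. Passing tests therefore show the pipeline recovers truth *under
the stated mixture model*, not that the biological claims hold in any real
cohort — the published concordance statistics are the only quantities here
anchored to real data.

## Numerical choices and degenerate inputs

- Ties at a threshold score 0 (strict exceedance); this is asserted, not
  incidental.
- Duplicate gene rows collapse by highest mean expression by default
  (`first` and element-wise `mean` available); duplicate sample ids are an
  error, as is any missing value unless row-dropping is explicitly enabled.
- Matrices are genes × samples; transposed files are accepted only via an
  explicit flag, never guessed.
- Zero-variance genes are dropped before z-scoring; signatures whose genes
  are entirely absent raise an error naming the signature; empty
  signature–matrix intersections elsewhere are reportable outcomes.
- Constant score or percent vectors make correlations undefined and raise
  explicit errors rather than returning NA.
- Fisher tests on zero-margin tables return 1 with a log message.

## Problem sizes

The test suite exercises the default cohort (500 genes × 200 samples) once
and otherwise uses scaled-down cohorts (60–180 genes, 30–120 samples) and
200-replicate null batches at n = 50, sizes at which every property checked
is already stable; the acceptance script runs the full default cohort.

## Known limitations

- The shipped GMT is a labelled synthetic placeholder: the true 15-gene,
  100-gene and 21-gene lists live in supplementary material and must be
  supplied as data. All machinery is list-agnostic.
- The classifier's all-genes-above rule is intentionally conservative;
  cohorts scored on platforms missing many panel genes lose power before
  the half-panel floor refuses to classify.
- Kappa is reported without a confidence interval; the published comparisons
  are point values and the synthetic checks are property-based.
- The generator's Dirichlet fractions are independent of stage and route
  beyond the stratum concentrations; real cohorts likely couple purity to
  site more intricately.
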