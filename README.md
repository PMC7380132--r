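# mesoscore

Tools for asking whether the **Mesenchymal (Mes) molecular subtype** of
high-grade serous ovarian carcinoma (HGSC) reflects *where a tumor sample was
taken* rather than an intrinsic property of the cancer cells. The Mes subtype
is defined by elevated myofibroblast/extracellular-matrix gene expression and
carries the worst prognosis of the four HGSC subtypes; if its signature is
carried by the stroma of upper-abdominal/omental lesions, then "Mes primary
ovarian tumors" are better read as intraperitoneal metastases to the ovary.
`mesoscore` implements the computational machinery needed to examine that
question and to validate it end-to-end on simulated cohorts:

- **15-gene median-threshold Mes classifier.** For each signature gene *g*, a
  threshold *t_g* is the median expression of *g* over an explicit reference
  population (all samples, or primary tumors only). A sample scores
  *s_g = 1* if its expression strictly exceeds *t_g*, else 0. The Mes score
  is (1/k) Σ *s_g* ∈ {0, 1/k, …, 1}; a sample is called Mes only when the
  score is exactly 1. Calls are invariant under any strictly increasing
  per-gene transform of the data.
- **Signature z-scores.** A data set is z-score transformed gene-wise
  (mean 0, sd 1 per gene); a signature's score for a sample is the unweighted
  mean of its genes' z-values. The **stromal contrast** combines the
  omental-metastasis and primary-ovarian stromal signatures with opposite
  signs (omental positive): positive values indicate
  omental-metastasis-like stroma.
- **Concordance statistics.** Cohen's kappa
  κ = (p_o − p_e)/(1 − p_e) and per-class accuracy for classifier
  agreement; two-sided Fisher exact tests (point-probability rule) for
  Mes-by-group contingency tables, with BH-adjusted columns reported
  alongside raw p-values.
- **Cell-content association.** Correlation (Pearson or Spearman) of
  signature scores with fibroblast / cancer-cell / immune percentages
  (percent of the three annotated classes), overall or stratified.
- **Synthetic cohort generator.** Bulk expression simulated as a
  Dirichlet-weighted mixture of cell-class archetype profiles with
  multiplicative lognormal noise; the stromal archetype (primary-ovarian vs
  metastatic/omental) depends on tumor location, and cohorts are structured
  by dissemination route (ov-ov, ov-per, per-ov, per-per) and FIGO stage
  group, with full ground truth.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the default
simulated cohort (n = 200, seed 1) and write tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_classify_mes.R
Rscript analysis/03_signature_scores.R
Rscript analysis/04_concordance.R
Rscript analysis/05_cell_content.R
```

`02_classify_mes.R` prints the Mes fraction per stage-group × route stratum:

```
  stage_group   route  n n_mes fraction_mes
1        I-II   ov-ov 40     0    0.0000000
2      III-IV   ov-ov 90    22    0.2444444
3      III-IV  ov-per 30    29    0.9666667
4      III-IV  per-ov 15    15    1.0000000
5      III-IV per-per 25    25    1.0000000
recovery of intended Mes labels: 99.0% (198/200 samples)
```

Early-stage tumors confined to the ovary are never called Mes; roughly a
quarter of late-stage ovarian-site samples are (those seeded with metastatic
stroma); samples collected at peritoneal sites are almost all Mes — the
location-dependence the package is built to expose. `04_concordance.R`
reproduces the published classifier-vs-subtype agreement from the printed
confusion counts:

```
TCGA: kappa = 0.733; Mes accuracy 91%, non-Mes accuracy 89% (n = 456)
GSE9891: kappa = 0.792; Mes accuracy 99%, non-Mes accuracy 84% (n = 184)
```

and `05_cell_content.R` shows the Mes 15-gene z-score tracking fibroblast
content in metastatic-site samples (r = 0.967, p ≈ 3e-42), running against
cancer-cell content (r = −0.811), and showing no association in early-stage
primary-site samples (p = 0.46) — the signature lives in the metastatic
stroma, not the cancer cells.

A minimal programmatic session:

```r
library(mesoscore)
arch <- generate_archetypes(seed = 1)
coh  <- generate_cohort(arch, default_cohort_design(), seed = 2)
res  <- classify_cohort(coh$matrix, arch$signatures$mes15, "all", coh$annotations)
res$summary
```

The gene lists shipped in `inst/extdata/signatures_synthetic.gmt` are
synthetic placeholders (the published supplementary lists are supplied as
GMT data at analysis time); real analyses should load their own GMT via
`read_gmt()`.

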