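# pniscore

Expression profiling and a percentile gene-score panel for perineural
invasion (PNI) in head and neck cutaneous squamous cell carcinoma
(HNcSCC).

Perineural invasion is an adverse prognostic feature of cutaneous SCC,
but histology alone separates poorly the incidental, focal form from the
clinically aggressive, extensive form that recurs and spreads along named
nerves. `pniscore` implements, as reusable and tested R functions, the
full analysis chain used to ask whether bulk expression profiling can
make that distinction on a NanoString nCounter codeset (740 endogenous +
30 housekeeping genes), and to build a simple risk score from it. It is
aimed at translational researchers analysing nCounter-style count data of
small stratified cohorts.

## What the package computes

* **nSolver-style normalization** — per-sample background from negative
  control probes, then positive-control and housekeeping ("CodeSet
  content") scaling by geometric-mean factors
  `f_s = mean_s'(g(s')) / g(s)`.
* **Moderated differential expression** — per-gene two-group fit on
  log2 values; empirical-Bayes shrinkage of the residual variances
  `s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d)` with `(d₀, s₀²)` estimated by the
  method of moments on `log s²_g`; moderated `t_g = β_g /(s̃_g·√(1/n₁+1/n₂))`
  on `d + d₀` degrees of freedom; Benjamini–Hochberg FDR; strict linear
  fold-change filters; DEG set (Venn) comparison.
* **Clustering** — gene-scaled Euclidean agglomerative clustering
  (deterministic lowest-index tie-break) with a cohort-segregation
  summary.
* **The gene score** — the top 10 DEGs by adjusted p; per-gene threshold =
  95th centile (type-7) of the Non/Focal training samples; a sample
  scores one point per gene strictly above threshold (score 0–10) and is
  called EXT-risk when the score exceeds 2.5; evaluated by sensitivity,
  specificity and the tie-corrected Mann–Whitney AUC.
* **Hypergeometric over-representation** of DEG lists against GMT gene
  sets within the codeset universe.
* **Cohort statistics** — chi-square and pooled-t comparisons of clinical
  covariates, and a nerve-fraction confounder stratification within EXT.
* **A synthetic-cohort generator** (negative-binomial counts, planted
  fold-change tiers, lane factors, Poisson background, control-probe
  ladders) with full ground truth, so every stage is testable without
  patient data.

## Worked example

```r
library(pniscore)

cohort <- generate_cohort(cohort_config(seed = 1))   # 9 Non / 11 Focal / 25 EXT
norm   <- normalize_nanostring(cohort$counts)
grp    <- factor(ifelse(cohort$annotation$cohort == "EXT", "EXT", "FOCAL_NON"),
                 levels = c("FOCAL_NON", "EXT"))
de     <- moderated_de(norm$x, grp)
summary(de, fc_cut = 2, p_cut = 0.01)
#> Moderated DE, EXT vs FOCAL_NON (740 genes)
#>   prior df 14.1, prior variance 0.1409
#>   at |FC| > 2 and adjusted p < 0.01: 135 up, 9 down
summary(de, fc_cut = 3, p_cut = 0.01)
#>   at |FC| > 3 and adjusted p < 0.01: 64 up, 6 down
```

144 genes pass the fold-change-2 filter and 70 the fold-change-3 filter —
the generator's planted two-tier design recovered exactly. The score
panel then separates the cohorts completely on this cohort:

```r
panel  <- score_panel(de, norm$x, cohort$annotation)   # top 10, 95th centile
scores <- classify_scores(predict(panel, norm$x, cohort$annotation), cutoff = 2.5)
table(score = scores$score, cohort = scores$cohort)
#>      cohort
#> score EXT FOCAL NON
#>     0   0     5   6
#>     1   0     5   3
#>     2   0     1   0
#>     9  25     0   0
m <- confusion_metrics(scores$predicted_ext, scores$cohort)
roc <- roc_curve(scores$score, scores$cohort)
#> sensitivity 1.00, specificity 1.00, AUC 1.000
```

Every Non/Focal sample scores ≤ 2 (by construction about one training
sample per gene sits above its own 95th centile) while every EXT sample
scores 9 of 10; at the 2.5 cutoff sensitivity and specificity are both
100% here. `run_pni_pipeline(pipeline_config(seed = 1))` runs the whole
chain — all four cohort contrasts, clustering, panel, enrichment,
cohort statistics, confounder check — and writes each stage's TSV/JSON
artifacts plus a run manifest.

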