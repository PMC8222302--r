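---
title: "Methods: PNI expression profiling and the percentile gene score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PNI expression profiling and the percentile gene score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pniscore)
```

`pniscore` analyses NanoString nCounter expression data from head and
neck cutaneous SCC cohorts stratified by perineural invasion (Non-PNI,
Focal-PNI, Extensive/EXT-PNI). This vignette documents the statistical
model behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
choices made where conventions genuinely diverge.

## The synthetic cohort generator

Because patient-level expression data for this disease setting are not
publicly deposited, the package ships a generator whose defaults encode
the study conditions every simulation-based check runs under:

* **Cohort**: 45 samples — 9 Non-PNI, 11 Focal-PNI, 25 EXT-PNI.
* **Codeset**: 740 endogenous genes, 30 housekeeping genes, 6 positive
  and 8 negative control probes.
* **Counts**: gene $g$ in sample $s$ is negative binomial with mean
  $\mu_{gs} = 2^{b_g}\,\lambda_s\,2^{\beta_g \mathbb{1}[s \in \mathrm{EXT}]}$
  and dispersion $\phi = 0.05$ (variance $\mu + \phi\mu^2$), plus an
  additive Poisson background with mean 10. Baselines $b_g$ are
  $\mathcal{N}(7, 1.5^2)$ on the log2 scale for endogenous genes and
  $\mathcal{N}(10, 0.5^2)$ for housekeeping genes — housekeeping probes
  are chosen by assay designers for high, stable expression, and high
  baselines keep their counting noise near the dispersion floor.
* **Technical structure**: each sample carries a multiplicative lane
  factor $\lambda_s = e^{\varepsilon_s}$, $\varepsilon_s \sim
  \mathcal{N}(0, 0.3^2)$, applied to all signal probes before background
  addition. Positive controls follow the nCounter convention of a fixed
  four-fold geometric ladder (top rung 32768 expected counts) scaled by
  $\lambda_s$ with Poisson noise; negative controls are pure Poisson
  background.
* **Planted effects**: 70 genes at $|\log_2 \mathrm{FC}| = 2.0$ and 74 at
  $|\log_2 \mathrm{FC}| = 1.3$, EXT-only, 6% of them down-regulated. The
  two tiers are chosen so the strict linear filters partition them
  cleanly: all 144 exceed fold change 2, and only the strong tier's 70
  exceed fold change 3. Focal and Non samples are exchangeable draws from
  the identical null distribution, so the Focal-vs-Non contrast is a
  built-in negative control.
* **Covariates**: the nerve-tissue fraction is uniform on
  $[0.005, 0.80]$, drawn independently of expression — by construction a
  non-confounder. Clinical covariates (age, sex, tumor size, recurrence)
  are descriptive draws with cohort-typical rates for exercising the
  cohort-statistics stage only.

A single master seed drives deterministic per-stage substreams (codeset,
cohort draw, held-out null draw), so `generate_null_samples()` yields
held-out controls on exactly the same codeset without perturbing the
cohort.

**What the generator does not emulate**: probe-specific hybridization
efficiencies, lot-to-lot codeset drift, RNA-quality (FFPE degradation)
gradients, correlated gene modules, or any dependence of expression on
clinical covariates. Passing simulation checks therefore demonstrate
that the *pipeline machinery* is correct and calibrated under a faithful
noise model — not that real cohorts of this size will reproduce the
published performance.

## Normalization

The chain follows the documented nSolver order: background, positive
controls, housekeeping. The background statistic per sample is the mean
of the negative controls (alternatives: mean + 2 sd, max), subtracted
from non-control probes and floored at zero. Both control
normalizations use the same construction: with $g(s)$ the geometric mean
of the control class in sample $s$, the factor
$f_s = \overline{g}/g(s)$ rescales the sample to the cohort's common
level; positive-control factors apply to all non-control probes,
housekeeping factors to endogenous probes only. Factors outside
$[0.3, 3]$ are flagged (the usual QC convention) but never dropped —
sample exclusion is an analysis decision. Geometric means are strict by
default: a zero control count is an error unless an explicit 0.5
pseudocount is requested, because silent pseudocounts can mask failed
lanes. An optional per-probe calibrator-ratio correction supports
multi-lot designs and is off by default.

Under the default noise model the combined correction
$f^{pos}_s f^{hk}_s$ tracks $1/\lambda_s$ with log-scale correlation
about 0.99. The residual per-gene housekeeping CV after normalization is
bounded below by the negative-binomial dispersion floor
($\sqrt{\phi} \approx 0.22$), so normalization removes the lane
component (CV $\approx 0.31$) but reduces total housekeeping CV by
roughly 40%, not more — a structural property of overdispersed counts
worth keeping in mind when judging normalization quality by CV alone.

## Moderated differential expression

Each contrast is a two-group comparison on $\log_2(x + 1)$ of the
normalized endogenous matrix: effect $\hat\beta_g$ = difference of group
means, pooled residual variance $s_g^2$ on $d = n_1 + n_2 - 2$ degrees
of freedom. Variances are shrunk toward a common prior by empirical
Bayes: with prior $s_g^2 \sim s_0^2 \chi^{-2}_{d_0}$, the posterior
variance is $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and
$t_g = \hat\beta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ is referred to a
t distribution on $d + d_0$ degrees of freedom. The hyperparameters are
estimated by the method of moments on $z_g = \log s_g^2$, solving a
trigamma equation for $d_0$ by a monotone Newton iteration (tolerance
$10^{-8}$). Degenerate cases are handled explicitly: if the observed
variances are no more dispersed than sampling noise alone, $d_0 = \infty$,
all posterior variances equal the mean variance, and a normal reference
is used; zero-variance genes participate with the smallest positive
variance (flagged) rather than being dropped, which would bias $d_0$;
a single gene falls back to the ordinary t with a warning. The
implementation is verified in the test suite against an independent
reference implementation to machine precision.

P-values are two-sided and Benjamini–Hochberg adjusted (step-up with
cumulative minimum from the largest rank). DEG selection applies strict
inequalities on the *linear* fold-change scale — `2^log2fc > 2` (or 3) —
matching how such thresholds are conventionally quoted. Tables are
sorted by adjusted p, ties broken by raw p then gene id, a rule stated
here because it fixes which genes enter the score panel.

The design is deliberately two-group only (EXT vs Non, EXT vs Focal,
Focal vs Non, EXT vs combined Focal/Non, and the within-EXT nerve-content
split); no covariate adjustment, voom-style weights or moderated F
statistics are provided.

## Clustering

Samples are clustered over the top DEGs (default 70) after each gene row
is centered and scaled to unit sample variance ($n-1$ denominator, so
the row $(1,2,3)$ becomes $(-1,0,1)$). Agglomeration uses Euclidean
distance with average linkage by default (complete, single and Ward
optional) via Lance–Williams updates; ties at the minimal merge distance
are broken by the lowest-index pair, making the dendrogram a
deterministic function of the input. The result is a standard `hclust`
object, and `evaluate_segregation()` cuts it into $k = 2$ clusters and
counts samples whose cluster majority label disagrees with their own —
the outlier notion used when asking whether EXT segregates from
Focal/Non. Merge heights are tested against an $O(n^3)$ re-agglomeration
oracle and against `stats::hclust`.

## The percentile gene score

The panel takes the top 10 genes by adjusted p-value. For each gene the
threshold is the 95th centile of the normalized expression over the 20
training samples (Non + Focal), computed with type-7 linear
interpolation between order statistics — the dominant software default,
chosen here also because it makes the in-training behaviour exact: with
20 training values the threshold lies between the 19th and 20th order
statistics, so *exactly one* training sample per gene exceeds it. A
sample scores one point per gene strictly above threshold (a value
exactly at the threshold scores 0), giving a score from 0 to 10;
EXT-risk is called when the score exceeds 2.5. The half-integer cutoff
cannot tie with integer scores; an alternative "score ≥ 2 is high risk"
rule in circulation for this kind of panel corresponds to `cutoff = 1.5`
and is available as configuration — the package surfaces both rather
than adjudicating.

Two properties worth making explicit:

* **Rank invariance.** Thresholding is rank-based, so the score is
  invariant under any strictly monotone per-gene transform applied
  consistently to training and test values; whether thresholds are
  computed on linear or log-scale normalized values is immaterial.
* **Small-sample threshold bias.** An empirical 95th centile from
  $n = 20$ is biased low as an estimator of the population centile: the
  expected held-out exceedance rate is roughly
  $0.95 \cdot 2/21 + 0.05 \cdot 1/21 \approx 0.093$, not 0.05. Held-out
  null samples therefore average a score near 0.9, while the
  idealised independence reference $10 \times (1-0.95) = 0.5$ is
  approached only as the training set grows (the calibration checks use
  400 training nulls). In-sample evaluation — scoring the training
  cohort itself, as small-cohort studies of this design do — is tighter
  still: each gene awards its single point to whichever training sample
  happens to be its maximum, so Non/Focal totals above 2 are rare. The
  package reports in-sample metrics openly as such and offers held-out
  evaluation through generated null samples.

Upper-tail scoring is the default, literally counting exceedances; a
direction-aware mode (5th-centile lower tail for down-regulated panel
genes) is available because strongly down-regulated genes can rank into
the panel.

ROC curves place cutoffs at midpoints between consecutive distinct
scores plus sentinels; the trapezoid AUC equals the Mann–Whitney
probability with half-weighted ties, verified against exhaustive pair
enumeration.

## Enrichment and cohort statistics

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ (observed overlap included) with BH adjustment across sets.
The universe is the endogenous codeset (740 genes), not the genome: the
assay's sampling frame constrains what could have been drawn, and a
genome universe would inflate significance. Gene identifiers are opaque
case-sensitive strings; no identifier mapping is attempted, and no live
pathway-database access is performed — a small synthetic GMT fixture
(`inst/extdata/synthetic_pathways.gmt`, generator-style gene ids) ships
for exercising the stage.

Cohort tables use Pearson chi-square without continuity correction by
default (Yates optional, expected-count-below-5 flagged) and the
pooled-variance Student t (Welch optional). Both the three-column and
the combined Focal/Non-vs-EXT layouts are supported.

## Pipeline, determinism and problem sizes

`run_pni_pipeline()` executes generate/read → normalize → four DE
contrasts → DEG sets and Venn comparison → clustering → panel/score/ROC →
optional enrichment → cohort statistics → nerve-fraction stratification
(low stratum = fraction ≤ 0.10, the boundary resolved downward), writing
per-stage TSV/JSON artifacts and a manifest (config snapshot, package
version, input MD5 checksums, per-stage wall time, accumulated warnings)
that is written even when a stage fails; failed stages abort downstream
work but preserve completed outputs. With a fixed seed the whole run is
bit-reproducible.

Simulation-based checks in the test suite use the full default cohort
(45 samples × 784 probes) with medians over 20 seeds for the headline
discrimination and recovery properties, 10 seeds for cluster
segregation, a 10,000-gene single-seed cohort for raw-p calibration, and
1400 null samples for score calibration — sizes at which the full suite
completes in well under a minute while estimator noise stays far from
the asserted margins.

## Known limitations

* In-sample panel evaluation is optimistic by construction (see above);
  the package quantifies but cannot remove this without external
  validation data.
* The generator's independence across genes means clustering and
  score-correlation behaviour on real, module-structured expression data
  may differ from simulation.
* Housekeeping-CV reduction is dispersion-limited (~40% under defaults);
  judging normalization by CV reduction alone will understate how well
  lane factors are removed.
* No survival modelling, bootstrap clustering confidence, or
  cross-validated panel selection is included.
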