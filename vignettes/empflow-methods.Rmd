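---
title: "Models and methods in empflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in empflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(empflow)
```

# Scope

`empflow` analyzes epithelial–mesenchymal plasticity (EMP) in single-cell
RNA-seq data from matched primary tumors and metastases across a panel of
tumor models profiled with two sequencing platforms (a deep plate-based and a
shallow droplet-based protocol). The pipeline runs: gene-set scoring → EMP
state classification → hurdle-model differential expression (DE) → multi-level
consensus signatures → preranked gene-set enrichment → expression-based CNV
profiles → Kaplan–Meier signature stratification. Because the package must be
verifiable without any external download, it ships a first-class synthetic
data generator that plants the statistical structure the analysis assumes and
a ground-truth object against which every stage is tested.

# Data model and normalization

The carrier object is an `ExpressionDataset`: an integer cell × gene count
matrix, a deterministic normalized layer, and cell/gene annotation tables.
Normalization is fixed to

$$\mathrm{norm}_{cg} = \log_2\!\left(1 + \frac{10^4\,x_{cg}}{\sum_g x_{cg}}\right),$$

i.e. log2 counts-per-10k. The scale factor is configurable, but the default
is deliberately shared across platforms: the EMP state thresholds at ±0.2
(below) are only comparable between platforms if both are scored on the same
normalized scale. Cells with zero counts are tolerated on input (their
normalized rows are zero, with a warning) but rejected by a strict
`normalize()` call, which otherwise recomputes the layer bit-identically.

Gene identity is symbol-keyed; duplicated input symbols are made unique by
suffixing and reported. Gene coordinates are 1-based; chromosomes sort
numerically with X and Y last.

# The synthetic panel

`simulate_panel()` draws, for each cell of model $m$, a latent EMP coordinate
$t \sim \mathrm{Beta}(a_m, b_m)$ on $[0,1]$ (0 = epithelial). The Beta law is
chosen per metastatic-potential class: low-potential models default to
$(2, 5)$ (mass near the epithelial end), moderate to $(3.5, 3.5)$, and high
to $(5, 2)$. A full-scale tumor panel is emulated at reduced scale by ten models
(4 low / 3 moderate / 3 high), 50 cells per model, tissue, and platform, and
500 genes.

Mean expression multiplies a lognormal gene baseline by a program factor:

* epithelial block (75 genes): $1.3 - 0.6\,t$;
* mesenchymal block (75 genes): $0.7 + 0.6\,t$;
* intermediate markers (30 genes): $0.2 + 5.8\,\exp(-(t-0.5)^2 / 2\sigma^2)$
  with $\sigma = 0.15$;
* background: constant 1;
* planted tissue-DE genes (40): multiplied by $2^{\pm 1}$ in metastatic
  cells (alternating sign);
* one CNV segment per model (60 consecutive genes, fold 0.5 or 2), applied
  to both tissue compartments so primary and metastasis share the genetic
  profile;
* per-model lognormal offsets (log-sd 0.25) on every gene create inter-model
  heterogeneity and act as the batch structure the DE covariate must absorb.

Counts are negative binomial (shared dispersion 0.4) on lognormal library
sizes (plate mean 20 000; droplet mean 5 000 plus 15% extra dropout), so the
droplet rendering detects strictly fewer genes per cell.

Three calibration choices deserve comment, all made once and fixed:

* The *program slopes* (±0.6 around a symmetric midpoint) were chosen so the
  combined EMP score crosses ±0.2 near $t = 0.35$ and $0.65$; the
  intermediate-marker bump width $\sigma = 0.15$ then makes the bump support
  roughly coincide with the scored intermediate band.
* The *intermediate markers* are modeled as on/off genes (~30× peak-to-tail
  contrast, near-zero detection in the flanking states). This mirrors the
  distinct marker behavior the analysis is designed to detect
  (keratin/crystallin-type genes that switch on mid-axis); a mild modulation
  of a ubiquitously expressed gene is not recoverable at droplet depth under
  the log2FC > 0.5 rule and would misrepresent what "marker gene" means here.
* The *program block sizes* (75 + 75 of 500 genes) keep the per-cell score
  average over enough genes that the shallow platform's score still tracks
  the latent axis; with 40-gene blocks the droplet score is too noisy for a
  fixed ±0.2 band to be meaningful.

The generator does **not** emulate ambient RNA, doublets, UMI duplication,
cell-cycle structure, or realistic gene–gene correlation beyond the single
latent axis; passing recovery tests therefore demonstrates correctness of the
statistical machinery under the stated generative model, not performance on
arbitrary real data.

`simulate_survival()` draws a latent score $s \sim N(0,1)$, expresses it on
the signature genes ($s$ plus Gaussian noise, sd 0.5), and generates event
times as $\mathrm{Exp}(\lambda_0 e^{\beta s})$ with $\lambda_0 = \log 2 / 24$
(median survival 24 months at $\beta = 0$). Censoring is independent uniform
on $[0, c_{\max}]$, with $c_{\max}$ solved numerically so the expected
censoring fraction at $\beta = 0$ equals the requested rate.

# EMP scoring and states

The published marker panel is turned into per-cell scores by bin-matched
control subtraction: genes are binned by mean normalized expression (25
equal-frequency bins), each signature gene draws up to 50 control genes from
its bin (the whole bin, deterministically, when the bin is small), and the
score is the mean over signature genes minus the mean over the pooled
controls. This centers scores of unstructured sets at zero — a property the
fixed ±0.2 thresholds presuppose — and is the standard approach for
depth-robust signature scoring. The control draw is seeded and reproducible.

The combined score is $\mathrm{EMP} = \text{mesenchymal} - \text{epithelial}$,
so positive values indicate a more mesenchymal than epithelial state. States
are assigned as epithelial-like ($< -0.2$), intermediate ($[-0.2, 0.2]$,
closed on both sides), mesenchymal-like ($> 0.2$).

# Hurdle differential expression

Expression $y$ is modeled in two parts: detection $1\{y > 0\}$ by logistic
regression, and $y \mid y > 0$ by a Gaussian linear model. Contrasts are
tested with a combined likelihood-ratio statistic: twice the gain in the
logistic penalized objective plus twice the gain in the Gaussian
log-likelihood, against $\chi^2$ with the total number of dropped columns as
degrees of freedom. Key numerical choices:

* The logistic part carries a small ridge penalty ($\varepsilon = 10^{-3}$)
  so complete separation cannot send coefficients to infinity. Both the full
  and the reduced design share the penalty, keeping the statistic
  non-negative.
* The contrast is coded $\pm 0.5$ rather than $0/1$: with a symmetric coding
  the penalized optimum maps exactly onto itself when the two groups are
  exchanged, so swapping groups negates every log2FC and leaves every
  p-value unchanged — exactly.
* The continuous part is ordinary least squares with the MLE variance; it is
  marked absent (contributing neither statistic nor degrees of freedom) when
  fewer than two cells express the gene or the design loses rank on the
  expressing subset.
* log2FC is the difference of group means of the normalized layer; genes
  expressed in fewer than `min_cells` (default 3) cells are skipped and
  reported.

Significance defaults to the conventional volcano rule: raw $p < 0.05$ with
$|\log_2\mathrm{FC}| > 0.5$; a flag switches to BH-adjusted p-values, and
recovery-style analyses in the tests use the adjusted scale to control the
false discovery rate. A cell-level detection-rate covariate is not included
by default; the tumor model is the covariate the analysis names.

Under a model-confounded null (batch offsets, no tissue effect, unbalanced
metastatic cell counts) the combined test holds its size at $\alpha = 0.05$
within ±0.01 over 2 000 genes, while omitting the covariate inflates the
type-I error roughly threefold — both checked in the acceptance suite.

# Consensus signatures

Per-model DE excludes models with fewer than 10 metastatic cells (exactly
10 passes the boundary). Sharing rules admit a gene into a group
signature when it passes the significance thresholds in the stated direction in at
least `min_models` models of the group (default 2), recording per-gene
support; raising `min_models` can only shrink a signature. Group-vs-rest DE
on primary tumors pools all cells of other potential groups (per-tumor
pairwise contrasts are available behind a flag). Cross-platform consensus is
the per-label set intersection with platform provenance.

The peak-profile check orders cells by EMP score, smooths the expression of
expressing cells with a centered running mean (window = 30% of expressing
cells), and asks whether the maximum falls strictly inside the intermediate
band. Two tie-breaks matter: a flat curve or a maximum at the edge of the
evaluated region is "not peaked", and the maximum is only evaluated where the
smoothing window has full support — the truncated curve ends average a
handful of extreme cells and would otherwise contribute single-cell noise
artifacts.

# Preranked enrichment

The enrichment score is the weighted Kolmogorov–Smirnov running-sum statistic
(weight 1 by default; weight 0 gives the classic KS form used by the
brute-force test oracle). The null distribution permutes gene labels
(size-matched random sets), matching how preranked lists are analyzed when no
sample-level phenotype is available for permutation. NES divides the observed
ES by the mean |null ES| of matching sign; p-values use the
$(1 + \#\text{extreme})/(1 + n_\text{perm})$ correction and are bounded below
by $1/(1+n_\text{perm})$; FDR follows the sign-stratified null-NES method.
Rankings derive from DE tables by log2FC (descending, ties broken
alphabetically for determinism), with signed $-\log_{10} p$ as an option.

# CNV profiles

Relative copy-number profiles are inferred from expression: per-gene
centering by the all-cells reference mean (tumor-only data has no normal
reference; an external reference is accepted), clipping at ±3, a 101-gene
moving average along each chromosome in genomic order (51 genes in the
synthetic runs, whose chromosomes hold only ~100 genes), and per-cell median
centering. The smoother truncates symmetrically at chromosome ends and never
crosses a boundary. Compartment similarity is the Pearson correlation (and
its square) between the pseudobulk profiles of a model's primary and
metastatic cells.

# Survival

Kaplan–Meier estimation and the log-rank test are implemented directly (the
`survival` package serves as an independent oracle in the tests): the
product-limit estimator over distinct event times, and the
observed-minus-expected statistic with hypergeometric variance, using the
$(g-1)$-dimensional quadratic form for $g$ groups. Ties use the standard
hypergeometric variance. Signature stratification scores each patient by the
mean expression of the signature genes and splits at the cohort median with
ties assigned to the low group; subtype-stratified analyses run the same
procedure within each subtype with at least 20 patients. A best-cutoff scan
(as some survival portals use) is deliberately out of scope; published
p-values from such tools are therefore not comparable.

One point where a commonly stated "invariance" is wrong deserves note: the
log-rank statistic is *not* invariant to adding a subject censored after the
last event — such a subject is at risk at every event time and changes the
expectations and variances (verified against `survival::survdiff`). The true
invariance, which the tests assert, is to subjects censored before the first
event.

# Association statistics

PCA runs on the centered normalized matrix over the top dispersion-ranked
genes (default 2 000), with a deterministic sign convention (the largest
|loading| gene is positive). Per-tumor analyses re-run PCA within each tumor.
EMP–potential association encodes low/moderate/high as 1/2/3 and correlates
per-tumor mean EMP with the encoding (one point per tumor — the per-tumor
reading of this summary statistic); the Pearson value is invariant up to sign
under affine re-encoding. Paired compartment analyses (primary vs metastasis,
plate vs droplet) correlate per-model mean EMP between the two levels and
report the least-squares line with 95% confidence intervals.

# Histology quantification

Metastatic foci are classed by cell count: micro (< 10), intermediate
(10–100, boundaries included), macro (> 100). Burden summaries report foci
per mm² and the metastatic area fraction. The qualitative low/moderate/high
potential call is encoded as explicit, configurable thresholds (low: density
below 0.05 foci/mm² and no macrometastasis; high: ≥ 3 macrometastases or
density ≥ 0.5/mm²; moderate otherwise), and the rule that fired is reported —
reproducibility is preferred over fidelity to an unstated judgment.

# Problem sizes and runtime choices

The default panel (10 models × 2 tissues × 2 platforms × 50 cells, 500
genes) runs the full recovery suite in a few minutes on one CPU. The null
calibration uses a dedicated 4-model panel with 2 000 genes and ~480 cells;
survival power/size use 200 replicates of 400 patients. The pipeline
determinism check uses a reduced configuration (4 models, 200 genes) since
it exercises orchestration, not statistics.

# Known limitations

* The generator's single latent axis induces all gene–gene correlation;
  real tumors have many correlated programs, so scoring specificity in real
  data will be lower than in recovery tests.
* The hurdle model uses a Gaussian continuous part on log-normalized values;
  MAST-style empirical-Bayes shrinkage and mixed effects are out of scope.
* GSEA NES magnitudes depend on the permutation scheme and are not
  comparable across tools.
* CNV inference is a smoothed expression proxy — no HMM state calling, no
  allele-specific information.
* The survival module stops at stratified log-rank; no Cox regression or
  multivariable adjustment.
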