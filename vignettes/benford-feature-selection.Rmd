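---
title: "Benford-law feature selection for cell-type and tissue classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benford-law feature selection for cell-type and tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benfordcell)
```

## The model

Leading (first significant) digits of naturally occurring numeric data tend
to follow the Benford distribution,

$$E_d = \log_{10}\!\left(1 + \frac{1}{d}\right), \qquad d = 1, \dots, 9,$$

so digit 1 leads about 30.1% of values and digit 9 only 4.6%. Gene
expression values — both bulk and single-cell — are Benford-adherent in bulk,
because expression spans several orders of magnitude. Individual genes,
however, differ: a gene whose expression within a homogeneous group of cells
is narrow (spanning less than a decade) concentrates its digits on one or two
values and departs strongly from $E$. Empirically those Benford-deviant genes
are narrow *and* lowly expressed, and they carry cell-type information.

`benfordcell` quantifies the departure per gene and per cell with the mean
absolute error over the nine digit frequencies,

$$\mathrm{MAE} = \frac{1}{9}\sum_{d=1}^{9} \left| A_d - E_d \right|,$$

where $A_d$ is the observed frequency of digit $d$. The score lives in
$[0, 0.2120539]$; the maximum is attained by a point mass on digit 9
(`benford_mae_max()`). The denominator is fixed at 9 even when digits are
unobserved, so sparse and dense digit histograms are on the same scale.
Adherence can also be tested formally with the 8-df Pearson chi-square
goodness of fit (`chisq_gof()`); following the field convention the null
hypothesis is adherence, so p > 0.05 reads "consistent with Benford". On
large samples the test detects minute deviations (tens of thousands of
digits reject at astronomical significance even when the histogram is
visually Benford), which is why the package always reports both the MAE and
the test rather than interpreting either.

**Gene-centered vs cell-centered.** The same score is used in two
orientations. *Gene-centered*: digits of one gene across the cells of one
group (used for feature selection). *Cell-centered*: digits of one cell
across a set of genes (used to summarize cells). The two agree by
construction: the cell-centered MAE over all genes equals the MAE of the
cell's full digit histogram.

## The pipeline

1. **Normalization.** Raw counts are normalized by median-ratio (MRN) size
   factors: the reference is the per-gene geometric mean over samples,
   computed on genes positive everywhere; a sample's factor is the median of
   its ratios to the reference. Factors are rescaled to geometric mean 1 —
   only their ratios matter downstream, and the convention makes factors
   comparable across runs. TPM inputs bypass normalization. Note that first
   digits are *not* invariant under MRN (each sample is divided by a
   different constant), so every score records which value kind produced it.
2. **Panels.** For each group ("focus group") a panel of `k = 200` genes is
   selected by one of three routes: highest/lowest gene-centered MAE
   (the Benford route), highest/lowest gene-centered mean expression, or
   differential expression (Welch t-test of focus vs all other groups
   combined, raw p ≤ 0.05, ranked by p). Ties break by gene id so panels are
   byte-reproducible.
3. **Scores.** Every cell is scored against every panel: cell-centered MAE,
   cell-centered mean expression, or the polygenic score
   $\mathrm{PS} = \sum_i s_i e_i$ (sign $s_i = \pm 1$ from the DE direction,
   $e_i$ the normalized expression). With $G$ groups each cell becomes a
   $G$-vector — the feature table for classification.
4. **Evaluation.** A stratified 80/20 split; panels are derived from the
   training cells only; five classifiers (random forest, linear and radial
   SVM, nearest shrunken centroids, LDA) are tuned by stratified 10-fold CV
   on the training scores and evaluated on the held-out cells by one-vs-one
   multiclass AUC (the Hand–Till-style average of directed pairwise AUCs).
   The split/evaluate cycle repeats (default 10 times) and the per-algorithm
   median AUC and IQR are reported.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 200 | panel size per group |
| `min_nonzero` | 10 | digits required before a gene-centered MAE is trusted |
| `alpha` | 0.05 | raw p cutoff for the DE route (no multiplicity correction, deliberately) |
| `fraction` | 0.8 | training fraction of the stratified split |
| `cv_folds` | 10 | CV folds for hyperparameter selection |
| `n_repeats` | 10 | repeated splits aggregated by median/IQR |

`min_nonzero` exists because an MAE estimated from one or two digits is
pure noise yet can be extreme; with fewer than 10 digits the gene is marked
ineligible rather than allowed to dominate a top-`k` panel. The value is a
compromise, not a fitted constant: it excludes only genes whose digit
histogram is essentially empty.

### Numerical choices

* **Digit extraction** reads the first character of a 12-significant-digit
  decimal rendering rather than computing
  $\lfloor x / 10^{\lfloor \log_{10} x \rfloor} \rfloor$, so binary-float
  artifacts (a stored `0.2999999999999998` meaning 0.3) cannot flip a digit.
  A property test checks both routes agree on a million log-uniform values.
* **Zeros carry no leading digit.** They are excluded from every digit
  histogram and reported as `n_zero_excluded`; with scRNA-seq dropout this
  count is substantial and worth inspecting.
* **Empty-panel cells.** A cell expressing none of a panel's genes gets the
  theoretical maximum MAE (0.2120539) with a warning: on that panel the cell
  is maximally non-Benford, and dropping it would break the fixed-width
  feature table. The alternative (NA) would silently shrink the test set.
* **Degenerate t-tests.** Zero variance on both sides with equal means is
  "no evidence" (NA); with unequal means the gene is infinitely significant
  (p = 0). Exactly equal means get sign +1 — arbitrary but fixed.
* **Ties** in panel ranking break by gene id ascending; ties in class
  probability break by the first class; both are logged design choices in
  favor of reproducibility over symmetry.
* **Wilcoxon comparisons** of focus-group scores against the rest use exact
  enumeration when both sides have ≤ 25 samples and no ties, and the normal
  approximation with tie and continuity correction otherwise.

### Classifier details

The five algorithms mirror a common expression-classification toolbox. The
"PAM" label that appears in that toolbox is implemented here as the nearest
shrunken centroids classifier (the supervised method usually tuned under
that name); partition-around-medoids proper is a clustering algorithm and
cannot be a supervised learner in this harness. Hyperparameter grids are
small and standard, declared rather than inferred: radial SVM
$C \in \{0.25, 1, 4, 16\}$ and $\gamma$ at the scale heuristic
$1/(p \cdot \mathrm{Var})$ times $\{0.5, 1, 2\}$; linear SVM
$C \in \{0.25, 1, 4\}$; random forest with 500 trees and `mtry` over
$1..G$; NSC shrinkage over 10 log-spaced thresholds up to the largest
standardized centroid deviation; LDA has no grid. Features are standardized
with training-set mean/sd before the SVMs and LDA; the forest uses raw
scores and NSC standardizes internally by pooled within-class sd. CV
selects on fold accuracy; the final model refits on the full training set
and is scored by multiclass AUC.

**Leakage discipline.** Panels, scaling constants, CV folds and
hyperparameters are derived from training cells only. The acceptance suite
verifies this mechanically: replacing every held-out cell's expression with
noise leaves the panels and the serialized trained models byte-identical.

## What the synthetic generator emulates

`generate_expression()` draws a genes × cells count matrix with known ground
truth:

* **Background genes** are `round(10^U)`, $U \sim \mathrm{Uniform}(lo, hi)$
  per entry — Benford-adherent by construction and spanning several decades,
  like the bulk of a real transcriptome.
* **Marker genes** (per group, disjoint) are rounded log-normals with a
  narrow, low median (`marker_location`, CV `marker_cv`) in their own
  group's cells and one fifth of that location elsewhere, with Bernoulli
  dropout zeros overlaid. They reproduce the empirical signature of
  Benford-deviant genes: narrow *and* lowly expressed, hence the large
  overlap between high-MAE and low-mean-expression panels.

The default scenario fixes six groups of 374, 173, 138, 105, 69 and 159
cells (1,018 in total, mirroring a published six-cell-type embryonic-lineage
scRNA-seq design), 5,000 background genes on $[10^0, 10^4]$, 200 markers per
group, CV 0.15 and 30% dropout, seed 1004.

**Why marker locations 6.7–8.2.** The defaults place every group's marker
median in a narrow band just below 10, staggered per group (6.7, 7.0, 7.3,
7.6, 7.9, 8.2). This band is not cosmetic; it is what makes the planted
structure self-consistent. A point mass on digit $d$ has
$\mathrm{MAE} = 2(1 - E_d)/9$, which grows with $d$. Inside its own group a
marker's digits concentrate on 6–9 (MAE ≈ 0.15–0.21); in other groups the
one-fifth-scaled values (1.3–1.6) spread across digits 1 and 2, whose large
Benford frequencies cap the MAE near 0.12. Own markers therefore outrank
every other group's markers in the focus group's high-MAE panel. Locations
near 9 or above would spill digits across 10 back onto digit 1 and *lower*
the own-group MAE, while locations near 5–6 would park the scaled-down
foreign values on a near point mass at digit 1–2 and *raise* the foreign
MAE; either breaks the intended ordering.

**What the generator does not model**, and what passing tests therefore do
not show: negative-binomial overdispersion trends, ambient RNA, batch
effects, doublets, gene–gene correlation, or any resemblance to a specific
real dataset's marginals. Tests on this generator demonstrate that the
machinery recovers a planted Benford-deviance structure under dropout and
integer rounding — not that any particular real dataset will classify at the
same accuracy.

**Integer rounding and the first decade.** Because counts are rounded
integers, values in $[1, 10)$ have distorted digit frequencies (e.g.
everything in $[1.5, 2.5)$ becomes digit 2), shifting digit-1 frequency by
up to ≈ 0.026 in that decade. Pooled background MAE stays below 0.01, but a
chi-square GOF on thousands of digits per cell *detects* the distortion, so
the generator's calibration property (≥ 95% of cells consistent with
Benford at α = 0.01) is checked on a high-magnitude background
($10^2$–$10^6$) where rounding is negligible. This mirrors real count data,
where the lowest decade is similarly quantized.

In the synthetic world every group's markers are narrow and low in *every*
group, so at panel sizes that cover the whole marker pool the DE route
selects nearly the same genes as the low-expression route; the
overlap comparison in the tests therefore asserts the mechanism-level
contrast (Benford-deviant panels coincide with lowly expressed genes and
are disjoint from highly expressed ones) rather than a strict ordering
between two near-identical overlaps.

## Problem sizes used by the test and acceptance runs

Property tests run on scaled-down scenarios (typically 3 groups × 40–100
cells, 300–800 background genes, 25–40 markers per group) — the properties
under test are size-free, and these sizes keep the suite quick to iterate.
The acceptance checks run on the full default scenario (1,018 cells, 6,200
genes): per-group marker recovery of the top-200 high-MAE panels, median
radial-SVM multiclass AUC over 10 repeated 80/20 splits, a permuted-label
negative control, chi-square type-I calibration at n = 10,000 digits × 1,000
replicates, and a million-value digit-extraction oracle comparison.

## Known limitations

* The method presumes values spanning multiple decades for the background;
  data pre-scaled to a narrow range (e.g. per-gene z-scores) are
  meaningless inputs and will score uniformly deviant.
* MAE estimates from few digits are noisy; `min_nonzero` guards the panels
  but per-gene scores for sparse genes remain unstable.
* The DE route deliberately uses raw p ≤ 0.05 (no FDR control) to stay a
  faithful comparator, not a recommended DE practice.
* Whether the comparator t-test should be Student's or Welch's is ambiguous
  in the surrounding literature; Welch is implemented. Users comparing
  against Student-based results should expect small rank differences.
* Multiclass AUC summarizes ranking quality only; calibration of the
  predicted probabilities is out of scope.
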