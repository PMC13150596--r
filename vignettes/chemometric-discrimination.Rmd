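---
title: "Discriminating plant-extract genera from spectral fingerprints: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating plant-extract genera from spectral fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crude plant extracts of two legume genera — a *Lupinus*-type class rich in
quinolizidine alkaloids and a *Mimosa*-type class rich in diverse
flavonoids — produce UV–vis (240–400 nm) and ATR-FTIR (1800–600 cm⁻¹)
fingerprints that are nearly identical in their gross band structure.
Discrimination therefore rests on small, chemically interpretable
differences: isoflavone Band II absorption near 259 nm, phenolic B-ring
absorption near 284 nm, flavonol Band I absorption near 356 nm, the
amide-I/quinolizidine C=O stretch near 1658 cm⁻¹, and C–O stretches near
1103–1107 cm⁻¹. `chemodisc` implements the complete chemometric workflow
for this setting: preprocessing, unsupervised exploration (PCA, HCA),
Kennard–Stone sample partitioning, SPA and GA wavelength selection coupled
to a two-class Fisher/LDA classifier, and confusion-matrix figures of
merit.

Because no raw spectra are distributed with the study this workflow
emulates, the package ships a synthetic-spectra generator whose planted
class markers provide ground truth for every downstream stage. All tests
and the acceptance script run on these synthetic data.

## The synthetic generator

Each class spectrum is a sum of Gaussian bands
$a\,\exp\!\big(-(x-c)^2/(2w^2)\big)$: a set of *shared* bands common to
both classes plus small *class-exclusive marker* bands. A replicate
spectrum of sample $i$, replicate $r$ is

$$
y_{ir}(x) = \big(s_{\text{shared}}(x) + s_{\text{class}}(x)\big)\,
(1 + \delta_i) + \alpha_{ir} + \beta_{ir}\,t(x) + \varepsilon_{ir}(x),
$$

with $\delta_i \sim N(0, \sigma_\text{scatter})$ a per-sample
multiplicative scatter factor, $\alpha_{ir} \sim U(0, b)$ and
$\beta_{ir} \sim U(-b, b)$ a per-replicate linear baseline
(offset and end-to-end tilt over the normalized axis position $t$), and
$\varepsilon \sim N(0, \sigma_\text{noise})$ i.i.d. per point. Scatter is
drawn per *sample* — it models preparation and concentration variation, so
samples keep an identity that survives replicate averaging — while
baseline and noise are instrument effects drawn per *replicate*. With all
three set to zero, replicates are identical and the pointwise class-mean
difference is exactly the difference of the planted marker sums, which the
test suite asserts.

Default study conditions mirror the emulated design: 15 class-A ("LU")
vs 18 class-B ("MI") samples; UV–vis in triplicate on 240–400 nm at 1 nm
(161 points); FTIR in duplicate on a *descending* 1800–600 cm⁻¹ grid at
2 cm⁻¹ (601 points, the instrument-export convention — every algorithm in
the package is axis-direction agnostic). Markers sit at 259 nm (class A)
and 284/356 nm (class B), and at 1658 cm⁻¹ (class A) and 1561/1103 cm⁻¹
(class B), with width 4 nm / 8 cm⁻¹, amplitude 0.10 absorbance (20× the
additive noise sd of 0.005), scatter sd 0.05 and baseline bound 0.05 —
values typical of bench UV–vis/ATR-FTIR work on crude extracts. What the
generator does **not** emulate: Beer–Lambert mixture physics, ATR
penetration-depth effects, detector nonlinearity, wavelength jitter, or
correlated (pink) noise. Passing tests therefore show that the
*algorithms* behave correctly on data with the stated statistical
structure, not that any particular real extract pair is separable.

```{r}
library(chemodisc)
gen <- generate_dataset(uv_default_config(seed = 7))
gen$dataset          # 99 spectra x 161 points
gen$ground_truth     # planted marker column indices per class
```

## Preprocessing

The chain, in fixed order, is

1. **Savitzky–Golay smoothing**, second-order polynomial, window 13
   points (defaults; both configurable). Edge points use the polynomial
   fitted on the first/last full window evaluated at the edge positions,
   so no axis shortening occurs. The implementation delegates to
   `signal::sgolayfilt` and is verified in the tests against a brute-force
   per-window least-squares oracle.
2. **Baseline correction.** The emulated protocol does not specify its
   baseline algorithm, so two deterministic substitutes are provided:
   `linear_endpoints` (default; subtracts the straight line through the
   two endpoint values — the standard offset/tilt correction for ATR
   spectra) and `offset` (subtracts the minimum). Because min–max
   normalization follows, residual baseline scale is absorbed and the
   precise baseline model is second-order for classification.
3. **Min–max normalization** of each spectrum to [0, 1] over its full
   range. A constant spectrum (dead detector/blank) raises an error.
4. **Mean-centering.** For exploratory analysis the whole data set is
   centered ("globally mean-centered"); for supervised runs the column
   means are fitted on the Kennard–Stone training partition and applied
   unchanged to the test partition, so held-out information never leaks
   into centering. `preprocess_dataset()` exposes this via its
   `fitted_means` argument.

Replicates are averaged to one spectrum per sample *before* multivariate
analysis (the convention of per-sample average figures); the averaging
step is a plain function call and can simply be skipped for sensitivity
analysis.

## Exploration

`pca()` is a thin wrapper over the SVD of the centered matrix: loadings
are right singular vectors (sign-fixed so the largest-magnitude entry of
each loading is positive, making score plots reproducible), and component
$i$ explains $100\,\sigma_i^2/\sum_j \sigma_j^2$ percent of variance.
An uncentered input is a contract error, not silently centered.

`hca()` is agglomerative clustering on Euclidean distances with
Lance–Williams updates (average — the default, a common chemometrics
choice — complete, or Ward.D2 linkage). The merge tie-break is
deterministic: among minimal-distance pairs, the lexicographically
smallest pair of active-cluster positions is merged, so dendrograms are
invariant to row order up to relabelling. The linkage behind the emulated
study's dendrograms is unrecoverable; these settings are substitutes, not
a reproduction, and the tests cross-check heights and cophenetic matrices
against `stats::hclust` on tie-free data. `two_group_separation()` cuts
the tree at the top merge and reports majority-class purity; on default
synthetic data it is 1.0. Outliers are never removed — the pipeline only
reports diagnostics, mirroring a retained-all-samples policy.

## Kennard–Stone partitioning

`kennard_stone()` is the classical max–min procedure: start from the
farthest pair (ties: lexicographically smallest index pair), then
repeatedly add the row maximizing the minimum distance to the selection
(ties: smallest index). `stratified_split()` runs it *within each class*
with per-class quota $\lfloor f\,n_{\text{class}} + 0.5\rfloor$ at
$f = 2/3$: on the 15 + 18 design this reproduces the 10 + 12 = 22
training / 11 test division exactly. Whether the emulated study split per
class or globally is not stated; per-class is the only rule that
guarantees those printed counts, and is therefore the default (an
inference, not a fact). Distances are Euclidean, computed on the
preprocessed, replicate-averaged spectra — note that column centering
leaves between-row Euclidean distances unchanged, so the split is
identical whichever centering scope is used.

## Variable selection

Both searches minimize the same cost: **leave-one-out LDA
misclassification on the training partition**. The emulated protocol says
training results use cross-validation without naming the flavor; LOO is
the deterministic choice at $n = 22$. The cost is implemented twice — a
readable R reference (`loo_cv()`) and a compiled RcppArmadillo kernel
(`loo_cost()`) used inside the search loops — and the suite asserts their
equality on random problems, including rank-deficient ones.

**SPA** (`spa_select()`): for every start column, a successive-projections
chain is grown to length 10 — each step appends the column with the
largest residual norm orthogonal to the span of the chain, the standard
minimal-collinearity construction — and every prefix ("selection windows"
1–10) is costed. Ties are broken toward fewer variables, then the smaller
start index (parsimony first). The chain step is tested against a
brute-force QR projection oracle, and the search's regret against
exhaustive subset enumeration is bounded on small problems.

**GA** (`ga_select()`): chromosomes are variable-length lists of up to 10
distinct column indices (the ≤10 cap is structural, not a repair step);
fitness is 1 − LOO error; selection is tournament of size 2; crossover
(probability 0.60) pools both parents' genes and deals them uniformly,
de-duplicating and truncating; mutation replaces each gene independently
with probability 0.05 by an unused index ("5% mutation" read per gene —
the per-chromosome reading is the other defensible choice); elitism 1
makes the best-ever fitness monotone. Runs are deterministic given the
seed. The three population/generation combinations 100/100, 200/200 and
300/300 can be swept by `run_pipeline()`, which flags the best-cost run.

`fisher_weights()` reports, per selected variable,
$(\bar x_{A} - \bar x_{B})^2 / (s_A^2 + s_B^2)$ with unbiased variances
and attributes the variable to the class with the larger mean; a zero
pooled variance yields a flagged infinite weight rather than an error.

### What "marker recovery" can and cannot mean

On synthetic data the planted markers are the only source of class-mean
difference, so one might expect selection to return the exact marker
columns. It cannot, in principle: the LOO cost is exactly zero on a
*plateau* spanning each marker band's support, and any cost-minimizing
search stops wherever it first touches the plateau. SPA's
smallest-index tie-break lands on the plateau edge a few grid steps from
the center — precisely the behavior seen in real SPA studies, where the
selected wavelength sits a few nm from the annotated band maximum. The
recovery tests therefore assert band-support recovery: SPA within 2
band-widths (2σ) of a planted center, GA — whose multi-variable
chromosomes can ride a band's tail farther out — within the full tail
support (4σ), in ≥95% of 20 seeded runs. Recovery is assessed on the
chain *without* min–max normalization: dividing each spectrum by its own
range couples every column to the global extremes and delocalizes class
information across the whole axis (with it, even the first axis column
becomes discriminative), so localization claims are only meaningful
pre-normalization.

## The discriminant and its figures of merit

`fit_lda()` is classical two-class LDA with equal priors (the 15/18
design is near-balanced; proportional priors are a one-line change at the
call sites): weights $S_p^{-1}(\bar x_{+} - \bar x_{-})$ with the pooled
covariance $S_p$ = within-class scatter / (n − 2), bias placing the
boundary at the class-mean midpoint. A score of exactly 0 classifies as
the negative class, and the positive class defaults to the first label in
sort order ("LU"); reports show both orientations since either genus
could be read as "positive". If $S_p$ is numerically singular
(reciprocal condition ≤ 1e−10), a ridge λ·trace/k·I is escalated by
decades from 1e−8 to 1e−2 and λ is recorded — a fit with λ = 0 is
identifiably "classical". Predictions provably equal the
Mahalanobis-closest-class rule, which the tests assert, alongside a
`MASS::lda` cross-check.

Figures of merit are the standard confusion-matrix quantities, in
percent: sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
(TP+TN)/n. Zero denominators raise named errors; the identity
ACC = (SEN·(TP+FN) + SPE·(TN+FP))/n is asserted. In `loo_cv()` a fold
whose covariance stays singular past the ridge cap counts as a
misclassification (with a warning) so the estimator remains total.

## Numerical choices and degenerate inputs

- SPA residual-norm eligibility threshold: 1e−9 × the largest column
  norm; columns below it are inside the span (collinear) and skipped.
  Exhausted rank either errors (listing the attained chain) or, in
  `partial` mode used by the full search, returns the attained prefix.
- Baseline `linear_endpoints` zeroes both endpoint columns exactly; the
  SPA search simply skips such numerically zero start columns.
- PCA centering contract tolerance: 1e−8 relative to the largest entry.
- HCA and Kennard–Stone tie-breaks are lexicographic on indices, making
  every "deterministic" claim bit-reproducible.
- The global seed is expanded into per-stage seeds by a fixed affine rule
  (`stage_seed()`), so changing, say, the GA configuration never perturbs
  the simulated data.

## Problem sizes and runtime

All tests and the acceptance analysis run the full study-sized problem:
33 samples, 161 (UV) or 601 (FTIR) variables, SPA over all starts × sizes
1–10, GA at population 100 × 100 generations. These sizes run in seconds
because the LOO-LDA kernel is compiled and GA fitness values are
memoized per chromosome; the full test suite completes in about two
minutes on a single core. Property suites use 10–20 seeded replicates, a
choice balancing statistical force against suite runtime.

## Known limitations

- Two classes only; multi-class SPA/GA-LDA, PLS-DA, SIMCA and QDA are out
  of scope.
- The synthetic generator's Gaussian bands and linear baselines are
  deliberately simple; conclusions about real extracts require real
  spectra.
- The exact PCA variance percentages, dendrogram settings and selected
  wavelengths of the emulated study depend on its unavailable raw data
  and are not reproduction targets; what the package reproduces are the
  printed *design* quantities (22/11 split with 10 + 12 training samples,
  ≤10 GA variables, 100% / ≥95% figures of merit on separable data) and
  the complete method.
- No plot rendering: every figure's data (scores, loadings, dendrograms,
  Fisher weights, discriminant values with train/test flags) is written
  as CSV/JSON/Newick for the user's plotting tool of choice.
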