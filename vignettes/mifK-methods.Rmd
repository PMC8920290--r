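---
title: "Quantifying spatial clustering of immune cells with a permutation CSR null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial clustering of immune cells with a permutation CSR null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mifK)
```

## The model

The positions of phenotype-positive immune cells in a tissue sample are
treated as a spatial point process observed in a window $W$. The summary
statistic is Ripley's K,

$$\hat K(r) = \frac{A}{n(n-1)} \sum_{i \ne j} w_{ij}\,
  \mathbf 1\{d(x_i, x_j) < r\},$$

with $A = |W|$, $n$ the number of positive cells, and $w_{ij} \ge 1$ an
edge-correction weight compensating for neighbours lost outside $W$. The
indicator is strict ($d < r$); ties at exactly $r$ are excluded. Under
complete spatial randomness (CSR) $E[\hat K(r)] = \pi r^2$; values above
indicate clustering, below indicate regularity. The bivariate (cross)
form replaces the single point set by anchors and a second type,
$\hat K_{12}(r) = \frac{A}{n_1 n_2}\sum_i \sum_j w_{ij}\mathbf 1\{d < r\}$;
the anchor centres every ring, and under the isotropic correction also the
circle used for $w_{ij}$, so cross K is not symmetric in its two types
under that correction (it is exactly symmetric under translation, because
$|W \cap W_{+v}| = |W \cap W_{-v}|$).

### Window

Tissue cores are not rectangles, so $W$ is the convex hull of **all**
measured cells in the sample — any marker status, not only positives: the
tissue region is defined by where cells could be measured. Hulls need at
least three non-collinear cells; the area is the shoelace formula on the
hull vertices. Non-convex tears are deliberately *not* traced by the
window (no alpha shapes); they are handled by the permutation null below.

### Edge corrections

Both standard corrections are computed exactly for convex polygon windows
(no grid approximations):

* **translation**: $w_{ij} = |W| / |W \cap W_{+(x_j - x_i)}|$, via
  Sutherland–Hodgman clipping of $W$ against its translate;
* **isotropic**: $w_{ij}$ is the reciprocal of the fraction of the
  circle centred at $x_i$ with radius $d(x_i,x_j)$ whose circumference
  lies inside $W$. For a convex window each edge half-plane excludes one
  arc, so the inside fraction is an exact interval union.

Weights are capped at the number of points, a guard against near-zero
overlap or arc fractions for extreme boundary configurations; no other
damping is applied. On a known rectangular window both estimators are
unbiased for $\pi r^2$ under CSR and agree closely. On hull windows both
inherit a small negative finite-$n$ bias (the hull is slightly smaller
than the region that generated the cells, of order $\log n / n$ in
relative area). This bias is shared by the observed K and the permutation
null below — both are computed on the same window with the same weights —
so it largely cancels in the degree of clustering, which is one more
reason to prefer the empirical null over the theoretical $\pi r^2$.

## The permutation CSR null and the degree of clustering

TMA cores frequently contain folded or torn regions in which no cell can
be measured. The theoretical CSR value $\pi r^2$ assumes cells could have
been anywhere in $W$, so in holey samples it *underestimates* K under CSR
and inflates apparent clustering. The empirical null conditions on the
observed cell geometry instead:

1. hold every measured cell location fixed (the null inherits the holes);
2. draw $n_\text{pos}$ locations without replacement from all cells in the
   compartment under analysis (equivalently: permute the marker labels,
   preserving the positive and negative counts);
3. recompute $\hat K(r)$ on the drawn set with the *same* window and
   weights;
4. repeat `n_perm` times (default 100) and average.

The per-sample summary is the **degree of spatial clustering**
$\hat K_\text{obs}(r) - \overline{\hat K_\text{CSR}}(r)$ at the analysis
radius, $r = 30$ µm by default. The bivariate null reassigns both labels
jointly (disjoint sets of $n_1$ anchors and $n_2$ others drawn without
replacement), and the cross degree is computed only when both types are
present. The full permutation matrix is retained on the `csr_null` object
so calibration quantiles are available, but the null is summarised by its
mean.

Estimability is explicit rather than silent: zero positives mean abundance
0 and no degree; a single positive cell means K (denominator $n(n-1)$) is
undefined and the sample is flagged, not zero-filled.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `r` | 30 | µm | analysis radius; diagnostic grids (e.g. 0–100 µm) supported everywhere. Radii are always microns — pixel inputs are converted at read time (`mpp = 0.4977` µm/pixel for the Vectra/HALO platform), since an undetected unit mismatch would rescale K by $\mathrm{mpp}^2$. |
| `correction` | translation | — | isotropic and uncorrected also available |
| `n_perm` | 100 | draws | permutation replicates; the Monte-Carlo SE of the null mean is `sd(null)/sqrt(n_perm)` |
| `compartment` | all | — | tumor/stroma restriction (PanCK-based calls); permutation runs within the filtered set |
| `k_folds` | 10 | — | cut-point cross-validation |
| `min_group` | 10 | samples | minimum size of each nonzero-abundance group for a candidate cut pair |

## The survival stage

Per-sample abundance (percent positive) and degree are categorized into
five groups: `None` (zero abundance — clustering undefined), then
Low/High abundance × Low/High clustering (`LL`, `LH`, `HL`, `HH`).
Boundary values go to High. Samples with positive abundance but a single
positive cell take the Low clustering level: one cell cannot exhibit
clustering; they remain flagged in the output for sensitivity analyses.
The bivariate analogue encodes absence/presence of each type (`AAN`,
`APN`, `PAN`) and grades co-occurrence only when both are present (`PPL`,
`PPH`); presence means at least one positive cell.

Cut-points are chosen by a constrained grid search under k-fold
cross-validation:

* folds partition **subjects**, not samples, so a subject's repeated cores
  never straddle training and selection (the fold assignment sorts
  subjects before the seeded shuffle, making results invariant to row
  order);
* candidate cuts are midpoints between consecutive observed values among
  nonzero-abundance training samples, quantile-thinned to at most 50 per
  dimension;
* a candidate pair is feasible only if each of `LL`, `LH`, `HL`, `HH`
  keeps at least `min_group` (default 10) training samples;
* the objective is the multi-group log-rank chi-square over the five
  groups — the standard operationalisation of "largest separation of the
  survival curves" in the optimal cut-point literature; ties take the
  first (smallest) candidate;
* the final cuts are per-dimension medians of the fold optima.

Group–survival association uses Cox proportional hazards on per-sample
rows: group factor (reference `None`), age at diagnosis (linear, years)
and stage (I–IV, indicators against I), with a cluster-robust sandwich
variance by subject for the repeated samples. Reported are per-group
hazard ratios with 95% CIs, and the overall robust Wald test of all group
terms (4 df when five groups are populated). The spatial-vs-abundance
comparison refits both groupings without the cluster term — likelihood
ratios are undefined for sandwich-variance fits — and refers twice the
log-partial-likelihood difference to a chi-square with df equal to the
difference in indicator counts (2 for five vs three univariate groups).
With repeated samples per subject this LRT is approximate (the rows are
not independent); it is exactly calibrated for one-sample-per-subject
designs, which is how the package's null-calibration checks exercise it,
and it is reported alongside the robust Wald tests rather than instead of
them.

## The synthetic-data generator

`simulate_points()` produces a homogeneous Poisson background and labels
positives either by independent Bernoulli thinning (CSR regime — thinning
a homogeneous process leaves K at $\pi r^2$) or as a **Thomas cluster
process** superposed on uniform negatives. Thomas was chosen because its
K has a closed form, $K(r) = \pi r^2 + (1 - e^{-r^2/4\sigma^2})/\kappa$,
and the permutation null on the superposition converges to the
superposition K,
$(\lambda_1^2 K_1 + \lambda_2^2 K_2 + 2\lambda_1\lambda_2\pi r^2)/(\lambda_1+\lambda_2)^2$,
so the expected degree has an analytic oracle. Parents are simulated in a
$4\sigma$ buffer around the window so cluster edges are not thinned.
Defaults ($\kappa = 5\times10^{-5}$ parents/µm², $\sigma = 15$ µm,
1000×1000 µm windows, positivity 1–30%) reflect immune-marker rates and
cluster scales plausible for mIF panels.

`punch_holes()` emulates TMA folds and tears by removing cells inside
random discs until a target fraction of the bounding region is covered
(measured on a fixed 101×101 grid). Real tears are irregular, but disc
unions reproduce the relevant failure — intensity inhomogeneity — that the
permutation null corrects for.

`simulate_cohort()` emulates the shape of an ovarian-cancer mIF study
(default 90 subjects, 3 samples each, mirroring cohorts of ~90 subjects
with ~260 cores/ROIs): a true group per subject, exponential survival with
log-hazard = age, stage and group effects (proportional hazards hold by
construction), and independent uniform censoring over a 120-month horizon
(`censor_max = Inf` disables censoring). Two fidelity levels: `"summary"`
draws abundance and degree directly from group-separated distributions
(true cuts at 2.5% abundance and half the High-clustering mean degree) for
fast exercise of the survival stage; `"cells"` generates an actual point
pattern per sample (Bernoulli labels for Low clustering, Thomas positives
for High). The truth record retains every generating quantity.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: segmentation and phenotype-calling errors,
intensity gradients within a core, non-disc tears, marker panels with
correlated positivity beyond the CD8/FOXP3 conflict rule, non-proportional
hazards, and informative censoring.

## Numerical choices and degenerate inputs

* Exact polygon clipping and arc-interval geometry; the only guard is the
  weight cap at $n$.
* Strict `d < r` indicator, as the estimator definition prescribes.
* Fewer than 3 cells: no window, sample flagged. One positive cell: K not
  estimable, flagged. All cells positive: the permutation null is
  degenerate (every replicate equals the observed K) and a warning is
  issued.
* Permutation seeds: every cohort-level function derives independent
  per-sample sub-seeds (< 2^31) from one master seed, so runs are
  bit-reproducible and the caller's RNG stream is never consumed.
* Cut-point ties take the smaller candidate; identical full and coarsened
  partitions give an LRT statistic of 0 with p = 1 by convention (0 df).

## Design choices where the design was open

* **Conflicting phenotypes**: cells flagged both CD8+ and FOXP3+ are
  demoted to CD3+ only (location retained, both subset flags cleared).
  Only this conflict is handled; other marker combinations pass through.
* **Phenotypes are strict conjunctions**: a CD8+ cell lacking CD3 belongs
  to no T-cell phenotype.
* **Radius units**: r = 30 is interpreted in microns, and everything is
  converted to microns at ingestion; the alternative (pixels) would change
  the radius by roughly 2× on the 0.4977 µm/pixel platform, so the unit is
  a visible argument rather than a hidden constant.
* **Fold splitting by subject** (not by sample): prevents leakage across
  repeated cores of one subject.
* **Log-rank as the cut-point objective** rather than a Cox-based
  statistic: fast, standard, and free of covariate-adjustment choices
  inside the selection loop.
* **Single-positive samples grouped as Low clustering**, flagged for
  sensitivity analysis.
* **Null summarised by its mean** (quantiles retained on the object).

## Problem sizes used by the test suite

The property suite runs at desk scale on one CPU: 100-sample batches for
the edge-correction agreement and hole-bias checks; 200 random instances
($n \le 50$) against naive double-loop oracles; 20 samples of ~1000 cells
for the $\pi r^2$ limit of the permutation null (known rectangular window,
so the hull finite-$n$ effect does not enter that comparison); 120 Thomas
samples for the closed-form degree oracle; 50 effect-free cohorts of 120
independent subjects for p-value calibration; 100 cohorts of 90 subjects ×
3 samples for hazard-ratio recovery and CI coverage. The whole suite
completes in a few minutes.

## Known limitations

* The convex hull overstates the tissue region for crescent-shaped
  sections; the permutation null compensates for the resulting
  inhomogeneity in the CSR reference, but K itself is still a
  whole-window average.
* The degree of clustering is correlated with abundance at low counts
  (fewer positives → noisier K), which is why the survival stage always
  categorizes abundance alongside clustering.
* 100 permutations give a null-mean Monte-Carlo SE of a few percent of
  $\pi r^2$ for typical positive counts; very sparse phenotypes (< 1%)
  may warrant more.
* The LRT ignores within-subject correlation (see above); with repeated
  samples treat its p-value as descriptive and rely on the robust Wald
  tests for inference.
* Optimal cut-points are data-snooping by construction; the
  cross-validation and the minimum-group constraint stabilise them but do
  not remove the need for external validation.
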