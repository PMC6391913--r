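---
title: "Measuring sub-cellular resolution with QSep: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sub-cellular resolution with QSep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsep)
```

# The problem

Gradient-based spatial proteomics assigns proteins to sub-cellular niches
by the similarity of their occupancy profiles across biochemical
fractions. Everything downstream — classification of unlabelled proteins,
detection of multi-localisation, comparison of conditions — rests on the
experiment having *resolved* those niches: marker proteins of one
organelle should form a tight cloud, far from the clouds of other
organelles. This vignette describes the statistic this package computes
to quantify that property, the conventions adopted where several were
defensible, and what the accompanying synthetic data generator does and
does not establish.

# The statistic

Let the experiment quantify $n$ proteins over $p$ fractions, and let a
curated annotation assign markers to $k \ge 2$ clusters. Two layers are
computed:

**Raw cluster distance matrix.** $d(i,i)$ is the mean Euclidean distance
over all unordered pairs of markers within cluster $i$ (self-pairs
excluded — including the zero self-distances would deflate the tightness
estimate by a factor $(n_i-1)/n_i$); $d(i,j)$ is the mean over all
$n_i n_j$ cross pairs. This matrix is symmetric and in the units of the
quantitation.

**Normalised (QSep) matrix.** $q(i,j) = d(i,j)/d(i,i)$: each *row* is
divided by the reference cluster's within distance. Rows were chosen as
the reference axis because each heatmap row then reads as "distances seen
from reference cluster $i$, in units of $i$'s own width"; the transpose
convention would be equally defensible and users can transpose the
matrix, but one convention has to be fixed for the exported artefacts.
The diagonal is identically 1 and the matrix is generally asymmetric —
a diffuse cluster scores small distances *to* everything even when tight
clusters score large distances to it.

**Summary.** The experiment-wide summary is the *median* of all
$k(k-1)$ ordered off-diagonal entries. Both $(i,j)$ and $(j,i)$ are
pooled: they carry distinct information (the two reference widths), and
the per-cluster boxplot display pools them the same way. The median, not
the mean, is used because a single overlapping cluster pair (e.g.
endosome/lysosome) produces outlying small entries that should not drag
the experiment-wide score.

## Missing values

Fractionation datasets — SILAC-based designs especially — can miss a
large share of entries. Two rules apply, and they are deliberately
different:

* **Distances retain missing values.** A pair of profiles jointly
  observed in $m \le p$ fractions contributes
  $\sqrt{(p/m)\sum_{complete}(x_f-y_f)^2}$: the observed squared
  differences are scaled up to the full dimensionality, so partially
  observed pairs remain comparable with fully observed ones. This is the
  convention of `stats::dist()`, so scores remain comparable with the
  wider ecosystem. A pair with *no* jointly observed fraction has no
  defined distance; it is dropped from both numerator and denominator of
  the affected cell (with a warning at the single-pair level, and the
  effective pair counts exported in `pair_counts` for transparency).
  Dropping, rather than erroring, keeps sparse datasets scoreable; a cell
  in which *every* pair is undefined is an error, because silently
  reporting nothing would hide a structurally unscoreable cluster pair.
* **Visualisation imputes zeros.** PCA has no pairwise-complete analogue
  that preserves its geometry, so the projection (and only the
  projection) runs on `zero_imputed_view()`. In relative-occupancy data
  a missing value mostly means "not detected in this gradient region",
  for which zero is the natural placeholder. The distance engine never
  sees imputed values.

## Marker hygiene

Within-cluster averages over very few markers are noisy, so clusters with
fewer than `min_markers = 7` markers *present in the scored experiment*
are dissolved into the unknown class before scoring. The threshold is
inclusive (a 7-marker cluster survives) and re-applied after marker
transfer, because intersecting identifier namespaces shrinks clusters;
a transferred annotation must clear the same bar as a native one.
Transfer itself is a wholesale replacement — a conflicting native label
loses — matching the intended use of judging one laboratory's data under
another laboratory's curation. Identifier matching is exact string
equality by default; a `normalise_id` hook (e.g. stripping accession
versions) is available but off, since silent fuzzy matching across
namespaces is a correctness risk.

## Comparing experiments

`compare_qsep()` applies a two-sided Welch (unequal-variance) $t$-test to
the natural-log-transformed off-diagonal entries. The log transform is
used because normalised distances are ratios with a hard floor near 1 and
a long right tail; Welch's form because two experiments differ in cluster
count and spread, and the pooled-variance assumption buys nothing. The
per-comparison result is reported as statistic, degrees of freedom and
p-value; no multiple-testing machinery is attached, as the intended use
is an ad-hoc contrast of two annotations or two experiments.

## Robustness to the annotation

`class_removal_scan()` recomputes the median for *every* subset of up to
`max_removed = 3` removed clusters (exhaustive, not sampled — for
$k \le 14$, at most 469 records). Because marker-to-marker distances do
not depend on other clusters, removal only requires subsetting the raw
matrix and renormalising; the suite verifies this shortcut against full
recomputation. An ordinary least-squares line of median against number
removed summarises the scan; a resolution metric fit for cross-experiment
comparison should show a slope near zero. The zero-removal baseline is
included in the fit by default (`include_baseline = FALSE` reverts to
removed-subsets only): the baseline is a legitimate observation of the
same quantity at $r = 0$, and excluding it changes the slope only when
the metric is *not* robust, which is exactly what the scan should expose.

# The synthetic generator

`synthetic_truth()` + `generate_experiment()` emulate the features of
fractionation data that QSep actually consumes:

* $k$ isotropic Gaussian marker clusters ($\sigma$, default 0.1) at
  centres with controlled minimum separation $\Delta$ (default 1). The
  default placement is a scaled simplex — all pairwise centre distances
  exactly $\Delta$ — so separation is a single dial; a `"random"` mode
  produces irregular geometry.
* background proteins (default 100) from a mixture: 30% from a diffuse
  component (sd $= \Delta$) around the centroid, 70% from a randomly
  chosen cluster at twice the marker dispersion — mimicking true
  organelle residents missing from the curated list plus genuinely
  multi-localised or soluble proteins. These proportions are aesthetic
  stand-ins for "unknowns blanket the marker clouds"; QSep never reads
  the unknowns, so they only exercise annotation handling and plotting.
* independent Bernoulli missingness (default rate 0 in the constructor;
  tests use 5–20%), and optional row normalisation to emulate
  relative-occupancy scaling.

Defaults (`k = 5`, `p = 10`, 30 markers per cluster) mirror a mid-sized
LOPIT design: ~10–20 fractions, ~10 niches, tens of markers each.

Ground truth supports closed-form checks: within a cluster, the pairwise
distance is $\sigma\sqrt{2}$ times a $\chi_p$ variable, with mean
$2\sigma\,\Gamma((p{+}1)/2)/\Gamma(p/2)$, so at large $\Delta$ the
normalised entries approach $\Delta$ divided by that quantity. The test
suite checks the empirical within mean against this formula, the
monotone response of the median to $\Delta$, the $\Delta/\sigma$ scaling
and the $\Delta = 0$ limit (median near 1).

What the generator does **not** emulate: density-gradient biochemistry
(profiles are not unimodal curves along the gradient), isobaric-tag ratio
compression, correlated or abundance-dependent missingness, or
anisotropic clusters. A green synthetic suite therefore establishes the
*arithmetic* of the metric and its stated invariances — not that QSep
ranks real instruments or protocols correctly. The four paper-data
acceptance tests retain that burden; they require the published datasets'
flat exports, which cannot be shipped inside this source tree (size and
redistribution) and so fail in offline environments by design rather
than being skipped.

# Numerical and degenerate-input policy

* A cluster whose markers share one profile has within distance 0;
  normalisation refuses it by name rather than emitting `Inf`.
* PCA: fractions are mean-centred, not variance-scaled (the quantitation
  scale is meaningful; a `scale` flag exposes the alternative). Component
  signs are fixed by making each component's largest-magnitude loading
  positive, so projections and regression tests are platform-stable.
  Constant matrices are rejected. Variance fractions are always relative
  to the *total* variance, so retained-component fractions sum to ≤ 1.
* The vectorised pairwise-distance kernel clips tiny negative
  sums-of-squares arising from floating-point cancellation to 0 before
  the square root; the suite pins it against a scalar longhand oracle at
  `1e-10`.
* Text round trip: profile matrices are written with 17 significant
  digits so that write-then-read reproduces doubles exactly; empty cells
  encode missingness. Recognised missing tokens on input: empty, `NA`,
  `NaN` (case-insensitive).
* Replicate combining joins on the protein-identifier intersection and
  concatenates fraction columns with `.repN` suffixes — the only join
  that keeps every retained profile complete. No alignment of unequal
  fraction designs is attempted; columns are concatenated as given.

# Known limitations

* QSep is defined on Euclidean distance only; correlation or Mahalanobis
  variants are out of scope.
* The score is relative to the marker annotation: poor or self-serving
  curation moves it (the marker-transfer tooling exists precisely to
  probe this), so scores should be read alongside the logged context —
  cluster count, marker counts, missingness — not as an absolute.
* Scores are comparable across experiments only under comparable
  quantitation conventions; the package applies no normalisation of the
  input profiles.
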