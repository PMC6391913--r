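# qsep — quantifying sub-cellular resolution in spatial proteomics

Spatial proteomics experiments (LOPIT, hyperLOPIT, protein correlation
profiling, dynamic organellar maps, …) separate a cell's contents along a
biochemical gradient and quantify each protein's relative occupancy across
the collected fractions. Proteins resident in the same organelle share
similar occupancy profiles, so the *resolution* of an experiment — how
cleanly the sub-cellular niches separate — determines how much the derived
localisation calls can be trusted. Visual inspection of PCA projections is
the traditional check, but it is qualitative and hard to compare across
experiments.

This package implements **QSep**, a simple quantitative resolution metric,
for data producers who want to optimise a fractionation protocol and data
consumers who want to judge a published map.

## The metric

Given curated marker proteins for *k* sub-cellular clusters, compute the
average Euclidean distance between the full *p*-dimensional occupancy
profiles

* **within** each cluster *i* (diagonal entries *d(i,i)* — cluster
  tightness), and
* **between** each pair of clusters (*d(i,j)* — cluster separation),

then normalise each row by the reference cluster's within distance:

```
qsep(i, j) = d(i, j) / d(i, i)
```

The diagonal becomes 1 and the matrix is no longer symmetric: entry
*(i, j)* says how many times further cluster *j* lies than cluster *i* is
wide. Tight, distant clusters — good resolution — give large normalised
distances. The experiment-wide **median** of the k(k−1) off-diagonal
entries is the headline summary used to rank experiments.

Conventions that matter (and match the reference ecosystem):

* Distances use the raw quantitation values; missing values are retained,
  not imputed. A pair observed in only *m* of *p* fractions contributes
  `sqrt(p/m * sum_complete (x_f - y_f)^2)`; pairs with no overlap are
  dropped from the averages.
* Zero-imputation is applied **only** for PCA and plotting.
* Clusters need at least 7 markers (configurable) to be scored.

## Worked example

```r
library(qsep)

## a synthetic experiment with known ground truth: 4 Gaussian marker
## clusters (12 markers each) separated by delta = 1 with dispersion
## sigma = 0.08 in 10 fractions, 40 unannotated proteins, 5% missingness
truth <- synthetic_truth(k = 4, p = 10, n_per_cluster = 12, n_unknown = 40,
                         delta = 1, sigma = 0.08, missing_rate = 0.05,
                         seed = 7)
exp <- generate_experiment(truth)
exp
#> ProfileExperiment: 88 proteins x 10 fractions
#>   missing values: 6.6%
#>   markers ('markers'): 4 clusters, 48 marker proteins

res <- qsep_score(exp, min_markers = 7)
round(res$raw$values, 3)     # raw: within on the diagonal, symmetric
#>       C01   C02   C03   C04
#> C01 0.373 1.089 1.101 1.088
#> C02 1.089 0.341 1.144 1.012
#> C03 1.101 1.144 0.345 0.979
#> C04 1.088 1.012 0.979 0.336

round(res$qsep$values, 2)    # normalised: diagonal 1, asymmetric
#>      C01  C02  C03  C04
#> C01 1.00 2.92 2.96 2.92
#> C02 3.19 1.00 3.35 2.97
#> C03 3.19 3.31 1.00 2.83
#> C04 3.24 3.01 2.91 1.00

res$summary
#> QSepSummary: 4 clusters, median between = 2.990
```

Every between-cluster distance is about 3 cluster-widths: the clusters are
well separated relative to their tightness (the dialled-in Δ/σ ratio
predicts ≈ Δ / (2σΓ(5.5)/Γ(5)) ≈ 2.9). The summary is robust to which
clusters are annotated:

```r
scan <- class_removal_scan(exp, max_removed = 2)
scan
#> RemovalScanResult: 11 records (up to 2 removed), baseline median 2.990, slope 0.0392
```

and tracks the true separation monotonically:

```r
separation_sweep(truth, c(0.2, 0.5, 1, 2))
#>   delta median_between
#> 1   0.2       1.184524
#> 2   0.5       1.769258
#> 3   1.0       2.989598
#> 4   2.0       5.639624
```

Diagnostic plots (PCA with transparency or hexagonal density binning,
annotated marker plots, per-cluster profile lines, cluster dendrograms,
QSep heatmaps/boxplots):

```r
pc <- pca_project(exp)
plot_pca(pc, markers(exp), style = "annotated", file = "pca.png")
plot_qsep(res$raw, res$qsep, file_prefix = "qsep_fig")
```

## Command line

```sh
qsep simulate --k 5 --p 10 --n 30 --delta 1 --sigma 0.1 --missing 0.1 \
    --seed 42 --out sim.tsv
qsep compute --input sim.tsv --markers-col markers --min-markers 7 --out out
qsep transfer --source a.tsv --target b.tsv --markers-col markers --out tr
qsep robustness --input sim.tsv --markers-col markers --out rob
qsep compare --input a.tsv --input2 b.tsv --markers-col markers --out cmp
```

(the `qsep` launcher is installed under `exec/`; equivalently call
`qsep::qsep_cli(c("compute", ...))` from R). Input is delimited text —
one identifier column, numeric fraction columns, and a marker column
whose empty cells mean "unknown". Exit code 0 on success, 2 on
input/validation errors.

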