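# mcopa

Outlier-centred analysis of cancer expression data.

Tumours of one cancer type are often heterogeneous: a transcript may be
extremely over- or under-expressed in only a handful of samples, which
mean-based statistics (differential expression, variance ranking) average
away. `mcopa` finds exactly those features in a normalised expression
matrix — per-sample, per-feature outlier calls with feature-specific
thresholds, in both directions — and turns them into outlier profiles,
subtype-specific feature lists and per-sample outlier lists for downstream
work (clustering, pathway analysis, tumour-suppressor hunting). It is aimed
at anyone analysing a feature-by-sample expression matrix with a control
group and a case group: bulk microarray or RNA-seq after normalisation,
and in principle any log-scale assay with two conditions.

## Method

Given a log2-scale matrix *x* with features *f* in rows, the first *n*
columns normal samples and the rest tumour samples:

1. **Robust standardisation (COPA transform).** For each feature,
   *y_fs* = (*x_fs* − med_f) / *s_f*, where med_f is the median over **all**
   samples and *s_f* a robust scale — by default the mean absolute deviation
   from the median (the median absolute deviation is available). Unlike
   z-scores, the denominator is not inflated by the very outliers being
   sought.
2. **Feature-specific fences.** From the **tumour** samples' transformed
   values: upper fence = Q75 + 1.5·IQR, lower fence = Q25 − 1.5·IQR
   (Tukey's rule; quantiles use the median-unbiased interpolation rule,
   type 8, by default). Every sample — normal or tumour — strictly beyond a
   fence is an outlier for that feature (over-expressed: code 1,
   under-expressed: code −1).
3. **Three retention criteria**, per direction: the feature must be
   (1) an outlier in at least one tumour sample, (2) an outlier of that
   direction in **no** normal sample, and (3) separated between groups:
   the nominated tumour and normal percentiles (default 90th for up, 10th
   for down, computed on the transformed scores) must differ by more
   than 2.

Retained features are reported with the tumour samples in which they are
outliers, and merged into a profile matrix of codes in {1, −1, 0}.

The package also ships the surrounding benchmark harness — an adjusted Rand
index (ARI) implementation, variance / COPA-rank / Welch-t+BH selectors,
seeded k-means (MacQueen, best of 20 starts) and PAM clustering — plus a
synthetic-data generator with planted ground truth, so the whole pipeline
is testable end to end without downloading any dataset.

## Worked example

```r
library(mcopa)
sim <- generate_expression(simulation_config(n_features = 1000, seed = 42))
res <- run_mcopa(sim$matrix)
res
#> mcopa_result: 49 up-regulated and 52 down-regulated outlier features
#>   profile: 101 features x 30 samples
#>   params: upper 90 / lower 10 percentile, estimator type 8, scale meanad, c3 on transformed scale

head(res$up[, c("feature_id", "outlier_sample_ids", "n_tumour_outliers")], 3)
#>   feature_id outlier_sample_ids n_tumour_outliers
#> 1     F00001            T06,T10                 2
#> 2     F00002            T15,T18                 2
#> 3     F00004            T13,T20                 2

score_recovery(sim$truth, res$up, res$down)
#>   direction   level precision recall n_true n_called
#> 1        up feature     0.959   0.94     50       49
#> 2        up    call     0.949   0.94    100       99
#> 3      down feature     0.923   0.96     50       52
#> 4      down    call     0.950   0.96    100      101
```

The simulated matrix plants 100 outlier features (Δ = 4 log2 units in 2 of
20 tumour samples each, noise SD 0.5) among 900 background/DE/noise
features; the run recovers them at ~94–96% precision and recall, and the
recovered features are outliers in almost exactly the planted samples. The
sharing histogram (`sharing_histogram(res$profile, tumour_samples(sim$matrix))`)
shows nearly all features shared by ≤ 2 tumour samples — outliers mark
individual tumours, not the cohort.

A command-line wrapper covers the same pipeline
(`inst/cli/mcopa run --matrix matrix.tsv --n-normal 10`, plus `simulate`,
`subtype`, `profiles` and `evaluate` subcommands); input is tab-separated
text with feature IDs in the first column and normal samples in the first
*n* data columns.

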