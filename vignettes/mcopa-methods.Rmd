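---
title: "Outlier profile analysis: model, parameters and design choices"
author: "mcopa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier profile analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcopa)
```

## The problem and the model

Differential expression asks "which features differ *on average* between
groups"; variance ranking asks "which features vary *overall*". Neither
sees a transcript that is extreme in two tumours out of twenty and
unremarkable elsewhere — yet such minority events (gene fusions, focal
amplifications, silenced tumour suppressors) are exactly what makes
individual tumours differ within a cancer type. `mcopa` targets them
directly.

The pipeline makes three statistical moves, each with a specific
assumption behind it:

1. **Robust per-feature standardisation.** Each feature is centred at its
   median across *all* samples and divided by a robust deviation. The
   median and robust scale are chosen so that the minority of extreme
   values being sought does not contaminate the location/scale estimates
   the way a mean/SD z-score would. The assumption is that a feature's
   bulk behaviour (normals plus most tumours) defines "normal expression"
   and that outliers are a minority — as a rule of thumb, fewer than a
   quarter of the tumour samples (see "breakdown" below).
2. **Feature-specific fences.** Outlier thresholds are Tukey fences
   (Q75 + 1.5·IQR, Q25 − 1.5·IQR) computed per feature from the *tumour*
   samples' transformed values and applied to every sample. Feature-specific
   fences adapt to each feature's own spread — a flat threshold on the
   transformed score would treat tight and noisy features identically.
   Computing them from tumours only makes the tumour group's own spread
   the reference; normals beyond a fence are detected too, and used by the
   filter below.
3. **Three retention criteria** per direction (up/down): at least one
   tumour outlier; no same-direction outlier among normals (an
   opposite-direction normal outlier is allowed); and a minimum separation
   between the nominated tumour and normal percentiles. The first two
   encode the biological contrast (tumour-specific events); the third
   removes features whose "outliers" ride on a tiny overall spread.

Everything downstream — profiles over {1, −1, 0}, subtype-exclusive
extraction, per-sample outlier lists, sharing histograms — is bookkeeping
over the retained calls, useful because outliers are properties of
*samples*, not only of features.

### Breakdown of the fences

The fences come from the tumour quartiles, so the method has a built-in
breakdown point: once planted/real extreme values occupy roughly a quarter
of the tumour samples, they enter Q75 (or Q25) themselves, the IQR
inflates, and the very signal sought stops being called. This is by
design — an event present in half the tumours is subtype marker territory,
which differential expression handles better. The synthetic benchmark
below keeps planted events at 10–20% of tumours for this reason.

## Tunable parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `upper_percentile`, `lower_percentile` | 90, 10 | percent | nominated percentiles of the separation filter (and the COPA-rank comparator) |
| `fence_multiplier` | 1.5 | IQR multiples | Tukey fence width; 1.5 is the classical "outlier", 3 would be "far out" |
| `fc_threshold` | 2 | transformed-score units (log2-fold-change-derived) | minimum tumour–normal percentile separation |
| `estimator` | 8 | Hyndman–Fan type 1–9 | quantile interpolation rule, used for every percentile in the pipeline |
| `scale_mode` | `"meanad"` | — | robust scale of the transform; `"mad"` available |
| `c3_scale` | `"transformed"` | — | scale on which the separation filter compares percentiles; `"raw"` available |

Three of these deserve their own sections, because the method's behaviour
hinges on them and the design space was genuinely open.

### Which robust scale

Both the mean absolute deviation from the median (`meanad`) and the median
absolute deviation (`mad`, un-normalised) are implemented. The outlier
*calls* are identical under either: fences are affine functions of the
transformed values, so a per-feature rescaling cancels out of every
comparison. What changes is the *unit* of the transformed score, and with
it the meaning of the fixed separation threshold: for Gaussian noise of SD
σ the mean-AD is 0.798σ and the (un-normalised) MAD 0.675σ, so a threshold
of 2 corresponds to 1.60σ under `meanad` but only 1.35σ under `mad` — the
MAD unit systematically loosens the filter by ~18%. The threshold of 2 is
calibrated against the mean-AD-scaled transform, which is also how the
transform is classically defined, so `meanad` is the default. On the
package's own planted-recovery benchmark (below) the default achieves
feature-level precision ≈ 0.94 at recall ≈ 0.96, versus precision ≈ 0.72 at
comparable recall under `mad` — consistent with the calibration argument.

### On which scale the separation filter operates

The nominated percentiles entering criterion 3 are computed from the
transformed scores (`c3_scale = "transformed"`, the default), not from the
raw expression values. The raw-scale alternative (`"raw"`, provided) reads
the criterion as a plain log2-fold-change of percentile values and is
attractive for interpretability, but it makes the criterion blind to each
feature's own spread and — more practically — it is too strict for sparse
outliers: with two affected samples among twenty tumours, the 90th
percentile interpolates between the top background value and the first
outlier, and the raw separation hovers around the threshold no matter how
large the planted effect, so recall collapses (≈ 0.50 on the benchmark,
versus ≈ 0.96 on the transformed scale). On the transformed scale the
separation is measured in units of the feature's robust spread, which is
the same normalisation the calls themselves use. Both modes are exposed;
tables record the percentile values actually used.

### Which quantile estimator

All nine classical interpolation rules are available; the default is the
median-unbiased rule (type 8), the general-purpose recommendation of the
quantile-estimation literature, and one rule is used consistently for
quartiles, fences and nominated percentiles. The choice moves fences by
fractions of an order statistic and matters only at small sample counts;
what matters more is consistency, so mixing rules across pipeline stages
is deliberately not supported.

## Numerical conventions and degenerate inputs

* Fence comparisons are strict (`>`, `<`): a value exactly on a fence is
  not an outlier.
* Features with zero robust scale (e.g. constants) are flagged degenerate;
  features with zero tumour IQR would have zero-width fences that call any
  deviation an outlier, so both classes are excluded from calling, with a
  message.
* Missing data: features, then samples, with more than 40% missing entries
  are dropped (one pass each, features first — the order the counts are
  reported in); remaining holes are filled by k-nearest-neighbour
  averaging over features (k = 10 by default). The distance is the RMS
  difference over the samples observed in both features, so sharing fewer
  samples does not make features artificially close; neighbours must be
  observed in the target column; distance ties break by feature order, so
  imputation is deterministic.
* ARI with a degenerate denominator (both partitions all-in-one or
  all-singletons) is defined as 1 when the partitions are identical and 0
  otherwise.
* Welch t-statistics with zero pooled variance return p = 1 when the group
  means are equal and p = 0 otherwise.
* The k-means harness seeds and keeps the best of `n_repeats` MacQueen
  starts by total within-cluster sum of squares; PAM is deterministic.
  Distances are Euclidean on the selected-feature submatrix with no
  further scaling — the matrix is assumed already normalised, and the
  transform would erase the magnitude differences the selectors rank on.
  The number of clusters is supplied by the caller (typically the number
  of annotated subtypes); automatic model selection is out of scope, and
  externally produced partitions can be scored directly with
  `adjusted_rand_index()`.

## The synthetic-data generator

`generate_expression()` emulates the data regime the method targets: a
log2-scale matrix with per-feature baselines ~ N(8, 1.5²), Gaussian
measurement noise (SD 0.5), and four planted classes — outlier features
(± 4 log2 units in `max(1, round(0.1 × n_tumour))` tumour samples each,
optionally confined to one subtype), classical DE features (± 1 in all
tumours), high-variance noise features (4–6× noise SD, no structure) and
background. Normal samples are pure background, matching the filter's
assumption that normals are outlier-free for retained features. Seeding is
per-feature (substreams derived from the master seed by feature index), so
enlarging a simulation leaves existing features bit-identical.

What it deliberately does **not** emulate: batch effects, probe
cross-hybridisation, heavy-tailed or skewed noise, correlated features,
missingness mechanisms beyond random holes, and intensity-dependent
variance. Green tests on this generator therefore demonstrate the
*arithmetic and logic* of the pipeline and its behaviour under the stated
Gaussian regime — not robustness to real-array artefacts, which should be
assessed on real data.

Default problem sizes were chosen once as representative desk-scale
conditions: 2000 features × (10 normal + 20 tumour) samples for recovery
benchmarks (20 seeded replicates), and 5000 features with two subtypes of
10 for the feature-selection comparison (planted subtype-specific outliers
in 4 of 10 subtype samples — 20% of tumours, below the fence breakdown
point; 200 noise features at 6× SD give the variance selector its natural
prey). With those conditions the package's acceptance suite checks: mean
feature-level precision and recall ≥ 0.9; false-positive feature rate
≤ 1% when nothing is planted; and k-means ARI from outlier-selected
features beating top-variance features in at least 15 of 20 replicates.

## The evaluation harness

The comparators mirror common practice: top-1000 variance ranking; the
original COPA ranking (nominated percentile of transformed tumour scores,
over-expression only, sized to match the outlier selection); and a
differential-expression selector. The DE selector is intentionally a plain
Welch-t + Benjamini–Hochberg procedure, labelled as such in its output —
no variance moderation — because its role here is relative benchmarking of
*selection strategies*, not state-of-the-art DE inference. Kruskal–Wallis
(rank-based, tie-corrected) compares ARI score groups without normality
assumptions.

## Known limitations

* Tumour sample counts below ~10 make the tumour quartiles, and hence the
  fences, noisy; the percentile-separation filter then does most of the
  work.
* The method is univariate per feature: coordinated but individually
  modest shifts across a pathway are invisible.
* Multiplicity is controlled only implicitly (criteria 2–3); retained
  features are candidates for inspection, not hypothesis-tested
  discoveries.
* PAM on minority-event signal is structurally handicapped (within-group
  distances stay large when group members share few active features);
  k-means with multiple starts is the more appropriate clusterer for
  outlier-selected features, and the benchmark criterion uses it.
* The subtype benchmark's "variance selects 1000 features" convention
  follows common practice but makes its dilution depend on matrix size;
  the harness exposes `variance_k` for sensitivity analyses.
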