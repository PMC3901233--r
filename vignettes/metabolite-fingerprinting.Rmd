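---
title: "Metabolite fingerprinting: models, conventions and design choices"
author: "metabofp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite fingerprinting: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabofp)
```

`metabofp` analyses metabolite fingerprinting experiments in which several
accessions of one plant species are profiled across organs on a mix of
targeted and non-targeted mass-spectrometry platforms. This vignette is the
package's own account of the science it implements: the statistic at its
core, the generative model behind the synthetic data, every convention that
was a genuine design choice, and the limits of what a green test establishes.

## 1. The data model

A dataset is a features x samples matrix of non-negative relative abundances
plus two annotation tables. Two kinds of "no value" are deliberately kept
apart:

* **zero** — the platform measured this feature in this sample and detected
  nothing. Zeros are real data: they enter rank correlations, group means
  and the distance statistic.
* **missing (`NA`, an empty CSV cell)** — the feature was not measured for
  this sample at all, e.g. it belongs to a platform block that was not run.
  Missing entries are removed pairwise everywhere.

The distinction matters because targeted and non-targeted platforms are
combined in one matrix; collapsing "not measured" into "not detected" would
bias every downstream statistic. The file format is plain UTF-8 CSV with
"." decimals and the empty cell as the missing marker; numerics are written
with 17 significant digits so a write/read cycle reproduces every double
bit-for-bit.

All matrices are keyed by `feature_id` / `sample_id` at every API boundary;
nothing is matched by position, which prevents silent misalignment between
matrix and metadata.

## 2. The weighted Manhattan dissimilarity

For samples $i, j$ with abundances $Y_{ki}, Y_{kj}$,

$$D_{ij} = \frac{1}{K^*} \sum_{k:\; Y_{ki}+Y_{kj}>0}
  \frac{|Y_{ki} - Y_{kj}|}{\sqrt{Y_{ki}^2 + Y_{kj}^2}},$$

where $K^*$ counts the metabolites present in at least one of the two
samples (after pairwise removal of missing entries). The denominator
$\sqrt{Y_{ki}^2+Y_{kj}^2}$ estimates the standard deviation of the abundance
difference, which gives the statistic its three defining properties, all of
which are enforced by tests:

* every per-metabolite term lies in $[0,1]$, so each metabolite contributes
  equally irrespective of the magnitude of its abundance;
* $D(c\,y_i, c\,y_j) = D(y_i, y_j)$ for any common factor $c>0$ — peak
  areas, relative abundances and concentrations give identical distances;
* $D = 0$ exactly for identical profiles and $D = 1$ exactly for samples
  with completely disjoint constituents.

**Normalization choice.** The published sources that use this statistic
state its range and the two boundary values but the normalization itself had
to be pinned down from those properties. Averaging over all $K$ metabolites
would dilute $D$ below 1 whenever some metabolites are absent from both
samples, so the boundary value forces the $1/K^*$ form with both-zero
metabolites excluded. A `strict = TRUE` mode dividing by all
pairwise-complete metabolites is provided for comparison; it is not the
default and reaches 1 only when no metabolite is absent from both samples.

**Caveat against over-claiming.** Invariance holds for a *common* rescaling
of both profiles. Rescaling a single sample (e.g. an uncorrected injection
volume) changes $D$; a test documents this deliberately. The per-sample
scale factors of the simulator exist precisely to exercise this: $D$ is
robust to them in practice but not invariant.

Pairs for which no metabolite is present in either sample have no defined
distance; the scalar function raises a structured error, and the matrix
builder records `NA` with a warning rather than inventing a value.

## 3. Differential abundance

The volcano surface is the classic pair: per feature, the log2 ratio of
group means against a two-sided p-value.

* **Welch, not Student.** Only "a t-test" is conventional for these
  comparisons; unequal-variance Welch with Satterthwaite degrees of freedom
  is the robust default for small MS replicate groups and is what the
  package uses. Two degenerate cases get explicit conventions: both groups
  constant and equal gives $t=0, p=1$; both constant and unequal is an
  error, since the difference is real but its variance inestimable.
* **Pseudocount.** Ratios of means are made finite by an additive constant
  $c$, defaulting to half the smallest positive value in the dataset. A
  data-scaled pseudocount keeps log-ratios finite *and* preserves the
  scale-consistency of the ratio axis; it is configurable for users who
  prefer a fixed constant.
* **Raw p by default.** The volcano y axis is the raw p-value (plus a
  $-\log_{10} p$ column); Benjamini–Hochberg q-values are available via
  `adjust = TRUE` but off by default, matching the conventional
  presentation of such plots.
* **Both ratio and log-ratio** columns are exported, since either axis
  convention is in use; log base 2 is used and labelled wherever a log is
  taken.

Ratio panels (one organ contrast per accession) and all-pairs accession
fingerprints (all organs pooled, each accession in turn as denominator)
share a single metabolite ordering so the panels are comparable row by row.
The ordering rule — platform, then chemical class (unclassified last), then
mean log-ratio across panels, ties broken by feature id — is a package
convention; published panel figures fix an order without stating its rule,
so the chosen rule is deterministic and is emitted with every result.
Panel outputs are exactly invariant to the input sample order (accessions
and replicate ids are sorted internally before averaging).

## 4. Replicate quality control

Replicate agreement is assessed by pairwise Spearman rank correlation within
each accession x organ x stage cell. Average ranks handle ties; missing
values are removed pairwise; fewer than three complete pairs or zero rank
variance raise structured errors rather than returning `NA` silently. Zeros
are retained in the ranking — a shared non-detect is genuine agreement.
Replicates whose median correlation to their co-replicates falls below a
threshold are flagged; the default of 0.7 is a configurable convention of
this package, not a published cutoff.

## 5. Ordination and clustering

* **Classical (Torgerson) scaling**, i.e. double-centering plus
  eigendecomposition, implements the "best two-dimensional approximation"
  of the distance matrix. "Best" is ambiguous between classical scaling and
  iterative stress majorization; classical scaling is chosen because it is
  deterministic, closed-form and exactly testable (it reconstructs planar
  Euclidean configurations to numerical precision, verified at Procrustes
  RMSE < 1e-6). Negative eigenvalues — expected, since the weighted
  Manhattan dissimilarity is not Euclidean — are reported, and their axes
  dropped, rather than hidden.
* **Max-standardization** divides each metabolite by its maximum over the
  selected samples, mapping it onto $[0,1]$. The published description of
  this step ("the maximum abundance of that metabolite in each sample") is
  internally contradictory — a per-sample maximum of a single metabolite is
  the value itself; the per-metabolite reading is the one consistent with
  "standardized abundances" and is what the package implements. The
  operation is idempotent and all-zero metabolites are dropped with a
  warning.
* **K-means** (best of `n_init` seeded starts) and **agglomerative
  hierarchical clustering** both operate on the standardized matrix;
  hierarchical clustering defaults to average linkage on Euclidean
  distances because no linkage is conventionally stated for this analysis.
  `k` is always user-supplied: the three accession groups of the motivating
  design are a finding, not a model-selection rule.
* **Adjusted Rand index** is the recovery metric, computed from the
  contingency-table closed form and cross-checked in tests against an
  independent implementation.

## 6. The synthetic-data generator

No public desk-scale dataset accompanies the motivating design, so the
package ships a generator whose defaults *are* the stated world of that
design, and every analysis stage is validated by recovery against its
planted truth.

Abundances follow a log-normal model with additive log-scale effects:

$$Y_{kj} = s_j \exp\!\big(\mu_k + \alpha_{g(a_j),k} + \beta_{o_j,k} +
  \varepsilon_{kj}\big)\cdot \mathrm{present}_{k,g(a_j),o_j}$$

with per-feature baselines $\mu_k$, accession-group effects $\alpha$, organ
effects $\beta$, replicate noise $\varepsilon$, per-sample scale factors
$s_j$, and a Bernoulli presence mask drawn once per feature x
accession-group x organ cell.

Fixed design facts of the preset (`prunella_preset()`): 5 accessions in 3
provenance groups (three North American accessions co-generated, one North
American outlier, one Georgian accession — the 3/1/1 structure of the
motivating study), 5 organs, platform blocks of 21 + 119 + 83 + 222 = 445
features. Five replicates per accession x organ is an inference from the
25-sample single-organ analyses of the motivating study (25 = 5 accessions
x 5 replicates), not a stated fact.

Chosen defaults (all on the natural-log scale; set once on scientific
grounds, not tuned to tests):

| parameter | default | rationale |
|---|---|---|
| `baseline_log_mean` | 7 | arbitrary abundance unit, median ~1100 |
| `baseline_log_sd` | 1.5 | metabolite abundances span orders of magnitude |
| `group_effect_sd` | 1.0 | strong accession differentiation (~e-fold), the regime in which fingerprinting is claimed to work |
| `organ_effect_sd` | 1.0 | organs differ as strongly as accessions |
| `replicate_cv` | 0.2 | ~20% technical noise, typical of MS platforms; gives the 5x group-to-noise separation of the clustering benchmark |
| `dropout_prob` | 0.1 | occasional constituent absence; applied per group x organ cell, not per replicate, so disjoint fingerprints (D = 1) are reachable |
| `scale_factor_range` | [0.8, 1.25] | ±25% per-sample loading variation, exercising the near-invariance of D |

The null/power generator (`null_two_group_dataset()`, `two_group_dataset()`)
uses `sdlog = 0.25` so that a t-test on raw (untransformed) log-normal
abundances with five replicates per group is close to nominal — mirroring
practice, where volcano t-tests are run on relative abundances as measured.

All randomness flows through a single explicit seed; the caller's RNG state
is saved and restored, and the same seed yields a byte-identical dataset.

**What the generator does not emulate:** chromatographic reality (retention
drift, co-elution, adducts, isotopes), heteroscedastic detector noise,
correlated metabolite blocks from shared pathways, batch effects, and
missingness from platform mixing (the preset measures every feature in
every sample). A green recovery test therefore establishes that the
pipeline's statistics behave as designed under the stated model — not that
any real pair of accessions is distinguishable.

## 7. Numerical conventions and degenerate inputs

* Distance bounds and oracle equivalence are asserted at 1e-12; MDS planar
  recovery at Procrustes RMSE 1e-6; ratio-panel antisymmetry is exact by
  construction (a difference of two log values).
* Degenerate designs (zero features or samples), singleton replicate
  groups, empty selections, overlapping volcano groups, all-zero features,
  undefined distances and constant-variance tests all have explicit,
  classed error conditions (`mfp_*`), so callers and tests can discriminate
  failure modes without string matching.
* `validate_dataset()` never throws: it returns the full violation list
  (duplicates, orphan keys, negatives, out-of-range annotations) and
  readers fail with that list attached.

## 8. The pipeline driver

`run_pipeline()` wires simulate/read → validate → qc → volcano → ratio
panels → distance (on a configurable organ x platform slice, by default the
surface lipids of the vegetative organs of shoots) → MDS → clustering.
Configuration is a named list or JSON file (JSON rather than YAML because
the deployment environment carries no YAML parser); unknown or invalid keys
are collected into a single schema error. Every artifact is plain CSV/JSON,
nothing is timestamped, and `manifest.json` records the package version,
seed, full configuration and the md5 of every output — identical
configurations produce byte-identical artifact directories, so any output
is reproducible from the manifest alone.

## 9. Known limitations

* Classical scaling of a non-Euclidean dissimilarity discards the variance
  carried by negative eigenvalues; the eigenvalue spectrum is reported so
  users can judge the two-dimensional approximation.
* The volcano t-test operates on raw abundances; heavy-tailed noise will
  make it conservative. No moderated/shrinkage statistics are provided.
* The outlier-flagging threshold, the panel ordering rule and the
  hierarchical linkage default are package conventions, clearly labelled as
  such, not published prescriptions.
* No raw spectral processing: the package starts from a peak-area matrix.
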