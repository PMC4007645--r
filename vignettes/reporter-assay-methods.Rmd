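---
title: "Methods: analysing plasma transcriptomic reporter assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing plasma transcriptomic reporter assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmnreporter)
```

## The assay and the analysis problem

A transcriptomic reporter assay measures the immunomodulatory content of
patient plasma indirectly: leukocytes from a healthy donor — neutrophils
(PMNs) are the reporter of choice for sepsis — are cultured for a few hours
with 20% patient plasma or with medium alone, and the reporter cells'
genome-wide transcriptional response is read out on bead arrays. The
scientific claims this package operationalises are that (i) the *amplitude*
of the PMN response tracks sepsis severity, and (ii) a small transcript
panel selected from the response discriminates severe from non-severe
sepsis in an independent patient cohort.

The pipeline has five analysis stages, each exposed as ordinary functions
and composed by `run_pipeline()`:

1. **Preprocessing** (`run_preprocess()`): quantile normalization within
   each (cell type, batch) culture experiment; intensity flooring at 10;
   the PALO detection filter ("present in at least one sample": detection
   p ≤ 0.01 in ≥ 1 sample, boundary inclusive); per-probe fold change and
   intensity difference against the mean of the same stratum's medium-alone
   cultures; and the 2FC100DIF differential filter (|log2 fc| ≥ 1 **and**
   |difference| ≥ 100 in at least one stimulated sample, both boundaries
   inclusive, down-regulation counted through absolute values).
2. **Response metrics** (`run_pca()`, `distance_to_reference()`): PCA of
   the log2 fold-changes (samples as observations, mean-centred, unscaled),
   then each sample's Euclidean distance from the centroid of the
   uninfected-plasma samples over the first two components — the amplitude
   statistic. Group differences are tested with the Mann–Whitney U-test.
3. **Clustering** (`hierarchical_cluster()`, `cut_clusters()`): complete
   linkage on Euclidean distances between transcript profiles, cut into a
   configurable number of clusters (default 12) and exported as plain
   gene lists for external enrichment tools.
4. **Marker selection** (`geometric_backward_elimination()`): random
   k-nearest-neighbour feature selection (RKNN-FS). An ensemble of kNN
   classifiers (k = 5), each on a random feature subset, scores every
   transcript by *support* — the mean leave-one-out accuracy of the base
   models containing it; the worst-supported fifth of the features is
   dropped and the procedure repeats. The winning stage is the one with
   the highest mean base accuracy among stages that can still supply a
   full panel, and its top 30 transcripts by support form the severity
   panel.
5. **Evaluation** (`evaluate_severity_panel()`): an RBF-kernel SVM and a
   500-tree random forest are trained on the training cohort only
   (features standardised with training statistics only) and scored on an
   independently collected cohort, one-vs-rest for the severe and
   not-severe classes, with ROC curves, AUC, and stratified-bootstrap
   percentile confidence intervals.

## Statistical conventions

* **Mann–Whitney U**: `U` counts (x, y) pairs with x > y plus half the
  ties (the `wilcox.test` convention). The p-value is exact for pooled
  n ≤ 12 without ties, otherwise a normal approximation with tie and
  continuity corrections; a perfectly centred U reports p = 1 by symmetry.
  Two-sided throughout, since the source analyses do not state sidedness.
* **AUC** is the trapezoidal area under the tie-grouped ROC curve, which
  equals (concordant pairs + half ties) / (n₁n₀) and hence U/(n₁n₀) —
  an identity the test suite checks to 10⁻¹².
* **Confidence intervals** for the AUC use a stratified percentile
  bootstrap (resampling within each class; 2,000 replicates by default),
  chosen because it is assumption-light and its coverage can itself be
  verified by simulation (the test suite requires ≥ 88% empirical coverage
  at nominal 95%).
* **PCA signs** are arbitrary; each component is oriented so its
  largest-magnitude loading is positive, making runs comparable.
* **Determinism**: every stochastic stage derives its seed from the run's
  single master seed keyed by the stage name (`stage_seed()`), so a full
  pipeline run is byte-reproducible and re-running one stage does not
  perturb the others. All kNN tie rules (distance ties to the smaller
  training index, vote ties to the nearest neighbour's class) are
  deterministic.

## The synthetic-data generator

Real deposits of this assay class cannot ship with a package, so the
generator (`generate_bundle()`) emulates the statistical structure the
analysis assumes, with known ground truth. The model is log-normal with
additive log2 effects:

* each expressed probe has a log2 baseline `b_g ~ N(7, 1.5)` (a typical
  bead-array intensity scale); 30% of probes are unexpressed, sit near the
  floor (`N(3, 0.5)`), and carry detection p-values above the PALO cutoff
  in every sample;
* a medium-control sample measures `b_g + batch_t + ε`, `ε ~ N(0, 0.25)`;
* a plasma-stimulated sample adds `δ_g · A_s` on the responsive probes,
  where the sample's response amplitude `A_s ~ N(a_group, 0.75)` with
  group means 0.2 (uninfected), 1.0 (not severe) and 2.5 (severe);
* marker probes add a severe-specific contrast `δ'_g` (severe samples
  only), oriented along the probe's own response direction — a cancelling
  orientation would make a marker separate severe from not-severe *less*
  than amplitude alone, defeating its definition;
* samples collected more than 48 h after admission have `A_s` multiplied
  by 0.15, emulating the resolution of the plasma response after treatment
  begins.

Effect-size scales were chosen to be realistic for this assay class and to
keep the planted structure recoverable, which is part of the generator's
contract: `|δ| ~ N(0.6, 0.2)` log2 per amplitude unit (i.e. 2–3-fold
changes at severe amplitudes, with 55% of responsive probes up-regulated)
and `|δ'| ~ N(1.0, 0.2)`. Substantially larger effects (several log2
units) are not only unrealistic — they push responding probes into the
extreme upper ranks of each array, where quantile normalization clamps
magnitudes to the reference tail and erases the very contrasts the
analysis must detect. The amplitude spread 0.75 makes not-severe samples
overlap uninfected controls while severe samples separate, matching the
qualitative pattern the assay reports (misclassification concentrated in
the non-severe/uninfected boundary).

Cohort defaults mirror the assay's largest experiment: 19 uninfected and
35 sepsis plasma donors (20 severe, 15 not severe), three medium-alone
control cultures per batch, one batch, all samples within 48 h. Two
cohorts measured "on the same platform" share their probe-level
architecture (identity and effect sizes of responsive and marker probes):
generate the second cohort with the first cohort's
`truth$architecture`, as `run_pipeline()` does for its test cohort.

What the generator deliberately does **not** emulate: probe
cross-hybridisation, bead-level variance structure, donor-specific
response repertoires, pathogen-specific signatures, and annotation
ambiguity. Passing tests on synthetic data therefore demonstrate that the
pipeline's machinery is correct and recovers planted structure of
realistic magnitude — not that the biological claims hold on any
particular real cohort.

## Marker-selection configuration

Two RKNN parameters the original method leaves open matter greatly at
this sample size (35 training samples), and the package's study
configuration differs from the textbook habit deliberately:

* **Subset size m.** The common random-subspace heuristic `m = √p`
  (the function default) is good for *classification*, but poor for
  *ranking* here: at p ≈ 1,050 a base model holds ~32 features, a single
  feature's marginal contribution to its leave-one-out accuracy (~1%, on a
  1/35 grid) is below the support estimator's noise floor, and once the
  surviving pool is marker-rich every subset contains a marker, support
  saturates near 1 and further elimination is a lottery. With `m = 2` a
  base model's accuracy is directly attributable to its two members, so
  support stays informative at every pool size. This is the configuration
  used by the study-scale analyses (`subset_size = 2`).
* **Ensemble size r.** Support noise scales as 1/√coverage with coverage
  ≈ r·m/p, so small subsets need large ensembles; the study configuration
  uses `r = 6000` per stage (function default 2,000).
* **Feature standardisation.** Distances are computed on z-scored
  features (`standardize = TRUE`): Euclidean kNN is scale-sensitive, and
  raw log2 fold-changes would let high-amplitude transcripts drown
  low-amplitude but highly discriminative markers.
* **Class space.** Markers are selected for severe versus not-severe on
  the sepsis samples only (20 + 15), the stated purpose of the panel;
  3-class selection including uninfected controls is equally supported by
  the API (pass the corresponding labels).
* **Winning stage.** Mean base accuracy rises monotonically as noise
  features are eliminated, so an unrestricted "highest accuracy" rule
  always lands on the smallest stage and would return a panel smaller
  than intended; the search is therefore restricted to stages that still
  hold at least `n_select` features, and falls back to the whole path
  when none is that large.

## Problem sizes used by the validation suite

The study-scale validation (test suite and `scripts/acceptance.R`) uses a
1,500-probe array — ~1,050 PALO-passing transcripts after the 30%
unexpressed fraction — with 150 responsive probes and 30 planted markers,
training on 19/20/15 cohorts and testing on an independent 18/17/12
cohort. These sizes preserve the structure that matters (markers are 3%
of detectable transcripts; the search space is three orders of magnitude
larger than the panel) at desk scale. Null controls use label permutation
and the after-48h attenuation arm; bootstrap coverage is verified on
binormal scores with known AUC 0.8.

## Numerical choices and degenerate inputs

* Quantile normalization delegates to `limma::normalizeQuantiles`
  (ties receive the mean of the reference values they span); a
  single-column matrix is returned unchanged with a warning; missing
  values are rejected.
* Flooring guarantees fold-change denominators ≥ 10, so ratios are always
  finite; a stratum without a medium-alone control is a validation error
  at bundle construction.
* `run_pca()` refuses a constant matrix; `confidence_ellipse()` refuses a
  degenerate (collinear) score cloud.
* Thresholds set to zero degrade gracefully: the differential filter then
  selects every PALO-surviving probe.
* Percentile bootstrap intervals are clamped to contain the point
  estimate, so the documented invariant (lower ≤ AUC ≤ upper) holds even
  in heavily tied resamples.
* `n_select ≥ p` selects the whole winning stage set; elimination always
  removes at least one feature per stage, so it terminates.

## Known limitations

* Support-based backward elimination cannot, in principle, distinguish a
  truly uninformative "hitchhiker" from a marker once base-model accuracy
  saturates; the small-subset configuration mitigates but does not
  abolish this, and a handful of weak markers whose finite-sample
  discrimination is matched by lucky noise transcripts are irrecoverable
  by *any* selector at n = 35.
* The per-batch medium reference consumes no degrees of freedom for
  batch-effect modelling beyond the referencing itself; systematic batch
  interactions with severity are out of scope.
* The confidence-ellipse and heatmap outputs are plotting support, not
  inference; no multiplicity correction is applied to the single
  Mann-Whitney comparison the pipeline reports.
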