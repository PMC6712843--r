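---
title: "Methods: pooled-plasma panel discovery with synthetic cohort augmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-plasma panel discovery with synthetic cohort augmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the data model

Label-free SWATH-MS quantitation of pooled plasma yields, per depletion
arm, a protein x run matrix of peak areas: five pooled samples (healthy
controls and disease stages I-IV), each measured in technical triplicate.
Plasma spans roughly ten orders of magnitude in protein concentration, so
experiments are repeated over several sample-preparation branches
("depletion arms": non-depleted, MARS-14, and the two ultradepletion
orderings MARS-14->API and API->MARS-14), each of which quantifies a
different, overlapping subset of the proteome.

`quant_matrix()` is the universal container: non-negative peak areas with
`NA` for missing cells, plus run metadata (condition, arm, replicate). All
downstream steps consume it or its normalized descendant.

## Normalization and replicate quality control

`total_area_normalize()` rescales every run so its summed signal equals
the mean of the original run totals. This removes loading and injection
differences while keeping values on a peak-area-like scale, which matters
later because the augmentation step works with raw-scale standard
deviations. Arms are normalized independently (each arm is a separate
experiment with its own total signal); a joint mode exists
(`by_arm = FALSE`) but is not the default.

Statistics are computed on log2 values (`log_transform()`). Zeros are
masked as missing rather than offset by a pseudo-count: inventing an
offset changes low-abundance fold changes in ways the data cannot
justify, and the number of masked cells is always reported. A pseudo-count
argument exists for users who prefer the other convention.

Total-area normalization carries a compositional assumption worth stating
explicitly: the bulk of the per-run signal must be condition-invariant.
If a protein carrying a large share of the total signal is itself
differentially expressed, normalization transfers its changes, inverted,
onto every other protein. The fixture generator (below) respects this
assumption by not planting differential expression in the top abundance
decile.

## Differential expression and candidate selection

For each protein and arm:

* one-way fixed-effects ANOVA across the five condition groups on log2
  values (`anova_per_protein()`), proteins lacking two observed replicates
  in any group being excluded and logged;
* unpaired two-sided t-tests of every stage against healthy
  (`pairwise_ttests()`), Welch by default (robust at n = 3; Student
  available for exact pooled-variance reproduction);
* stage fold changes `FC_s = mean(stage) / mean(healthy)` on the linear
  normalized scale (`stage_fold_changes()`).

Selection (`select_candidates()`) requires ANOVA p < 0.05, a maximum
symmetric fold change `max(FC, 1/FC)` strictly above 1.5 in at least one
stage, and a consistent direction of change in all four stages. Degenerate
cases have a fixed policy: identical group means with zero within-group
variance give F = 0 / p = 1; zero within-group variance with distinct
means gives p = 0. No multiple-testing correction is applied by default
(the criterion is a raw per-protein threshold); Benjamini-Hochberg
adjustment is available and reported alongside when requested. Ordering is
always ascending p then accession, so outputs are reproducible.

`consolidate_arms()` takes the union of per-arm selections. A protein
selected with opposite directions in different arms is conflict-flagged
and excluded from the default candidate list - agreement in direction is
part of what "consistent" means once arms are merged.

## Unsupervised structure

`condition_dissimilarity()` computes run-to-run distances (Euclidean on
log2 profiles by default) and `classical_mds()` performs Torgerson
scaling: double-center `-D^2/2`, eigendecompose, scale eigenvectors by
root eigenvalues. Negative eigenvalues from non-Euclidean inputs are
truncated and their relative mass reported; only an all-non-positive
spectrum is an error. `pca_check()` verifies the embedding: for Euclidean
distances, PCA of centered run profiles and classical scaling agree up to
rotation, and the orthogonal-Procrustes RMS residual between the two
configurations is attached to the result (it is ~1e-12 in practice and
tested below 1e-8).

`protein_dissimilarity()` compares protein stage profiles (the five
condition means). Profiles are z-scored across the five means before
Euclidean distances, otherwise absolute abundance - ten orders of
magnitude of it - rather than stage response drives the geometry;
correlation distance (1 - r), which is standardization-invariant, is also
available. Flat profiles (zero variance) cannot be standardized or
correlated and raise an error rather than silently contributing zeros.

## Replicate variance and cohort augmentation

`replicate_variance_report()` computes, per condition, the per-protein
replicate CV (sample SD / mean, linear scale) and its mean +/- SD across
proteins. This is the verification step before augmentation: the
augmentation reuses replicate SDs as its noise scale, which is sensible
only if per-stage variances are comparable.

`augment_cohort()` draws each synthetic patient value independently per
protein from `Normal(class centroid, k_sd x replicate SD)` with
`k_sd = 10` and 1000 patients per class by default (5000 total). The
deliberate 10-fold inflation of technical variance emulates a
heterogeneous patient population and makes the downstream classification
exercise conservative. Draw order is fixed as (class, patient, protein)
under a single seeded generator, so cohorts are bit-reproducible across
machines. Negative draws are truncated to zero by default (concentrations
are non-negative); `resample` and `allow` policies exist, and moment-based
tests use `allow` because truncation intentionally distorts moments.
Each class uses its own replicate SDs; a pooled-SD pattern (build the SD
matrix by averaging across classes) is useful when class-specific variance
signatures would confound an analysis - the noise-degradation test below
is an example.

## Classification

`split_cohort()` partitions 70/15/15 (train/validation/test), stratified
per class, seeded. `train_nn()` is a one-hidden-layer network: 10 tanh
units, softmax output, cross-entropy loss, full-batch Adam
(learning rate 0.02), early stopping on validation loss with patience 30
within at most 400 epochs, keeping the best-validation weights. This is a
deliberate interpretation of a classical pattern-recognition network
("10 hidden neurons", 70/15/15 split); the loss, optimizer and stopping
rule are not dictated by that description, so they were chosen to be
deterministic under a seed - an explicit contract: identical (data,
config, seed) give bit-identical weights and predictions, with argmax
ties broken toward the lowest class index. Inputs are z-scored by
training-set statistics by default; raw peak areas span orders of
magnitude and would otherwise reduce training to the most abundant
feature.

`train_baselines()` provides k-nearest-neighbor and decision-tree
comparators (`class::knn`, `rpart`), with k and depth picked on the
validation set over small grids. `class::knn` breaks vote ties with the
global RNG; predictions here run under a fixed local RNG state so the
pure-function contract holds for all classifier kinds.

`evaluate()` returns the 5x5 confusion matrix (rows = true) and the
correct-classification rate, 100 x trace / total. `deploy_on_real()`
classifies the real pooled runs that never entered training - each
technical replicate independently (15 items) by default, or per-condition
replicate means (5 items) under `unit = "pooled_mean"`; features are
aligned by protein id, never by column position.

## Panel minimization

`rank_protein_groups()` clusters candidate stage profiles
(average-linkage on the protein dissimilarity); the number of groups
defaults to the silhouette-best cut over 2..min(8, n-1). Within groups,
proteins are ranked by mean dissimilarity to their own group
(representativeness), ties lexicographic. `minimize_panel()` runs greedy
forward selection seeded by the group representatives: at each step every
remaining candidate is evaluated end-to-end (augment, split, train,
test, deploy) over a seed set, the best marginal median synthetic-test
accuracy wins, and the search stops when the target accuracy is met,
returning the full audit log of every evaluated panel. Exhaustive subset
search is available for up to 12 candidates. Median (not mean)
aggregation over seeds is used throughout because network training
variance produces occasional outliers.

## The fixture generator

`generate_fixture()` emulates the statistical structure of the pooled
five-class plasma experiment so that every stage of the pipeline is
testable without any external data:

* healthy centroids log-uniform over 10 orders of magnitude (the plasma
  dynamic range that motivates depletion);
* 37 planted differentially-expressed proteins with stage-consistent
  directions and symmetric fold-change magnitudes uniform in [1.5, 8],
  sorted non-decreasing with stage by default (progressive disease); the
  five largest-effect proteins are designated drivers so panel searches
  have a recoverable truth;
* technical triplicates with per-stage target CVs of 33 / 36 / 42 / 45 /
  31 percent (healthy, I-IV) - the replicate-variance profile of pooled
  plasma measured in triplicate;
* four depletion arms retaining each protein with probability 1 / 0.9 /
  0.8 / 0.8 (non-depleted arm complete), the consolidated multi-arm
  design the selection step is built for.

Replicate noise is multiplicative: `value = centroid x max(0, 1 + tau z)`
with `z ~ N(0,1)`. A configured CV is the *target observed* triplicate
CV, and `tau` is calibrated so that the expected sample CV over
`n_replicates` zero-truncated draws equals it. The naive choice
`tau = CV/100` would be recovered ~8% (relative) low: the sample SD of
three normal draws underestimates sigma by the c4(3) ~ 0.886 factor, the
random denominator of CV = s/mean inflates the ratio, and zero truncation
trims the lower tail. The calibration solves for tau by root-finding
against a fixed, deterministic standard-normal simulation block, so
generation stays bit-reproducible. Observed triplicate CVs saturate near
130% under zero-truncated noise; targets are accepted up to 110%.

An optional heteroscedastic mode draws each protein's CV from a truncated
normal with the per-stage spread (e.g. 33 +/- 28), mirroring the wide
across-protein CV dispersion of real data; the fixed-CV default keeps
oracle tests clean.

What the generator does **not** emulate: correlation among proteins (both
the augmentation and the generator draw independently per protein - a
stated simplification), peptide-level structure, retention-time or
spectral artifacts, and run-level loading variation (each run is generated
on a common scale, so normalization is an identity in expectation). Tests
passing on fixtures therefore demonstrate the pipeline's statistical
behaviour under its own assumptions, not performance on any particular
real dataset.

## Numerical choices and edge policies

* Log base 2, recorded in the object and configurable.
* Zero totals, unknown runs, negative cells, duplicate accessions: errors
  naming the offending run/protein/cell.
* Zero-variance groups in tests: fixed degenerate policies (above) rather
  than NaN propagation.
* Normalization targets the mean run total (not 1.0) to preserve the
  peak-area scale for SD export; any common target is equivalent up to
  scale, and selection is invariant to global rescaling (tested).
* MDS negative eigenvalues truncated with reported mass; rank-deficient
  embeddings zero-padded to the requested dimension.
* Confusion-matrix argmax ties toward the lowest class index.

## Problem sizes used by the test and acceptance runs

The reference end-to-end run uses the full default scale: 300 proteins,
four arms, 5000 synthetic patients (1000 per class), k_sd = 10, seed 17;
it completes in a few seconds and its synthetic-test (686/750 = 91.47%)
and real-deploy (11/15 = 73.3%) accuracies are frozen in the test suite
and recomputed bit-for-bit. Recovery and type-I statistics use 20
generator seeds at 300 x 3; classifier sanity checks use 10 seeds at 120
patients per class with a 12-protein panel; the panel-search tests use
deliberately small, decidable configurations (25-30 proteins, 40-60
patients per class). These sizes were chosen so the whole suite runs in a
couple of minutes while every stochastic bound retains a 3-SE margin.

A note on the 5-protein driver panel: under the default conditions
(fold changes at most 8, CVs 31-45%, 10x noise inflation) five features
cannot match the accuracy of the full consolidated candidate set (~57% vs
~90% median synthetic-test accuracy) - with 10x-inflated noise the
per-feature signal is weak and accuracy is carried by feature count. A
printed-size panel matching a full-set accuracy within a few points
implies per-protein effects much larger than this generator's default
fold-change range plants; the panel tests therefore verify the search
mechanics (grouping recovery, greedy optimality per step, determinism,
restriction-identity) rather than a fixed accuracy gap.

## Known limitations

* Independence of proteins in both generator and augmentation; real
  plasma proteins are strongly co-regulated.
* The raw p < 0.05 selection criterion is permissive by design (it is the
  classical workflow); the BH option quantifies the difference.
* Total-area normalization's compositional assumption (see above).
* The network is a fixed small architecture; no calibration of predicted
  probabilities is attempted.
* Real-data deployment classifies 15 (or 5) pooled items - a sanity check
  of the trained model against the measurements that parameterized the
  cohort, not an external validation.
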