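---
title: "Diagnosing feature-sharing leakage in enhancer-promoter interaction benchmarks"
author: "EPLeakage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing feature-sharing leakage in enhancer-promoter interaction benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Supervised models of enhancer-promoter (EP) interaction take a candidate
pair of elements on one chromosome and predict, from epigenomic signal
summarized over the enhancer (E), the promoter (P) and the intervening
window (W), whether the pair interacts.  Candidate sets built from
chromatin-contact data have a peculiar dependence structure:

* **Shared promoters.**  Many pairs connect different enhancers to one
  promoter.  All of them carry *identical* P-feature vectors.
* **Shared windows.**  Two pairs whose windows overlap are summaries of
  partly the same genomic signal, so their W features are correlated —
  enhancers on the same side of one promoter are the extreme case, with
  nested windows.
* **Imbalanced groups.**  Within one promoter's group the
  positive:negative split is usually far from even (globally about 1:20
  positive:negative), so the group's *majority class is predictable from
  the promoter's features alone*.

When pairs are dealt to cross-validation folds at random, a fold's test
pairs share P and W features with training pairs.  A high-capacity model
can then score test pairs by *memorizing* which promoters were positive
in training, with accuracy `max(n_pos, n_neg) / (n_pos + n_neg)` on each
group — e.g. 7/9 ≈ 78% on a group with 7 positive and 2 negative pairs —
without learning anything that generalizes.  Measured "test" performance
then reflects training-set fit, not generalization.

## The diagnostic procedure

The package separates the question into four steps.

**1. Audit the sharing structure** ([`promoterGroups()`],
[`sharingMatrix()`], [`leakyPairFraction()`],
[`windowSharingComponents()`]).  The sharing matrix counts promoter
groups (or their pairs) by their `(n_pos, n_neg)` signature; a
pair-weighted cell of 27 at (7, 2) corresponds to 27/(7+2) = 3 distinct
promoters.  `leakyPairFraction()` reports the fraction of pairs that
both share a promoter and sit in a ≥2-fold imbalanced group — the pairs
exposed to promoter-feature contamination.  Window-overlap components
are the connected components of the positive-overlap graph on windows;
for intervals this equals membership in the same merged interval, so the
implementation reduces the windows with zero gap tolerance and the test
suite checks it against an explicit transitive-closure oracle.

**2. Build partitions that do or do not leak.**  `randomFolds()` is the
conventional, leaky scheme.  `chromosomalFolds()` sorts pairs by genomic
position, cuts the ordering into near-equal contiguous blocks and snaps
every cut forward past any straddling promoter group or window
component.  `promoterFolds()` keeps promoter groups whole (greedy
assignment to the smallest fold) but lets window overlap cross folds —
isolating the two mechanisms.

**3. Certify.**  `certify()` counts, exactly, cross-fold pairs of pairs
sharing a promoter or overlapping windows.  A chromosomal partition must
certify (0, 0); a promoter-segregated partition certifies 0 promoter
links but typically positive window links.  Certification is
independent of any model and makes "leakage-free" a checkable property
of the partition rather than a hope.

**4. Benchmark train against test.**  `runBenchmark()` fits one model
per fold and records precision, recall, F1, AUROC and AUPRC on both the
training folds and the held-out fold.  The leakage signature is a large
train-test gap under the certified partition coexisting with high
"test" performance under random folds.  `parameterScan()` sweeps tree
counts or SVM `(C, gamma)` grids to show the capacity dependence:
training F1 approaches 1 with many trees or large gamma while certified
test F1 stays near the class-imbalance baseline.

The relevant baseline for imbalanced data is the all-positive rule,
`allPositiveF1(p) = 2p/(1+p)`: at prevalence 1/21 this is exactly 1/11 ≈
0.091, the natural "random" floor for F1.

## What the synthetic generator emulates

No public EP training table is needed: `simulateEPDataset()` builds
datasets with the three structural phenomena above and a *known* amount
of genuine signal.

* **Groups.**  Each of `nPromoters` (default 400) promoters hosts
  `2 + Geometric(mean = groupSizeMean - 2)` pairs, truncated at
  `groupSizeMax` (defaults 8 and 30): a simple over-dispersed count law
  producing the long-tailed group-size profile seen in real candidate
  sets, with every promoter shared by at least two pairs.
* **Labels.**  In the default `pure_mixture` mode a group is entirely
  positive with probability `targetPosFraction` (default 1/21) and
  entirely negative otherwise — the maximal-leakage configuration in
  which every multi-pair group is fully imbalanced while the expected
  global positive fraction equals the target.  `beta` mode draws each
  group's positive fraction from Beta(`betaA`, `betaB`) (defaults 0.2,
  4.0, mean ≈ 1/21) and mixes classes within groups, which is the more
  realistic profile and the one used for the calibration experiments
  below.
* **Geometry.**  Promoters (2 kb) are placed uniformly on
  `nChromosomes` × `chromLength` (default 5 × 50 Mb), kept clear of the
  chromosome ends; enhancers (1 kb) land on a random side at a gap whose
  log-scale position in [`minDistance`, `maxDistance`] (defaults 10 kb –
  2 Mb) is Beta(1, 3) distributed.  The distance-decay shape mirrors
  real EP candidate sets (contact frequency falls with distance) and
  keeps window-overlap components local: with log-uniform gaps instead,
  overlap chains fuse whole chromosomes into a handful of components and
  position-blocked cross-validation degenerates.  Elements never
  overlap; draws that would collide are rejected and redrawn.
* **Features.**  P features are a standard-normal latent vector per
  promoter, copied bit-for-bit to each of its pairs.  E features are an
  independent latent per enhancer.  W features are means, over the
  pair's window, of a per-chromosome piecewise-constant standard-normal
  track with `trackSegmentBp` (50 kb) segments, so window correlation
  decays with decreasing overlap and equals 1 for identical windows.
  All three blocks have `marksPerRegion` (136) columns — 408 EPW
  features, matching the dimensionality at which the E/EP/EPW feature
  subsets are conventionally compared (136/272/408).
* **Signal.**  `signalStrength` (δ) is added to the first
  `nSignalFeatures` (16) E features of positive pairs.  The default δ =
  0 makes the label conditionally independent of *all* features given
  promoter identity, so any above-random performance under a certified
  partition is a bug, and any above-random performance under random
  folds is pure leakage.  δ > 0 provides a positive control: the signal
  is recoverable by a leakage-free evaluation.

What the generator does **not** emulate: real mark semantics or signal
magnitudes, distance-dependent interaction probability, enhancer
reuse across promoters, cell-type structure, or the exact empirical
group-size histogram.  Passing tests therefore demonstrate properties
of the *evaluation schemes* under the named sharing mechanisms, not
biological performance numbers; headline statistics from real corpora
(e.g. a specific shared-promoter percentage) are not reproduced here.

## Models and numerical choices

* **Gradient boosting** is XGBoost with the classic GBM settings
  (learning rate 0.1, depth 3, logistic objective) and the histogram
  algorithm with 64 bins, single-threaded.  Histogram binning at this
  resolution leaves the memorization phenomenon intact (promoter latents
  remain separable) while keeping 4000-tree × 10-fold runs tractable on
  one CPU.  Tree count defaults to 4000, the capacity regime in which
  the leakage inflation is fully expressed.
* **Random forest** is ranger with probability trees (default 500).
* **SVMs** are e1071 with standardization computed from the training
  fold only and applied to the test fold — without it an RBF kernel on
  raw features is degenerate.  `gamma = NA` means 1/n_features.  For
  thresholded metrics the SVM's own decision boundary is used (decision
  values mapped through the logistic, so the 0.5 score threshold equals
  the decision threshold); Platt-scaled probabilities are deliberately
  avoided as they refit an internal CV on every fold.
* **Thresholds and conventions.**  P/R/F1 threshold probability-scale
  scores at 0.5.  Precision is 0 with no positive calls, recall 0 with
  no positive labels, F1 is 0 when P + R = 0; AUROC uses midranks for
  ties; AUPRC is average precision with tied scores entering as one
  threshold.  Both ranking metrics are `NA` on single-class inputs, and
  a test fold without positives is recorded as `NA` with a warning
  rather than failing the run.  A training fold containing a single
  class yields constant scores for that class.
* **Determinism.**  The generator is a pure function of its
  configuration (including `seed`); partitions are deterministic given
  scheme and seed (chromosomal folds take no seed at all, with window
  midpoint and pair-id tie-breaks and natural chromosome ordering);
  per-fold model seeds derive from the run seed.

## Problem sizes and what the package's experiments show

The package's own experiments (test suite and the acceptance script)
use these sizes, chosen to exercise each property at the smallest scale
at which it is statistically decisive:

* The central contrast runs at the default scale — ~3100–3300 pairs, 408
  features, 10 folds, 4000 trees.  On zero-signal pure-mixture data,
  random CV yields mean held-out F1 ≈ 1 while certified chromosomal CV
  yields F1 ≈ 0 (nothing is learnable), reproducing the
  inflated-versus-near-random contrast.
* Null calibration uses beta-profile data (300 promoters), where
  positives spread over many groups: fold-averaged held-out AUROC under
  chromosomal folds, averaged over 8 generator seeds, must lie in
  [0.45, 0.55].  Pure-mixture profiles are unsuited to this particular
  check — positives concentrate in so few groups that per-fold AUROC is
  dominated by a handful of effective units.  Fold-averaged (not pooled)
  AUROC is used because pooling scores across folds is biased downward
  under class imbalance: holding out a positive-rich region depresses
  that fold's score offset.
* Signal recovery scans δ ∈ {0, 0.5, 1, 2} over 3 seeds (150
  promoters); certified test AUROC rises from ≈0.5 to ≈1, monotonically
  up to Monte-Carlo noise.
* Structural oracles (brute-force certificates, overlap closure,
  sharing-matrix identities) run on ≤300-pair datasets where quadratic
  enumeration is instant.

## Known limitations

* The chromosomal scheme needs at least `k` mergeable units; data whose
  window components chain across an entire chromosome cannot be split
  leakage-free at that `k`, and the partitioner refuses rather than
  silently leaking.
* `leakyPairFraction()` reads the sharing-and-imbalance condition
  conjunctively (groups of size ≥ 2 that are ≥ 2-fold skewed, with pure
  groups counted as skewed); balanced sharing groups still share
  features but their majority rule carries no class information.
* Random folds are unstratified; with ~5% positives and small fold
  counts a fold can lack positives, which is reported as `NA` rather
  than imputed.
* The generator's independence assumptions (latents independent across
  promoters and enhancers, no distance-label coupling) are the null
  model's point, but they also mean absolute performance numbers on
  synthetic data should not be read as predictions for real corpora.
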