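---
title: "Hypernetwork integration of paired multi-omic studies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypernetwork integration of paired multi-omic studies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypernet)
```

## The analysis problem

The package targets a common design in physiological 'omics: a small
two-period crossover in which every subject is measured under two
conditions (here called *exposure* and *withdrawal*, after glucocorticoid
exposure studies) across several molecular layers — e.g. two tissue
transcriptomes, a circulating miRNA panel, and a serum metabolome. The
questions are (i) which elements respond to the condition within
individuals, (ii) which responses are *co-regulated across layers*, and
(iii) whether a compact, robust subset of elements classifies the two
conditions well enough to serve as a candidate biomarker panel.

With ten subjects, no single correlation between two 'omic elements is
trustworthy. The package's core therefore summarizes the full correlation
structure into a **hypernetwork**: a network whose edges may join many
nodes at once, represented here by the count of thresholded correlations
that two elements *share* against a common background. Shared-edge counts
aggregate hundreds of individually noisy correlations, which is what makes
the construction robust to false positives at small n.

## Paired differences as the analysis space

Every sample is first resolved to a (subject, condition) pair and each
layer collapsed to one vector per feature of per-subject differences
`exposure − withdrawal` (`paired_difference()`, the +1/−1 sign
convention). All correlations, all paired tests, and the hypernetwork are
computed in this difference space. This removes subject-level intercepts
(the main nuisance in a within-individual design) exactly, rather than
hoping a between-sample normalization absorbs them. Whether thresholded
correlations should be computed on ±1-coded per-sample values instead is
not settled by convention; the difference-vector reading is the package's
choice because it is the space in which "response to the condition" is
defined, and the per-sample alternative can be assembled from the same
primitives by the user.

Standard per-layer normalizations are provided and applied where the data
type calls for them: sample-median normalization and log2 transform for
raw metabolite intensities (`median_normalize()`, `log_transform()`), an
interquartile-range filter retaining the top fraction of features by IQR
(`iqr_filter()`, by default applied only to the metabolome layer with
keep fraction 0.8 — a conventional variance filter, not a tuned value),
and per-feature standardization for the miRNA layer
(`scale_mean_center()`). The sample standard deviation (n − 1) is used
everywhere; at n = 10 the distinction from the population convention is
material and the inferential convention is the defensible one.

## Differential expression

`paired_t_test()` is the textbook one-sample t on each feature's
difference vector (df = n − 1, two-sided). Features with zero difference
variance get t = 0, p = 1 — conservative and keeps result tables
rectangular. FDR control is Benjamini–Hochberg (`bh_fdr()`, via
`stats::p.adjust`); BH is the field default where a report says only
"FDR". Nonparametric analogs for clinical variables are thin wrappers
over `stats::wilcox.test` (exact for small n without ties).

Two selection conventions coexist deliberately: hypernetwork
*integration* anchors on the raw p < 0.05 sets (DEOEs, differentially
expressed 'omic elements), while every other decision uses FDR < 0.05.
Integration benefits from a generous anchor set because the hypernetwork
itself filters false positives; downstream claims need the stricter
criterion. Both alphas are configurable (`pipeline_config()`).

A note on power at this design's scale: with ten subjects and a
standardized paired effect of 1, per-feature raw-p power is moderate but
BH discoveries over thousands of features are few. The pipeline's signal
gate therefore treats a study as informative if either the anchor layer's
FDR set reaches `min_anchor_fdr` (default 10) or its raw-p fraction is at
least twice the nominal alpha; a global-null study fails both and yields
a clean "no signal" report.

## The hypernetwork

Let the *anchor* set be the m DEOEs of the anchor layer and the
*background* the n elements called present (in the pipeline: every
feature of every layer, pooled). `correlation_matrix()` computes the
m × n Pearson matrix **r** between their difference vectors.

`dichotomize()` maps r to a binary incidence matrix
`M[i, j] = 1 ⟺ |r_ij − mean(r)| ≥ k · sd(r)`, default k = 1.5. The
threshold is expressed in standard deviations of the pooled r
distribution, which is close to normal in this setting; a raw cutoff
|r| ≥ 1.5 would be meaningless. `adjacency()` forms
`sM = M %*% t(M)`: entry (i, j) counts background elements correlated
(past threshold) with both i and j — the number of shared edges — and the
diagonal holds node degrees. `hypernetwork()` chains the three steps and
returns a classed object with `print`, `summary`, and `plot` (heat map)
methods.

### Choosing k: the chi-squared signal window

`chi2_signal()` measures structure in sM as
`Χ² = Σ (m_i − m_e)² / m_e`, summed over all N² elements. Two readings of
the expected element value m_e are implemented because the defining
phrase "total number of correlations divided by the order of the matrix"
is ambiguous: `mean_element` (default) uses `sum(sM)/N²` — an expectation
on the element scale, which is what a chi-squared distance requires — and
`literal` uses `sum(sM)/N`. Both scale linearly in sM, so the argmax over
k is usually the same; neither is asserted to be the original intent. The
summation is likewise configurable in spirit: the package sums over all
elements (diagonal included), the natural reading of an N-ordered matrix
sum. `threshold_sweep()` evaluates Χ² over a k grid and returns the
maximizer, breaking ties toward the smaller k (the more inclusive
network).

### The central cluster

`central_cluster()` clusters the rows of sM (Euclidean distance, complete
linkage by default — the original analysis does not record its choices,
so the most common defaults are used and exposed as arguments), scans
cuts k = 2..10, and among clusters of at least `min_size = max(5, 2% of
N)` members picks the one with the largest **excess connectivity**: the
sum over intra-cluster pairs of shared-edge counts above the overall
off-diagonal mean. A plain mean-connectivity score was evaluated first
and discarded: it always prefers a tight sub-core inside the true block
(the mean can only fall as a coherent block is completed), which defeats
the purpose of recovering the whole co-regulated module. The excess score
is modularity-like — it grows with every above-average pair added — and
still guarantees the returned cluster's mean connectivity exceeds the
overall mean. Diagonal entries (degrees) are excluded from both scores
because they measure a different quantity. Ties break toward the larger
cluster, then the earlier cut; node order never affects the member set.

### Dissimilarity robustness

`dissimilarity_robust()` rebuilds the hypernetwork from the complement
incidence `M′ = 1 − M` (shared *absences* of correlation), extracts the
complement network's central cluster by the identical procedure, and
removes from the similarity cluster any member also central there. An
element prominent in both networks correlates strongly with one part of
the background while sharing aligned non-correlation with another — an
unstable profile that is purged before prediction. When M′ carries no
off-diagonal variation (e.g. M all ones) there is no dissimilarity
cluster and nothing is eliminated.

### Centrality

`centrality_rank()` ranks nodes by the principal eigenvector of sM with
self-loops removed (max-normalized, ties broken by node ID after rounding
at 1e-9 to absorb floating-point noise). This is the standard
eigenvector-centrality summary of a weighted module hierarchy and stands
in for heavier overlapping-module decompositions, which are out of the
package's scope.

## Classification

The predictive refinement runs on the anchor layer's robust set:

* `plsda_separation()` — two-component PLS-DA (via `mixOmics::plsda`,
  features standardized — the conventional preprocessing when none is
  recorded). "Perfect separation" is decided *exactly*: the two classes'
  convex hulls in score space are tested for disjointness by a
  separating-axis test (hull-edge normals plus all pairwise difference
  directions, which covers degenerate collinear hulls). Note that PLS-DA
  overfits when features approach the sample count; the package reports
  separation but leans on out-of-bag forests for honest accuracy.
* `shadow_select()` — shadow-permutation feature selection: each
  iteration trains a forest on the real features plus a permuted
  ("shadow") copy of each, and a real feature scores a hit when its
  permutation importance beats the best shadow. After `n_iterations`
  (default 100) a two-sided binomial test at 0.01 against hit probability
  0.5 marks features confirmed, rejected, or tentative; confirmed and
  tentative are carried forward. This is a fixed-iteration variant of the
  well-known shadow-feature algorithm: features are not dropped between
  iterations, which keeps the importance history rectangular and the run
  deterministic for a given seed at a small cost in iterations.
* `rf_oob_auc()` — a random forest (default 5000 trees; each tree sees a
  bootstrap ≈63% of samples) whose out-of-bag class-vote fractions yield
  the ROC AUC (rank/trapezoid form with midrank ties) and the
  out-of-bag majority-vote error. At very small n the out-of-bag vote
  estimate is pessimistically biased under the null (a sample's own class
  is underrepresented in the in-bag sets of the trees that score it), so
  null calibration checks are run at 40 samples.
* `direction_consistent()` — retains candidates whose log2 fold change
  has the same nonzero sign in both tissues' result sets, optionally
  requiring FDR significance in both; `external_validate()` re-scores a
  gene set on any labeled expression matrix, requiring ≥50% coverage.

## The synthetic-data generator

`generate_study()` emulates the statistical structure the pipeline is
built for, with known ground truth:

* log2-scale data; per-feature baselines N(7, 1);
* subject random intercepts (sd 0.5) shared by a subject's two samples,
  so the paired design has a genuine advantage over an unpaired analysis;
* a configurable responsive subset per layer whose per-subject paired
  difference is shifted by `effect_size · noise_sd` with random sign. The
  default responsive fractions (≈15%, 12%, 5%, 23% of the four layers)
  mirror the proportions of significant elements reported in the kind of
  study the generator emulates;
* one or more cross-layer latent factors: each subject draws a factor
  score z, and member features receive `loading · z` inside their
  difference noise (`sqrt(1 − loading²)` scales the residual), giving
  member–member correlation loading² and member–factor correlation
  loading, exactly in the space where the hypernetwork operates;
* `noise_sd` is defined as the sd of the paired difference itself, so a
  responsive feature's standardized paired effect equals `effect_size`
  by construction — the convention that makes power statements exact;
* an optional dropped withdrawal sample (`dropout_subject`) to exercise
  the incomplete-pair path ("nine matching samples" of ten).

Defaults (10 subjects, effect size 1, loading 0.8, one factor, layer
sizes 2000/2000/252/164 standing in for two 28,869-probe transcriptomes,
252 miRNAs and 164 metabolites) are the study conditions; tests and the
acceptance script scale the transcriptome layers to 400 features for
speed, which leaves all per-feature distributions unchanged.

What the generator does **not** emulate: probe-level microarray noise,
mass-spectral artifacts, missingness, heavy-tailed or heteroscedastic
noise, correlated null features, or batch structure. Passing tests
demonstrate that the machinery recovers planted structure under Gaussian
log-scale noise — a necessary condition, not evidence about any
particular real data set. The noise distribution of real normalized data
is not documented in studies of this design; Gaussian is an assumption.

## Numerical and degenerate-input choices

* Zero-variance vectors: correlations set to 0 with a warning (never
  NA); zero-variance paired tests give p = 1; constant features are
  dropped by standardization with a warning.
* `dichotomize()` refuses a degenerate r distribution (sd 0);
  `chi2_signal()` refuses an all-zero sM; `centrality_rank()` refuses a
  network with no off-diagonal edges. Failing loudly beats silently
  returning structure that is not there.
* Determinism: the only stochastic stages are the forests; both accept a
  seed, and `run_pipeline()` derives all stage seeds from one config
  seed, so identical config + seed reproduces byte-identical reports.
  For that reason the pipeline writes into the configured output
  directory as-is and keeps timestamps out of every artifact.
* The pipeline's report keeps the stage sets nested by construction:
  selected ⊆ robust ⊆ central cluster, and the significant
  direction-consistent set inside the direction-consistent set.

## Problem sizes used by the test suite

Unit and acceptance tests run at transcriptome layers of 150–2000
features, 10 subjects (40 samples for forest null calibration), 20
simulation seeds for recovery properties, 100 shadow iterations at 500
trees, and 20 null studies of 2000 features for calibration — sizes at
which every distributional property they assert has converged adequately
while the whole suite stays fast.

## Known limitations

* The hypernetwork threshold default k = 1.5 is a convention; the
  chi-squared sweep is provided precisely because no single k suits every
  correlation distribution.
* Cluster extraction depends on hierarchical-clustering choices the
  original methodology leaves unrecorded; all are exposed as arguments
  and the defaults documented above.
* Out-of-bag AUC at 20 samples is a noisy, pessimistically biased
  estimate; treat small-n AUCs as qualitative.
* The generator's independence assumptions (between non-member features,
  between subjects) make recovery easier than in real data with
  pervasive co-expression; external validation on held-out labeled data
  (`external_validate()`) is the honest check for any proposed panel.
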