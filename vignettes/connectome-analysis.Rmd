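---
title: "Graph-theoretical analysis of resting-state functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretical analysis of resting-state functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

rsfcnet implements the full analysis chain used to compare resting-state
functional brain networks between a lesioned and a control group of small
animals: cleaned ROI BOLD time series are turned into Pearson connectivity
matrices, thresholded into sparsity-matched binary graphs, summarized by
global and nodal topology measures normalized against degree-preserving
random networks, and compared between groups by a mixed ANOVA, nodal tests
with false-discovery-rate control, and the network-based statistic (NBS)
with permutation family-wise error control. Because animal rsfMRI data are
rarely shareable, the package ships a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes; every stage of
the pipeline is validated against it.

This vignette documents the model, the defaults and why they were chosen,
the numerical conventions, and what the validation on synthetic data does
and does not establish.

## The analysis model

**From signal to graph.** Each subject contributes a $T \times R$ matrix of
BOLD-like signals over $R$ ROIs. After preprocessing (below), the
functional connectome is the $R \times R$ matrix of pairwise Pearson
correlations $r_{ij}$. A binary undirected graph is obtained by keeping the
$K = \mathrm{round}(SP \cdot R(R-1)/2)$ strongest correlations at a given
sparsity $SP$; fixing the edge count rather than a correlation cutoff
equalizes wiring cost across subjects, so group differences in topology are
not confounded by differences in overall correlation level. All analyses
sweep $SP$ over a grid, by default $0.05, 0.10, \ldots, 0.50$.

**Topology measures.** At each threshold the package computes node degree
$k_i$, local clustering $c_i = 2t_i/(k_i(k_i-1))$ (with $c_i = 0$ for
$k_i < 2$), breadth-first shortest-path distances, nodal efficiency
$e_i = \frac{1}{R-1}\sum_{j \ne i} 1/d_{ij}$ (with $1/\infty = 0$), global
efficiency $E_{glob} = \overline{e_i}$, characteristic path length $L$
(mean distance over reachable ordered pairs), and modularity $Q$ with
module count $m$ from greedy agglomerative optimization of Newman's
$Q = \sum_c (e_{cc} - a_c^2)$. Clustering and path length are normalized
against the means of $n_{rand}$ degree-preserving random reference networks
(double-edge-swap rewiring), giving the small-world index

$$S = \frac{\bar{C}/\bar{C}_{rand}}{L/L_{rand}},$$

which is well above 1 for small-world networks and near 1 for
Erdős–Rényi graphs. Nodal measures are additionally summarized by the
trapezoidal area under their curve (AUC) over the sparsity grid, a
threshold-independent per-node statistic.

**Group inference.** Three layers: (1) each global metric enters a mixed
two-factor ANOVA with group as the between-subject and sparsity as the
within-subject factor, with per-threshold Bonferroni-corrected post hoc
comparisons; (2) each node's AUC is compared between groups with two-sided
pooled-variance t-tests, reported both uncorrected ($p < 0.05$) and with
Benjamini–Hochberg FDR ($q < 0.05$) and a direction label; (3) the NBS
operates on the *unthresholded* correlation matrices: edge-wise
t-statistics, a primary threshold, connected components of the
suprathreshold graph, and a permutation null distribution of the maximal
component extent, giving each component a family-wise-corrected p-value.

## Preprocessing

The per-subject chain is fixed in order:

1. **Initial-volume removal** (`n_drop = 50`): discards magnetization
   saturation at the start of an EPI run.
2. **Artifact interpolation**: volumes flagged invalid are replaced by
   linear interpolation between neighbouring valid volumes. The flags are
   kept, and the interpolated volumes are discarded again at the masking
   step; interpolation exists solely so that large-amplitude spikes can
   neither act as high-leverage points in the nuisance regression nor ring
   through the band-pass filter into neighbouring valid volumes. Without
   this step a handful of spikes, once smeared by the filter's impulse
   response, measurably inflates the between-subject variance of every
   correlation estimate.
3. **Nuisance regression**: OLS residuals against an intercept, six
   rigid-body motion parameters and the mean CSF signal. The intercept is
   always included — residualizing without one leaves mean offsets that
   corrupt correlations. Residuals are orthogonal to every regressor to
   machine precision.
4. **Band-pass filtering** (0.01–0.1 Hz at TR = 1 s): zero-phase
   forward–backward Butterworth, order 2 per pass (4th-order effective),
   applied per ROI after de-meaning. The filter family and order are not
   dictated by the analysis model; a zero-phase Butterworth is the standard
   phase-preserving choice in resting-state work and both are configurable.
   Filtering is applied to the continuous series *before* masking, so the
   filter always sees an unbroken time axis.
5. **Temporal masking** (`target = 300` volumes): if the first 300 volumes
   are artifact-free they are used as a continuous block; otherwise valid
   volumes are concatenated in temporal order until 300 are collected. The
   possibly non-continuous result is analysed under the stationarity
   assumption that the functional network does not change over the
   acquisition.

A helper (`flag_motion_volumes()`) derives validity flags from realignment
parameters for data arriving without them, using the conventional
2.5 mm / 2.5° exclusion rule on frame-to-frame changes.

## The synthetic cohort generator

`generate_cohort()` draws each subject's series from a multivariate normal
whose correlation matrix has a modular block structure: `n_modules`
bilateral communities (a left-hemisphere block plus its mirrored
right-hemisphere block, reflecting homotopic connectivity) with
`within_corr = 0.4` inside and `between_corr = 0.05` outside. These values
give subject-level connectomes with clear community structure and
small-world indices around 2–3 at mid-range sparsities, comparable to what
cleaned rodent connectomes show. Defaults mirror a typical acquisition:
900 volumes at TR = 1 s over 150 ROIs (75 per hemisphere), 13 lesion and
11 sham subjects.

On top of the correlated signal the generator layers exactly the nuisance
structure the preprocessing stage claims to remove: per-ROI sinusoidal
drift below 0.01 Hz (amplitude 0.5 SD), a low-pass "CSF" signal mixed into
every ROI with random weights 0.2–0.6, six smooth random-walk motion
traces, and a fraction (`spike_fraction = 0.02`) of volumes — always after
volume 50, so the initial trim never absorbs them — corrupted by offsets of
6–10 SD and flagged invalid.

**Planted group effects.** An `effect_spec()` designates a reduced block
(the "ipsilesional cortex" analog) and an increased block (the bilateral
"thalamus" analog). Correlations within a block are multiplied by the
effect factor and every correlation between a block node and the rest of
the brain by its square root — the pattern obtained by scaling the block
nodes' community-factor loadings. This choice matters: scaling only the
within-block entries produces a target matrix that is not positive
definite whenever the block sits inside a strongly correlated module (a
block cannot correlate at 0.4 with a common community signal while its
members correlate at only 0.2 with each other), and repairing that by
shrinkage toward the identity either plants a spurious global group
difference (if only the lesion matrix is shrunk) or halves the planted
effect (if both are shrunk equally). The loading form keeps the target a
valid correlation matrix, needs no shrinkage in practice, and models what
a focal lesion does — the region loses connectivity coherently, within the
block and to everything else. A positive-definiteness check with shared
identity-shrinkage remains as a guard for extreme requested patterns; when
it engages, both groups are shrunk by the same factor so the group
difference stays exactly the planted pattern.

The magnitudes of the planted effects are free parameters: the reference
analysis reports directions and significance on real data, not effect
sizes. The validation suite uses a 50% reduction and a 30% increase, large
focal effects of the kind the method is meant to detect.

**What the generator does not emulate:** voxel-level anatomy, haemodynamic
response dynamics, scanner noise physics, non-stationary (dynamic)
connectivity, or physiological rhythms beyond the CSF-like regressor.
Passing tests therefore establish that the pipeline recovers the
statistical structure it assumes — not that any particular real dataset
satisfies those assumptions.

## Numerical conventions

* **Edge-count rounding**: $K$ is rounded half away from zero, so edge
  counts are bit-reproducible across platforms (559 edges at $SP = 0.05$
  and 5588 at $SP = 0.5$ for $R = 150$).
* **Ties at the K-th correlation** are broken lexicographically by node
  index, which also makes edge sets nested across increasing sparsity.
* **Signed vs absolute ranking**: edges are ranked by signed correlation by
  default (strongest positive first); `edge_rank = "absolute"` lets strong
  negative correlations compete.
* **Disconnected graphs** (unavoidable at low sparsity): $L$ averages over
  reachable ordered pairs only, efficiency uses $1/\infty = 0$, isolated
  nodes contribute $c_i = 0$. A graph with zero edges is an error, not a
  NaN.
* **Degenerate randomization**: if the random references of a very sparse
  graph have zero mean clustering, the small-world index is undefined and
  signalled as an error.
* **Nodal efficiency** follows the whole-network definition (propagation
  to all other nodes); the neighbourhood-subgraph "local efficiency"
  variant is available as `local_efficiency()` but is not used by the
  default profile.
* **NBS p-values** use the add-one permutation estimator
  $(b+1)/(n_{perm}+1)$, so no component ever gets $p = 0$. Both one-sided
  contrasts are evaluated by default, sharing one permutation set. A
  warning is raised when the design admits fewer distinct relabelings than
  requested permutations.
* **t-tests** default to pooled variance (Welch available); the edge-wise
  NBS statistic operates on raw correlations by default with a Fisher-z
  option.
* **ANOVA** uses the classic split-plot decomposition with no sphericity
  correction, and degenerates exactly to $F = t^2$ when the grid has one
  threshold.
* **Determinism**: every stochastic step (cohort generation, rewiring,
  permutations) takes a seed; the pipeline derives all stage seeds from
  one master seed and records them in the run manifest.

## Validation design and problem sizes

The test suite validates each measure against independent brute-force
implementations (explicit-loop degree/triangle counts, Floyd–Warshall
distances, definition-level modularity, exhaustive partition search at
small $n$) on 100 random graphs of up to 30 nodes, and checks closed-form
values on canonical graphs. Statistical calibration is checked by
simulation: the NBS family-wise error rate on 200 null cohorts (10 vs 10
subjects, 60 nodes, artifact-free, 500 permutations each), and the ANOVA
and nodal t-test null rejection rates over 500 simulated metric tables.
Effect recovery is demonstrated on a 13 vs 11 cohort of 60-node, 900-volume
subjects with the full artifact model and preprocessing chain, using 1000
NBS permutations at a primary threshold set to the one-sided $p < 0.01$
critical t for the design's degrees of freedom — the conventional way to
choose an NBS primary threshold when effect sizes are unknown. These sizes
keep the whole suite fast while leaving every code path exercised at full
fidelity; the pipeline itself runs unchanged at 150 nodes, 100 random
references and 10000 permutations, which are its defaults.

## Known limitations

* Binary undirected graphs only; no weighted or directed variants, no
  betweenness or hub classification.
* Pearson correlation only; no partial correlation or regularized
  precision estimation.
* Stationary connectivity is assumed throughout; the temporal masking
  step explicitly relies on it.
* The greedy modularity optimizer is the classic agglomerative heuristic;
  it can undershoot the true maximal $Q$ on graphs with subtle community
  structure (the suite only bounds it against exhaustive search at small
  $n$).
* The mixed ANOVA treats sparsity as a categorical repeated factor without
  sphericity correction; with 10 correlated levels this is anti-
  conservative for the within-subject effects, which is why group
  conclusions rest on the nodal and NBS layers.

## A minimal run

```{r example}
library(rsfcnet)

cfg <- run_config(
  cohort = cohort_spec(n_lesion = 6, n_sham = 6, n_nodes = 60,
                       n_hemisphere = 30, n_volumes = 900, n_modules = 3,
                       seed = 1),
  effect = effect_spec(reduced_block = 1:10,
                       increased_block = c(11:13, 41:43)),
  n_rand = 20, n_perm = 1000, seed = 42,
  output_dir = "rsfcnet_demo")
run_pipeline(cfg)
```

The run directory then contains the simulated cohort, preprocessed series,
correlation matrices, tidy metric tables, ANOVA and nodal test results,
the NBS edge list with component p-values, per-node abnormal-connection
counts, and a manifest with seeds and checksums for exact reproduction.
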