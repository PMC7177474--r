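---
title: "Geometry-based analysis of protein loop conformer ensembles"
author: "loopshape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry-based analysis of protein loop conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopshape)
```

## Scope and model

Surface loops of enzymes often gate access to the active site. Two
behaviours matter in practice: a *static* loop holds one arch shape and
varies mostly near its attachment points, while a *flexible* loop swings
its whole arch between conformations (for lid-like loops these group into
*closed*, *semi-open* and *open* states relative to the active site).
`loopshape` quantifies loop shape with nine plain Euclidean descriptors,
and builds three analyses on top of them:

1. **Representative selection** — reduce a large conformer ensemble
   (e.g. thousands of homology models of the same loop) to a few
   structurally diverse representatives.
2. **Flexibility classification** — call a loop static or flexible from
   the dispersion of its descriptors over the ensemble.
3. **State assignment** — assign trajectory frames to discrete loop
   states and report occupancies and transition counts.

A *loop* is specified by a chain, two anchor residues (the attachment
points), and one or more reference residues (typically a conserved
active-site tryptophan). By default the loop comprises the residues
strictly *between* the anchors; `includeAnchors = TRUE` counts the
anchors in. The choice is configurable because conventions differ on
whether attachment points belong to the loop; the anchors are treated as
fixed stems by default.

## The nine descriptors

For loop C-alpha positions $c_1,\dots,c_L$, anchor C-alphas $a_1,a_2$
with midpoint $\bar a$, and reference centroid $r$ (mean of the reference
residues' C-alphas):

| descriptor | definition |
|---|---|
| `loop_anchor_mean` | $\frac1L\sum_i \lVert c_i-\bar a\rVert$ — how far the arch bends from its stems |
| `loop_ref_min` | $\min_i \lVert c_i-r\rVert$ — proximity to the reference (active site) |
| `ach_ach_dist` | $\lVert a_1-a_2\rVert$ |
| `loop_max_distance` | $\max_{i<j}\lVert c_i-c_j\rVert$ |
| `every_two_mean` | mean of $\lVert c_i-c_{i+2}\rVert$ |
| `every_three_mean` | mean of $\lVert c_i-c_{i+3}\rVert$ (needs $L\ge 4$) |
| `loop_max_cons_distance_bb` | max distance between consecutive bonded backbone atoms (N–CA, CA–C, C–N′) |
| `loop_prot_sh` | min distance from any loop heavy atom to any non-loop protein heavy atom (`NA` without protein context) |
| `loop_prot_v2a` | convex-hull volume-to-area ratio of the loop heavy atoms |

All nine are invariant under rigid motion and scale linearly with the
coordinates; the test suite asserts both properties against an
independent brute-force implementation (tolerances $10^{-9}$ Å for
oracle agreement, $10^{-8}$ Å over 100 random rigid motions).

The convex hull is computed by an incremental hull in C++ (no suitable
hull package is available to this package); degenerate (rank < 3) point
sets return ratio 0 with a warning rather than failing. Closed forms fix
the implementation: a cube of side 2 Å gives exactly $1/3$ Å and a
regular tetrahedron of edge 1 Å gives $(\sqrt2/12)/\sqrt3 \approx
0.06804$ Å.

```{r descriptors}
gen <- generateLoopEnsemble(EnsembleSpec(nModels = 50, seed = 1,
                                         regime = "flexible"))
dm <- descriptorMatrix(gen$ensemble, gen$spec, scores = gen$scores)
round(descriptorValues(dm)[1:3, 1:5], 3)
```

## Representative selection

`runSelection()` implements: column standardization (mean 0, sample
sd 1) → PCA → K-means → one medoid per cluster, plus the lowest-DOPE
model as the conventional single-model baseline.

Parameters and rationale:

* `varianceRetained = 0.95` — retain the smallest number of principal
  components explaining ≥ 95 % of the variance. Standardization is
  applied first because the descriptors mix length scales.
* `k = 3` — default number of clusters/representatives; configurable.
  `silhouetteSweep()` reports mean silhouette widths over a k range as a
  diagnostic, but no automatic k selection is performed.
* `seed = 1`, `nInit = 10` — K-means uses k-means++ seeding and Lloyd
  iterations, keeping the best of `nInit` restarts; the seed makes the
  result deterministic. Empty clusters are repaired by reassigning the
  point farthest from its centre.
* `useScores = TRUE` — DOPE/SOAP score columns (when present) enter the
  PCA alongside the geometry; set `FALSE` for geometry only.
* "Median model" of a cluster is operationalized as the **medoid** in
  the reduced space (the member minimizing the summed Euclidean distance
  to its cluster mates; ties break to the lowest model index), because a
  multivariate median is otherwise not an actual model.

```{r selection}
res <- runSelection(dm, config = SelectionConfig(k = 3, seed = 1))
representatives(res)
```

## Flexibility call

`rsdProfile()` computes, per geometric descriptor, the relative standard
deviation $\mathrm{RSD} = 100\,s/\bar x$ (sample sd over mean, percent)
across the ensemble; RSD is unchanged by uniform rescaling of all
coordinates. `classifyLoop()` then applies a 2-of-3 rule over the three
*arch-shape* descriptors `loop_anchor_mean`, `loop_ref_min`,
`loop_max_distance` at a default threshold of 8 %:

* ≥ 2 over threshold → **flexible**
* 0 over threshold → **static**
* exactly 1 → **indeterminate**

`ach_ach_dist` is always reported but never votes: high anchor-distance
dispersion occurs in static ensembles too (the variability of a static
loop concentrates near its attachment points), so it cannot discriminate.
The threshold and the decision set are this package's operationalization
of the qualitative contrast; the threshold is configurable.

```{r classify}
classifyLoop(rsdProfile(dm))
```

## State assignment

`clusterStates()` pools frames from one or more runs, standardizes the
four state parameters (`loop_anchor_mean`, `loop_ref_min`,
`ach_ach_dist`, `loop_max_distance`), and K-means-partitions the pool
(same deterministic clustering as above). States are named by the
ascending mean raw `loop_ref_min` of their members — the state wrapped
closest to the reference is `closed`, the farthest `open`, the middle
`semi-open` (for k ≠ 3, ordinal names `state-1..k`). Per-run occupancies
and k×k transition-count matrices (diagonal included) come from the
per-run label sequences. Standardization before clustering is a package
choice and is flagged as such.

If a series has fewer distinct frames than `k` (e.g. a constant series),
the effective number of clusters is capped so the remaining states stay
genuinely empty instead of being force-split.

`averageStructure()` gives the per-atom coordinate mean (optionally after
Kabsch superposition of every model onto the first), and `kabschRmsd()`
the RMSD with or without optimal superposition (least-squares rotation
excluding reflections).

## The synthetic generator

`generateLoopEnsemble()` models a loop as $L$ C-alphas on a circular arc
joining two anchors, with pseudo N/C atoms ±1.2 Å along the local
tangent (plus a ±0.3 Å out-of-plane offset so the loop points are never
coplanar). Variability enters through three dials:

* `sigmaArch` (radians) — rotation of the arc plane about the
  anchor–anchor axis: whole-arch motion.
* `sigmaRadial` (fraction) — arc-radius jitter. The arc is rebuilt at the
  exact C-alpha spacing, so the anchor separation absorbs the radius
  change; consecutive loop C-alpha spacing stays within ±0.1 Å of
  `caSpacing` (default 3.8 Å) in every model.
* `sigmaAnchor` (Å) — jitter of the two anchor residues only.

Presets: `regime = "static"` (`sigmaArch = 0.02, sigmaAnchor = 0.6`)
pins the arch and wobbles the anchors; `regime = "flexible"`
(`sigmaArch = 0.6, sigmaRadial = 0.15`) swings the arch. These defaults
are the study conditions of the package's recovery tests. The `"shell"`
context surrounds the loop with 60 fixed pseudo-atoms on a hemisphere so
the contact descriptor is exercised. Pseudo-DOPE/SOAP scores are explicit
toys — the mean loop-to-context distance plus small noise — encoding only
the bias of statistical potentials towards compact conformations.

`generateStateSeries()` builds a state-switching trajectory: k arc
orientations (negative = rotated towards the reference = closed) with
per-state radius factors (a closed, wrapped loop is more compact than an
open one — without this, states would differ in only one of the four
parameters), geometric-like dwell segments hitting the target state
fractions *exactly*, and iid Gaussian coordinate noise per frame.

Deliberate non-goals of the generator: Ramachandran statistics, side
chains, clash checking, and any physically realistic sampling. It exists
to give ground-truth labels for the selection, classification and state
machinery, not to imitate a real conformer distribution.

## Numerical conventions

* Sample (n−1) standard deviation everywhere.
* PCA via singular value decomposition of the standardized matrix; each
  component's largest-magnitude loading is made positive so signs are
  reproducible. An eigen-decomposition oracle agrees to $10^{-9}$ in the
  tests.
* All stochastic steps (generation, k-means++) take explicit integer
  seeds; identical inputs and seeds give identical results, and
  generation restores the caller's RNG state.
* PDB coordinates are written in `%8.3f` columns; round-trips are exact
  on topology and within 0.001 Å on coordinates. Model ids read from a
  PDB are its MODEL numbers. Insertion codes are not supported (hard
  error); the highest-occupancy altloc is kept; hydrogens, waters and
  HETATM records are dropped on read by default.

## Limitations

* The 8 % threshold and the 2-of-3 decision set are fixed conventions of
  this package, not fitted quantities; borderline ensembles return
  `indeterminate` rather than a forced call.
* State naming assumes the closed state minimizes the loop-to-reference
  distance; exotic geometries violating that assumption would be
  mislabeled (the clustering itself is unaffected).
* `loop_prot_sh` is only as meaningful as the protein context provided;
  with no non-loop atoms it is `NA` and is dropped (with a warning) from
  downstream standardization.
* No significance testing of RSD differences, no solvent-accessible
  surface areas, no energy evaluation, and no full-scale homology-model
  or molecular-dynamics reproduction — those require external engines.
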