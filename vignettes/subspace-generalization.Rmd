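---
title: "Subspace generalization: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspace generalization: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subgen)
```

## The measure

Consider a population of `n` units (neurons or voxels) observed in two
tasks, giving two activity matrices `A1` and `A2` of size `units x states`
(states are spatial bins for rodent recordings, or experimental conditions
for fMRI betas). The question the package answers is: *does the
low-dimensional structure of the population carry over between the tasks?*

The second-moment matrix of each task (`A A^T`, optionally centered or
z-scored per unit) is summarized by its principal components — patterns
across units ordered by explained variance. Projecting task 2's states onto
the PCs of task 1,

```
V_k = sum_s ( u_k' a2_s )^2 ,
```

gives the variance of task 2 along each of task 1's directions. The
normalized cumulative sum of `V` over the PC index, prefixed with an origin
point and integrated by the trapezoidal rule with the index axis rescaled
to `[0, 1]`, is the **subspace generalization AUC**. If the leading
directions of task 1 also dominate task 2, the curve rises early and the
AUC approaches `1 - 1/(2K)`; if the two tasks are unrelated, the expected
variance along any fixed direction is flat and the AUC's expectation is
exactly 0.5 — the chance level, which holds for *any* data matrix by
linearity of expectation. `subspace_generalization()` symmetrizes the
measure by default, averaging both projection directions, and
`auc_difference()` forms the inferential statistic, the within-task
baseline AUC minus the across-task AUC.

This second-moment formulation deliberately ignores *when* each state
occurred: no correspondence between the states of the two tasks is needed,
which is what makes the measure applicable across environments (rodent) and
across stimulus sets (fMRI).

### Scaling modes

The literature this implements is not uniform about centering: covariance
wording appears alongside correlation-matrix recipes and raw uncentered
`B B^T` equations. We therefore expose `scaling_mode` as an explicit
parameter everywhere:

* `"zscored"` (per-unit center and scale, sample sd with `n - 1`) — default
  for firing-rate-map pipelines, matching the correlation-matrix recipe;
* `"raw"` — default for the beta-matrix (fMRI) pipeline, matching the
  uncentered printed equations;
* `"centered"` — the covariance reading, available throughout.

Z-scoring near-constant voxel maps amplifies their residual structure;
this is intended (it is exactly why randomly grouped, noise-free
pseudo-voxels still generalize; see below) but it means `"zscored"` must
not be applied to exactly constant units, which raise an error naming the
unit.

### AUC discretization

The cumulative curve gets an explicit origin `(0, 0)` and is integrated by
trapezoids over `K` equal steps. With this convention a uniform variance
profile gives exactly 0.5, so the printed chance level is a property of the
estimator, not an approximation; a single dominant component gives
`1 - 1/(2K)`. Eigenvalues below `1e-12` of the largest are clipped to zero;
ordering among tied eigenvalues is solver-dependent but cannot affect any
partial sum across the tie, hence no canonicalization is attempted. PC
signs are irrelevant because only squared projections enter.

## Rate maps from events

`make_ratemaps()` bins a 2-D session into (default) `64 x 64` half-open
bins (last bin closed), accumulates occupancy per bin (each position sample
carries the interval to the next sample; the final sample carries the
median interval) and spike counts (each spike takes the position of its
nearest time sample), and divides. Three conventions the source recipes
leave unstated are fixed and documented rather than guessed per call:

* occupancy epsilon 0.1 s — bins visited less than this are "unvisited";
* unvisited bins are `NA` and are imputed by the boxcar's renormalized
  neighborhood mean during smoothing (policy `"zero"` is available);
* the 5-bin boxcar renormalizes its kernel over in-bounds, visited bins,
  so constant maps are preserved exactly and no padding bias enters at the
  walls; mass is conserved up to this edge renormalization.

## The grid-cell simulator

A grid cell's map is a zero-thresholded sum of three 2-D cosines whose wave
vectors are 60 degrees apart with `|k| = 4*pi/(sqrt(3)*spacing)`; zero
clipping is the simplest reading of a "thresholded" sum and gives
non-negative hexagonal fields. A module places one cell at each node of a
(default) `116 x 116` lattice of phases tiling the unit rhombus — 13,456
cells — so the population mean map is constant up to discretization (the
test-suite bounds its coefficient of variation by 0.05). The evaluation box
is `10 x 10` at `50 x 50` resolution. Module spacings default to
`{3.0, 4.2, 5.9, 8.3}` box units — roughly sqrt(2) progression, the
standard module series — with staggered orientations.

**Realignment.** Across environments a module shifts coherently: every cell
receives the same phase offset, so relative phases — and with them the
cells' coactivation structure — are preserved. For multi-module
populations we make every module shift by the *same fraction of its own
unit cell* (`default_env2_shifts()`). During design we found that letting
modules draw independent shifts changes the *cross-module* covariances of
grouped pseudo-voxels enough to open a within-vs-between AUC gap an order
of magnitude above the 0.02 preservation bound the test-suite enforces,
destroying the property the simulation is supposed to exhibit; the
shared-fraction rule keeps the gap well inside that bound for arbitrary
fractions, which is the realignment concept the simulation encodes.
A caveat for exactness-minded readers: because maps are sampled on a
finite box, a shifted periodic pattern is not a permutation of its
unshifted samples, so pairwise cell correlations across environments are
preserved only to ~1e-2, not machine precision.

**Pseudo-voxels.** Cells are grouped `ratio_random` at random and the rest
by phase (lexicographic rhombus order cut into equal contiguous blocks;
with 4 groups per module, 3,364 cells per voxel at full scale). Cell maps
are peak-normalized before averaging so the random-vs-phase amplitude
contrast reflects phase coherence rather than absolute rate. Voxel noise
is zero-mean Gaussian per voxel per bin, added after averaging, sd 0 to
0.1 — the regime in which randomly grouped voxels fall to chance while
phase-grouped voxels degrade slowly.

**Place cells** are single Gaussian fields with uniformly drawn centers,
redrawn independently in environment 2 (global remapping): the
within-environment structure is intact while the across-environment
coactivation is destroyed, the control against which grid generalization
is dissociated.

## Resampling inference

All permutation p-values use the `+1` smoothing, `p = (1 + #{null <=
observed}) / (1 + n_perms)`, one-sided toward "difference smaller than
chance" (generalization); two-sided is a flag. The within-environment
baseline defaults to self-projection — the ceiling — with an odd/even
split-half mode available, since the source recipes never state how
"within" was computed.

* `permutation_test_identity()` permutes unit identities of the second
  environment and recomputes the within-minus-across statistic; the
  self-projection baseline is invariant under the shuffle, so the null
  isolates the across term.
* `matched_subsample_test()` subsamples control populations (without
  replacement) to the recorded grid-cell counts per animal and pools
  the resulting AUC differences across animals and draws.
* `lowres_bootstrap()` emulates voxel-like resolution from single cells:
  per draw and animal, two groups of 7 cells drawn *with* replacement
  (groups independent, the stricter reading; the same cells are used in
  both environments), averaged into one unit each; 400 draws evaluated in
  both projection directions give the 800-value distribution.
  Distributions are compared by the two-sample KS test, displayed as
  50-bin histograms smoothed with a 9-bin moving average.

## The cross-validated fMRI pipeline

For each held-out run `j` and ordered graph pair `(a, b)`: PCs come from
the mean beta matrix of graph `a` over the other runs; graph `b`'s held-out
matrix is projected; the curve is normalized by the held-out matrix's own
total variance (for a complete orthonormal basis this equals the summed
diagonal of the projected second-moment matrix). Entries are averaged over
the four folds, so diagonal entries always compare *different runs* of the
same graph and never a matrix with itself; all four fold assignments are
averaged rather than a fixed one. The full voxel basis is retained by
default (the rank is limited by the 10 conditions anyway); truncation is a
parameter.

The named contrasts are `structural`,
`[HlHl + HlHs + HsHl + HsHs] - [HlCl + HlCs + HsCl + HsCs]`, and `visual`,
`[HlHl + ClCl + HsHs + CsCs] - [HlHs + HsHl + ClCs + CsCl]`, with rows
indexing the PC-source graph.

Searchlights take the `k = 100` nearest in-mask voxels by Euclidean
distance on integer grid coordinates, center included, ties broken by
linear voxel index — deterministic and geometry-free. Group inference is a
one-sample t per voxel with a max-statistic sign-flip null: each iteration
flips each subject's map sign and records the maximum t over the mask, so
the per-voxel p-values are familywise-error corrected by construction. We
use the max statistic rather than a cluster-enhancement statistic: it keeps
the same permutation scaffold and inferential contract without introducing
cluster-forming parameters. When all `2^n_subjects` flip patterns fit in
the iteration budget the enumeration is exhaustive and p-values are exact
fractions; voxels with zero across-subject variance get `t = sign(mean) *
Inf` so the degenerate case stays well-ordered.

## Synthetic group data

`generate_beta_set()` plants the statistical structure the pipeline is
meant to detect: per run `r` and graph `g` the betas are `W_{g,r} Z_{g,r} +
noise`, with voxel loadings `W_{g,r} = sqrt(a) W_family + sqrt(1 - a) E`
mixing a structure-family loading matrix (`Hl`/`Hs` share one, `Cl`/`Cs`
the other) with fresh run-specific noise. The mixing weight `a` equals
`overlap` inside the effect region and 0 elsewhere, and the condition codes
`Z` are fresh draws for every run and graph. Two consequences matter: at
`overlap = 0` *nothing* is consistent across runs, so every AUC-matrix
entry sits at chance and contrasts are honestly null — the calibration
voxels; and any generalization the pipeline finds can only come from
shared voxel loadings, never from condition correspondence, which is the
stricter test of the method. Generators are pure functions of (spec, seed).

What the generator does *not* emulate: fMRI temporal autocorrelation, HRF
shape, physiological noise spectra, inter-subject anatomical variability
(synthetic subjects share one grid), or noise-normalized beta estimation.
Passing tests therefore demonstrate the estimator's statistical behavior
under its own assumptions, not robustness to fMRI preprocessing realities.

## Problem sizes used by the test-suite

The simulator's standard scale (four `116 x 116` modules, `50 x 50` box) is
used for the cell-count, chance-level, noise-free preservation and
noise-degradation checks; the noise sweep uses 50 grouping/noise draws at
the highest noise level plus a paired six-point noise grid over 8 draws.
The rodent-style dissociation uses populations of 20 cells sampled from a
reduced module (`20 x 20` phases, `30 x 30` box — the subspace statistics
depend on the sampled cells, not the lattice density behind them) over 100
seeds, 500-permutation identity tests over 50 seeds, and 200 bootstrap
draws. The group-level pipeline runs 12 synthetic subjects on a `6 x 6 x 6`
volume with a `3 x 3 x 3` planted block, 27-voxel searchlights and 1,000
sign flips, over 20 seeds; null-region calibration voxels are chosen so
their searchlights contain no planted voxel.

## Known limitations

* Box-sampling inexactness of realignment (above) puts a floor of ~1e-2 on
  cross-environment correlation preservation; the AUC-level effect is two
  orders of magnitude smaller.
* The pipeline starts at beta (or rate-map) matrices; first-level GLM
  estimation, registration and smoothing are out of scope.
* The KS comparison and one-sample t are delegated to base R; the package
  does not reimplement standard tests.
* Serialization uses delimited text (plus NIfTI-1 for volumes); container
  directories carry a JSON manifest. Binary scientific containers are not
  emitted.
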