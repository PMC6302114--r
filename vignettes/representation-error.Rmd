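---
title: "Evaluating neural input-state representations geometrically"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating neural input-state representations geometrically}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irmetric)
```

## The model

Feed-forward supervised-learning circuits such as the cerebellar granular
layer present a readout neuron (a Purkinje cell) with a population activity
pattern per input state.  With `m` distinct states and `n` input neurons,
the representation is an `m x n` non-negative matrix `C`: entry `C[k, l]`
is the activity effectiveness (typically a spike count per time slot) of
neuron `l` in state `k`.  The readout output is a weighted sum `d = C w`
with excitatory-only, hence non-negative, weights `w >= 0`.

The set of outputs the readout can realize is therefore the conical hull
of the columns of `C`,

    coni(C) = { C w : w >= 0 },

a pointed polyhedral cone in `R^m`.  For a desired output `d_des` the best
achievable fit is the non-negative least-squares (NNLS) solution, and the
committed error is the squared Euclidean distance from `d_des` to
`coni(C)`.  Since scaling `w` scales the output, it suffices to score the
representation over the unit hypercube of desired outputs.  The
representation error is the mean of that squared distance,

    Ir(C) = integral over [0,1]^m of  || s - C w_hat(s) ||^2  ds,

and its normalization `IrN(C) = Ir(C) / (m/3)` lies in `[0, 1]`: the
denominator is the value attained by the all-zero matrix, whose only
achievable output is the origin (`integral of ||s||^2 over the cube
= m/3`).  Low values mean the population code can be trained to any
output assignment; high values mean many state combinations interfere.

## The analytic pipeline

`representation_error(C)` computes `Ir(C)` exactly (up to geometric
tolerance) in five steps:

1. **Extreme rays** (`extreme_ray_indices`, `build_cone`).  Zero columns
   are dropped, columns are normalized to unit length (only direction
   matters), parallel duplicates keep the lowest index, and a column is
   discarded when its NNLS residual against the remaining candidates is
   below `1e-18`: it is then a conical combination of the others and
   does not change the hull.
2. **Face lattice** (`build_cone`).  Facets of the cone are enumerated by
   brute force over ray subsets within the cone's linear span; proper
   faces are the closures of intersections of facet incidence sets,
   which for a simplicial cone with `r` rays reduces to all `2^r - 2`
   nonempty proper ray subsets.  When the columns span only a
   `d < m`-dimensional subspace, the cone itself is kept as a face: its
   points still carry a positive residual in the ambient space.
3. **Adjacent cones** (`adjacent_cone`).  The points projecting onto a
   face form the face plus its normal cone, generated by the face rays
   and the outward normals of incident facets; for a degenerate cone the
   orthogonal complement of the span is attached as a lineality space.
4. **Regions** (`intersect_with_cube`, `partition_cube`).  Each adjacent
   cone is converted to halfspace form and intersected with `[0,1]^m`;
   polytope vertices are enumerated from all constraint subsets, and the
   polytope is triangulated by coning a vertex over recursively
   triangulated facets.  Regions of volume below `1e-12` are dropped.
5. **Closed-form integration** (`residual_projector`,
   `integrate_quadratic_over_simplex`, `integrate_region`).  On the
   region of face `F` the squared distance is the quadratic form
   `s' Q s` with `Q = I - P_F` the projector complement of the face
   span.  Over a simplex with vertices `v_0..v_d` the integral is

       Vol * ( V' Q V + sum_i v_i' Q v_i ) / ((d+1)(d+2)),  V = sum_i v_i,

   the exact order-two moment of the uniform simplex distribution.  The
   formula was validated against a brute-force Monte-Carlo oracle (10^6
   uniform samples per simplex) on one- and two-dimensional reference
   integrals and random higher-dimensional cases; the test suite repeats
   this comparison at smaller sample sizes.

The per-region integrals are summed to give `Ir(C)`; the volume not
covered by any region is the achieved-output volume
(`achieved_output_volume`), the fraction of desired outputs realizable
with zero error.

Two design choices deserve mention.  First, region vertices are
enumerated from the halfspace representation rather than by pairing cone
elements with cube elements by dimension; the H-representation route
handles lineality spaces and non-simplicial cones uniformly and subsumes
the dimension-pairing enumeration.  Second, the apex region is
enumerated only for the all-zero matrix: for any cone with a nonzero
non-negative ray, every interior cube point has positive inner product
with that ray, so the polar cone meets the cube in a measure-zero set.
The all-zero matrix short-circuits to the closed form `Ir = m/3` rather
than running the apex machinery.

## Numerical evaluators

`method = "grid"` implements the midpoint rule: the mean squared NNLS
residual over the `N^m` cell midpoints `((n1..nm) - 1/2) / N`.  The
default `N = 16`; grids beyond `10^7` midpoints are refused with a
pointer to the Monte-Carlo evaluator, which averages over uniform random
samples and reports a standard error.

Both evaluators compute the squared distance of many points to the cone
with a vectorized exact solver: after extreme-ray reduction, the NNLS
projection is supported on at most `m` linearly independent rays, so
minimizing the restricted least-squares residual over all feasible ray
subsets attains the optimum for every point simultaneously.  The test
suite asserts pointwise equality (to `1e-10`) with per-point
Lawson-Hanson NNLS solves; single-point queries
(`solve_nonneg_weights`) use Lawson-Hanson directly.

## Tolerances and degenerate inputs

All geometric predicates operate on unit-normalized data with absolute
tolerance `1e-9` (exposed as the `tol` argument and the `geometry.tol`
config key of the command-line interface); vertex de-duplication and
polytope feasibility use `1e-8`; volumes below `1e-12` are treated as
empty; NNLS residuals below `1e-18` classify a point as covered.
Matrices whose columns span a strict subspace (including a single
column) are handled by working inside the span and attaching its
orthogonal complement as lineality, a case the geometric construction
must cover even though typical spike-count matrices are full rank.  The
normalized score is clamped to `[0, 1]` within `1e-9` of the bounds;
an analytic value outside that band raises an internal-consistency
error, while a Monte-Carlo estimate may exceed `m/3` by sampling noise
and is clamped silently.

Spike binning uses half-open slots `[(k-1) t_s, k t_s)`, so a spike on a
boundary belongs to the later slot; the convention is a package decision
(any fixed convention conserves counts and determinism is what matters).

## What the random generator emulates

`random_state_matrix` draws entries that are zero with probability
`sparsity` (default 0.3) and otherwise uniform on `value_range` (default
`[0, 10]`), emulating a sparse population code with up to ~10 spikes per
slot.  Real granule-cell activity is temporally structured, correlated
across neurons and integer-valued; the generator reproduces none of
that, so passing property suites demonstrates the geometry and the
metric's invariances (column scaling, permutations, redundancy,
monotonicity under column addition), not biological realism of the
inputs.

## Problem sizes and limitations

Brute-force facet, vertex and subset enumeration is exponential in `m`;
the package targets the regime the metric is used in, small numbers of
states (`m` up to ~5-6) with any number of neurons, since columns
collapse to at most a handful of extreme rays.  The test and validation
suites run at `m` in `2..5`, with random suites of 100 matrices for the
normalization range, 20 matrices for analytic-versus-Monte-Carlo
agreement at `10^5` samples, and grid resolutions up to `N = 20`.
Exact rational arithmetic is not used, so adversarially near-degenerate
cones could in principle misclassify a facet at the `1e-9` scale.
Weighted or non-uniform state-occurrence probabilities and
signed-weight (excitatory/inhibitory) readouts are out of scope: the
metric assumes equal state relevance and non-negative inputs and
weights throughout.
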