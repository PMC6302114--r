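# irmetric

Geometric evaluation of neural input-state representations for
supervised-learning circuits with excitatory (non-negative) coding, such
as the cerebellar granular layer feeding Purkinje cells or the avian
inferior colliculus.

## The problem and the metric

A readout neuron receiving `n` inputs across `m` distinct input states
sees the representation as an `m x n` non-negative activity matrix `C`
(rows = states, columns = neurons; entries are spike counts per time
slot, or real-valued effectiveness measures).  With non-negative
synaptic weights the outputs it can produce are exactly the conical hull
of the columns,

```
coni(C) = { C w : w >= 0 },
```

so some assignments of desired outputs to states cannot be learned at
all.  The representation error scores `C` without running any
simulation or training: it is the squared distance from a desired
output vector `s` to the hull, averaged over every possible assignment
in the unit hypercube,

```
Ir(C)  = ∫_[0,1]^m  || s − C ŵ(s) ||²  ds ,      ŵ(s) = argmin_{w ≥ 0} || s − C w ||²
IrN(C) = Ir(C) / (m/3)                            ∈ [0, 1]
```

`IrN = 0` means every output assignment is learnable (best case,
e.g. columns containing all standard basis vectors); `IrN = 1` is the
all-zero matrix (only the zero output is achievable).  The package
computes `Ir` **analytically** — enumerate the extreme rays and face
lattice of `coni(C)`, partition `[0,1]^m` into the polytope regions
closest to each face, and integrate the residual quadratic form in
closed form over each region — and **numerically** by the midpoint rule
or Monte-Carlo sampling with a non-negative least-squares solve per
point, which serve as independent cross-checks.

## Worked example

The 3-state, 3-neuron reference matrix:

```r
library(irmetric)
C <- example_matrices()$three_state_3n
representation_error(C)
#> input-representation error (analytic method)
#>   C: 3 states x 3 neurons; extreme-ray columns: 1, 2, 3
#>   Ir  = 0.0249   (full precision 0.0248692060448)
#>   IrN = 0.0249
#>   achieved-output volume = 0.3730
```

All three columns are extreme rays of the cone, whose face lattice has
6 proper elements (3 two-dimensional faces, 3 edges).  The unit cube
splits into 5 positive-volume integration regions — the region of the
third edge is empty — plus the 37.3% of output space covered by the
hull itself (zero error):

```r
representation_error(C)$per_region
#>   face_dim rays     volume    integral
#> 1        2  1,2 0.12281197 0.003264966
#> 2        2  1,3 0.27065527 0.013587552
#> 3        2  2,3 0.13148148 0.002092593
#> 4        1    1 0.06604507 0.004571105
#> 5        1    2 0.03599034 0.001352990
```

The contributions sum to `Ir = 0.0249`: a good representation, since
most of the cube is close to (or inside) the achievable cone.  The
midpoint-rule evaluator converges to the same value
(`representation_error(C, method = "grid", grid_n = 20)` gives 0.0247).

A command-line interface covers the same operations on files:

```sh
exec/irmetric evaluate --input states.txt --method analytic
exec/irmetric bin-spikes --input spikes.txt --slot-duration 0.1 --num-slots 4 --num-neurons 3
exec/irmetric generate --m 3 --n 10 --sparsity 0.3 --seed 7 --output states.txt
```

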