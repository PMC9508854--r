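---
title: "Methods: chromatin unfolding analysis at nucleosome resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin unfolding analysis at nucleosome resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoclutch)
```

# The problem and the data model

A nucleosome wraps ~147 bp of DNA around a histone octamer; a string of
nucleosomes (chromatin) can fold into a compact two-start zigzag fiber in
which nucleosome *i* stacks on nucleosome *i + 2*. Under piconewton pulling
forces, and in crowded environments with inter-chain contacts, the fiber can
instead unfold into irregular configurations with nucleosome *clutches* —
trimers/tetramers held together by stacking, separated by unwrapped DNA.
This package implements the quantitative machinery for studying that
unfolding at nucleosome resolution.

Each nucleosome is reduced to a rigid body: a geometric center (nm), an
orthonormal frame whose `normal` is perpendicular to the nucleosomal plane,
and a scalar wrap fraction `w`. Only the outer DNA layer detaches at low
force, so `w` is confined to `[0.5, 1]`: `w = 1` is fully wrapped, `w = 0.5`
has the whole outer layer released while the inner wrap stays bound. A
configuration is one or two chains of such frames; bead-level input (e.g. a
LAMMPS text dump plus a bead-to-nucleosome map) is converted to frames
immediately (centers are unweighted bead means; axes are principal
components of the wrapped-DNA beads, with the smallest-variance axis as the
normal — the choice of bead set for the "geometric center" is a convention
of this package, since only the frame-level quantities enter the analysis).

DNA endpoints for end-to-end extension are, for frame-only data, the
terminal nucleosome centers optionally extrapolated outward along the
terminal linker direction (`overhang`, default 0 nm); explicitly stored
endpoints take precedence. The zero default keeps the extension a pure
function of the frame table and makes generator examples exact.

# Collective variables

* `d_stack`: mean of `|c_i − c_{i+2}|` over the chain, nm. Small (≈6 nm) in
  a stacked fiber, large when unstacked. For two chains the dispatcher
  averages the per-chain values, which is the two-chain extension coordinate.
* `q_wrap`: mean wrap fraction. The frame-level definition is used
  throughout; for bead-level data `q_wrap_beads()` scores the fraction of
  outer-layer DNA beads within 1 nm of their wrapped-reference positions, a
  model variant calibrated so a fully wrapped nucleosome scores 1.
* `alpha = max d_{i,i+2} / min d_{i,i+2}`: the clutch ratio. Exactly the
  (i, i+2) pair set is used — no wrap-around pairs. α = 1 iff all (i, i+2)
  distances are equal; clutched configurations give α ≫ 1 because bridges
  between clutches dwarf intra-clutch distances.
* `shear/normal`: the displacement to another nucleosome decomposed in
  nucleosome *i*'s plane, `normal = |r·n_i|`, `shear = |r − (r·n_i) n_i|`,
  so `shear² + normal² = |r|²`. The decomposition is asymmetric in (i, j)
  by construction; a symmetrized variant averages both orderings.
* `inter_chain_contacts`: nucleosome pairs, one per chain, strictly closer
  than 15 nm. The strict `<` makes ties at the cutoff (a measure-zero event)
  excluded, so the count is insensitive to the convention.
* `ee_per_nuc` / `ee_z`: end-to-end distance (or its signed z component)
  divided by the chain length. Under a constant z-axis pulling force the
  signed z projection is the thermodynamically conjugate coordinate, so all
  force reweighting defaults to it.

# The toy simulator

The sampler stands in for cluster-scale residue-level molecular dynamics:
it is a nucleosome-level toy model built to reproduce the *statistical
structure* the analysis assumes, not a re-parameterization of any
residue-level force field. Energy terms (kcal/mol, nm):

| term | form | defaults | rationale |
|---|---|---|---|
| stacking | `−eps_stack · exp(−(r − r_stack)²/2w²) · (n_i·n_j)² · ½((r̂·n_i)² + (r̂·n_j)²)` | 3.0 at 6.0 nm, width 1.5 | face–face coaxial stacking is favorable; side-side contact gains nothing from this term — the stacking/side-side asymmetry that drives fiber formation |
| excluded volume | `eps_rep / s¹²`, `s²` the smaller of the two frame-ellipsoid scalings | 0.5; semi-axes 10 (in-plane) / 5.5 (normal) | nucleosomes are oblate: ~11 nm wide, ~5.5 nm tall |
| linker | asymmetric spring about rest length `L0 + (λ/2)[(1−w_i) + (1−w_j)]` | `k_link` 30 beyond rest, 0.2 under; `L0` 10.5; `λ` 13.6 | DNA cannot stretch past its contour (stiff branch) but slack linkers bend cheaply (soft branch). A symmetric spring would let the chain extend indefinitely at quadratic cost and erase the unwrapping physics entirely. `L0` matches the neighbor distance in the generated fiber; `λ` is the linker contour released per unit unwrapping (~40 bp over the full outer layer) |
| unwrapping | `eps_unwrap · (1 − w)` | 8 | full outer-layer release costs 4 kcal/mol and buys 6.8 nm of contour, so unwrapping becomes thermally competitive near 4 pN — the force regime where clutches appear |

`allow_unwrap = FALSE` freezes `w`, mirroring control simulations in which
the full 147 bp of nucleosomal DNA is rigidified with the core.

Moves are single-nucleosome rigid translations (uniform in ±0.8 nm), rigid
rotations (random axis, uniform angle in ±0.35 rad) and wrap increments
(uniform in ±0.05, reflected at the `[0.5, 1]` boundaries) — each proposal
symmetric, so Metropolis acceptance at `kB·300 K = 0.596 kcal/mol`
satisfies detailed balance; the test suite verifies the sampled
distribution of a harmonically tethered nucleosome against the exact
Boltzmann Gaussian (Kolmogorov–Smirnov at 10⁵ samples) and that the
incrementally updated total energy agrees with a from-scratch recompute to
10⁻⁶ kcal/mol over ≥10⁴ moves. A constant force `f` (pN) along z enters the
energy as `−f·(z_last − z_first)/6.948`, using the fixed conversion
1 kcal/(mol·nm) = 6.948 pN. R's RNG drives the C++ kernel, so a seed gives
bitwise-identical trajectories.

What the generators emulate — and what they do not: `generate_fiber`,
`generate_clutch` and `generate_uniform` produce idealized geometries whose
collective variables are exact by construction (the clutch generator keeps
the lateral alternation global, so within-clutch (i, i+2) distances are
exactly `intra` and bridges exactly `gap`, making α = gap/intra to machine
precision). The toy ensemble reproduces, qualitatively: a compact low-force
state; a linear-then-flattening force–extension curve; unwrapping becoming
populated near 4 pN; and a 4 pN α free-energy minimum strictly higher with
unwrapping than without. It does *not* reproduce residue-level energetics,
sequence effects, histone tails, electrostatics (beyond the Debye-length
helper), or experimental force–extension magnitudes — passing tests say the
analysis pipeline is correct and the toy physics is qualitatively right, not
that real chromatin numbers are predicted. In particular, with the default
energy scales the constant-force 4 pN minimum is *not* a hard clutch state:
uniform unstacking is slightly cheaper per nanometer than unwrapping, so the
α separation between the unwrapping and rigid-DNA ensembles comes from wrap
heterogeneity (released contour concentrating on a few linkers) rather than
from long-lived trimers. The ordering of the minima — the property the
analysis checks — is robust across seeds; the magnitude of the separation is
model-dependent and should not be over-read.

# Free-energy reconstruction

`wham()` is a standard self-consistent weighted-histogram estimator, in log
space, iterated until the window free energies change by less than
10⁻⁷ kcal/mol (cap 10⁵ iterations). Binning defaults to 100 bins (1D) or
50×50 (2D) spanning the sampled range; bins never visited are `NA`, never
zero, and are propagated as missing — not interpolated. The profile minimum
is referenced to 0. Window-overlap failures are detected as disconnected
components of the graph joining windows that share at least one occupied
bin; the profile is then flagged and a warning raised rather than silently
returning garbage.

Errors follow the three-block protocol exactly: each window's series is cut
into three equal consecutive blocks, the estimator is re-run per block, and
the sample standard deviation (ddof 1) of the three estimates is the error
of the mean. Autocorrelation within blocks is deliberately not subtracted.
Fixing one grid (`grid_from_windows()`) across the block re-estimates keeps
the per-bin errors aligned.

Force–extension prediction tilts the zero-force profile,
`F_f(x) = F_0(x) − f·x·n_scale/6.948` (with `n_scale = n` for
per-nucleosome axes), and takes the Boltzmann mean over defined bins. The
fluctuation identity `d⟨x⟩/df = Var(x)/kBT ≥ 0` guarantees monotonicity,
which the suite checks on random landscapes. `harmonic_fit()` fits the bins
within 2 kcal/mol of the minimum and flags anharmonicity when the RMS
residual exceeds 0.25 kcal/mol (a threshold of this package) or the
curvature is non-positive — the flat-bottomed high-force profiles are
exactly the flagged case. Both analysis routes for pulling data are
provided: reweighting the 0 pN profile and direct constant-force means; the
acceptance suite checks they agree within overlapping three-block error
bars at 1–3 pN.

`debye_length()` evaluates κ⁻¹ = sqrt(ε₀εr kBT / 2NAe²I); at 150 mM, 300 K,
εr = 78.4 the conventional 4κ⁻¹ electrostatic truncation is 3.14 nm.

# The surrogate free-energy model

The surrogate maps the vector of pairwise nucleosome center distances
(fixed i<j order; 6 entries for a tetranucleosome, 66 for a 12mer) through
z-scoring (training statistics stored in the model; population standard
deviation, so duplicating the training set changes nothing) into a small
tanh MLP (two hidden layers, 64 units each — the shape is a design choice,
as is the smooth activation, which force matching requires) producing one
scalar energy. Training minimizes the mean squared deviation between
`−∇_centers E` and supplied reference mean forces. The gradient of that
loss with respect to the weights is computed analytically (reverse-mode
differentiation through the gradient network), verified against finite
differences in the tests, and optimized with full-batch Adam — full-batch
deliberately, so training is deterministic given the seed and exactly
invariant under duplication of training examples. The reported quality
metric is the held-out force RMSE relative to the RMS reference force.

Longer chains are scored as the sum of the model over all sliding windows
of its native size (i…i+3 for a tetranucleosome-trained model). This
composition rule is this package's reading of how tetranucleosome
energetics transfer to a 12mer — the natural additive choice, documented as
such rather than claimed unique. `mc_most_probable()` then searches
configuration space by Metropolis sampling of the surrogate plus umbrella
biases, returning the lowest-energy configuration visited; a 4 nm minimum
center separation keeps features inside the training domain, where the
network interpolates instead of extrapolating (held-out errors concentrate
in configurations far outside the training distribution). The surrogate's
role is bounded on purpose: it proposes initial/most-probable structures;
every quantitative result is recomputed by the toy simulator and WHAM.

# Clustering and representatives

RMSD is computed over nucleosome centers (the resolution of the data model)
after Kabsch superposition with the usual determinant correction; it is
symmetric and zero for rigid-motion copies, but superposition RMSD does not
satisfy the triangle inequality and nothing here assumes it does.
Single-linkage clustering at cutoff `c` is implemented as connected
components of the strict `dist < c` graph via union–find (equivalent to
cutting the single-linkage dendrogram at `c`, which the tests verify against
`hclust`), the default cutoff being 3 nm — half the stacking distance, a
package choice. Representatives are medoids (minimum summed RMSD within the
cluster; ties broken toward the lowest trajectory index), and
`select_representatives()` reproduces the force-dependent protocol: filter
to configurations near the target mean extension, cluster, return the
medoids of the most populated clusters.

# Pipeline, problem sizes and limitations

`run_experiment()` chains the stages — extension umbrella windows at 0 pN
from the fiber, WHAM with block errors, tilted force–extension table,
constant-force runs per force for α profiles and representative PDB
structures, optionally the paired rigid-DNA comparison at 4 pN — and writes
a manifest with MD5 hashes so reruns are bit-identical. Any stage failure
aborts with the stage name. Defaults are desk-scale by design: 10⁴–10⁵
Monte Carlo sweeps per window and ~14 extension windows give converged toy
profiles in minutes on one CPU, and those are the problem sizes used
throughout the tests and the acceptance script (2 000 training
configurations and 3 000 Adam iterations for the surrogate; 8 windows ×
5×10⁴ exact samples for the WHAM oracle; 2 × 6×10⁴ sweeps per condition for
the 4 pN comparison). Production-scale equivalents are a matter of raising
`steps` and window counts in the experiment config.

Known limitations: the toy model's clutch physics is qualitative (see
above); q_wrap umbrella centers below 0.5 are legal as bias targets but
unattainable, since the wrap coordinate is bounded; two-chain support
covers the collective variables and the sampler, while two-chain
free-energy surfaces are left to the same WHAM machinery with user-built
windows; and the surrogate extrapolates poorly outside its training
distance distribution, which is why its sampler enforces the minimum
separation and why its stated accuracy is a held-out, not extrapolation,
error.
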