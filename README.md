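# chromoclutch

Nucleosome-resolution analysis of how chromatin fibers unfold under tension
and crowding.

Chromatin *in vitro* readily folds into compact two-start zigzag fibers, yet
such fibers are rarely seen *in vivo*, where imaging instead reveals small
nucleosome *clutches* — trimers and tetramers separated by stretches of
unwrapped DNA. One proposed reconciliation is mechanical: pulling forces in
the piconewton range (and contacts with neighboring chromatin chains)
unfold the fiber through clutched intermediates rather than through uniform
extension. This package provides the quantitative toolbox for studying that
scenario at nucleosome resolution, for computational chromatin biophysicists
who want the analysis layer without a cluster-scale residue-level force
field:

* **Data model & I/O** — nucleosome rigid-body frames (center, orthonormal
  axes, outer-layer wrap fraction `w ∈ [0.5, 1]`), one- and two-chain
  configurations, frame-table CSV, extended-XYZ trajectories, JSON window
  metadata, pseudo-atom PDB export (wrap as B-factor), a LAMMPS-dump text
  reader, and residue-level bead accounting (one bead per amino acid, three
  sites per nucleotide, 5'-terminal phosphates omitted: the 12×147 bp + 11×20
  bp 12mer counts exactly 23 590 sites).
* **Collective variables** — the stacking distance
  `d_stack = mean |c_i − c_{i+2}|`, the wrapping degree `q_wrap`, the clutch
  ratio `α = d_max/d_min` over (i, i+2) distances (α ≈ 1 for uniform
  extension, α ≫ 1 for clutches), shear/normal decomposition of
  inter-nucleosome displacements, per-nucleosome end-to-end extension, and
  inter-chain contacts at a 15 nm cutoff.
* **Toy simulator** — a Metropolis Monte Carlo sampler (C++ core) of a
  nucleosome-level energy model with anisotropic stacking wells,
  contour-limited linkers, and an unwrapping coordinate that trades an
  energetic penalty for released linker length; umbrella and constant-force
  (z-axis, pN) biases; `allow_unwrap = FALSE` reproduces rigidified-DNA
  control simulations.
* **Free energies** — self-consistent WHAM in 1D/2D, three-block error bars,
  profile tilting `F_f(x) = F_0(x) − f·x/6.948`, Boltzmann mean extensions
  (force–extension curves), harmonic fits near the minimum, and the Debye
  screening length (4κ⁻¹ = 3.14 nm at 150 mM).
* **Surrogate model** — a small MLP free-energy model over pairwise
  inter-nucleosome distances trained by force matching (exact analytic
  gradients), with exhaustive Monte Carlo search for most-probable
  configurations under umbrella biases.
* **Clustering** — Kabsch-superposition RMSD, single-linkage clustering at a
  cutoff, and medoid (central-configuration) extraction of representative
  structures near a target extension.

## Worked example

```r
library(chromoclutch)

# the 12mer two-start fiber and a clutched configuration
fiber  <- generate_fiber(12)
clutch <- generate_clutch(12, c(3, 3, 3, 3), intra = 6, gap = 24)
sprintf("fiber : d_stack = %.1f nm, alpha = %.2f", d_stack(fiber), alpha(fiber))
sprintf("clutch: d_stack = %.1f nm, alpha = %.2f", d_stack(clutch), alpha(clutch))

# umbrella sampling on the extension, WHAM, force-extension prediction
model   <- toy_energy_model()
windows <- lapply(0:13, function(w)
  sample_window(model, fiber, umbrella_bias("ee_z", w, 5),
                steps = 20000, seed = 100 + w))
profile <- wham(windows, grid_from_windows(windows))
for (f in 0:4)
  cat(sprintf("f = %d pN: <ee/nuc> = %5.2f nm\n", f,
              mean_extension(profile, f, n_scale = 12)))
```

prints

```
fiber : d_stack = 6.0 nm, alpha = 1.00
clutch: d_stack = 16.8 nm, alpha = 4.00
f = 0 pN: <ee/nuc> =  3.08 nm
f = 1 pN: <ee/nuc> =  6.89 nm
f = 2 pN: <ee/nuc> =  8.68 nm
f = 3 pN: <ee/nuc> = 10.05 nm
f = 4 pN: <ee/nuc> = 11.26 nm
```

The fiber is maximally stacked and perfectly regular (α = 1); the clutch
generator's bridging (i, i+2) distances are exactly the 24 nm gap, so
α = 24/6 = 4. Reweighting the zero-force profile shows the familiar shape of
a pulling curve: a steep linear rise at low force and flattening growth
beyond ~3 pN. Comparing constant-force runs at 4 pN with and without DNA
unwrapping,

```
alpha minimum at 4 pN: 1.38 (unwrapping) vs 1.19 (rigid DNA)
```

the free-energy minimum of α sits strictly higher when unwrapping is
allowed: released linker length accumulates on a few nucleosomes, so
extension is irregular, whereas rigid-DNA chains must extend uniformly.

A complete experiment (umbrella windows → WHAM → force–extension → α
profiles → representative PDB structures, with a hashed manifest for
bit-identical reruns) runs from one declarative config via
`run_experiment(experiment_config(...))`, or from the shell through the thin
CLI in `scripts/chromoclutch.R` (subcommands `simulate`, `cv`, `wham`, `fx`,
`cluster`, `report`).

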