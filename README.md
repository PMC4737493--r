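# gsdyn

Ensemble analysis of glutamine synthetase (GS) dynamics, solvation,
energetics, and rigidity.

## The scientific problem

Human glutamine synthetase (EC 6.3.1.2) catalyzes the ATP-dependent ligation
of glutamate and ammonia to glutamine. Three clinically relevant point
mutations — R324C, R324S, and R341C — impair catalysis through distinct
molecular mechanisms: loss of a direct arginine/β-phosphate salt bridge to
ATP (partially rescued in R324S by water-mediated hydrogen-bond bridges),
destabilization of the substrate-anchoring residue R340 in the apo enzyme,
and long-range mechanical destabilization of helix 8 (residues ~266–288),
which gates glutamate binding.

Dissecting such mechanisms from molecular-dynamics ensembles requires a
reproducible chain of analyses: geometric ensemble statistics, water-bridge
detection, binding-energy aggregation with error propagation, and
rigidity-theoretic stability maps. `gsdyn` implements that chain as a tested
R package for structural bioinformaticians, with synthetic-ensemble
generators carrying machine-readable ground truth so every stage is
verifiable without multi-microsecond trajectories.

## What the package computes

* **Ensembles** — multi-model PDB I/O (fixed-width v3.3), a small atom
  selection grammar, replicate bookkeeping with the
  mean ± SEM-across-replicates convention.
* **Geometry** — Kabsch superposition; RMSD series with separate fit and
  measure selections; RMSF about the iterated mean structure; the 90%
  lowest-RMSF core region; centroid/min distances.
* **Interactions** — hydrogen bonds with the heavy-atom distance criterion
  (≤ 2.8 Å strong, ≤ 3.2 Å weak, donor–H–acceptor angle ≥ 120°, inclusive
  boundaries), salt bridges at d < 4.0 Å (strict), interaction occupancies.
* **Solvation** — water density grids on a 0.33 Å cubic lattice with
  80%-of-maximum isopleth thresholds and OpenDX export; radial distribution
  functions g(r) with periodic (N/V) or count-matched normalization;
  water-mediated hydrogen-bond bridges (chains through 1–3 waters, every
  link satisfying the criteria of the requested class).
* **Secondary structure** — Kabsch–Sander electrostatic hydrogen-bond
  energies (bond iff E < −0.5 kcal/mol) restricted to helix classes, and
  per-residue loop probabilities.
* **Energetics** — 1-trajectory effective binding energies
  ΔG = E(complex) − E(receptor) − E(ligand) per frame, from a documented toy
  model (screened Coulomb at ε_int = 4 + Lennard-Jones + γ·ΔSASA) or an
  external per-frame component table; least-squares drift slopes; relative
  binding energies ΔΔG = ΔG_mutant − ΔG_wild-type with root-sum-square SEM
  propagation (SEM = √(SEM₁² + SEM₂² + SEM₃²), SEM_total =
  √(SEM_mut² + SEM_wt²)) and a one-sample t-test against 0; conversion to
  association-constant changes, fold = exp(ΔΔG/RT).
* **Rigidity** — body-bar constraint networks (rotatable bonds 5 bars,
  locked bonds 6, hydrogen bonds/salt bridges 5 with Mayo-potential
  energies, hydrophobic tethers 2), the (6,6) pebble-game rigid-cluster
  decomposition, thermal unfolding over the 0–6 kcal/mol cutoff ladder in
  0.1 steps, per-residue-pair stability maps rc_ij, and Welch-tested
  difference maps Δrc_ij.
* **Synthetic data** — seeded generators for harmonic (Gaussian-fluctuation)
  ensembles, binding-site water bridges with designed occupancy, helix/coil
  switching with designed loop probabilities, effective-energy series with
  designed mean/drift/noise, and random generic bar networks.

## Worked example

Two binding-site ensembles with designed water-bridge occupancies emulating
the serine and cysteine mutants, followed by a relative binding energy and
its thermodynamic conversion:

```r
library(gsdyn)

g_ser <- gen_bridge_site(gap = 7.5, occupancy = 0.310, n_bridge_waters = 2,
                         n_frames = 1000, n_replicates = 3, seed = 1)
g_cys <- gen_bridge_site(gap = 7.5, occupancy = 0.118, n_bridge_waters = 2,
                         n_frames = 1000, n_replicates = 3, seed = 2)
freq <- function(g) bridge_frequency(g$ensemble, "name OG", "name O1 O2 O3",
                                     class_level = "strong",
                                     equilibration = 0.2)
freq(g_ser)
#> 0.3146 +/- 0.002732 (SEM, n = 3 replicates)
freq(g_cys)
#> 0.1158 +/- 0.00532 (SEM, n = 3 replicates)

wt  <- gen_energy_series(mean = -24.29, slope = 0.02, noise_sd = 2,
                         n_frames = 2000, seed = 3)
mut <- gen_energy_series(mean = -20.00, slope = 0.02, noise_sd = 2,
                         n_frames = 2000, seed = 4)
dd <- delta_delta_g(mean_binding_energy(mut), mean_binding_energy(wt),
                    labels = c("R324S", "wild type"))
dd
#> ddG(R324S - wild type) = 4.230 +/- 0.268 kcal/mol, p = 5.1e-05
conv <- kassoc_change(dd, temperature = 300)
sprintf("fold decrease: %.0f (%.2f log10 units)", conv$fold,
        conv$log10_units)
#> "fold decrease: 1207 (3.08 log10 units)"
```

The bridge frequencies recover the designed occupancies (0.310 and 0.118)
within replicate SEM; the designed 4.29 kcal/mol offset is recovered as
ΔΔG = 4.23 ± 0.27 kcal/mol, i.e. a ~1200-fold weaker association constant.

A full pipeline run (validation → geometry → solvation → energetics →
rigidity, with TSV/JSON/OpenDX artifacts and a MANIFEST) is one call:

```r
run_pipeline(demo_config(seed = 1, outdir = "gsdyn_run"))
```

or from the shell via the thin dispatcher `inst/cli/gsdyn`
(`gsdyn run --seed 1 --out gsdyn_run`).

## Selection grammar

`select_atoms(top, expr)` accepts: `resid N` / `resid N-M`, `resname X`,
`name X [Y ...]`, `chain A`, `element O`, the bare classes `water`,
`protein`, `all`, combined with `and`, `or`, `not`, and parentheses.
Evaluation is deterministic and returns ascending, duplicate-free atom
indices.

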