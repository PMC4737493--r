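---
title: "Methods: ensemble statistics, solvation, energetics, and rigidity in gsdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble statistics, solvation, energetics, and rigidity in gsdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsdyn)
```

`gsdyn` packages the analysis chain used to dissect how point mutations in
glutamine synthetase (GS) impair catalysis: geometric ensemble statistics,
water-mediated hydrogen-bond bridging, effective-binding-energy aggregation,
secondary-structure loop probabilities, and rigidity-theory stability maps.
This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Ensembles and the replicate-SEM convention

An `ensemble` is one topology plus one or more replicate trajectories
(typically three independent simulations). Throughout the package a
statistic is first computed per replicate and then summarized as the mean of
the per-replicate means with SEM = sd(means)/sqrt(n replicates)
(`replicate_stat()`). This treats the replicates — not the (autocorrelated)
frames — as the independent observations, the convention under which
trajectory results are quoted as mean ± SEM. Significance between two
conditions uses the two-sided Student t-test on replicate means
(`t_test_two_sided()`); stability-map comparisons use the Welch test
(`welch_test()`); relative binding energies are tested against zero with a
one-sample t-test (`one_sample_t()`). All three are wrappers over
`stats::t.test()` with one added convention: two zero-variance samples with
equal means give p = 1 (a defined "no difference" answer), unequal constant
means are an error rather than a spurious p-value.

Analyses discard the first 20% of each replicate by default
(`equilibration = 0.2`), mirroring the practice of analysing the 20–100 ns
interval of a 100 ns production run; the fraction is an argument everywhere
it applies.

## Geometry

Superposition is the closed-form Kabsch/SVD construction; the returned RMSD
is the global minimum over rigid motions, which the test suite verifies
against direct numerical minimization over rotation angles. RMSF is measured
about the ensemble mean structure after iterated superposition (2
iterations; the fitting reference is a package choice, since ensemble-mean
fitting is the common default in trajectory tools). For a harmonic ensemble
with per-coordinate displacement SD sigma the expected RMSF is
sigma·sqrt(3); the rigid-body fit absorbs six degrees of freedom, so
recovered profiles sit a factor ~sqrt(1 − 6/(3N)) below that for N fitted
atoms — negligible for realistic selections and well inside the 5% recovery
tolerance used in the tests.

The "core region" is the fraction (default 90%) of residues with the lowest
RMSF, with ties broken by ascending residue serial so the selection is
deterministic.

## Hydrogen bonds, salt bridges, bridges

The hydrogen-bond criterion is heavy-atom based: donor–acceptor distance
≤ 2.8 Å (strong) or ≤ 3.2 Å (weak), and donor–H–acceptor angle ≥ 120° at the
hydrogen. Both boundaries are inclusive; strong events are by construction a
subset of weak events. The distance is read as the donor-to-acceptor
heavy-atom separation (not H–acceptor) because the angle criterion is
separately anchored at the hydrogen. Donors lacking an explicit hydrogen
(e.g. crystallographic waters) fall back to the distance-only test with a
logged warning — hydrogen placement for such waters is deliberately out of
scope. Salt bridges use the distance-only strict criterion d < 4.0 Å.

A water-mediated bridge is an alternating solute–water–…–solute chain in
which *every* link satisfies the criteria of the requested class. Chains are
simple paths over water oxygens, found by depth-first search over the
hydrogen-bond graph and depth-bounded at `max_waters = 3` — the geometric
deduction from a 7–8.5 Å donor–phosphate gap and a ~2.9 Å water diameter is
that two to three waters can span the gap. Each water–water or water–solute
link may donate in either direction; a link qualifies if either side has a
hydrogen with a valid angle. A frame counts as bridged if at least one chain
exists, regardless of multiplicity. The search is pinned to a brute-force
enumeration over all ordered water subsets in the test suite.

## Water density grids and RDFs

Density grids count water-oxygen incidences per cell of a cubic lattice
(default spacing 0.33 Å) over analysed frames, with optional
pre-superposition on a solute fit selection; the grid origin is snapped to a
multiple of the spacing so that reruns are reproducible. The grid invariant
— total counts equal total in-bounds incidences — holds exactly and is
tested. Isopleth thresholds are a stated fraction (default 80%) of the
maximum cell occupancy. Grids export as plain-text OpenDX fields.

g(r) is the standard shell-normalized radial distribution. Two reference
densities are provided and logged: N/V with minimum-image distances when the
topology carries a periodic box, and a count-matched density of the
enclosing r_max sphere for non-periodic site models. For an ideal-gas
fixture g(r) = 1 within sampling error; with only three replicates the SEM
estimate is itself noisy, so the test tolerances include a Poisson counting
floor per bin.

## Secondary structure and loop probability

The backbone hydrogen bond is scored with the Kabsch–Sander electrostatic
energy E = 0.084·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)·332 kcal/mol, bond iff
E < −0.5 kcal/mol; amide hydrogens are reconstructed geometrically (N–H
along the bisector away from the preceding carbonyl and the CA) when absent.
Classes are restricted to what the loop-probability contrast needs: residue
i is H when its carbonyl accepts the i→i+4 turn bond, G (3₁₀) when it
accepts only i→i+3, and L otherwise; strand and bend classes are omitted by
design. Two consequences are worth stating. First, the last four residues of
a chain can never be H and are reported as loop; loop-probability analyses
should target interior residues, as the figures for helix 8 do. Second, the
acceptor-turn rule makes residue classes *local in the carbonyl*: a coil
state that only reorients residue i's carbonyl changes residue i's class and
no other. The helix/coil generator exploits exactly this, which is why its
ground-truth labels are recovered frame-exactly and the recovery tests can
use plain binomial error bands. Whether 3₁₀ counts as loop is switchable
(`count_310_as_loop`), defaulting to "not loop".

## Effective binding energies

The 1-trajectory convention evaluates complex, receptor, and ligand in every
frame of the complex trajectory: ΔG_frame = E(complex) − E(receptor) −
E(ligand). Two energy models exist:

* a **toy interaction model** — screened Coulomb with a uniform interior
  dielectric of 4 (the convention recommended for highly charged binding
  sites), Lennard-Jones where van-der-Waals parameters are present, and a
  nonpolar surface term γ·ΔSASA with γ = 0.00542 kcal·mol⁻¹·Å⁻², the
  surface-area coefficient conventionally paired with Parse radii (the
  intercept β = 0.92 kcal/mol of that pairing is excluded from the
  complex-minus-parts difference so that non-interacting separated partners
  score exactly zero). SASA uses a deterministic Shrake–Rupley sphere
  sampling (92 golden-spiral points, 1.4 Å probe). This model exists to
  exercise the aggregation machinery on synthetic systems; it is **not** a
  Poisson–Boltzmann solver, and no PB solver is implemented.
* a **table pathway** that ingests external per-frame component tables
  (frame, time_ns, e_mm, g_polar, g_nonpolar) from a solvation solver, with
  frame-count validation; components must sum to the series.

Per-replicate SEMs of the frame mean use block averaging (5 blocks by
default) to respect frame autocorrelation; the naive sd/sqrt(n) estimator is
available (`estimator = "naive"`). Replicate SEMs combine by root-sum-square
— SEM = sqrt(SEM₁² + SEM₂² + SEM₃²) — and the relative energy
ΔΔG = ΔG_mutant − ΔG_wild-type is formed per matched replicate, with
SEM_total = sqrt(SEM_mut² + SEM_wt²) and a one-sample t-test of the
replicate differences against zero. Entropic and conformational-adaptation
contributions are deliberately excluded. The drift slope (ordinary least
squares of energy versus time in ns) is the convergence diagnostic.
Conversions use fold = exp(ΔΔG/RT) with R = 1.9872×10⁻³ kcal·mol⁻¹·K⁻¹;
positive ΔΔG (weaker binding in the mutant) maps to an x-fold *decrease* of
the association constant.

## Rigidity analysis

Structures become body-bar frameworks: rotatable covalent bonds 5 bars,
locked (peptide, carbonyl) bonds 6, hydrogen bonds and salt bridges 5 bars
labelled with an energy, hydrophobic tethers 2. These multiplicities are the
standard molecular body-bar convention of the rigidity literature; the
hydrogen-bond energy is a Mayo-style 12-10 potential with well depth
−8 kcal/mol at 2.8 Å and linear donor–H–acceptor geometry, modulated by
cos² of the angular deviation and clamped at zero in the repulsive region.
Both choices are package decisions where the rigidity literature leaves
room, and precomputed energies can be supplied instead (`hbond_table`).

Generic rigidity is decided by the (6,6) pebble game: each body carries six
pebbles, a bar is independent iff seven pebbles can be gathered on its
endpoints, and two bodies are mutually rigid iff a virtual extra bar between
them would be redundant. Bars are inserted in canonical sorted order, making
the decomposition independent of input order. Correctness is pinned — exact
degrees of freedom, independent-bar counts, and cluster partitions — to a
generic rigidity-matrix rank/null-space oracle on random networks; that
equivalence is an acceptance-level test.

Thermal unfolding retains a hydrogen-bond bar at cutoff c iff |E| ≥ c,
over the ladder 0.0–6.0 kcal/mol in 0.1 steps (the ladder includes 0.0;
covalent and hydrophobic bars always persist). The stability-map entry
rc_ij is the largest cutoff at which residues i and j are co-rigid; pairs
never co-rigid at c = 0 carry an NA sentinel that is excluded from means
with count bookkeeping, never folded into arithmetic. rc_ii is 6.0 by
convention. Unfolding is monotone by construction (bars only disappear as c
grows), and the cluster partition at a higher cutoff refines the partition
at a lower one — both tested properties.

Ensemble stability maps average rc_ij element-wise over per-structure maps;
difference maps Δrc_ij = mean rc(reference) − mean rc(perturbed) are
Welch-tested per pair at alpha = 0.05, with pairs sentinel-masked on either
side in more than half the structures excluded from testing. The
alanine-scan perturbation (`mutate_to_alanine()`, or equivalently deleting
one residue's hydrogen-bond bars) leaves every other atom bitwise untouched,
so observed destabilization is attributable to the removed interactions.

## Synthetic-data generators

All generators hang off one integer seed; per-generator, per-replicate
streams derive from a stable string hash (`derive_seed()`), so adding a
generator never perturbs another's stream and identical configurations are
bitwise reproducible.

* `gen_harmonic_ensemble()` — i.i.d. isotropic Gaussian displacements about
  a reference; expected RMSF sigma·sqrt(3). Default study conditions follow
  the replicate convention: 3 replicates, 2000 frames at 20 ps spacing.
* `gen_bridge_site()` — a two-endpoint minimal solute (donor hydroxyl vs
  phosphate-like acceptor triad, default gap 7.5 Å spanning the 7–8.5 Å
  regime) with a designed Bernoulli bridge occupancy realized by placing the
  chain waters on the axis at equal spacing (links well inside the strong
  criterion), decoys placed to violate the chain criteria, and positional
  noise of 0.01 Å — small enough that the designed links never leave the
  strong class, so the returned truth labels are exact. The default
  occupancy 0.31 echoes the weak-bond bridge frequency scale reported for
  the serine mutant.
* `gen_helix_coil_ensemble()` — an ideal α-helix backbone (φ = −57°,
  ψ = −47°, standard bond geometry via internal-coordinate chain building)
  whose per-residue coil state flips only that residue's carbonyl
  orientation; see the secondary-structure section for why this makes truth
  labels exactly recoverable.
* `gen_energy_series()` — mean + slope·t + Gaussian noise on a 20 ps grid
  (4000 frames ≅ 80 ns, the scale of the reported production analyses).
* `gen_bar_network()` — random or specified bars with generic (seeded
  uniform) attachment points, so ground truth is computable by the rank
  oracle.

What the generators emulate is the *statistical structure* of trajectory
data: designed fluctuation amplitudes, designed interaction occupancies,
designed drifts and offsets, and replicate-to-replicate variation. What they
do not emulate: anharmonicity and autocorrelation of real dynamics, water
exchange kinetics, force-field energetics, or periodic solvation boxes.
Passing recovery tests therefore demonstrates that the *analysis chain* is
unbiased and correctly calibrated at realistic amplitudes — not that the
original simulations are reproduced. The headline trajectory-derived
quantities (bridge frequencies near 31% vs 12%, RMSF 1.00 vs 0.74 Å, ΔΔG of
2–6 kcal/mol, drift 0.04 kcal·mol⁻¹·ns⁻¹) appear here as designed amplitudes
for parameter-recovery tests, at desk-scale problem sizes chosen as a
package decision: 2000–4000 analysed frames, 3 replicates, 8–16 residue
model systems, 100 random networks of ≤ 12 bodies for the oracle
equivalence.

## Numerical choices and degenerate inputs

* PDB I/O is fixed-width v3.3; coordinates round-trip to 10⁻³ Å, serials
  wrap modulo 99999, altloc A is kept with a warning, and elements fall back
  from columns 77–78 to atom-name inference.
* Mismatched atom counts across MODEL blocks abort naming the model;
  single-frame RMSF, all-zero density grids, constant time axes, zero-length
  selections, GLY alanine-scans, and replicate-count mismatches are all hard
  errors rather than silent NA propagation.
* Ties in the core-region ranking break by residue serial; grid origins
  snap to the spacing; pebble-game bars insert in sorted order — the three
  places where determinism would otherwise depend on input order.
* The 3-4-5 error-propagation identity and the ΔΔG antisymmetry under label
  swap are exact on rational inputs and tested as such.

## Known limitations

Strand/sheet secondary structure is not assigned; the toy energy model is
not a solvation solver (use the table pathway for solver output); hydrogen
placement and protonation assignment are out of scope; mmCIF and binary
trajectory formats are not read; atom-mode rigidity networks use simple
distance-based covalent detection that is not a substitute for a full
topology perception. The pipeline targets desk-scale synthetic systems and
dimer-scale model analyses, not decamer-scale production work.
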