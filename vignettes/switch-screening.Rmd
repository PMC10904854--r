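---
title: "Screening disordered proteins for ligand-induced conformational switches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening disordered proteins for ligand-induced conformational switches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(switchtile)
```

## The problem and the screening strategy

Intrinsically disordered proteins (IDPs) such as the c-MYC transcription
factor have no stable fold to dock a ligand against. A productive
alternative is to look for *conformational switches*: short regions whose
ensemble can be pushed between an open (binding-competent) and a closed
(collapsed, inactive) state by a small molecule. `switchtile` implements
the computational side of that strategy as a reusable pipeline:

1. **Tile** the protein sequence into fixed-width peptides
   (`tile_sequence()`; 50 residues, non-overlapping, by default, plus an
   offset overlapping pass).
2. For each tile, obtain a conformational **ensemble** in a reference
   condition (water) and a perturbed condition (hydrophobic probe or
   bound ligand) — in practice from MD, here from files
   (`read_multimodel_pdb()`) or from the synthetic generator.
3. Compare the per-frame **radius of gyration** distributions of the two
   conditions (`rg_series()`, `rg_histogram()`) and flag probe-induced
   compaction with a quantitative **switch rule**
   (`switch_statistic()`).
4. Characterize hits: R_g–energy landscapes (`rg_landscape()` with the
   MM/GBSA `energy_series()`), ligand contact maps
   (`contact_score()`, `cluster_poses()`), binding energetics
   (`binding_energy()`, `residue_decomposition()`), and gas-phase
   compaction via projection-approximation collision cross sections
   (`pa_ccs()`) for comparison with ion-mobility MS.

`run_screen()` orchestrates steps 1–3 over all tiles and returns a tidy
one-row-per-tile report.

## The switch rule

Visual comparison of R_g histograms is made quantitative by three
components, computed from the reference (`ref`) and perturbed (`pert`)
R_g series:

* **spread reduction** `1 − IQR(pert)/IQR(ref)` — has the distribution
  narrowed?
* **tail depletion** `P_ref(R_g > T) − P_pert(R_g > T)` with
  `T = 15` Å — has the extended population vanished? The threshold is
  the natural boundary for ~50-residue peptides, whose compact
  ensembles sit below ~15 Å while switch-prone ones reach ~35 Å.
* **KS distance** — are the two ensembles distinguishable at all?

A tile is flagged when all three clear their thresholds (defaults 0.5,
0.25, 0.3; see `switch_rule()`). The defaults are deliberately
conservative: they are calibrated by a null experiment — two independent
draws from the same compact ensemble must flag in at most 5% of 100
seeded repeats — which the test suite re-runs. A tile with a missing
perturbed ensemble is reported `"untested"`, never flagged.

## The synthetic ensemble generator

Microsecond explicit-solvent MD is far outside a desk-scale test budget,
so every stage is exercised against a seeded generator with the same
*statistical* structure as the real data:

* `sample_chain()` draws one-bead-per-residue chains (bond 3.8 Å, the
  C-alpha virtual bond; hard core 3.5 Å) by Metropolis Monte Carlo with
  pivot *and* local kink moves under a square-well attraction of depth
  `epsilon` (kT units) between sticky (hydrophobic) beads. Burn-in
  anneals the well depth from zero so deep quenches reach the collapsed
  equilibrium rather than a metastable trap — pivot-only sampling is
  known to stall in dense globules.
* `epsilon` alone spans the regimes the screen must distinguish:
  `epsilon = 0.3` (the default `compact_chain_model()`) gives narrow
  compact ensembles, mean R_g ≈ 10–12 Å with under 2% of frames above
  15 Å; `epsilon = −4` (`extended_chain_model()`) gives swollen chains,
  mean ≈ 25 Å. A 50/50 `mixture_ensemble()` of the two spans roughly
  5–35 Å — the broad, switch-prone regime. The compact default sits just
  *past* the collapse transition on purpose: exactly at the transition,
  independent runs drift between basins and the ensemble is not narrow.
  `calibrate_compaction()` bisects `epsilon` to a target mean R_g; near
  the transition, seed-to-seed reproducibility of the mean is about
  ±1 Å, which the calibration tests account for.
* `plant_ligand()` appends a pseudo-ligand with known per-frame contact
  occupancy, and `toy_complex()` builds a two-chain bead complex with a
  planted strongly interacting residue pair for the energy tests.

What the generator does **not** emulate: atomistic packing, secondary
structure, explicit probe molecules (probe effects are represented by
`epsilon` shifts), solvent friction or kinetics. Passing tests therefore
demonstrate that the *analysis* is correct and well calibrated on
ensembles with realistic R_g statistics — not that any particular real
protein switches.

## The energy model

`total_energy()` evaluates the MM/GBSA enthalpy
`G = E_bon + E_vdw + E_ele + E_pol + E_npol` per frame:

* `E_vdw`, `E_ele`: Lennard-Jones 12-6 and Coulomb sums
  (k = 332.0637 kcal·Å/mol/e²). Without a bonded topology all pairs
  interact and `E_bon = 0` (bead systems; in single-trajectory binding
  differences bonded terms cancel identically). With a topology, 1-2/1-3
  pairs are excluded and 1-4 pairs scaled by 1/1.2 (electrostatic) and
  1/2 (LJ).
* `E_pol`: generalized Born with OBC-I effective radii (the `igb = 2`
  parameterization: α = 0.8, β = 0, γ = 2.909125, dielectric offset
  0.09 Å, HCT pairwise descreening with a uniform 0.8 screening factor
  for bead systems). Salt (default 150 mM) enters as exponential Debye
  screening of the GB pair term, `exp(−0.73 κ f)` with κ from ionic
  strength near 300 K. Note the standard screened-GB form makes a single
  ion's self-energy slightly *deeper* with salt while attenuating
  charge–charge interactions; the tests assert both directions.
* `E_npol = γ·SASA` with γ = 0.0072 kcal/mol/Å², probe 1.4 Å. SASA is
  Shrake–Rupley with a 960-point golden-spiral lattice; coordinates are
  first rotated into a molecule-fixed principal-axes frame so areas are
  exactly invariant under rigid motion.

`binding_energy()` applies the single-trajectory convention
(`ΔG = G_complex − G_A − G_B` on shared coordinates, 1000 evenly spaced
frames by default, 5000 for single peptides in `energy_series()`), and
`residue_decomposition()` splits pairwise terms half/half between the
partner residues, assigns self and surface terms to the owner, and
reports residues at or below −2 kcal/mol as mean ± SD over frames. The
decomposition conserves the total exactly by construction. Parity is
defined against the equations above and their brute-force oracles, not
against any production force field.

## Contacts and pose clustering

A residue's contact score is the mean number of ligand heavy atoms
within 4.5 Å of any of its heavy atoms per frame — a definition chosen
so the conventional "score > 1" report threshold means *more than one
ligand atom engaged on average*. Binary per-frame fingerprints feed
average-linkage (UPGMA) clustering under Jaccard distance, cut at 0.5.
Binary fingerprints produce exactly tied merge distances, so the
tie-break is part of the algorithm's definition: among tied pairs the
one with lexicographically lowest member frame indices merges first, and
representatives minimize summed distance to their cluster (lowest frame
wins ties). This makes the clustering reproducible and testable against
an independent O(n³) oracle.

## Collision cross sections

`pa_ccs()` implements the projection approximation: for each seeded,
quaternion-uniform random orientation, atoms project to disks of radius
r + probe (probe 1.0 Å by default) and the union area is estimated by
uniform sampling over the bounding box (4000 points); the CCS is the
mean over up to 300 orientations with early stopping at 1 Å² standard
error. Absolute parity with nitrogen-drift experimental values would
require an instrument calibration (`calibrate_ccs()` is identity by
default), so CCS supports *ordering* statements — compact ensembles
project smaller than extended ones — rather than absolute comparison.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout; tile names use an ASCII
  hyphen (`parent_101-150`).
* Percentiles are type 7 (linear interpolation); histograms use 1-Å bins
  over 0–40 Å by default and renormalize to unit mass.
* The KS statistic is computed as the exact ECDF supremum (correct under
  ties, which bead ensembles produce).
* A reference with zero IQR makes spread reduction undefined; it is
  reported as 0 with a warning flag and the tile cannot be flagged.
* All-identical energies normalize to 0 in landscapes, with a warning.
* Profile smoothing windows are odd and truncated at the termini; the
  smoothing width of hydropathy profiles defaults to 9 residues
  (configurable — published profiles do not state theirs).
* The hydrophobic set defaults to {A, C, F, I, L, M, V, W}, the
  classification under which the coreMYC epitope is exactly 50%
  hydrophobic (25/50); it is an argument, not a constant.
* Disorder scores are read from external predictor output
  (`read_disorder_csv()`); `disorder_proxy()` is a documented
  fold-index-style fallback, not a predictor reimplementation.

## Problem sizes

The shipped tests and the acceptance script use 50-bead chains, 120–150
frames per condition, 100-seed null calibrations, 400–500-frame contact
recoveries, and 25-frame toy complexes. These sizes were chosen so the
statistical guarantees (3-SE recoveries, ≤5% null false-flag rate) are
meaningful while a full run stays comfortably interactive on one CPU.

## Known limitations

* The bead generator cannot validate sequence-specific claims about any
  real protein; it validates the pipeline's statistics.
* The energy model omits entropy, explicit solvent, and production
  force-field parameters; binding energies are comparative, not
  absolute.
* `E_bon` requires a user-supplied topology; none is generated from
  sequence. Whether peptide-ensemble enthalpies include `E_bon` is
  controlled by supplying or omitting that topology (default: omitted
  for bead systems, where it does not exist).
* CCS values are uncalibrated projection areas; trajectory-method or
  hard-sphere-scattering accuracy is out of scope.
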