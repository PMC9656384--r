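---
title: "Characterizing protein–polymer binding interfaces from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing protein–polymer binding interfaces from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchbind)
```

## The problem

When a therapeutic protein is loaded into polymeric nanoparticles
(PLGA–PEG and its homopolymer constituents are the canonical carriers),
the strength and location of protein–polymer contact during formulation
decide how much protein is encapsulated and how it is released. Atomistic
MD studies of one protein with a few polymer oligomers probe this directly:
oligomers are held at a target radius of gyration $R_g$ (emulating good,
intermediate, or poor solvent) for a restrained phase and then released.
`patchbind` implements the complete post-simulation analysis for such
studies: interaction-class timelines, per-residue occupancy interfaces,
contact surface areas, and a surface-patch method that localizes and
chemically characterizes binding hotspots — plus a scripted synthetic-data
generator with exact ground truth so every stage is testable without
running MD.

## Interaction classes and time frequencies

Each oligomer $i$ at each frame is classified from two center-of-mass
distances: $d_i^{COM}$ to the protein and $d_{i-j}^{COM}$ to every other
oligomer. With inclusive cutoffs (defaults 4.3 nm and 2.3 nm):

* **protein–polymer only**: $d_i \le 4.3$ nm and no pair within 2.3 nm;
* **polymer–polymer only**: some $d_{i-j} \le 2.3$ nm, protein far;
* **both** when the two conditions hold together; **free** otherwise.

The 4.3 nm default suits a globular protein whose largest ellipsoid
semi-axis is ~3.5 nm ([ellipsoid_axes()] measures this) plus the reach of a
~10.5 nm contour-length oligomer; 2.3 nm spans the pair COM distance at
which chains of that contour length can touch across their accessible
conformations (collapsed chains have $R_g < 1.2$ nm, extended ones
$> 1.8$ nm). "Polymer–polymer" for oligomer $i$ means *at least one*
partner within the cutoff, since aggregation events involve one or more
partners.

The time frequency $TF_i$ of a class is the fraction of window frames
oligomer $i$ spends in it; the four classes partition unity per oligomer.
Aggregation is two-level with fixed order — oligomers within a trial
($TF_{avg}$), then trials within a polymer ($TF^{poly}_{avg}$) — because
that order defines the reported statistic even though it coincides with a
flat average at equal oligomer counts. Windows default to the two restraint
phases analyzed separately; whole-trajectory windows are available, and
both are labeled in exports, since per-phase versus whole-trajectory
reporting is a choice the analyst must see.

## Occupancy interfaces and contact surface area

A residue is *occupied* in a frame if any polymer atom lies within 4 Å of
any of its atoms (a residue counts once per frame, however many atoms
touch). Percent occupancy divides by the analyzed window's frame count.
Any-atom contact is the default because the rule is a proximity criterion,
not a bond inventory; a heavy-atom-only variant is a flag. By default all
oligomers pool into one map and per-oligomer maps are also emitted.

Per-trial interfaces (non-zero-occupancy residues) are merged across
trials into a **collapsed interface**: the union of residues contacted in
at least one trial, averaging occupancies over their *non-zero*
occurrences — a residue bound at 60% in one trial and untouched in six
others keeps 60%, recording the binding mode that did occur rather than
diluting it; averaging over all trials is available behind a flag.
Occupancy filters are strict (`> cutoff`): above 50% selects favorable
(possibly reversible) binding, above 90% isolates irreversible binding.

The **contact surface area** of an interface is the sum of its members'
solvent-accessible surface areas,
$CSA = \sum_{i=1}^{N_{interface}} SASA_i$, taken from the reference
structure. SASA is computed once on the reference (static) because surface
residues are selected once and the per-residue areas enter only through
this sum; per-frame SASA is a configuration option. Group fractions over
the interface use five categories — negative {ASP, GLU}, positive
{LYS, ARG}, polar {SER, THR, ASN, GLN, CYS, HIS}, hydrophobic
{ALA, VAL, LEU, ILE, MET, PRO, GLY, PHE, TRP, TYR} — with aromatic
{PHE, TRP, TYR} counted inside hydrophobic, so the four primary fractions
partition unity and the aromatic fraction never exceeds the hydrophobic
one. HIS is treated as neutral/polar at pH 7, which is also why formal
charge counts only LYS/ARG against ASP/GLU; termini are ignored by default
because prepared constructs are typically loop-modeled and tail-truncated.

## Solvent accessibility and surface selection

[shrake_rupley_sasa()] implements Shrake–Rupley quadrature: each atom's
sphere (van der Waals radius from the Bondi table plus a 1.4 Å water
probe) is sampled with a deterministic golden-spiral point set, 960 points
per atom by default; a point is accessible if outside every neighboring
expanded sphere. 960 points put the isolated-sphere quadrature error well
under 1%, and the deterministic point set makes reruns bit-identical.
Residues with SASA strictly greater than 1 Å² count as surface — the
threshold under which a water molecule (radius ~1.4 Å) cannot plausibly
reach the residue.

## Surface patches

The patch method asks what distinguishes the binding interface from the
rest of the surface, and which contiguous residue cluster best captures
it.

1. **Solvent vectors.** For each surface residue, neighbors are the
   surface Cα atoms within a calibrated radius —
   [calibrate_neighbor_radius()] scans 8–16 Å for the radius at which the
   largest share of residues has exactly 10 neighbors, reproducing the
   construction where most surface residues have 10 neighbors and the
   remainder 11–12. The solvent vector is the *negative* of the normalized
   vector from the residue's Cα to its neighbors' Cα centroid: it points
   away from local protein mass, toward solvent. Residues whose neighbors
   are symmetric about them (centroid within $10^{-6}$ nm) are degenerate,
   logged, and skipped.
2. **Patches.** One patch per surface residue: a neighbor within 13 Å
   joins iff the angle between its solvent vector and the center's is
   strictly below 125° (dot products clamped to $[-1, 1]$ before `acos`).
   The angular test removes residues on the far side of the surface or
   across concavities that a pure distance search would sweep in. Because
   both the distance and the angle tests are symmetric, membership under
   this fixed-radius construction is a symmetric relation — a property the
   test suite asserts; k-nearest-neighbor variants would not have it,
   which is why the calibrated fixed radius is used everywhere.
3. **Descriptors.** Each patch (and each trial interface) is summarized by
   arithmetic means of four per-residue side-chain descriptors from the
   Fauchère scale: hydrophobicity (water–octanol), polarizability, graph
   shape index, and normalized van der Waals volume. The table ships as a
   TSV resource and can be replaced.
4. **Decile ranks.** An interface descriptor is ranked 1–10 against the
   patch population: rank $= 10 - \lfloor 10F \rfloor$ clamped to
   $[1, 10]$, with $F$ the fraction of patch values *strictly below* the
   interface value — so rank 1 is the top decile and boundary values
   promote to the better rank. Self-ranking the population fills every
   decile with 10% ± 1 of the patches.
5. **Percent patch overlap** is
   $100 \times |patch \cap interface| / N_{interface}$; the co-maximal
   patches (ties are all reported) localize the binding hotspot.

## The synthetic-data module

The generator is a *geometry scripter*, not a simulator: it produces
trajectories whose interaction classes, contacts, and $R_g$ traces are
known exactly, at the study's scales (3 oligomers around one protein,
10 ps frame spacing, restraint flip halfway, 11 nm box carried as
metadata; the restraint constant k = 140 kJ/mol is bookkeeping only).

* [synth_protein()] builds a spherical-shell stand-in surface: residues on
  a Fibonacci lattice, one Cα plus one side-group bead each. Defaults —
  300 residues on a 3.4 nm shell — give ~48 Å² of shell per residue,
  which reproduces both the scale of a ~500-residue globular protein
  (largest semi-axis ~3.4 nm) and the characteristic ~10 Cα neighbors
  within 13 Å. Composition defaults to 12% negative, 9% positive, 30%
  polar, 48% hydrophobic (residual to polar), apportioned exactly by
  largest remainder; names are drawn within groups weighted by natural
  amino-acid abundances so that, e.g., TRP stays rare and aromatics are
  ~9% of the surface as on real proteins.
* [synth_trajectory()] executes per-oligomer scripts of FREE / BIND /
  AGGREGATE / BOTH segments. Placements keep every decision distance
  outside a guard band of ± the scenario margin (default 0.2 nm) around
  its cutoff, and bead–residue distances outside the same band around the
  4 Å contact cutoff; every frame is verified geometrically before
  truncated Gaussian noise (σ = 0.05 nm, clipped at 3σ = 0.15 nm < margin)
  is added. Ground truth is therefore exact by construction, and the suite
  checks 100% frame-label agreement and exact occupancy recovery.
  Mass-weighted COMs are used throughout — diblock chains with 65/44 Da
  beads have their COM off the geometric center, which matters at these
  margins.
* [synth_restrained_chain()] holds a chain's mass-weighted $R_g$ within a
  ±2.5% resampling band around the target during the ON phase (inside the
  ±5% restraint tolerance) and relaxes it exponentially on release:
  collapse toward a 1.0 nm plateau (below the 1.2 nm collapsed-state
  mark) or expansion toward 1.9 nm, with a 15 ns default time constant so
  collapse completes within ~50 ns at full scale. Targets above the rigid
  rod bound $L_c/\sqrt{12}$ are rejected.

What the generator does **not** emulate: excluded volume, bond-length
fidelity under $R_g$ rescaling, solvent, kinetics of class transitions,
or protein flexibility (the protein is static). Passing tests therefore
validate the *analysis* — classification, counting, geometry, ranking —
not any thermodynamic statement about real trajectories.

The packaged study scenario ([standard_study_scenario()]) encodes the
qualitative behavior such studies report, as generator conditions chosen
once: binding prevalence increases with extension for PLGA and PLGA–PEG
and peaks at medium extension for PEG; PLGA aggregates most;
PLGA/PLGA-PEG binding persists after release while PEG binding is
transient (and PEG chains expand on release, the others collapse); an
extended chain contacts more residues (3 targets at low extension up to 9
at high), which is what drives larger contact surface areas at high
extension. Per-trial variability (±15% on bound fractions, randomized
hotspot orientation within the approach cone) emulates the trial scatter
of independent initial configurations.

## Statistics and numerical choices

* Extension levels are compared on per-trial CSA with the Wilcoxon
  signed-rank test, paired by trial index (the pairing the design
  implies); raw p-values are reported as in the source studies, with
  Holm-adjusted values alongside, clearly labeled. All-zero difference
  sets are flagged `degenerate` with `NA` rather than a fabricated p.
* $R_g$ series are smoothed with a 100-frame centered moving average
  (1 ns at 10 ps/frame; the window is a package choice) and densities use
  fixed 0.05 nm bins normalized to integrate to 1 per phase.
* Superposed backbone RMSD uses Kabsch least squares before the deviation
  sum (an unsuperposed variant is a flag); cutoff comparisons are
  inclusive; occupancy and patch filters are strict inequalities;
  `acos` arguments are clamped; minimum-image displacements apply when a
  periodic box is present (synthetic data is non-periodic).
* Seeds: design rows carry counter-derived seeds below $2^{31}$ from one
  master seed; all generators restore the caller's RNG state.

## Problem sizes

The shipped examples, test suite, and acceptance script run the full
factorial design (3 polymers × 3 extensions × 7 trials = 63) at 200
frames per trial on a 300-residue synthetic surface — sizes chosen so the
whole validation cycle completes in about two minutes while exercising
every stage at the study's geometry. The analysis code is
frame-count-agnostic; full-scale trajectories (20,000 frames) stream
through the same functions.

## Known limitations

* XTC trajectories are not read (no available reader); DCD, multi-model
  PDB, GRO, and a plain-text XYZ dialect are supported.
* The descriptor table and grouping cover the 20 standard residues;
  modified residues must be mapped by the caller (no silent defaulting).
* SASA is quadrature-based; analytic SASA and curvature/depth descriptors
  are out of scope, as are hydrogen-bond/salt-bridge inventories and
  energy decompositions.
* On a convex synthetic sphere the 125° angular cutoff rarely excludes
  anything (all solvent vectors point outward); its effect shows on real,
  corrugated surfaces. Patch-size distributions on the synthetic surface
  are therefore governed by the neighbor density alone.
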