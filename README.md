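# patchbind

Post-simulation analysis of **protein–polymer binding** from molecular
dynamics trajectories of one protein with several polymer oligomers —
the setting of nanoparticle-formulation studies in which PLGA, PEG, or
PLGA–PEG oligomers are restrained at a target radius of gyration
(high 2.0 / medium 1.5 / low 1.1 nm) around a therapeutic protein for
100 ns and then released for another 100 ns.

For people who run such simulations and need the downstream numbers,
`patchbind` provides the four analysis layers:

1. **Interaction-class timelines.** Each oligomer *i* at each frame is
   classified from center-of-mass distances — protein–polymer only
   (d_i ≤ 4.3 nm), polymer–polymer only (some d_i−j ≤ 2.3 nm), both, or
   free in solution — and class **time frequencies** are averaged over
   oligomers and trials:
   TF_i = frames in class / frames in window, TF_avg = Σ TF_i / N_olig,
   TF_avg^poly = Σ TF_avg / N_trials.
2. **Occupancy interfaces.** Per-residue **percent occupancy** =
   100 × (frames with any polymer atom within 4 Å of the residue) /
   (frames in window); per-trial interfaces collapse across trials
   (union of contacted residues, non-zero occupancies averaged), filter
   at >50% / >90%, and yield the **contact surface area**
   CSA = Σ SASA_i over the N_interface members (Shrake–Rupley SASA,
   1.4 Å probe; surface residues have SASA > 1 Å²).
3. **Surface patches.** Overlapping residue clusters built from **solvent
   vectors** (the inverse of the normalized Cα→neighbor-centroid vector,
   neighbors from a calibrated ~10-neighbor search): a neighbor within
   13 Å joins a patch iff its solvent vector is within 125° of the
   center's. Patches and interfaces carry four physiochemical descriptors
   (Fauchère hydrophobicity, polarizability, graph shape index,
   normalized van der Waals volume) as member means; interfaces get
   **decile ranks** (1 = top 10%) against the patch population and
   **percent patch overlap** = 100 × |patch ∩ interface| / N_interface
   localizes the binding hotspot.
4. **Synthetic ground truth.** A scripted generator builds spherical-shell
   proteins and FREE/BIND/AGGREGATE/BOTH oligomer trajectories whose
   class labels and contact fractions are exact by construction
   (guard-band placement, noise truncated below the margins), so the whole
   pipeline is validated end to end without any simulation output.

## Worked example

```r
library(patchbind)

## a 300-residue synthetic surface at the study's geometry
protein <- synth_protein(n_residues = 300, radius_nm = 3.4, seed = 42)
sasa    <- shrake_rupley_sasa(protein)                 # 960 pts/atom, 1.4 A probe
surface <- select_surface_residues(sasa, threshold = 1)

ellipsoid_axes(protein, surface)
#> <ellipsoid_fit> semi-axes a=3.39 b=3.38 c=3.38 nm

ca  <- calpha_coords(protein)[surface, ]
cal <- calibrate_neighbor_radius(ca, target_count = 10)
#> calibrated radius 13.5 A; 41% of residues have exactly 10 neighbors
vecs    <- surface_solvent_vectors(ca, surface, cal$radius_A)
patches <- generate_patches(ca, surface,
                            protein$residues$resname[surface], vecs)
patches
#> <patch_set> 300 patches, modal size 10 residues (theta_cut 125 deg, search 13 A)

## a scripted mini-study: PLGA at high vs low extension, 2 trials each
design <- enumerate_design(n_trials = 2, base_seed = 42)
design <- design[design$polymer == "PLGA" &
                 design$extension %in% c("high", "low"), ]
res <- run_study(design, protein = protein, n_frames = 100)

g <- res$report$groups[["PLGA|high|ON"]]
round(g$tf$tf_avg_poly, 3)
#> PROT_POLY POLY_POLY      BOTH      FREE
#>      0.19      0.24      0.00      0.57
```

The high-extension group reports `CSA 1438 +/- 1 A2`, an interface of 9
residues above 50% occupancy, and a maximum patch overlap of `88.9%` —
the patch that captures the scripted binding hotspot; the low-extension
group's CSA drops to `479 A2` because collapsed chains contact fewer
residues. `res$report$csa_tests` holds the paired Wilcoxon signed-rank
comparisons across extension levels (raw and Holm-adjusted p-values).

Real data enter through `read_structure()` (PDB/GRO) and
`read_trajectory()` (DCD, multi-model PDB, plain-text XYZ), assembled with
`study_trajectory()` and analyzed with the same `run_trial()` /
`aggregate_study()` calls. Exports include CSVs, JSON with provenance, and
PDB copies with occupancy painted into the B-factor column for
visualization.

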