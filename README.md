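# lipmap

State-dependent protein–lipid interaction mapping from coarse-grained
membrane trajectories.

## The problem

Pentameric ligand-gated ion channels (pLGICs) such as the glycine receptor
sit in lipid bilayers whose composition modulates their function: cholesterol
and anionic lipids are required for activation of related receptors, and
structural work keeps resolving lipids in modulator pockets. Coarse-grained
simulations of a receptor held in a fixed conformational state (inactive vs
active), embedded in an asymmetric neuronal model membrane, let one ask
*where* each lipid species concentrates around the protein and *how long* it
stays — and whether those preferences differ between states. `lipmap`
implements that analysis for R users:

- **Leaflet-resolved densities.** Per frame, each lipid is assigned to the
  extracellular or intracellular leaflet by the sign of its anchor bead
  (phosphate, or hydroxyl for cholesterol) relative to the instantaneous
  midplane. Time-averaged 2D maps `rho(x, y)` (molecules/nm², one anchor per
  molecule) and 3D fields `rho(x, y, z)` (molecules/nm³, selectable by bead
  role: cationic headgroup, phosphate, hydroxyl, tail) are accumulated on
  fixed grids so repeats stay commensurate, with the exact conservation
  property `sum(rho) * bin_area = <N>`.
- **Equal-composition isovalues.** To compare species of very different
  abundance at one visual level, an isovalue `c` for a lipid with mole
  fraction `f` in an `n`-type membrane is rescaled as `c' = c * f * n`
  (`equal_composition_isovalue()`).
- **C5 symmetry diagnostics.** Around a five-fold symmetric receptor the
  converged density must be C5-symmetric. `symmetrize_c5()` averages a grid
  with its four 72° rotations (computed in a canonical polar representation,
  so the operation is exactly idempotent), and `c5_deviation()` reports the
  normalized L1 asymmetry `sum|g - S(g)| / (2 sum g)` in [0, 1] — a
  convergence diagnostic for individual repeats versus the repeat average.
- **Contact durations.** A residue–lipid contact exists when any bead pair is
  within 6 Å (minimum image, triclinic hexagonal cell). For every (residue,
  lipid type), maximal runs of consecutive contact frames give continuous
  contact durations; the pooled mean across molecules, repeats and the five
  subunits is the per-residue residence statistic, and `lipid_hierarchy()`
  ranks species by it (cholesterol > phosphatidylserine > PC/PE/SM in the
  motivating system).
- **Ligand-site overlap.** Sites defined from a user-supplied structure
  (e.g. an ivermectin or PIP2 pose) or as subunit-interface wedges are scored
  by density enrichment over bulk, and `interface_penetration()` measures how
  deep supra-threshold density reaches into the five interface crevices —
  the signature of a state-gated cholesterol site.

Because suitable trajectories are large and rarely deposited, the package
ships a fully synthetic test-bed with planted ground truth: an asymmetric
five-lipid neuronal membrane builder (POPC/POPE/DOPS/SM/CHOL at published
mole percents), a static C5-symmetric toy pentamer, and an overdamped
Brownian lipid dynamics with Gaussian-well binding sites of tunable depth,
state availability, and rare cholesterol flip-flop. Every statistic above is
validated by parameter recovery against this truth.

## Worked example

```r
library(lipmap)

# asymmetric neuronal membrane around the toy pentamer, active state,
# one cholesterol site planted in the subunit-interface wedges
run <- synthetic_reference_run(interface_truth("active"), seed = 21)
spec <- neuronal_membrane_spec()
apportion_counts(spec$per_leaflet_percent$extracellular, 1000)
#> POPC POPE DOPS   SM CHOL
#>  244  111    0  199  447        # 44.7 mol% cholesterol, leaflet total 1001

g <- density3d(run$trajectory, run$system$topology, "CHOL", "hydroxyl",
               voxel_size = 0.25)
site <- site_definition("interface",
                        wedge = list(index = 0, half_width_deg = 15,
                                     leaflet = "extracellular"))
site_enrichment(g, site, footprint_radius = run$system$pentamer$footprint_radius)
#> Site 'interface' (CHOL): mean density 2.369, bulk 0.1403, enrichment 16.89,
#> occupancy 6.81 molecules
```

The same run in the `"inactive"` state (where the planted site is absent)
gives enrichment 1.33 for this wedge at this run length (≈ 0.9 averaged over
the five wedges of a longer paired run, as in `interface_state_study()`):
the package resolves the state dependence of the site. Contact analysis on
the hierarchy test-bed:

```r
st <- hierarchy_study(seed = 202)
st$hierarchy_max
#> [1] "CHOL" "DOPS" "SM"   "POPC" "POPE"
```

i.e. the planted well depths (CHOL 6 kT > PS 4 kT > PC = PE = SM 1 kT) are
recovered as the contact-duration hierarchy.

A YAML-driven pipeline (`validate_config()` + `run_pipeline()`, or
`inst/scripts/lipmap-pipeline.R` from a shell) chains
synthesize → window → leaflets → densities → contacts → sites and writes
CSV/OpenDX outputs plus a JSON manifest.

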