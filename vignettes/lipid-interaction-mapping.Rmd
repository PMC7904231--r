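---
title: "Mapping state-dependent protein-lipid interactions with lipmap"
author: "lipmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping state-dependent protein-lipid interactions with lipmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lipmap)
```

## Scope and model

`lipmap` quantifies where individual lipid species concentrate around a
membrane-embedded pentameric receptor and how long they stay, comparing two
receptor conformational states (inactive vs active) that are each held
fixed while the lipids equilibrate around them. The receptor being
positionally restrained is what licenses two analysis shortcuts used
throughout: frames are centred on the protein by translation only (no
rotational fitting), and all site geometry is expressed in a fixed frame
around the pore axis.

The package has two layers:

1. **Analysis** of coarse-grained coordinates and trajectories (GRO/PDB +
   DCD): leaflet assignment, 2D/3D time-averaged number densities, C5
   symmetry diagnostics, per-residue continuous contact durations, and
   density overlap with structurally defined ligand sites.
2. **A synthetic test-bed** that generates membranes and toy lipid dynamics
   with *planted* ground truth, so each analysis can be validated by
   parameter recovery rather than by eyeballing.

## The synthetic membrane and its dynamics

The default composition is a five-lipid asymmetric neuronal plasma-membrane
model (mole percents; extracellular / intracellular): POPC 24.4/13.7,
POPE 11.1/21.5, DOPS 0/16.9, sphingomyelin 19.9/3.0, cholesterol 44.7/44.9.
Counts are apportioned per leaflet as `round(percent * n / 100)` with
round-half-up, deliberately *without* renormalizing: the extracellular
column sums to 100.1, and preserving that means a nominal 1000-lipid leaflet
realizes 1001 molecules while reproducing every printed one-decimal percent
exactly. Largest-remainder apportionment would hit the nominal total but
distort the percents; reproducing the composition was judged the more
important contract.

Lipids are placed uniformly at random per leaflet (minimum anchor spacing
0.45 nm, a coarse-grained headgroup diameter), outside a disc around the
protein, at `z = leaflet_z + N(0, 0.1 nm)` with `leaflet_z = ±1.8 nm`, a
typical phosphate-plane offset. Each molecule carries a small rigid bead
stack (headgroup, phosphate/hydroxyl anchor, tails) so bead-role density
selectors and the any-bead contact rule are exercised.

The toy pentamer is five exact copies of one subunit under 72° rotation:
four vertical pseudo-helices per subunit on three concentric rings — a
pore-lining inner helix, two middle helices flanking it at ±20°, and an
outer lipid-facing helix at 2.1 nm whose residues additionally carry a
sidechain bead at 2.35 nm. The sidechain beads are the lipid-facing
"antennae": a lipid parked at a surface site sits essentially on top of
them, so a genuinely bound lipid stays within the 6 Å contact cutoff
instead of flickering across it with every thermal fluctuation. The hard
protein core seen by the dynamics is built from backbone beads only
(exclusion radius 0.2 nm), leaving the five ~32°-wide subunit-interface
gaps lipid-accessible — the crevice geometry the interface analyses probe.

Dynamics are overdamped Brownian motion of each lipid's in-plane anchor:
`dx = D F dt + sqrt(2 D dt) xi`, with energies in kT (so mobility = D), the
force from planted Gaussian wells `U = -depth * exp(-r^2 / 2 width^2)`
restricted to the matching lipid type, leaflet and receptor state, periodic
wrapping in the hexagonal (triclinic) cell, and Metropolis-style rejection
of moves into the protein core — which preserves an exactly uniform
stationary density on the accessible region, a property the flat-density
test checks by chi-square. Cholesterol flips leaflet as a Poisson process
(default 1e-4 /ns per molecule, i.e. a handful of events per microsecond
trajectory); the flip teleports its z to the other leaflet plane, since
only the fact of exchange, not transit kinetics, matters downstream.
Diffusion defaults are 0.03 nm²/ns for phospholipids and 0.05 for
cholesterol, the coarse-grained lateral-diffusion scale. The integrator
refuses steps whose RMS displacement exceeds half the smallest site width;
with the defaults (dt = 0.1 ns, narrowest wells 0.3 nm) it operates just
inside that bound.

Randomness is organised as one independent pre-seeded stream per molecule,
derived from the global seed and the molecule id. Adding or removing
molecules therefore does not reshuffle anyone else's noise — a property the
test-suite asserts — and identical seeds give bit-identical trajectories.

### What the generator does and does not emulate

It reproduces the features the statistics depend on: asymmetric
composition, type-selective binding hotspots with controllable depth and
state availability, annulus–bulk exchange, leaflet exchange for cholesterol
only, and exact C5 symmetry of the planted truth. It deliberately omits
force-field realism: no excluded volume between lipids (wells can host
several molecules), no membrane undulations or curvature, no solvent, no
protein motion. Passing the recovery tests therefore demonstrates that the
*analysis* is correct and sensitive at realistic signal levels — not that
the generator is a membrane simulator.

## Study conditions for the validation suite

Two canonical studies are frozen in `hierarchy_truth()` /
`interface_truth()` and driven by `hierarchy_study()` /
`interface_state_study()`:

- **Hierarchy recovery.** One C5-replicated site per lipid species, all
  centred on the outer-helix sidechains (radius 2.35 nm, width 0.3 nm),
  with depths CHOL 6 kT > PS 4 kT > PC = PE = SM 1 kT. The width is chosen
  so that the bound-state positional spread, `width / sqrt(depth)`, stays
  within the contact shell for the deep sites — the condition under which
  continuous contact duration actually measures residence. Runs are 1332 ns
  (13320 steps), frames every 2 ns, 301 lipids: ~2×10^5 lipid-frames. At
  half this length the per-residue mean for a rare species can still be
  dominated by a single long event, which makes the extreme-value "max"
  statistic unstable; at the chosen length both ranking statistics recover
  the planted order across seeds with roughly two-fold margins.
- **State-gated interface site.** A single cholesterol site buried in the
  subunit-interface wedges (radius 1.6 nm, depth 6 kT), available only in
  the active state; paired runs share the seed. Enrichment is the mean over
  the five wedges (angular half-width 15°, the wedge limited to the
  footprint radius and leaflet slab), against a bulk defined as in-cell
  voxels beyond twice the footprint radius in the same z-slab. The
  penetration threshold is three times the bulk density of the anchor
  layer (one voxel layer at the headgroup plane) — thresholding against
  the full-slab mean would be swamped by the empty z-volume.

## Analysis conventions and numerical choices

- **Windowing.** `select_window()` keeps frames with time strictly greater
  than `(1 - last_fraction) * T_end` (half-open; the boundary frame is
  excluded; `last_fraction = 1` keeps everything), then subsamples from the
  first kept frame at the requested stride. A 40 μs trajectory at 10 ns
  spacing windowed to its last half at 10 ns stride yields exactly 2000
  frames spanning (20 μs, 40 μs].
- **Minimum image.** Distances search the 27 neighbouring images after
  reduction to the central cell, exact for separations below about a
  quarter of the cell — enforced by the requirement that contact cutoffs be
  below half the shortest box vector. Bulk pairwise operations use the
  reduced image directly, valid in the same regime.
- **Contacts.** Any-bead/any-bead, cutoff 0.6 nm. A single non-contact
  frame terminates a run (no gap smoothing); runs touching the window edges
  are counted at their observed length, uncensored, and the output records
  this so the bias is auditable. Per-residue means pool events across
  molecules, repeats and (optionally) the five subunit copies; pooling
  weights evidence by event count, and a per-molecule mean-of-means is
  available behind a flag. Detection prunes residue/molecule pairs by a
  bounding-sphere test on centroids before the exact bead-pair check; the
  plain all-pairs scan is retained as `method = "brute"` and the two are
  asserted identical on random frames.
- **Densities.** 2D maps use one anchor bead per molecule; 3D fields bin
  selected beads and record the beads-per-molecule normalization. Grids are
  anchored to the cell's bounding rectangle so repeats are commensurate by
  construction, and conservation (`integral = time-averaged count`) is
  exact to rounding. Default bins: 0.2 nm (2D), 0.1 nm (3D).
- **C5 symmetrization.** Averaging a grid with interpolated rotations is
  not idempotent, so "the deviation of a symmetrized grid" would never be
  zero. `symmetrize_c5()` instead samples the grid once into a polar
  representation whose angular dimension is divisible by five (360 bins,
  radial step half the grid spacing), where the five-fold average is an
  exact index-shift projection; the result carries that representation, so
  symmetrizing twice is the identity and `c5_deviation()` of a symmetrized
  grid is zero to floating noise. The Cartesian rendering is rescaled to
  preserve the integral exactly. The deviation metric
  `sum|g - S(g)| / (2 sum g)` is this package's construction (the
  underlying convergence check is usually done by eye); it is 0 for
  symmetric fields and 4/5 for mass confined to one sector.
- **Sites.** Default inclusion radius around ligand atoms is 0.7 nm, about
  one coarse-grained contact distance. Structure-to-trajectory registration
  is the caller's responsibility; the package only validates overlap.
  Voxels whose footprint straddles the periodic cell boundary are excluded
  from bulk averages (they carry diluted counts). The occupancy integral is
  reported in molecules so claims like "an ensemble of three cholesterol
  molecules fits this site" have a computable analogue.

## Degenerate inputs and failure behaviour

Empty selections raise errors rather than returning zero grids, so
misconfigured lipid names fail loudly. All-zero grids make the symmetry
deviation undefined (error), mismatched grids refuse voxelwise subtraction
(no silent resampling), lipids without an anchor bead are reported by
molecule id, GRO/DCD parse failures carry line/record positions, and the
residence-time oracle raises a budget error that still carries its partial
estimate.

## Known limitations

Contact durations are reported at frame resolution and uncensored, so they
underestimate residence at sites comparable to the window length. The toy
dynamics has no lipid–lipid excluded volume, which inflates site occupancy
at deep wells. The 2D density convention (one anchor per molecule) differs
from bead-count conventions used elsewhere; the metadata records it.
Koff estimation by survival-curve fitting and binding-site clustering from
contact networks are natural extensions deliberately out of scope.
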