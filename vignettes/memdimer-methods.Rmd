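---
title: "Methods: geometry, lipids and landscapes for a transmembrane helix dimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, lipids and landscapes for a transmembrane helix dimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(memdimer)
```

## The system and the questions

The C-terminal transmembrane helix of Bax ("helix alpha-9", residues
169-189, sequence `TWQTVTIFVAGVLTASLTIWK`) anchors the protein in the
mitochondrial outer membrane (MOM) and homodimerizes there. Cysteine
crosslinking experiments distinguish at least three dimer interfaces:

* an **intersected** dimer, crosslinkable at I175, G179, A183, I187 and
  packing through the G179xxxA183 motif with a right-handed crossing angle
  near +40 degrees;
* a **parallel** dimer, crosslinkable at Q171, A178, T182, L185, with
  |crossing angle| under 15 degrees;
* an **iso-parallel** intermediate whose interface brings the T172 and
  T186 pairs within disulfide-linkable distance.

`memdimer` implements the quantitative trajectory analyses used to
characterise such dimers — axis and crossing-angle geometry,
rotation-angle collective variables, crosslink-distance validation,
anionic-lipid distribution/stoichiometry/diffusion, polar-contact
statistics, and minimum free-energy path extraction on two-dimensional
rotation-angle landscapes — together with a synthetic-data module that
generates every input with known ground truth. Simulation trajectories of
this system are not publicly deposited, so the synthetic module is what
makes every analysis verifiable end to end at desk scale.

## Synthetic data: what it emulates, and what it does not

**Ideal helices.** `build_ideal_helix()` places backbone N, CA, C, O and
CB atoms on a canonical alpha helix (rise 1.5 Å per residue, twist 100
degrees, CA radius 2.3 Å) with the axis exactly on +z. Atom offsets in the
per-residue cylindrical frame were derived once from an
internal-coordinate construction at phi = -57.8, psi = -47 degrees with
standard bond geometry and frozen as constants; every residue therefore
has identical, canonically helical local geometry (helicity reads 100%).

**Dimer fixtures.** `build_dimer_fixture()` docks a second helix copy
against a fixed first copy by random-restart rigid-body minimisation
(6 degrees of freedom, 24 restarts plus perturbation-polish rounds) of the
summed squared CB-CB distances over the state's crosslinkable pairs
(CA at glycine 179), under a hard no-clash constraint (no inter-monomer
heavy-atom pair under 2.5 Å; one C-C bond, 1.5 Å, models the A183I side
chain extension). The crosslink-compatible distance is taken as CB-CB
<= 7.0 Å: a formed disulfide has CB-CB near 4-5 Å, and 7 Å adds the
flexibility an engineered cysteine pair samples. Crossing angles and
rotation-CV readings of the fixtures are *emergent* from this
optimisation: the intersected pair set (spacing i, i+4 on a right-handed
helix) produces right-handed crossing near +40 degrees; the parallel set
produces |angle| near 12 degrees.

Two properties of this construction deserve honesty. First, the
distance-only objective leaves the *split* of interface rotation between
the two monomers nearly degenerate (a flat valley: docking runs from
different seeds reach equal objectives at different splits while the SUM
of the two monomer rotations is tightly pinned). A small deterministic
tie-break (weight 0.002 per squared degree of monomer spin asymmetry,
matching the valley's depth) selects the more two-fold-symmetric member —
the physically expected configuration for a homodimer — and makes
fixtures reproducible across seeds. Second, because the objective pulls
the declared pairs as close as the clash constraint allows (~2.6 Å),
residues only 40-60 degrees off the interface azimuth can also fall under
the 7 Å cutoff; the fixtures reproduce the *documented* exclusivity (the
T172/T186 pairs are not linkable in the intersected or parallel fixtures)
but not exclusivity of every pair set against every state. Likewise the
single-pseudo-atom A183I model clears the partner monomer by ~3.6 Å in
the iso-parallel fixture, so the prescribed clash-triggered re-dock does
not engage; reproducing the experimentally observed disruption of the
T186-T186' pair would need a fuller side-chain steric model. These
limits are asserted as-is in the test suite rather than patched over.

**Bilayer and lipid dynamics.** `build_membrane()` represents each lipid
by one headgroup bead — every analysis in scope (density, stoichiometry,
MSD, bead polar contacts) consumes headgroup positions only, so acyl
tails add nothing but cost. The default composition is the MOM model
mixture 46.5% PC, 28.4% PE, 8.9% PI, 8.9% PS, 7.3% cardiolipin (CL); PI,
PS and CL are anionic, and CL's bulky four-tail footprint enters as an
area weight of 2 in stoichiometry percentages, not as geometry. Type
counts use largest-remainder apportionment (exactly 465/284/89/89/73 at
1000 lipids); beads are placed without lateral overlap (6 Å minimum
separation; keep the packing fraction below ~0.4, e.g. 200 lipids in a
110 Å box, or random placement jams). `simulate_lipid_trajectory()` runs
an independent 2D Gaussian walk per bead (variance 2 D dt per lateral
dimension, periodic wrapping) with an optional deterministic radial drift
toward the protein for "enriched" types; a single seed makes runs
bit-for-bit reproducible. Realistic bilayer values are D around 4-8 x
10^-4 Å^2/ps (4-8 x 10^-8 cm^2/s); recovery tests also use faster walks
(0.02-0.05 Å^2/ps) purely to decorrelate statistics at desk scale. The
walk has no inter-lipid interactions, no leaflet coupling and no membrane
deformation, so passing tests demonstrate correctness of the estimators,
not realism of membrane physics.

**Analytic landscapes.** `make_analytic_fes()` sums negative Gaussian
basins E(a,b) = -sum_i depth_i exp(-d_i^2 / 2 w_i^2) and shifts the global
minimum to zero (the original offset is retained). Basin parameters,
numerically refined minima and the continuous energy function ride along
as ground truth. `fes_six_state_surface()` provides a six-basin layout —
four low-energy states at (0,0), (30,20), (60,40), (70,90) and two
shallow intermediates — with the origin basin deepest and the final basin
3.5 kcal/mol higher, mimicking a landscape in which an intersected-like
state is the global minimum and a parallel-like state is reachable
through two transitions.

## Geometry observables

**Helix axis.** The axis is the principal eigenvector of the CA
coordinate covariance (sign fixed N-to-C), origin at the CA centroid.

**Rotation-angle collective variables (alpha, beta).** Each monomer's
spin about its own axis is read as the signed azimuth — right-handed
about the N->C axis direction — of the axis->CB(I175) direction,
measured from the *interface anchor*: the projected direction toward the
partner monomer's axis origin. The CV is the difference between this
reading on the analysed frame and on the zero-angle reference dimer, so
it is (0, 0) at the reference, recovers scheduled rigid rotations about
the monomer axes to well under a degree, and is invariant under global
rigid-body motion. Anchoring to the interface (rather than to a
laboratory direction) is what makes two *independently built* dimers
comparable; for trajectories that only rotate monomers about their own
axes the two definitions coincide. I175's CB is used as the spin
reference because it is mid-helix, present in both monomers, and central
to the intersected interface. An alternative anchor through the
inter-axis mutual perpendicular foot was evaluated and rejected: it is
ill-conditioned as the helices approach parallel.

**Crossing angle.** The signed angle between the two fitted axes,
computed as the torsion angle about their mutual perpendicular and
folded to at most 90 degrees in magnitude. The sign convention reports
*right-handed* packing as positive — the packing mode of GxxxA/GxxxG
(spacing i, i+4) interfaces; in the crystallographic convention these
crossings carry a negative torsion, so the raw torsion is negated.

**Backbone RMSD** is a standard Kabsch (SVD) superposition over matched
N/CA/C/O atoms; the suite pins it to an independent superposition oracle
at 1e-6 Å.

**Helicity** is the percentage of assignable residues (those with both
phi and psi) inside phi in [-100, -30] and psi in [-67, -7] degrees — a
window that contains the canonical helix with margin. A dihedral
criterion is used instead of hydrogen-bond-based assignment because bead
and backbone-only models carry no amide hydrogens.

## Lipid analyses

`center_and_dewrap()` shifts every frame so the protein centroid sits at
the box centre (removing overall drift), re-wraps laterally by minimal
image, and accumulates minimal-image inter-frame increments into
continuous ("unwrapped") coordinates for MSD use.

`radial_stoichiometry()` counts headgroups whose lateral minimal-image
distance to the dimer centroid is at most 20 Å (the disc is 2D because
the cutoff is radial in the membrane plane), time-averages within each
window, and reports mean +/- SD across windows (the default is three
10-ns windows, matching the convergence check used for such analyses).
The anionic percentage is area-weighted — sum(weight x count, anionic) /
sum(weight x count, all) x 100 with CL counting twice — computed per
leaflet and averaged; per-leaflet values are retained since reported
counts in this field rarely state the leaflet convention.

`lateral_diffusion()` renders the mean-square-displacement relation in
its 2D (in-plane) form: per lipid, MSD(tau) is averaged over all time
origins in the window and fitted linearly over lags between 10% and 50%
of the window (short lags are bead-noise dominated, long lags
statistics-poor); D = slope/4. Reported per type as mean +/- SD over
molecules, in Å^2/ps and cm^2/s (1 Å^2/ps = 1e-4 cm^2/s). A fit-quality
R^2 is computed on the type-averaged MSD against the through-origin line
(exact for diffusion, since MSD(0) = 0); coherent drift gives MSD
proportional to tau^2 and R^2 below the 0.9 flag. Note the estimator's
statistics: with the 10-50% lag range the per-molecule D has order-one
relative error regardless of window length, so per-type means need on
the order of 100 molecules of that type for ~10% accuracy.

## Polar contacts

A contact is a pair of polar atoms (protein N/O; the lipid bead, standing
in for headgroup O/N/P) within 3.6 Å. Per-frame booleans are merged into
maximal events with zero gap tolerance by default (a 1-frame bridge is
available but off, preferring reproducibility over smoothing); an event
of k frames contributes k frame-intervals, so summed event duration over
trajectory length equals occupancy exactly. A pair is classified
**transient** when its longest event is shorter than 1 ns and
**frequent** otherwise (the complement rule; only the transient side of
the boundary is defined by the duration criterion).

## Landscape analysis

`detect_states()` finds local minima on the 8-connected grid (exact-value
ties drain to one representative, so flat far-field plateaus do not
fragment), assigns basins by steepest descent, and merges minima whose
depth over their lowest boundary saddle is under 0.5 kcal/mol. States are
labelled by increasing minimum energy.

`extract_block_minimum_path()` renders the block-extraction construction:
the landscape is tiled into 20 x 20 degree blocks (a config default, not
a constant — the axes are rotation angles in degrees), each block
contributes its minimum-energy cell as a candidate point, and candidates
are chained from the start to the end block under 8-connected block
moves. The route's quality is scored by the maximum grid energy actually
crossed — including the straight cell-lines between consecutive
candidates and from the true endpoints to their blocks' candidates — and
the chain minimising that maximum is selected (ties by total candidate
energy, then block index, making the result deterministic). Path points
report grid values only; nothing is interpolated.

`minimax_cell_path()` is the independent oracle: the exact
minimum-bottleneck route at cell resolution, obtained by bisection over
energy levels with flood-fill connectivity. Every block-extracted route
is a particular cell-resolution route, so its bottleneck can never beat
the oracle's — asserted over random multi-basin surfaces.

`barrier_analysis()` reads, per consecutive pair of states visited,
barrier = (maximum path energy between the two centres) minus the origin
centre's energy, plus the endpoint free-energy difference and the overall
barrier. Angle axes are treated as bounded (no periodic wrap) since the
landscapes of interest span a bounded angular range; a periodic variant
was considered and left out of scope.

## Pipeline, determinism and sizes

`run_generate()` / `run_analyze()` / `run_report()` orchestrate the
stages under one `run_config()` (YAML-overridable); every report cites
the config hash, and identical config + seeds give byte-identical
bundles. All randomness flows through explicit seeds; each generator call
has exactly one. Default desk-scale sizes — 200 lipids in a 110 Å box, 30
ns of Brownian dynamics saved every 100 ps, 1-degree landscape grids,
24-restart docking — keep a full generate-analyze-report cycle in the
low minutes on one core while leaving every estimator inside its
validated statistics regime; they are choices of the package, stated
here so users can scale up.

## Known limitations

* Fixtures are crosslink-constraint-compatible approximations, not
  reconstructions of any deposited model; their residue-level contact
  maps (e.g. charged-terminus salt bridges) are limited by the
  backbone+CB representation.
* The lipid model has no excluded volume during dynamics, no
  electrostatics, and a flat bilayer; enrichment is a phenomenological
  drift.
* Helicity uses a dihedral window, not DSSP classes; only the helix/not
  distinction is supported.
* XTC trajectories are not readable (no installed reader); multi-model
  PDB and DCD are.
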