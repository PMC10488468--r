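---
title: "Membrane-drug trajectory analysis with memtraj: models, parameters and design choices"
author: "memtraj authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane-drug trajectory analysis with memtraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`memtraj` post-processes molecular-dynamics trajectories of small,
hydrophilic drug molecules — the motivating case is nucleoside
reverse-transcriptase inhibitors (NRTIs) such as zalcitabine (ddC),
stavudine (d4T), didanosine (ddI) and apricitabine (ATC) — interacting
with one-component phospholipid membranes (zwitterionic POPC, anionic
POPG), as bilayers or as opposed monolayer pairs flanking a water slab.
It computes the standard battery of membrane observables (density
profiles, area per lipid, thicknesses, chain order parameters), drug
localization and mobility (Einstein-relation diffusion coefficients,
adsorbed/in-solution classification), geometric hydrogen-bond
statistics, classical interaction-energy decompositions, supermolecular
complex extraction, and conceptual-DFT reactivity descriptors from
tabulated quantum-chemistry output. It never runs MD or quantum
chemistry itself: inputs are structures, trajectories and plain-text
tables.

The package is organised around three S4 containers with validity
checks — `Topology` (per-atom element, mass, charge, Lennard-Jones
parameters, molecule membership, functional-group labels), `Trajectory`
(frames of coordinates with orthorhombic boxes and times) and
`QMStateTable` (fixed-geometry energies and fitted charges of the
(N−1)-, N- and (N+1)-electron states). Everything downstream consumes
only these.

## Conventions and units

* Coordinates in Å; the membrane normal is z and the membrane is
  oriented in the xy plane. Boxes are orthorhombic only.
* Energies in kcal/mol for classical terms and hartree for QM tables;
  time in ns; diffusion coefficients in cm²/s, with the single unit
  conversion 1 Å²/ns = 10⁻⁷ cm²/s applied exactly once, in
  `fitDiffusion()`.
* Atom indices are 0-based in all on-disk tables (the `index` column);
  R-level function arguments take ordinary 1-based row positions.
* Output coordinates live in the centred primary cell
  \[−L/2, L/2); all pair geometry uses the minimum-image convention.

# Density profiles

`computeDensityProfile()` bins a labelled group's mass along z, per
frame, after shifting the chosen reference to z = 0: the bilayer
midplane (mean z of P-labelled atoms) or, for opposed monolayers, the
water-slab centre — a monolayer pair has no midplane. Drug molecules
are binned as centres of mass. The histogram uses an odd number of bins
with the central bin centred on the reference, so mirrored structures
produce exactly mirrored profiles. Density is mass per bin volume
(kg/m³, 1 amu/Å³ = 1660.539 kg/m³) with one global normalization for
all groups, and the discrete integral ∑ρΔz·LxLy returns the group's
mass exactly — this conservation identity is tested on every synthetic
run. The default bin width of 0.5 Å resolves headgroup features at the
~10 Å scale; it is a repository default, as is everything about the
absolute normalization (figure-axis values of published density plots
are not reproduction targets).

`locateModes()` reports local maxima with a topographic-prominence
filter (default 5% of the global maximum) and, given the phosphate-peak
position, classifies each mode as surface adsorption versus adsorption
into the headgroup region — the two adsorption modes distinguishable in
ρ(z) for membrane-active drugs, the deeper one shifted toward the
interface.

# Structural metrics

* Area per lipid: time average of LxLy divided by the leaflet's lipid
  count.
* Bilayer thickness: frame-averaged distance between the mean z of the
  phosphorus atoms of opposite leaflets; hydrophobic thickness uses the
  C2 carbons instead. The leaflet-mean definition is used deliberately
  (not nearest-neighbour pairings) because that is the printed
  definition of these observables.
* Monolayer thickness: within one leaflet, distance between mean P and
  mean terminal-carbon z.
* Leaflets are assigned once, from the first frame, by splitting the
  per-lipid mean z at the largest gap of its sorted values; lipids
  diffuse laterally only at the surface pressures considered, so
  flip-flop is not modelled and the assignment is never revisited. A
  largest gap under 5 Å is rejected as a single-leaflet system.

## Chain order parameter S_mol

For carbon n of a chain, S_mol(n) = ⟨(3cos²θ − 1)/2⟩ over lipids and
frames, with θ the angle between the C(n−1)→C(n+1) vector and z.
The molecular-axis definition with the heavy-atom C(n−1)→C(n+1) vector
is the standard choice when no explicit hydrogens are available; since
only cos²θ enters, both leaflets contribute symmetrically without a
sign flip. This choice matters: absolute S_mol values depend on the
axis convention, so published order-parameter curves are treated as
qualitative, not numeric, references. Values are bounded in
\[−0.5, 1\]; all-trans chains along z give exactly 1, the magic angle
(54.74°) gives 0, and isotropic orientations average to 0.

# Diffusion and localization

`unwrapMolecule()` rebuilds continuous centre-of-mass paths by
accumulating minimum-image increments (valid while per-frame
displacements stay below half the box). `msdCurve()` averages squared
displacements over all time origins; `fitDiffusion()` takes the
least-squares slope m of MSD versus lag τ and returns D = m/(2d) —
the Einstein relation — with d = 3 for drug molecules (they exchange
between water and membrane) and d = 2 appropriate for lipids, which
diffuse laterally. Defaults:

* analysis segment: the second half of the trajectory, mirroring the
  practice of estimating D from the second half of a production run;
* fit window: 10–50% of the largest lag — below 10% the curve is
  dominated by short-time noise, above 50% too few origins remain;
* negative slopes are clipped to D = 0 with a warning.

`classifyLocation()` calls a molecule adsorbed when its centre of mass
stays within a z threshold of the membrane reference in at least half
the frames. The default threshold is the phosphate-density peak
position plus 5 Å — the cutoff used by the original analysis protocol is
not published, so this package states its own and makes it
configurable. `partitionByD()` splits coefficients at 2×10⁻⁶ cm²/s,
the boundary between the two empirically observed D ranges: molecules
below it are the ones penetrating the hydrophilic headgroup region,
molecules above it are in solution. Ties go to the fast set.

# Hydrogen bonds

`detectHBonds()` applies the standard geometric criterion:
donor–acceptor (heavy-atom) distance below 3 Å and an angle cutoff of
20°. The angle is measured between the donor→hydrogen and
donor→acceptor vectors (deviation from linearity), the convention of
the common trajectory-analysis tools; the distance is donor-heavy-atom
to acceptor-heavy-atom, not H···A. Donor hydrogens are atoms labelled
`donor_H`, paired with the nearest N/O of their molecule; acceptors are
atoms labelled `acceptor`. The choline N(CH₃)₃ nitrogen is not a
standard hydrogen-bond acceptor; it participates only when
`extendedAcceptors = TRUE` and is tabulated under its own partner class,
so drug–choline contacts can be counted without contaminating the
conventional classes. Statistics are cross-tabulated by drug role
(drugs can donate and accept) and partner class (phosphate, ester,
glycerol/hydroxyl, choline, water), per system and per molecule.

Lifetimes: a bond instance is a maximal run of frames in which the same
donor–H–acceptor triple is detected, optionally bridging interruptions
up to `gapTolerance` frames (bridged frames count toward the lifetime);
lifetime = frames in the run × frame stride. Whether published
lifetime numbers allowed gap frames is not stated, so the tolerance is
exposed with a strict default of 0.

The production detector evaluates all donor–acceptor pairs with
vectorized minimum-image arithmetic rather than cell lists — at the
desk-scale system sizes this package targets (10³–10⁴ atoms) the dense
evaluation is both simpler and faster in R, and a scalar double-loop
recount retained in the test suite serves as the independent oracle.

# Interaction energies

`pairEnergy()` implements the CHARMM-style non-bonded pair sum between
two disjoint groups:

* Lennard-Jones: ε_ab\[(r_min,ab/r)¹² − 2(r_min,ab/r)⁶\] with geometric
  ε combination and additive r_min/2 (no NBFIX);
* Coulomb: 332.0636·q_a·q_b/r (kcal·Å/mol·e²);
* both multiplied by the CHARMM switching polynomial, identically 1
  below 10 Å and 0 above the 12 Å cutoff, making the potential
  continuous at both radii.

Electrostatics is deliberately a cutoff approximation: no Ewald/PME
term is computed. Production simulations use PME for long-range
electrostatics, but the per-group interaction energies this module
reproduces are those of cutoff-based post-processing tools, and that
approximation is inherited knowingly. Frame selection defaults to the
final sixth of the trajectory thinned to at most 100 frames, the
convention of extracting 100 frames from the final 20 ns of a 120 ns
run.

`decomposeDrugLipid()` classifies each drug per frame
(adsorbed/solution, same rule as `classifyLocation()` applied
frame-wise) and averages drug–lipid and drug–water electrostatic and
van der Waals energies within each class; `groupContribution()`
restricts the drug side to one functional-group label (e.g. ribose
oxygens, or the 3′-position sulfur of ATC versus the CH₂ of ddC) —
pairwise additivity guarantees the labelled groups of a partition sum
exactly to the whole-molecule energy, which is tested. Published
per-system averages require the original trajectories and are not
desk-scale targets; the machinery and its identities are.

`extractComplex()` implements the supermolecular-geometry cut: the drug
plus every lipid with any atom within 3 Å, whole lipids only, drug
first, lipids by molecule id, writable as PDB for external
semi-empirical or DFT single points. `supermolecularInteraction()`
evaluates ΔE = E(complex) − E(drug) − E(lipids) from externally
supplied energies; on this package's own pairwise-additive classical
energies, ΔE collapses identically to the direct drug–lipid pair
energy, which serves as an internal consistency test.

# Conceptual-DFT reactivity descriptors

From fixed-geometry state energies: I = E(N−1) − E(N),
A = E(N) − E(N+1), chemical potential μ = −(I+A)/2 and hardness
η = I − A (finite-difference/parabolic approximations of the first and
second energy derivatives with respect to electron number). From
per-state fitted charges (e.g. CHELPG), condensed Fukui indices via
populations N_i = Z_i − q_i:

f^n_i = N_i(N+1) − N_i(N), f^e_i = N_i(N) − N_i(N−1),
f^r_i = (f^n_i + f^e_i)/2.

The charge-to-population sign convention N_i = Z_i − q_i is the single
largest silent-error risk in this arithmetic and is fixed and
documented here. When the input charge sets change the total electron
count by exactly one between adjacent states, the index sums are
normalized to unity (∑f^n = ∑f^e = 1); electrostatic-fitting schemes
need not conserve populations exactly, so deviations beyond 10⁻³ are
reported as warnings and never corrected — the finite-difference
formulas as written perform no renormalization. Negative indices are
preserved: such atoms respond opposite to the molecule as a whole.
`classifySoftHard()` labels atoms soft when f^r reaches a fraction
(default one half) of the per-molecule maximum; the fraction is a
display convention, since published soft/hard colourings are not
quantified. `compareEnvironments()` reports percentage changes of μ and
η between two environments (vacuum versus aqueous continuum); the
published magnitude of such environment effects requires the original
QM outputs and is not asserted.

# The synthetic-data module

Because the motivating study deposits no trajectories, every analysis
is validated against generated data with known ground truth, produced
by code paths independent of the analyses:

* `generateMembraneTrajectory()` builds coarse bead lipids (choline, P,
  C2, tail beads ending in a terminal CH₃) on a lattice of exactly
  `apl` Å² per lipid, with per-lipid P heights drawn from
  Normal(±19 Å, 1 Å), mirrored across leaflets and frozen — lipids
  perform lateral-only Brownian motion, reflecting the observation that
  phospholipids diffuse laterally at these surface pressures. Defaults
  emulate the simulated systems: 100 lipids per leaflet, area per lipid
  67.3 Å² (the equilibrated POPC value; 69.4 Å² for a POPG-like
  system), 18 drug molecules, frames every 50 ps. Drugs are two-atom
  rigid donor bodies split into an adsorbed population
  (D = 0.5×10⁻⁶ cm²/s) and a free population (D = 5×10⁻⁶ cm²/s),
  straddling the 2×10⁻⁶ cm²/s partition boundary. Brownian steps use
  per-axis variance 2DΔt; paths are unwrapped internally (retained as
  ground truth for MSD tests) and wrapped on output, so the unwrapping
  code is genuinely exercised. Reflecting z-walls confine each drug
  population to its region — the headgroup band or the water slab —
  emulating populations that remain adsorbed or in solution over the
  analysis window and guaranteeing that free drugs stay beyond the
  12 Å energy cutoff from any lipid. Same seed, same bytes.
* `generateBrownianEnsemble()` provides unconfined Brownian reference
  ensembles for Einstein-relation recovery tests.
* `generateHBondFixture()` constructs isolated donor–H···acceptor
  triples with exact requested distance and angle.
* `generateEnergyFixture()` builds isolated charged LJ pairs whose
  reference energies come from an independent scalar closed form.
* `generateQMFixture()` builds state tables from drawn I/A values and
  per-atom Fukui weights summing exactly to one, so electron counts
  differ by exactly one between states and all descriptor ground truths
  follow from the construction.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: no inter-particle forces (configurations
are not energy-minimized, so absolute LJ magnitudes on synthetic frames
are dominated by accidental overlaps; only closed-form fixtures test
energy *values*), no lipid packing correlations or undulations, no
electrostatic self-assembly, no monolayer surface-pressure physics, no
drug exchange between the adsorbed and free populations.

# Numerical and design choices

* Leaflet assignment, the S_mol axis, the 10–50% fit window, the
  z-threshold default and the soft/hard fraction are the genuinely open
  design points; each is documented above with its rationale and
  exposed as a parameter.
* Degenerate inputs: zero interatomic distances, overlapping energy
  groups, empty selections, non-increasing frame times, truncated
  trajectory files and missing QM states all raise immediate, specific
  errors rather than propagating NaNs; a flat density profile yields
  zero modes; an empty D list partitions into two empty sets.
* The trajectory container stores frames dense in memory; at the
  problem sizes used throughout (≤ ~3,000 atoms × ≤ 1,000 frames,
  chosen so the full test battery of recovery experiments — e.g. 50
  molecules × 1,000 frames for diffusion recovery, 500 frames for
  density-width recovery — runs comfortably on a laptop) this is far
  below memory limits. The text `.trj` format trades compactness for
  transparency and diffability; coordinates are stored at 10⁻⁴ Å.
* `runAll()` orchestrates all modules from one configuration (YAML or
  list) with a single seed, writes TSV/JSON outputs plus a provenance
  report, and is byte-deterministic for a fixed configuration.

# Known limitations

* Cutoff electrostatics (no PME): absolute electrostatic energies for
  charged systems are approximations; relative and per-group
  comparisons are the intended use.
* The geometric hydrogen-bond criterion has no energetic component and
  no special handling of bifurcated bonds.
* PSF/CHARMM topology dialects are not parsed; the documented TSV
  topology table is the only authoritative parameter source.
* Fixed-geometry finite differences assume the same external potential
  for all three charge states; tables violating that assumption are the
  caller's responsibility.
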