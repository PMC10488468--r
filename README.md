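# memtraj

Analysis toolkit for molecular-dynamics studies of small hydrophilic
drugs — nucleoside reverse-transcriptase inhibitors (NRTIs) are the
motivating case — interacting with phospholipid monolayers and
bilayers (POPC/POPG), plus conceptual-DFT reactivity descriptors from
tabulated quantum-chemistry output.

**Who it is for.** Computational membrane biophysicists who already have
trajectories (or want validated synthetic stand-ins) and need the
standard post-processing battery with tested, reproducible numerics:

* partial mass-density profiles ρ(z) along the membrane normal, with
  adsorption-mode detection (surface vs into-the-headgroups maxima);
* structural metrics: area per lipid, bilayer thickness (mean P–P
  distance of opposite leaflets), hydrophobic thickness (C2–C2),
  monolayer thickness (P to terminal carbons), chain order parameters
  S_mol(n) = ⟨(3cos²θₙ − 1)/2⟩;
* Einstein-relation diffusion coefficients D = slope(MSD)/2d from
  unwrapped centre-of-mass paths, with the empirical two-range
  partition at 2×10⁻⁶ cm²/s separating membrane-penetrating from
  in-solution molecules, and an explicit adsorbed/solution classifier;
* geometric hydrogen bonds (donor–acceptor distance < 3 Å, angle
  ≤ 20°), role- and partner-resolved statistics and lifetimes,
  with choline N(CH₃)₃ as an optional extended acceptor class;
* CHARMM-style interaction energies (LJ + Coulomb, switching over
  10–12 Å), drug–lipid/drug–water decompositions by location class,
  per-functional-group contributions, supermolecular complex
  extraction (drug + all lipids within 3 Å) and
  ΔE = E(complex) − E(drug) − E(lipids);
* conceptual-DFT descriptors: I = E(N−1) − E(N), A = E(N) − E(N+1),
  μ = −(I+A)/2, η = I − A, and condensed Fukui indices
  f^n = N(N+1) − N(N), f^e = N(N) − N(N−1), f^r = (f^n + f^e)/2 from
  per-state atomic charges via populations Nᵢ = Zᵢ − qᵢ.

A synthetic-data module generates membrane-like trajectories, exact
hydrogen-bond geometries, closed-form energy fixtures and toy QM tables
with known ground truth, so the whole pipeline is testable without
simulations or downloads. See the vignette
(`vignettes/membrane-drug-analysis.Rmd`) for the models, conventions
and design decisions.

## Worked example

A small synthetic bilayer (30 lipids/leaflet at 67.3 Å²/lipid, P bands
at ±19 Å) carrying 6 membrane-adsorbed and 6 free drug molecules:

```r
library(memtraj)

spec <- membraneSpec(n_lipids_per_leaflet = 30, n_frames = 200,
                     n_drugs_adsorbed = 6, n_drugs_free = 6,
                     n_waters = 150, seed = 5)
traj <- generateMembraneTrajectory(spec)

structuralReport(traj)
#>                  metric value sd
#> 1             apl_upper 67.30  0
#> 2             apl_lower 67.30  0
#> 3     bilayer_thickness 38.02  0
#> 4 hydrophobic_thickness 30.02  0

dc <- diffusionCoefficients(traj)
dc$location_class <- vapply(dc$molecule_id,
                            function(m) classifyLocation(traj, m),
                            character(1))
head(dc, 4)
#>   molecule_id  D_cm2_s fit_r2 location_class
#> 1         210 1.68e-07  0.972       adsorbed
#> 2         211 1.74e-07  0.882       adsorbed
#> 3         212 4.34e-07  0.992       adsorbed
#> 4         213 3.56e-07  0.986       adsorbed

partitionByD(setNames(dc$D_cm2_s, dc$molecule_id))
#> $slow
#> [1] "210" "211" "212" "213" "214" "215"
#> $fast
#> [1] "216" "217" "218" "219" "220" "221"
```

The APL is recovered exactly (the box is constructed from it), the P–P
thickness matches the planted 38 Å band separation, and the slow set of
the D partition coincides with the adsorbed classification and with the
planted populations: the molecules with small D are the ones sitting in
the hydrophilic headgroup region. Drug–lipid energies show the same
split — nonzero only for the adsorbed class (absolute LJ magnitudes on
synthetic frames are dominated by random overlaps, since the generator
applies no forces; energy *values* are validated against closed-form
fixtures instead):

```r
decomposeDrugLipid(traj)$byClass
#>   location_class target elec       vdw n_obs
#> 1       adsorbed  lipid -2.3  1.73e+04   204
#> 2       adsorbed  water  0.0 -4.16e-03   204
#> 3       solution  lipid  0.0  0.00e+00   204
#> 4       solution  water  0.0  1.64e+03   204
```

Reactivity descriptors from a toy three-state table:

```r
r <- reactivityDescriptors(generateQMFixture(5, seed = 1)$table)
#> I = 0.4834  A = 0.1025  mu = -0.2930  eta = 0.3809 hartree
sum(fukuiIndices(generateQMFixture(5, seed = 1)$table)$f_n)
#> [1] 1
```

The Fukui index sums equal one whenever the charge tables change the
electron count by exactly one between states.

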