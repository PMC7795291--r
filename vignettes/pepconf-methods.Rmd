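---
title: "Methods: conformational and energetic analysis of blocked tripeptides"
author: "pepconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational and energetic analysis of blocked tripeptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepconf)
```

# Scope and model

`pepconf` analyses ensembles of capped X–X tripeptides (ACE–X–X–NME,
two copies of a titratable residue X blocked by acetyl and N-methyl
caps), the standard minimal system for studying intrinsic backbone
propensities of an amino acid under conventional or discrete
constant-pH molecular dynamics.  The package covers five analyses and a
synthetic-data generator that stands in for trajectories:

1. **Ramachandran free-energy surfaces.**  Backbone torsion pairs
   (φ, ψ) are counted on a periodic grid (1° spacing by default) and
   converted to relative Gibbs free energies by Boltzmann inversion,
   ΔG~i~ = −k~B~T ln(n~i~/n~max~), with k~B~ = 0.0019872041
   kcal mol^−1^ K^−1^ and T = 300 K by default.  The most populated
   cell defines ΔG = 0 exactly.  Empty cells are *masked* — the
   inversion is undefined at n~i~ = 0 — and are never interpolated;
   they appear as white regions in plots and as `NA` sentinels in the
   gnuplot-style grid files.  No kernel smoothing is applied: the grids
   are plain population histograms.

2. **Nine-region classification.**  The φ/ψ torus is partitioned into
   the nine classical conformational regions (C5, P~II~, α~D~, β~2~,
   C7~axial~, α~L~, α′, α~R~, C7~eq~).  Population fractions per
   monomer (monomer 1 = N-terminal residue, monomer 2 = C-terminal)
   summarise conformational propensities, with the four dominant
   regions (P~II~, α~R~, C7~eq~, C5) reported individually and the
   remaining five grouped as "others".

3. **Side-chain orientation (θ) maps.**  θ is the torsion
   (side-chain atom 1)–CA1–CA2–(side-chain atom 2), a single angle
   describing the relative orientation of the two side chains across
   the monomers.  Paired with φ or ψ of either monomer it yields four
   maps (φ~1~/θ, θ/ψ~1~, φ~2~/θ, θ/ψ~2~), processed with the same
   binning/inversion machinery.  Interatomic distance distributions
   between the selected side-chain atoms complement the maps.

4. **Single-point energetics.**  An AMBER-style force-field evaluation
   on coordinate frames: harmonic bonds and angles, cosine torsions,
   12-6 Lennard-Jones, Coulomb electrostatics, and an
   Onufriev–Bashford–Case (OBC) Generalized Born solvation term.
   Normalized (unit-area) per-term histograms support distribution
   comparisons, and the electrostatic terms can be decomposed into
   backbone and side-chain contributions.

5. **Protonation-state analysis.**  Discrete per-frame state series
   (e.g. the four carboxyl sites syn-O1/syn-O2/anti-O1/anti-O2, or the
   histidine δ/ε tautomers) are summarised as per-residue populations
   with user-defined aggregates, transition counts, and
   state-conditioned splits of dihedral series for conditioned
   Ramachandran maps.

# Conventions

All angles are degrees on the half-open interval [−180°, 180°),
wrapped by `x − 360·floor((x+180)/360)`; +180° maps to −180°, so
binning is unambiguous.  Torsions follow the IUPAC sign convention
(positive clockwise viewed from the second toward the third atom).
Note that a torsion is *invariant* under reversing the atom order — a
property the test suite asserts.  Units are fixed package-wide:
Ångström, kcal/mol, elementary charge, picoseconds.

Binning uses the half-open rule: angle *a* falls in bin
`floor((a+180)/spacing)`, so each cell owns its lower edge and every
sample lands in exactly one cell.  The spacing must divide 360.

# Free-energy minima

Minima are located on a coarser grid (2° by default) than the surface
itself, which suppresses spurious minima arising from counting noise.
A cell is a minimum when it is strictly lower than all eight toroidal
neighbours (periodic across the ±180° seam) **and** none of those
neighbours is masked.  The second condition is deliberate: an isolated
occupied cell on the sparse fringe of a basin has eight empty
(infinite-ΔG) neighbours and would otherwise register as a minimum —
precisely the artifact the coarser grid is meant to remove.  Ties
produce no minimum.  For very large samples on fine grids, clusters of
shallow noise minima can survive inside one basin; `locate_minima()`
optionally merges minima closer than `min_separation` degrees
(toroidal Chebyshev distance), keeping the deepest per cluster, which
reduces the list to one entry per physical basin when the separation
is of the order of the basin width.

# The nine-region table

The boundary coordinates of the nine regions are a shipped,
documented *convention*, not a claim of fidelity to any particular
published partition: the package uses a rectangular decomposition of
the torus whose cells contain the canonical centers of each region
(P~II~ near (−75°, 150°), α~R~ near (−57°, −47°), C7~eq~ near
(−80°, 80°), C5 near (−150°, 150°), α~L~ near (60°, 40°), and so on).
The table lives in `extdata/regions_default.json`; every API accepts a
user-supplied table of polygons in the same format, so a lab's
preferred partition can be dropped in.  Polygons are given in an
unwrapped chart (vertices may exceed ±180°) so that seam-crossing
regions stay contiguous; membership is tested against the nine torus
images of each polygon, boundary-inclusive, in the listed priority
order — a point on a shared boundary deterministically belongs to the
earlier region.  Full coverage is verified by rasterization when the
table is loaded.

# Energetics details

Nonbonded bookkeeping follows AMBER: 1–2 and 1–3 pairs are excluded,
1–4 pairs are scaled (electrostatics ÷ 1.2, Lennard-Jones ÷ 2.0), the
Coulomb constant is 332.0636 kcal Å mol^−1^ e^−2^, and Lennard-Jones
combination is Lorentz–Berthelot on R~min~/2 and geometric on ε.

The GB term is OBC flavour I (α = 0.8, β = 0, γ = 2.909125) with
ε~in~ = 1 and ε~out~ = 78.5.  One convention deserves emphasis: the
topology's `gb_radius` is the *offset-corrected* intrinsic radius used
directly in the pairwise descreening integrals and the tanh rescaling,
so an isolated atom's effective Born radius equals its `gb_radius`
exactly and the analytic Born limit
ΔG = −166.0318·q²·(1/ε~in~ − 1/ε~out~)/R holds by construction.  Users
converting AMBER prmtop radii should subtract the usual 0.09 Å
dielectric offset themselves.  Salt enters as a Debye–Hückel factor
exp(−κ f~GB~) on the pairwise dielectric term, with κ computed from
first principles for a 1:1 electrolyte at the run temperature
(κ ≈ 0.104 Å^−1^ at 0.1 M, 300 K); no empirical rescaling of κ is
applied.

## Backbone/side-chain decomposition

How a backbone–side-chain *cross* pair should be attributed is
genuinely ambiguous, so both conventions are implemented:

* `cross = "half"` (default) splits every pair energy half to each
  atom's group; backbone + side chain equals the total exactly, which
  is the right choice when the decomposition must be conserving.
* `cross = "separate"` sums only pairs internal to each group and
  reports the cross term separately.  This reproduces the semantics of
  a masked trajectory analysis, and has the important property that
  the backbone value depends on backbone charges alone.

Cap atoms (ACE/NME) count as backbone in both modes: they are
main-chain extensions.

The `"separate"` mode is what makes the constant-pH charge artifact
visible in its purest form.  Discrete constant-pH residues in AMBER
keep the *protonated* form's backbone partial charges in every
protonation state, changing only side-chain charges (with Cβ absorbing
the net-charge difference).  On identical frames, backbone
electrostatics under such a "CPHMD-style" deprotonated charge set is
therefore *bit-identical* to the protonated result, while a properly
matched deprotonated residue (whose backbone charges differ, as in the
conventional-MD libraries) gives a shifted distribution.  The package's
toy topologies carry all three charge sets (`protonated`,
`deprotonated`, `deprotonated_cphmd`) so this comparison is a two-line
computation.

# The synthetic-data generator

The generator produces inputs with the statistical structure the
analyses assume — it emulates *sampling*, not dynamics.

* **Dihedrals** are i.i.d. draws from a mixture of independent von
  Mises pairs (one concentration per angle component), one basin per
  named region.  A bivariate sine model was considered and rejected:
  independent components suffice to place mass in named regions and
  are exactly analysable, so mixture weights and free-energy gaps have
  closed-form targets.  The default scenario uses four basins centered
  in P~II~, α~R~, C7~eq~, C5 with weights 0.4/0.3/0.2/0.1 — the
  typical ranking of the dominant regions in blocked-tripeptide
  simulations — and κ = 100 (≈ 5.7° spread), which keeps each basin
  well inside its region.
* **Protonation series** are first-order Markov chains: at each frame,
  with probability `switch_prob` a new state is proposed from the
  stationary fractions and always accepted.  The stationary law
  therefore equals the requested fractions *exactly*, while the chain
  retains the switching cadence of a discrete constant-pH run.  The
  default `switch_prob = 0.1` corresponds to a 0.01 ps^−1^ trial
  frequency at a 10 ps frame interval.  `switch_prob = 0` freezes the
  initial state regardless of fractions (documented precedence).  The
  default scenario samples the four carboxyl sites at 96% syn / 4%
  anti, split evenly between the two oxygens.
* **Toy peptides** are built from ideal internal coordinates: a
  P~II~-like backbone (φ = −75°, ψ = 150°), trans amides, χ~1~ = 65°
  (a rotamer chosen so that no template has steric clashes), and
  schematic side chains (the histidine imidazole is closed by an
  explicit ring bond; the acidic proton sits syn on O2).  Bonded
  equilibrium parameters are read off the template geometry, so the
  template sits at the bonded-energy minimum and Gaussian coordinate
  jitter (`perturb_frames()`, default σ = 0.05 Å) yields well-behaved
  energy distributions.  Charges are schematic stand-ins with exact
  per-residue sums; they are never claimed to equal any force field's
  values.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: temporal autocorrelation of dihedrals,
correlated φ/ψ within a basin, coupling between conformation and
protonation state, realistic rotamer statistics, or solvent-mediated
structure.  Conclusions about the analysis code transfer to real
trajectories; conclusions about sampling efficiency or kinetics do
not.

# Numerical choices

* k~B~ = 0.0019872041 kcal mol^−1^ K^−1^; default T = 300 K.
* The reference cell of a free-energy grid is set to exactly 0 (not
  merely −k~B~T ln 1 in floating point).
* Histograms share a binning grid by anchoring bin edges at integer
  multiples of the bin width, so overlap coefficients
  (Σ min(f~A~, f~B~)·Δ) are well defined without re-binning.  Energy
  histograms default to 1 kcal/mol bins; distance histograms to 0.1 Å,
  which resolves sub-Ångström shifts.
* Atom pairs closer than 10^−6^ Å in a nonbonded pair raise a
  singularity error rather than returning astronomical energies.
* Degenerate inputs fail loudly: all-empty count grids, torsions with
  collinear bonds, region tables with coverage gaps, charge sets whose
  sum misses the declared net charge by more than 10^−6^ e.

# Reproducibility

Every stochastic operation takes an explicit integer seed, and the
end-to-end `run_report()` driver derives all stage seeds from the one
scenario seed; two runs with the same scenario produce byte-identical
artifact manifests (MD5 per file).  The test suite exercises the full
pipeline at reduced problem sizes (10^3^–10^5^ frames for unit tests;
10^6^ frames for the statistical recovery checks, matching the designed
operating scale of the analyses), and checks the energetics against an
independent naive double-loop evaluator to 10^−8^ kcal/mol, the minima
search against an exhaustive toroidal scan, and the classifier against
independent interval logic.

# Known limitations

* The energetics is single-point only: no forces, no integration, no
  periodic electrostatics, no nonpolar (SASA) solvation term; kinetic
  energy is accepted as a pass-through column in energy tables but
  never computed.
* The nine-region boundaries are a convention (see above); population
  numbers depend on the table in use.
* The θ-angle atom selection per residue type is a shipped editable
  table, not a fixed definition.
* The Markov state generator's per-residue chains are independent;
  cooperative titration is out of scope.
* No pKa estimation or titration-curve fitting is provided — the
  protonation module analyses state series, it does not generate
  thermodynamics.
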