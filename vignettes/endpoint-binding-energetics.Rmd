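---
title: "End-point binding energetics: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-point binding energetics: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmgbsa)
```

## The model

`mmgbsa` estimates relative protein–ligand (or protein–protein) binding
energies from conformational ensembles with the end-point MM-GBSA /
MM-PBSA scheme.  The binding energy is the thermodynamic-cycle difference

$$\Delta G_{bind} = G_{complex} - G_{receptor} - G_{ligand},$$

with each species' free energy approximated as

$$G = E_{MM} + \Delta G_{pol} + \Delta G_{np},$$

i.e. the gas-phase molecular-mechanics energy, the polar (electrostatic)
solvation free energy from an implicit-solvent model, and a nonpolar
solvation term proportional to the solvent-accessible surface area (SASA).
Configurational entropy is **not** computed — the `entropy` field of every
result is fixed at `"omitted"` — so the numbers are *relative* binding
energies, suitable for ranking ligands against a common receptor but not
for absolute affinity prediction.

### Single-trajectory protocol

All three terms are evaluated on the *same* frames of the complex ensemble
(the receptor and ligand terms reuse the complex coordinates).  Because the
conformations are identical, every intramolecular contribution — bonded
terms and intra-chain nonbonded sums — cancels exactly in the difference,
leaving only the intermolecular cross terms for $E_{MM}$.  The package
exploits this: `interaction_energy()` computes only the cross-group Coulomb
and Lennard-Jones sums, and a brute-force complex-minus-parts loop oracle
in the test suite verifies the cancellation to $10^{-10}$ relative.  The
multi-trajectory variant (separate receptor/ligand simulations) is out of
scope: it would reintroduce intramolecular terms that this code never
computes.

### Gas-phase terms

Electrostatics use $E = k_e \sum_{i \in A, j \in B} q_i q_j / r_{ij}$ with
$k_e = 332.0636$ kcal·Å/(mol·e²); van der Waals terms use the 12-6 form
$\epsilon_{ij}[(r_{min,ij}/r)^{12} - 2 (r_{min,ij}/r)^{6}]$ with
Lorentz–Berthelot combination on $(r_{min}/2, \epsilon)$.  No nonbonded
cutoff is applied: a cutoff belongs to the dynamics engine that generated
the ensemble, not to the analysis, and exact pairwise sums are what the
oracle tests certify.

### Polar solvation: GB

The default polar model is the pairwise generalized Born form

$$\Delta G_{pol} = -\frac{k_e}{2} \sum_{i,j}
\left(\frac{1}{\epsilon_{in}} -
\frac{e^{-\kappa f_{GB}}}{\epsilon_w}\right) \frac{q_i q_j}{f_{GB}},
\qquad
f_{GB} = \sqrt{r_{ij}^2 + \alpha_i \alpha_j
e^{-r_{ij}^2 / 4 \alpha_i \alpha_j}},$$

where the double sum includes self terms ($f_{GB} = \alpha_i$ at
$r_{ij} = 0$).  Effective Born radii $\alpha_i$ come from
Hawkins–Cramer–Truhlar pairwise descreening of offset-corrected intrinsic
radii ($\tilde\rho = \rho - 0.09$ Å), with the closed-form descreening
integral validated in the tests against Monte-Carlo volume integration.
Two numerical details worth knowing:

* deeply buried atoms can drive $1/\alpha$ through zero under pairwise
  descreening; the inverse radius is clamped so that $\alpha \le 50$ Å;
* Debye–Hückel salt screening enters through the $e^{-\kappa f_{GB}}$
  factor.  Increasing $\kappa$ *strengthens* polar solvation (makes
  $\Delta G_{pol}$ more negative) — ionic screening stabilizes charges in
  solvent — and the property tests assert that direction.

$\kappa$ is derived from the ionic strength via the SI closed form
(0.1 M, 80, 300 K gives $\kappa \approx 0.1027$ Å⁻¹) unless set
explicitly.

### Polar solvation: PB

`pb_polar_energy()` solves the linearized Poisson–Boltzmann equation on a
uniform grid by successive over-relaxation (compiled kernel, ω = 1.9,
convergence when the largest potential update falls below $10^{-5}$
kcal/(mol·e)).  Choices:

* the dielectric boundary is the plain union of atom spheres (intrinsic
  Born radii) sampled at grid-face midpoints — no reentrant molecular
  surface, which keeps the solver small and its convergence testable;
* $\kappa^2$ acts on all nodes outside the atom spheres (no Stern layer);
* charges are spread trilinearly; boundary potentials use the analytic
  Debye–Hückel superposition;
* the reported energy is the difference between the solvated solve and a
  uniform-dielectric reference solve on the identical grid, which cancels
  the grid self-energy.

On a Born ion (q = 1 e, radius 2 Å) the solver lands within 1.6 % of the
closed form at 0.25 Å spacing and within 5 % at 0.5 Å, with the error
shrinking monotonically under refinement; the acceptance suite pins the
5 % bound at 0.25 Å.  The solver is deliberately capped at 2000 atoms —
it exists to make the PB route exact-testable at desk scale, not to
compete with production PB codes.  Only the *linearized* equation is
implemented.

### Nonpolar solvation

$\Delta G_{np} = \gamma \cdot SASA + \beta$ with $\gamma = 0.0072$
kcal/(mol·Å²) and $\beta = 0$ by default.  SASA uses the Shrake–Rupley
sphere-point algorithm with a deterministic 960-point Fibonacci lattice
per atom and the Lennard-Jones $r_{min}/2$ as atomic radius.  A
deterministic sphere-point method was chosen over approximate
neighbor-overlap schemes (LCPO-style) precisely because it has analytic
test surfaces: an isolated sphere is exact to the lattice resolution and a
two-sphere overlap matches the spherical-cap closed form to 2 %.  The one
caveat of a fixed lattice is that SASA (hence $\Delta G_{np}$) is only
invariant under rigid rotation to lattice tolerance (~1 %); the exactly
rotation-invariant components are the MM and GB terms.

## Decomposition

Per-residue contributions attribute every component of the binding energy:

* **MM terms** — each intermolecular pair's energy is split half-and-half
  between the two partner atoms (the standard end-point convention);
* **GB** — each atom's attribution (self term plus half of each pair term)
  in the complex, minus the same attribution in its isolated species; the
  radii change on binding, so intra-chain terms contribute to the
  difference;
* **nonpolar** — per-atom SASA difference times $\gamma$.

On the GB path residue sums reproduce every `binding_energy()` component
to $10^{-6}$ kcal/mol by construction, and the tests enforce it.  For PB
there is no pairwise decomposition, so residues are attributed by charge
perturbation.  Plain zero-out marginals double-count cross terms (their
sum approaches twice the total when cross terms dominate), so the package
uses the *symmetrized* marginal
$\tfrac12\,[\,G(\text{all}) - G(\text{without } r)\,] +
\tfrac12\,G(\text{only } r)$: the linearized PB energy is a quadratic form
in the charges, making this two-point average exactly additive up to
solver tolerance.  It is still residue-resolved (spread uniformly over the
residue's atoms) and costs two extra PB solves per residue, which is why
the PB route is reserved for small systems.

## Interface analysis

Hydrogen bonds use the donor-heavy–acceptor distance cutoff 3.2 Å and, in
explicit-hydrogen mode, a D–H⋯A deviation-from-linearity cutoff of 30°
(hydrogens are associated to donors by < 1.25 Å proximity within the
residue).  The phrase "angle between donor and acceptor" is ambiguous in
common usage; this package fixes the deviation-from-linearity convention
and records the geometry mode in every output row.  When a structure has
no hydrogens, a heavy-atom distance-only mode applies and is flagged.  A
unique bond is a (donor atom, acceptor atom) pair; records below a 10 %
occupancy (lifetime) filter are dropped by default.  Salt bridges pair
acidic side-chain oxygens (ASP OD1/OD2, GLU OE1/OE2, terminal OXT) with
basic side-chain nitrogens (LYS NZ, ARG NE/NH1/NH2, HIS ND1/NE2) at an
O–N cutoff of 3.4 Å, reported per residue pair.  Histidine follows the
neutral NE2-protonated tautomer convention: ND1 accepts, NE2 donates.
Detection is validated against per-frame all-pairs distance scans with
exact set equality.

`kabsch_rmsd()` provides optimal-superposition RMSD via the SVD
construction with a proper-rotation determinant correction, cross-checked
against an independent quaternion implementation.

## Frame windows and replicates

`frame_window(ensemble, start, end, stride)` keeps frames with times in
the **closed** interval and samples at the stride measured from the window
start (nearest in-window frame per stride target, earlier frame on ties).
Window count is always derived from the data — a window of 19–25 ns at
100 ps yields 61 frames under this convention — and both bounds and stride
are configuration, never hard-coded counts.  Replicate aggregation reports
component means as means of per-run means and the standard error *across
runs* (`NA` for a single run); per-frame standard errors are carried as a
diagnostic only, because frames within a run are autocorrelated in real
data.  `rank_ligands()` sorts by ascending mean ΔG, breaks ties by label
(and flags them), and marks pairs whose gap is below the combined standard
error as statistically unresolved.

## The synthetic generator: what it does and does not show

`make_toy_complex()` builds two rigid pseudo-atom clusters with residue
bookkeeping, parameterized from the shipped table.  The docked geometry
creates explicit contacts: the receptor atoms on the interface face meet
dedicated ligand partner atoms directly across a 3.8 Å gap, carrying
opposite charges $\mp s q_0$ ($q_0 = 0.3$ e, 4 pairs by default), and each
chain is kept net-neutral by compensating charges on the far side.
Ensemble frames add i.i.d. Gaussian jitter (σ = 0.1 Å default) to every
coordinate as a stand-in for thermal fluctuation.  Generation is a pure
function of the spec including the seed.

`make_ligand_series()` replicates one geometry across a charge-scale
series — the synthetic analogue of a ligand panel with graded affinity —
whose ground-truth order (stronger interface charges bind more strongly)
is itself *verified* by direct computation in the tests, not assumed.
Under the default study conditions (30 + 10 atoms, 10 frames, 5 strengths,
σ = 0.1 Å) the ranking pipeline recovers the true order with Spearman
ρ = 1 across all tested seeds, and ρ = 1 exactly at σ = 0.

What this does **not** show: the generator has no realistic protein
geometry, no conformational response to binding (clusters are rigid up to
isotropic jitter), no explicit solvent, no rotamers, and the jitter has
none of the correlation structure of real dynamics.  Passing the recovery
test demonstrates that the *analysis machinery* — energies, solvation,
averaging, ranking — is internally correct and noise-robust at the tested
noise scale; it says nothing about force-field accuracy or sampling
adequacy on real complexes.

## Parameters that matter

| Parameter | Default | Units | Where |
|---|---|---|---|
| $\epsilon_w$ solvent dielectric | 80 | – | `solvent_model()` |
| $\epsilon_{in}$ solute dielectric | 1 | – | `solvent_model()` |
| ionic strength | 0.1 | mol/L | `solvent_model()` |
| $\gamma$ surface tension | 0.0072 | kcal/(mol·Å²) | `solvent_model()` |
| $\beta$ nonpolar offset | 0 | kcal/mol | `solvent_model()` |
| probe radius | 1.4 | Å | `solvent_model()` |
| GB radius offset | 0.09 | Å | `effective_born_radii()` |
| SASA points/atom | 960 | – | `sasa()` |
| H-bond distance / angle | 3.2 / 30 | Å / ° | `detect_hbonds()` |
| occupancy filter | 0.10 | fraction | `detect_hbonds()` |
| salt-bridge O–N cutoff | 3.4 | Å | `detect_salt_bridges()` |
| PB spacing / padding | 0.5 / 6 | Å | `pb_polar_energy()` |

The shipped parameter table (`default_parameter_table()`) is a synthetic,
representative set — element-typed Lennard-Jones values, descreening-style
Born radii and scale factors, rough integral-charge side chains — adequate
for exercising and validating the machinery; for production analyses users
should supply their force field's charges and radii through
`read_parameter_table()`.

## Conventions and other design choices

* Atom indexing is 1-based everywhere, matching R and the R structural
  packages; residue numbering follows the PDB (1-based, per chain).
* Multi-model PDB is the canonical trajectory format: text, portable, and
  round-trips through `read_pdb()`/`write_pdb()` to the format's 10⁻³ Å
  precision.
* Validation problem sizes were chosen for exactness rather than scale:
  random oracle toys of up to ~20 atoms and ~15 frames (the brute-force
  oracles are $O(n^2 f)$), ranking studies at 40 atoms × 10 frames × 5
  ligands × 20 seeds, PB grids of ~65³ nodes.
* Reports print energies with two decimals in TSV (units in the header)
  and at full precision in JSON; JSON reports round-trip through
  `read_report()`.

## Known limitations

* Relative energies only; no entropy, no absolute ΔG.
* Single-trajectory protocol only.
* Linearized PB with an atom-sphere dielectric boundary; no nonlinear PB,
  no molecular (reentrant) surface, no Stern layer.
* GB lacks neck/surface corrections — intended for the pairwise model's
  validity regime, not for quantitative comparison to other GB flavors.
* Heavy-atom H-bond mode is distance-only and deliberately permissive.
* The PB residue attribution is residue-resolved, not atom-resolved.
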