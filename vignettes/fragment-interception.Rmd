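---
title: "Cluster models for harmonic IR spectra of molecular crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster models for harmonic IR spectra of molecular crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibrafrag)
```

## The problem

Harmonic vibrational frequencies of pharmaceutical solids are routinely
computed from a single molecule optimized in vacuum. That model discards two
things the measured mid-IR spectrum of a crystal depends on: the conformation
the molecule adopts inside the lattice, and the intermolecular hydrogen bonds
that shift the stretching and bending modes of donor/acceptor groups by tens
to hundreds of cm^-1. Empirical scale factors (a single multiplier such as
0.99 applied to all computed wavenumbers) compensate the systematic harmonic
overestimation on average, but cannot repair missing physics that acts
selectively on hydrogen-bonded functional groups.

`vibrafrag` implements a family of finite cluster models that reintroduce
that physics at controlled cost:

1. **single** -- one molecule extracted from the crystal and optimized in
   isolation (the conventional approach, kept as the control);
2. **repeating unit** -- a chosen central molecule plus every molecule
   hydrogen-bonded to it, extracted from a supercell and optimized as a
   whole;
3. **central** -- the central molecule alone, with the geometry it acquired
   inside the optimized repeating unit (configuration information without
   explicit neighbors);
4. **fragment** -- the optimized repeating unit trimmed to the parts that
   matter for the central molecule's modes: everything within a distance
   cutoff, the covalent functional groups engaged in hydrogen bonds to the
   central molecule, and conjugated groups touching retained atoms; severed
   single bonds are closed with hydrogen link atoms.

Frequencies from each model are matched against an experimental peak list
and summarized as MAE and RMSE, optionally split into functional-group (FG)
and non-functional-group (NFG) vibrations.

## Harmonic analysis

For a cluster of $N$ atoms with Cartesian Hessian $H$ (Hartree/Å$^2$) and
masses $m_i$ (amu), the mass-weighted Hessian
$\tilde H_{ij} = H_{ij}/\sqrt{m_i m_j}$ is projected onto the complement of
the rigid-body space (3 translations and 3 rotations at the center of mass;
2 rotations if the geometry is collinear, detected at 1e-6 Å perpendicular
extent) and diagonalized. Eigenvalues convert to wavenumbers as
$\tilde\nu = \mathrm{sign}(\lambda)\sqrt{|\lambda|}/(2\pi c)$ with packaged
CODATA constants; negative eigenvalues — non-minimum geometries — are
reported as negative wavenumbers, the common convention for imaginary modes.
The rigid-body block magnitudes before removal are kept as a diagnostic
(`rigid_frequencies`); at a true minimum with an accurate Hessian they are
well below 1 cm^-1.

Scale factors multiply all frequencies; all reported tables round half-up
to two decimals, matching the precision of published comparison tables.
The packaged worked examples reproduce published scaled entries:
`3517.12 * 0.99 = 3481.95` and `3656.99 * 0.99 = 3620.42` cm^-1. Two
vendored rows are *not* consistent with the stated 0.99 factor (one
Lamivudine row, and the whole Repaglinide scaled column, which matches
roughly 0.9795); they are shipped as printed and excluded from the
reproduction checks.

## Energy backends and the toy force field

The electronic-structure engine is abstracted behind a two-function
contract: `energy(geometry)` in Hartree and `gradient(geometry)` in
Hartree/Å. Any adapter honouring it (e.g. around an external quantum
chemistry code) plugs into the optimizer, the finite-difference Hessian and
the pipeline. The built-in `toyff` backend is a transparent harmonic force
field

$$E = \sum_b k_b (r - r_0)^2 + \sum_a k_\theta (\theta - \theta_0)^2
    + E_{\mathrm{LJ}} + E_{\mathrm{Coulomb}} + E_{\mathrm{HB}},$$

with analytic gradients, 1-2/1-3 nonbonded exclusions, and a 12-10
hydrogen-bond term
$E_{\mathrm{HB}} = \varepsilon\,[5 (r_0/r)^{12} - 6 (r_0/r)^{10}]$
applied to the H···acceptor pairs detected geometrically when the backend is
constructed. The topology is frozen at construction, consistent with a
harmonic treatment around a reference structure. It is a *testing* backend:
it makes every property of the surrounding workflow checkable against closed
forms and brute-force oracles, it is not a chemistry model.

Parameter choices for the packaged fixtures are physically plausible round
numbers: X–H stretching constants of 0.75–1.0 Hartree/Å$^2$ put the
stretches at 3600–3950 cm^-1, angle constants of 0.12–0.15 Hartree/rad$^2$
put bends in the fingerprint region, and a hydrogen-bond well depth of
0.005 Hartree (≈3 kcal/mol) at $r_0 = 1.8$ Å gives stretch shifts of order
100–200 cm^-1 — the magnitude real hydrogen bonds produce.

## Geometry optimization and Hessians

The optimizer is BFGS with a backtracking (Armijo) line search. Convergence
requires, on one accepted step, *simultaneously*: energy change ≤ 1e-5
Hartree, maximum force ≤ 0.002 Hartree/Å and maximum displacement ≤ 0.005 Å.
Force and displacement are measured as the maximum over atoms of the
per-atom Euclidean norm (the norm convention is a package choice; published
criteria rarely state one). Energy never increases between accepted steps,
and failure to converge raises a typed condition carrying the last geometry
rather than silently returning it.

Hessians are central differences of analytic gradients, symmetrized as
$(H + H^\top)/2$. The default step of 0.005 Å matches the displacement
tolerance scale. Two numerical facts matter when *measuring properties* of
the Hessian: the finite-difference truncation error is $O(\delta^2)$, so at
0.005 Å the rotational rigid-body block of a stiff X–H oscillator picks up
an artifact of order 15 cm^-1 and the acoustic sum rule holds only to about
1e-5 Hartree/Å$^2$. At a 2e-4 Å step (still far above gradient round-off
for analytic gradients) the rigid residues drop below 1 cm^-1 and the sum
rule below 1e-6; the test suite and the acceptance script probe at that
step, while vibrational frequencies themselves differ by well under
0.1 cm^-1 between the two steps.

## Design choices in the paper-shaped gaps

Several steps of the workflow are underdetermined by published descriptions;
the package fixes them as follows.

* **Bond perception**: minimum-image distance ≤ sum of Cordero-style
  covalent radii + 0.40 Å (user-overridable); H–H bonds excluded. All
  lattice images within the cutoff are recorded, so a pair bonded through
  two different images — a periodic polymer — is detected and rejected
  during molecule extraction.
* **Hydrogen-bond criteria**: H···A ≤ 2.5 Å, D···A ≤ 3.5 Å, D–H···A ≥ 120°,
  donors {N, O}, acceptors {N, O, S} (sulfur included for thio-drugs).
  Bifurcated contacts are all reported; no pruning heuristics.
* **"Conjugated structures"**: operationalized geometrically — an atom is
  unsaturated if it sits in a bond shorter than a multiple-bond threshold
  for its element pair (C–C 1.45, C–N 1.40, C–O 1.30 Å, ...), O/N atoms
  bonded to such atoms are included, and conjugated groups are the connected
  components of the flagged atoms. This is a reproducible stand-in, not a
  claim about electronic structure.
* **Fragment retention predicate**: a neighbor atom survives if it is within
  `radius` (default 4 Å) of a central atom, OR belongs to the hydrogen-bond
  functional group — the donor/acceptor heavy atom plus its direct covalent
  neighbors, with attached hydrogens following by the closure rule — OR sits
  in a conjugated group touching a retained atom. The two-bond hydrogen
  shell emerges from the closure rule; taking *heavy* atoms two bonds out
  would drag in whole alkyl chains, which is exactly what interception is
  meant to remove.
* **Link atoms**: severed single covalent bonds are capped with hydrogen
  placed along the cut direction at standard lengths (C–H 1.09, N–H 1.01,
  O–H 0.96 Å). Cutting through a conjugated group is refused with advice to
  enlarge the radius.
* **Central-molecule selection**: deterministic default (centroid nearest
  the supercell centroid) instead of random choice, so results are
  reproducible; any index can be forced.
* **Assignment matching**: published tables pair peaks by expert judgment.
  The package provides `nearest_greedy` (descending experimental peaks, each
  taking the nearest unused calculated value within a window) and `optimal`
  (minimum total absolute deviation via a shortest-augmenting-path
  assignment solver, maximizing the number of matched pairs first). Ties —
  which arise whenever two calculated values bracket two experimental ones
  from the same side — are broken toward the rank-preserving pairing, which
  reproduces published table layouts. Greedy and optimal genuinely differ on
  such instances; both are exposed and user tables can be supplied verbatim.
* **FG/NFG classification**: a row counts as a functional-group vibration if
  its label involves an N–H, O–H, S–H or C=O stretch/bend — the
  hydrogen-bonding moieties; this rule is user-overridable per row.

## What the synthetic fixtures emulate — and what they do not

`make_toy_crystal()` generates four deterministic toy crystals with known
ground truth: `hf_chain` (H–F molecules hydrogen-bonded head-to-tail along
one axis), `water_sheet` (a 2-D donor/acceptor lattice, every interior
molecule donating and accepting twice), `formamide_sheet` (amide chains
with an O=C–N conjugated group, so interception interacts with conjugation),
and `ethanol_dimer_cell` (an O–H···O dimer whose acceptor has an alkyl tail,
the canonical capping case). At `noise = 0` each geometry is an exact
stationary point of its accompanying force-field parameters — bonds, angles
and hydrogen-bond contacts all at their reference values — so optimizer,
Hessian and projection properties can be asserted tightly. Gaussian jitter
(`noise > 0`, seeded) produces perturbed variants for recovery tests.

Because H–F falls outside the default donor/acceptor element sets, the
`hf_chain` ground truth carries its own criteria with fluorine added; the
package defaults are unchanged.

The fixtures reproduce the *topology* of hydrogen-bonded crystals, not the
packing, dispersion or anharmonicity of real drugs. Passing tests show the
workflow — extraction, detection, model construction, projection, matching —
is correct; they say nothing about the accuracy of any particular quantum
backend on a real crystal. Published headline MAE/RMSE values for the three
drug systems require the original CCDC structures, a commercial DFT engine
and complete expert assignment lists, none of which ship here; the vendored
tables serve as worked examples for the scaling and statistics machinery.

In the end-to-end pipeline the experimental spectrum is, by default, stood
in for by the *pseudo-experimental* peak list: the central-localized modes
(≥ 50% mass-weighted amplitude on central atoms) of the optimized repeating
unit, restricted to ≥ 400 cm^-1 because mid-IR acquisition does not record
lattice modes below that. On the `hf_chain` fixture this produces the
method's signature ordering: the fragment model reproduces the
hydrogen-bond-shifted stretch exactly (MAE 0), while the single-molecule
and central models miss it by the full coupling shift (~170 cm^-1) and
uniform 0.99 scaling makes the single model *worse* — the same qualitative
behavior reported for real drug crystals. A 300 cm^-1 matching window is
used for these runs because the pseudo-experimental stretch band sits ~170
cm^-1 from the single-molecule value; published tables show deviations of
the same order (up to 274 cm^-1) for hydrogen-bonded N–H stretches.

## Problem sizes and determinism

The shipped studies are intentionally small: supercells up to 5×5×1 of
2–9-atom molecules, clusters of 6–30 atoms, Hessians up to 90×90. A full
four-model pipeline on `hf_chain` takes well under a second; the complete
test suite runs in seconds. Everything is deterministic given the fixture
seed: identical configuration and inputs produce a byte-identical report
payload, and the report carries the configuration (with an MD5 hash) for
provenance.

## Known limitations

* No space-group symbol database: CIF files must be P1 or carry explicit
  symmetry operator lists. No disorder/partial occupancy handling.
* Clusters are treated in vacuum; there are no periodic energies, and net
  neutral molecules are assumed.
* The toy force field has no torsional terms, so rotatable tails contribute
  zero-frequency internal modes; they are harmless to the workflow but mean
  toy frequencies below the fingerprint region are not meaningful.
* IR intensities default to unit values unless a backend supplies dipole
  information; synthesized spectra are therefore mode-position overlays,
  not absorbance predictions.
* Anharmonic corrections are out of scope by design; the package operates
  entirely within the harmonic approximation.
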