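---
title: "Hybrid QM/MM rescoring of docking poses: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid QM/MM rescoring of docking poses: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmmdock)
```

## The problem

Classical docking scores struggle exactly where electronic structure
matters: metal coordination (zinc sites, heme iron), covalent
ligand-receptor bonds, and strong polarization. A hybrid
quantum-mechanics/molecular-mechanics (QM/MM) treatment keeps the cheap
classical description for most of the receptor and treats only a small
*primary system* (PS) — the ligand, plus optionally bound metals,
coordinating side chains, or an active-site shell — quantum mechanically,
embedded in the point charges of the classical *secondary system* (SS).

`qmmdock` implements this rescoring scheme end to end as a self-contained
engine: partitioning with hydrogen link atoms, charge-scaled electrostatic
embedding, the subtractive energy combination, classical and hybrid
MM-GBSA-style scores, pose clustering/selection/optimization/refinement,
and redocking evaluation. Because licensed QM and MM programs cannot ship
with a package, the QM backend is a pluggable contract with two built-in
engines (below) and an external-adapter file-exchange protocol, and a
deterministic synthetic-complex generator replaces curated experimental
benchmark sets. Everything is therefore testable at desk scale.

## Energy model

All units are CHARMM-compatible: Angstrom, kcal/mol, elementary charges,
Coulomb constant 332.0637 kcal A/mol/e2.

### Subtractive QM/MM energy

The total energy of a complex is assembled subtractively:

$$E_{QMMM} = E_{QM}(PS) + E^{elec}_{QM}(PS \leftrightarrow SS)
  + E_{MM}(Complex) - E_{MM}(PS) - E^{elec}_{MM}(PS \leftrightarrow SS)$$

The QM engine evaluates the PS (capped with hydrogen link atoms) in the
field of the SS embedding charges; the MM terms it replaces are subtracted.
Engines that treat the external charges like nuclei (Hartree-Fock/DFT-like
codes) additionally fold the SS-SS charge-charge repulsion into their
energy; such engines declare `includes_ss_self_energy = TRUE` and the
pipeline subtracts `ss_self_repulsion()` a posteriori to avoid double
counting. Every term is stored separately in an `EnergyBreakdown`, so
totals always re-sum from components.

One convention deserves emphasis: **all** MM energies in the package omit
terms internal to the rigid receptor ("score-relevant convention"). These
terms are constant for any pose, and omitting them *consistently* — in
`E_MM(Complex)`, in `E_MM(PS)`, and in the mirror engine — gives the
subtractive scheme and the classical score one common zero of energy. This
makes two exact identities hold, which the test suite exploits heavily:
with the mirror engine the QM/MM score equals the classical score to
machine precision, and a partition with an empty SS reduces `E_QMMM` to
`E_QM(PS)`.

### Partitioning and boundary treatment

PS selection modes: the ligand (`"lig"`, plus the covalently bound protein
residue, added automatically); additionally metals within 5 A of a ligand
heavy atom plus their coordinating residues (`"lig+MB"`); additionally
every residue with at least one atom inside a cubic box around the ligand
centroid (`"lig+Box+MB"`). With side-chain-only inclusion the boundary is
cut at the CA-CB bond; with backbone inclusion boundaries are shifted so
that all cuts fall on C-CA bonds of the flanking peptide groups. Each cut
bond receives one hydrogen link atom at 1.10 A (configurable; the boundary
alignment is part of the scheme, the length is a standard C-H value) along
the cut-bond direction. Link atoms carry no classical charge and no
Lennard-Jones parameters; the embedding charge of the first classical
neighbor is set to zero. Cutting through ring bonds is refused.

Embedding charges are the SS force-field charges scaled by a fraction,
default 0.5: halving the charges mimics a dielectric constant of 2 and
avoids over-polarization of the QM region. The zeroed boundary-neighbor
charge is *not* redistributed — the embedding set may carry a non-integer
total charge; only the zeroing itself is part of the scheme, and inventing
a redistribution rule would be a stronger assumption than omitting one.
Metal "coordination" is defined as any residue with a heavy atom within
2.8 A of the metal (typical first-shell distances; configurable).

### Scores

The classical score is an MM-GBSA-style free-energy estimate:

$$\mathrm{Score}_{class} = E^{intra}(Lig) + E^{intra}(Rec_{flex})
 + E^{vdW}(Lig \leftrightarrow Rec) + E^{elec}(Lig \leftrightarrow Rec)
 + \Delta G^{solv,elec} + \Delta G^{solv,np}$$

with an optional Morse-like metal binding potential
`E(r) = D(1 - e^{-a(r - r_0)})^2 - D` added per metal (parameters are
user-supplied configuration; none are bundled). The hybrid score replaces
the MM interaction terms by the subtractive QM/MM energy:

$$\mathrm{Score}_{QMMM} = E_{QMMM} + \Delta G^{solv,elec} + \Delta G^{solv,np}$$

For solvation the PS charges can be either the force-field charges or the
engine's QM-derived (Mulliken-like) charges; in the latter case a link
atom's charge is folded into its QM host atom, a choice documented here
because no convention is canonical (the link atom has no classical
identity for the continuum model to see).

### Solvation surrogate

The original scoring uses the FACTS continuum model, whose internal
equations are out of scope here. The package substitutes a standard
pairwise-descreening generalized-Born expression (Hawkins-Cramer-Truhlar
effective radii, canonical `f_GB`) with the externally specified
parameters: solute dielectric 2, solvent dielectric 78.5, nonpolar
surface-tension coefficient 0.015 kcal/mol/A2, probe 1.4 A, 12 A nonbonded
cutoff. Intrinsic radii are LJ Rmin/2 clamped to >= 1 A. The score
contract is agnostic to the GB flavor; the "dielectric constant of 2" is
interpreted as the solute dielectric, which is flagged as an
interpretation rather than an equivalence.

The nonpolar term is `gamma x SASA` with a Shrake-Rupley numerical surface
(96 golden-spiral points per atom by default). Two numerical choices
matter:

* the burial test is smoothed over 0.1 A (logistic weight) instead of a
  hard inside/outside decision. For an isolated sphere the result is
  unchanged (the single-sphere value is exact up to quadrature); for
  overlapping atoms the area becomes a differentiable function of the
  coordinates. With a binary test the score is a step function with
  `gamma * 4 pi R^2 / n_points` (about 0.02 kcal/mol) corrugation, which
  defeats any gradient-based optimizer;
* any fixed spherical quadrature is rotation-invariant only to quadrature
  accuracy (2-3% at 96 points). The analytic terms (bonded, LJ, Coulomb,
  GB polar) are invariant at 1e-8 kcal/mol; the tests hold the nonpolar
  term to its quadrature accuracy.

## QM engines

An engine is a registry entry with a `compute(system, partition, spec)`
function. Two engines ship with the package:

* **mirror-mm** returns exactly the MM energy of the PS and the exact MM
  PS-SS Coulomb energy, with force-field charges. By construction the
  subtractive scheme then collapses to the plain MM energy. This engine is
  the oracle backbone of the test suite: it turns deep pipeline identities
  into machine-precision assertions.
* **eem** is a toy electronegativity-equalization model: charges solve the
  charge-equilibration linear system (electronegativity + hardness +
  Coulomb coupling, total charge constrained) in the field of the
  embedding charges, giving genuinely polarizable QM-like charges and a
  variational energy (embedding always lowers the electronic energy
  relative to gas phase). The shipped per-element parameters (H, C, N, O,
  S, Fe, Zn) are engine configuration, not physics claims.

Method, basis set and multiplicity are pass-through metadata for the
built-in engines (a real application would set, e.g., an open-shell
doublet for ferric heme); they matter for external adapters, which plug in
through a tagged text-file exchange (`write_qm_exchange()` /
`read_qm_result()`) so a real semi-empirical or DFT code can be wired in
without touching the pipeline. No such program is bundled, deliberately:
determinism and licensing both argue against it.

## Pose workflow

Poses are clustered by greedy leader clustering on the symmetry-adapted
ligand RMSD (radius 2 A by default; the clustering procedure of the
classical docking stage is external prior art and its radius is not
printed, so the default is a documented choice). Selection takes either
the best pose of the best N clusters or all poses of the best N clusters
(N = 10 by default), and the relaxed native pose can be appended to the
ensemble so rescoring benchmarks are not confounded by sampling failures.

Optimization is quasi-Newton (BFGS with backtracking Armijo line search,
steepest-descent restart on failure) on the Cartesian coordinates of the
movable set — ligand only, or all PS atoms. Gradients combine the analytic
MM gradient (mirror engine) or central-difference QM gradients with an
analytic gradient of the smoothed surface-area term (verified against
finite differences to 1e-8) and central-difference gradients of the
generalized-Born polar term. Accepted steps never increase the score; a
rejected quasi-Newton direction triggers a steepest-descent restart before
the run is declared converged. Termination is
on the energy change between accepted steps (default 0.05 kcal/mol, with
0.01 appropriate for covalent/metal work) or a step cap. Whether solvation
is re-evaluated during optimization or frozen at the starting geometry is
a flag (`solv_mode`), default re-evaluated — the published procedure is
ambiguous on this point, and keeping the optimization target identical to
the reported score is the interpretation that keeps "score" singular.
Non-converged poses score `+Inf`, are flagged, and are excluded from
rankings and from success-rate denominators (the converged fraction is
reported separately).

Evaluation: redocking success means the best-scored converged pose lies
within 1.5 A (inclusive) symmetry-adapted RMSD of the native pose; a
scoring failure means some pose scores better than the relaxed native
while lying beyond that cutoff. Symmetry-adapted RMSD minimizes over the
ligand's graph automorphisms (element- and bond-order-preserving,
computed with VF2 via igraph), heavy atoms only, with no superposition —
the docking convention of a fixed receptor frame.

## The synthetic world

`make_toy_complex()` emits a rigid cage of 4-atom pseudo-residues around a
flexible heteroatomic ligand chain, with fully specified toy parameters,
optionally a divalent metal site (2 coordinating residues at 2.1 A, metal
4.5 A from the ligand), a covalent ligand-side-chain bond (1.8 A), and one
explicit water. Design choices that took iteration to get right, recorded
here because they are what make the planted-native property meaningful:

* **Lock-and-key contacts.** Each cage contact atom is aimed at one
  specific ligand atom, at the exact Lennard-Jones minimum distance for
  that pair and with a complementary partial charge. A generic cage around
  a quasi-periodic chain has nearly degenerate register-shifted and
  flipped binding poses — a property of the artificial symmetry, not of
  real pockets.
* **A charged head atom** (+0.45 e) with its complementary contact anchors
  the ligand orientation; without it, end-to-end flips score within a few
  hundredths of a kcal/mol of the native pose.
* **Well depths** of 0.30 kcal/mol for cage atoms: each 4-atom
  pseudo-residue stands in for a whole side chain, so deeper-than-atomic
  effective wells are the realistic coarse-grained choice, and they give
  the pocket multi-kcal discrimination over 1 A displacements — the regime
  real scoring functions operate in.
* **Native settling.** The generator relaxes the built pose under the full
  classical score, probes neighboring basins (re-minimizing from perturbed
  starts and adopting any deeper endpoint), verifies that every +/-0.2 A
  single-atom displacement raises the score, and polishes to a 1e-6
  kcal/mol energy change. The emitted "native" is therefore a verified
  local minimum of the same score the pipeline optimizes.
* Equilibrium bond lengths/angles/torsion phases are set to the as-built
  geometry, so internal strain is zero at construction and the ligand's
  internal terms do not fight the placement.

What a green test does **not** establish: the generator emulates none of
the hard features of experimental structures — no protonation ambiguity,
no crystallographic disorder, no water networks beyond one optional
molecule, no real chemistry in the EEM engine. Green acceptance means the
*scheme* (partitioning, embedding, subtraction, scoring, optimization,
evaluation) is internally exact and behaviorally correct, not that any
particular redocking success rate on experimental sets is reproduced;
those numbers require licensed QM/MM programs and curated structure sets
and are explicitly out of scope.

## Degenerate inputs and numerical edges

Empty SS reduces to gas-phase PS scoring; a one-atom PS has zero gradient;
coincident embedding charges raise a singularity error; EEM with
coincident atoms reports non-convergence (and non-converged results rank
last rather than erroring the pipeline); clustering an empty pose list
returns an empty list; glycine-like residues selected in side-chain-only
mode are skipped with a warning. Atom indices are 1-based throughout (the
R-native choice). Config files use nested JSON with dotted-path accessors
(`ps.mode`, `embedding.scale`, ...), standing in for the nestable
key-value format of the original toolchain.

## Known limitations

The GB surrogate is not FACTS: absolute solvation energies differ, and
only the external parameters match. The EEM engine is a polarizable toy,
not a semi-empirical method; results with it demonstrate plumbing, not
chemistry. Shrake-Rupley areas carry quadrature noise. The optimizer is a
local minimizer: from a 2 A perturbation an individual trajectory recovers
the native basin roughly a third of the time on the default fixture, and
it is the *ensemble* best-scored pose — the quantity the docking protocol
actually uses — that is reliably native-like. Periodic boundary
conditions, Ewald electrostatics, polarizable MM, conformer generation
and protonation-state prediction are out of scope; receptors must arrive
protonated.
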