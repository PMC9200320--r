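---
title: "flexidock: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flexidock: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the sampling and
scoring model, the tunable parameters that matter, what the synthetic
fixtures do and do not establish, and the choices made where the design was
genuinely open. It states no empirical result that the test suite does not
itself compute.

## The docking model

`flexidock` treats a two-body complex in a reduced representation: per
residue the backbone heavy atoms N, CA, C, O, a Cβ (synthesized from ideal
geometry for glycine) and a sidechain centroid. The ligand's placement
relative to the receptor is carried by a rigid *jump* transform, so the six
rigid-body degrees of freedom and the backbone degrees of freedom are
cleanly separated: rigid moves update the jump, backbone moves update
coordinates and re-derive the ligand's local frame.

Backbone flexibility enters through the *Backrub* operator: a rotation of
all residues strictly between two pivot residues about the axis through the
pivot Cα atoms. We implement the primary single-axis rotation without the
compensating sub-rotations sometimes layered on top of it: the primary
rotation is the minimal operator with exactly testable contracts (pivots
fixed to machine precision, internal bond geometry of the moved block
preserved as a rigid motion, exact inversion by the negative angle). The
peptide geometry distortion this leaves at the pivots is deliberately
visible to the torsion and clash score terms rather than hidden.

Mobile residues are chosen by one of five policies: interface patches at
5.5 Å or 8 Å (any coarse atom of a residue within the cutoff of the
partner), either patch united with all loop residues of the monomers, or a
user-directed list (*directed induced fit*). Interface selection is
recomputed "on the fly" at exchange-round granularity (every
`swap_interval` trials, default 1 000) rather than every trial: a full
O(N²) scan per trial would dominate runtime while changing the selection
only marginally between consecutive trials. Fragments shorter than three
residues are skipped for backbone moves (a Backrub needs an interior) but
still count as interface for scoring.

Secondary structure, needed only for the loop-augmented policies, is
assigned from dihedral boxes (helix: φ ∈ [−100, −30], ψ ∈ [−80, −5], runs of
≥ 4; strand: φ ∈ [−180, −40], ψ ∈ [90, 180] ∪ [−180, −170], runs of ≥ 3;
else loop). A hydrogen-bond-based assignment would be disproportionate for a
loop/non-loop split; the box bounds are exposed as arguments.

## The energy model

The low-resolution score is a weighted sum of six terms.

* **Residue-pair-transform term.** Every inter-chain residue pair whose
  Cα–Cα distance is within range (default 10 Å) contributes a score keyed by
  the 6-D transform (3 translation + 3 rotation-vector coordinates) between
  the two backbone frames — a quantity invariant under global rigid motion,
  which is what makes it tabulable. The package ships the exact binned
  lookup machinery and a builder (`build_pair_table()`): foreground counts
  from training complexes against a shuffled-orientation background, scored
  as −log((count + pc)/(expected + pc)). Since no PDB-mined table can be
  shipped offline, the default is a smooth analytic surrogate well
  (distance- and orientation-dependent, favoring sidechains pointing at each
  other). The binning defaults (1 Å translation, 30° rotation bins, 10 Å
  range) are explicitly non-canonical and exposed as arguments.
* **Lennard-Jones split.** A single coarse atom type with pair minimum
  `r_min = 3.2 Å`, well depth 0.2, cutoff 8 Å; the repulsive branch
  (r < r_min, shifted to zero at r_min) continues linearly below
  0.6 · r_min so deep overlaps stay finite, and the attractive branch spans
  [r_min, cutoff). `r_min` was set so that ideal secondary structure
  (closest long-range intra-chain approach ≈ 3.9 Å in the fixtures) and
  surface contact (3.5–4.5 Å) sit in the attractive basin and only sub-3.2 Å
  approaches are penalized. Summation covers all inter-chain pairs and
  intra-chain pairs more than 4 residues apart — intra-chain clashes matter
  precisely because the backbone moves.
* **Torsion statistics.** −log p(φ, ψ | class) from an analytic surrogate
  surface (mixtures of von Mises products for the general, glycine, proline
  and pre-proline classes), an omega planarity penalty
  k · min((ω−180)², ω²) with k = 0.005 deg⁻², and −log p(class | φ, ψ) from
  the same surface normalized the other way. These are surrogates that
  preserve the scoring roles (penalize implausible backbones), not fits to
  PDB statistics.

Default weights put the pair-transform term at 1.0 and everything else at
0.1, mirroring a down-weighted non-motif scheme; all weights are arguments.
Energies are treated as kcal/mol-compatible with the Boltzmann constant
folded into the inverse temperatures, so the ladder values apply directly.

The refinement stage replaces all-atom rescoring, which is out of scope
without a rotamer library: a zero-temperature quench with the stated fine
move magnitudes (Gaussian 0.1 Å / 3°), accepting only downhill proposals of
the LJ + torsion score, optionally followed by golden-section coordinate
descent over the six jump parameters. Its contracted roles — clash relief
and re-ranking — survive the simplification; its limits (no side chains, no
backbone minimization) should be kept in mind when interpreting interface
scores. The ranking quantity is interface score: total(complex) −
total(receptor) − total(ligand), which vanishes for separated chains.

## Replica exchange

Three replicas at β = 1/1.5, 1/3, 1/5 (cold to hot), exchange attempts every
1 000 trials, 8 trajectories of 2.5 × 10⁵ trials for local docking. Three
decisions deserve notice:

* **Swap criterion.** The implemented acceptance is the standard
  min{1, exp[(βᵢ−βⱼ)(Eᵢ−Eⱼ)]}. It is the only form satisfying detailed
  balance across the ladder (verified numerically in the tests), and the
  uniform random draw is used for acceptance — a fixed 0.5 threshold would
  break detailed balance.
* **Swap scheduling.** Deterministic even/odd alternation of adjacent pairs
  (DEO): reproducible and round-trip efficient.
* **Candidate storage.** After every exchange round with at least one
  accepted swap, a snapshot of the *coldest* replica is stored (all replicas
  with `store_all`). The coldest chain is the production ensemble; storing
  all replicas would inflate candidate counts several-fold.

Each trajectory runs on its own seeded RNG stream (`seed + k`), so the
merged candidate set is independent of execution order, and a cached-energy
drift trap (tolerance 1e-4) aborts a run on any bookkeeping bug.

## What the synthetic fixtures establish — and what they do not

All tests run offline on synthetic mini-proteins built by internal-coordinate
chain extension with ideal bond geometry: ideal helices (φ = −57°,
ψ = −47°), helix–loop–helix receptors whose loop is displaced by a known
Backrub angle to create "unbound" monomers with controllable
unbound-to-bound deviation, and a single-helix ligand docked by random
orientation and a slide-into-contact. Loop conformers alternate between
(−80°, 60°) and (100°, 40°) — outside both secondary-structure boxes and
chosen so the helix–loop–helix fold is clash-free (minimum long-range
approach ≈ 3.9 Å).

The `funnel_energy_factory()` fixture substitutes for the composite score in
integration tests: energy = depth·(1 − exp(−lrmsd²/width²)) + tether·lrmsd²
plus a soft Cα clash term, zero at the native pose and monotone outward on a
clash-free ray. Two of its defaults are deliberate: the curvature
depth/width² (25 / 16 Å⁻²) places the coldest temperature's equilibrium
ligand RMSD — roughly √(3·T·width²/depth) by equipartition over the six
rigid degrees of freedom — below the 2 Å near-native boundary, and the weak
quadratic tether (0.02) keeps the hottest replica within local-docking range
instead of diffusing over the otherwise-flat plateau, without which exchange
with the cold chain stalls and funnel-recovery becomes a lottery.

A green funnel-recovery test therefore establishes that the scheduler,
move set, storage and ranking machinery can descend a known funnel under the
stated ladder — it does *not* establish docking accuracy on real proteins,
which depends on the fidelity of the pair-transform table and the score
weights, neither of which a desk-scale offline test can validate. Likewise
the synthetic decoy sets validate the N5 bootstrap machinery (degenerate
and signal-free limits), not the discriminative power of any score.

## Numerical choices and degenerate inputs

* Kabsch superposition via SVD with reflection correction; configurations of
  rank < 2 (fewer than 3 points, collinear sets) are rejected as degenerate
  rather than silently resolved.
* Dihedrals are reported in (−180°, 180°] and are `NA` — never 0 — at
  termini and across chain breaks (C–N > 2 Å); ±180° is treated circularly
  in all comparisons.
* Rotations are parameterized as rotation vectors internally (gimbal-free
  composition) and degrees at every user surface; the angle-π branch of the
  matrix log is resolved from the symmetric part.
* The 45° local-docking rotation is applied about the receptor→ligand
  centroid axis (through the ligand centroid, so the separation grows by
  exactly 15 Å); the axis choice is not dictated by the protocol description
  and is an argument. The start perturbation is Gaussian with σ = 1 Å per
  translation axis and σ = 1° about a random axis.
* `slide_into_contact` steps in 0.2 Å increments until the closest
  coarse-atom distance first enters [3.5, 4.5] Å, backing off one step if it
  lands below, and errors after 200 Å of travel.
* Score ties in ranking, top-5 selection and enrichment are broken by
  candidate serial, making every ordering (and hence N5 given the RNG
  stream) deterministic.
* The difficulty boundary 2.2 Å is assigned to the *medium* class (the
  printed inequalities overlap there); 1.2 Å likewise belongs to medium.
* The per-trial move mix (rigid vs backbone) is unstated in the protocol
  description; the default is p_rigid = 0.5 with the ratio exposed, and move
  magnitudes (0.7 Å / 5° rigid, ±20° Backrub) are similarly exposed
  defaults. Move sigmas are uniform across replicas.
* An equal-β ladder is permitted (useful for exact storage-contract tests)
  even though production ladders are strictly decreasing.

## Known limitations

No side-chain rotamers, hydrogen bonding, electrostatics or solvation; no
torsion-space minimization with gradients; no mmCIF input; single-model PDB
files only; the shipped pair-score surrogate is a stand-in, and users who
want the knowledge-based term at full strength must train a table on their
own complex set with `build_pair_table()`.
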