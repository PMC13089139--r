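---
title: "Constrained carbocation docking: methods and design choices"
author: "cationdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained carbocation docking: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Class I diterpene synthases ionize copalyl diphosphate and steer the
resulting carbocation cascade toward one of many possible products. In the
abietane-type synthases of the pine family, the first cyclic intermediate is
the isopimara-15-en-8-yl cation (here species **A**): a trivalent C8 cation
flanked by five abstractable protons (two on C7, two on C14, one on C9).
Deprotonation at those positions yields, respectively, isopimara-7,15-diene
("7"), isopimara-8(14),15-diene ("8"), or isopimara-8,15-diene ("10").
Alternatively, the cascade proceeds by rearrangement to the
abieta-8(14)-en-13-yl cation (species **B**), which is captured by an
active-site water at one of the two prochiral faces of C13 to give the
abietaenol epimers 13α ("6a") and 13β ("6b").

A hydroxyl-introducing substitution at the helix-break residue 723
(alanine → serine/threonine) redirects the product spectrum toward "7". The
mechanistic hypothesis this package interrogates computationally is that the
introduced hydroxyl acts directly as the catalytic base: if poses of **A**
that satisfy proton-transfer geometry toward the 723 hydroxyl are docked
under each of the five site hypotheses, and the reactant water required by
the native reaction is additionally placed and restrained, does the pose
population concentrate on the deprotonation site that forms the observed
product?

`cationdock` implements that entire constrained-docking analysis as a
self-contained, deterministic desk-scale pipeline: species graphs and
outcome enumeration, conformer generation, flat-bottom restraint sets for
every hypothesis, rigid-body pose sampling with a documented scorer, the
three-stage filter cascade, and geometric product classification with
per-product tallies.

## The restraint model

Every mechanistic hypothesis is a `constraint_set` of flat-bottom
restraints. A restraint on a measured coordinate $x$ (a distance in Å or an
angle in degrees) with bounds $[l, u]$, softness $s$ and weight $w$
penalizes

$$\mathrm{pen}(x) = \begin{cases} 0 & l \le x \le u \\
w\,\left(\frac{x - \mathrm{nearest\ edge}}{s}\right)^2 & \text{otherwise.}\end{cases}$$

A pose *satisfies* a set when, for every ligand body independently (the
carbocation, the water, the pyrophosphate–Mg cluster), the sum of penalties
of the restraints naming that body is strictly below one. The normalization
is deliberate: a single violation of exactly one softness unit beyond the
flat bottom scores 1.0 and fails the gate.

The default restraint magnitudes are hydrogen-bond / proton-transfer
geometry norms — declared package defaults, all configurable via
`cst_defaults()` overrides:

| restraint | bounds | softness |
|---|---|---|
| base O···H(site) distance | 1.6–2.6 Å | 0.3 Å |
| C–H···O approach angle | 120–180° | 20° |
| vinyl methylene C16···PP anchor | 2.5–4.5 Å | 0.5 Å |
| water O···C13, reactive (species B) | 2.6–3.4 Å | 0.4 Å |
| water O···C13, loose (species A) | 2.6–5.0 Å | 0.4 Å |
| water face-approach angle | 0–35° | 10° |
| C7···residue-723 tip (mechanism check) | 3.5–5.5 Å | 0.5 Å |

"Either end of the pyrophosphate co-product" is mapped to the two maximally
separated terminal phosphate oxygens of the rigid cluster model (`OT1`,
`OT2`); the bridging oxygen `OB` — the former ester oxygen — is labeled
separately because the water-position taxonomy distinguishes it. The
face-approach restraint measures the angle between the signed normal of the
C12/C14/C15 plane at C13 (sign selected by the hypothesized epimer) and the
C13 → water-oxygen vector; prochiral face assignment itself is the sign of
the scalar triple product $(s_2{-}s_1)\times(s_3{-}s_1)\cdot(p{-}c)$, with a
coplanarity tolerance of $10^{-6}\,\text{Å}^3$ below which a degenerate
geometry error is raised (numerically safe; never triggered by real poses).

## Conformers

The quantum-chemistry stages of full-scale versions of this workflow (DFT
re-optimization and metadynamics conformer searching) are outside this
package's scope. In
their place, `generate_conformers()` performs a seeded randomized
bounded-distance-geometry embedding of the heavy atoms (bond lengths at
reference values, 1–3 distances at ≈111°, a 2.45 Å nonbonded floor,
BFGS-refined from random starts with up to 10 retries), places hydrogens by
idealized local geometry, and scores each conformer with a pluggable energy
function. The default energy is a torsional rule term plus a capped soft
Lennard-Jones self-clash on distant heavy pairs
($k_t = 0.3$, $\epsilon = 0.1$ kcal/mol, $\sigma = 3.0$ Å, cap 10);
`energy_table_fn()` lets users inject externally computed (e.g. QM)
energies instead. Libraries are filtered with the 5 kcal/mol energy window
above the minimum and deduplicated at 0.25 Å heavy-atom Kabsch RMSD — the
window is the protocol's stated value, the duplicate threshold is a package
default chosen below the thermal-vibration scale, standard for conformer
dedup. Filtering is idempotent and can never discard the global minimum.

## Docking and scoring

The receptor is held rigid (the available crystal structure is an
apo/not-fully-closed form; side-chain repacking is out of scope). The
residue-723 variant is set by ideal-geometry grafting: A → S/T adds
OG/OG1 (1.43 Å, 109.5°, anti to N) plus the hydroxyl proton and, for
threonine, CG2; S/T → A strips beyond CB.

Pose sampling is fully seeded. Orientations are uniform on SO(3) via
Shoemake quaternions; the translation starts uniform in the pocket sphere
and then receives a deterministic constraint-guided refinement — the whole
ligand is iteratively shifted by the mean displacement that would bring each
ligand-vs-fixed-point distance restraint into its flat bottom (12
fixed-point iterations; angles are left to the filters). Pure rejection
sampling of rigid placements essentially never satisfies a distance + angle
+ anchor set simultaneously; the refinement mirrors the role of the
grid-based transformer in full-scale constrained-docking engines, which
*place* ligands subject to the constraints. Orientation uniformity is untouched; the
translation distribution becomes the projection of the uniform draw onto
the restraint-feasible region.

The water oxygen, when a set carries a water mode, is placed on a
deterministic local grid around its constraint target (C13; ±3.0 Å at
0.75 Å spacing). Sterics are a *hard domain constraint* of the placement:
only grid points with ≥ 2.25 Å clearance from every receptor, cofactor and
ligand atom are candidates (a water cannot interpenetrate the protein), and
the restraint-optimal allowed point wins. If no point clears, the
best-clearance point is used and its restraint penalties report the
infeasibility — this is how a sterically blocked water face shows up in the
stage-1 constraint scores. Poses whose carbocation restraints alone already
reach the stage-1 bound receive an analytic ideal-point placement instead —
they cannot pass the cascade, so only bookkeeping is affected. The pyrophosphate–Mg cluster,
when not supplied by the receptor file, is placed by an exhaustive
translation-grid scan inside the pocket minimizing clash plus any cofactor
restraints; the grid is anchored at the pocket center so halving the
spacing refines (supersets) the previous grid, ties break to the
lexicographically smallest grid index, and the scan fails explicitly if no
clash-free point exists.

Scoring replaces the original molecular-mechanics score function with a
documented two-term surrogate plus the restraint term:

* repulsion: soft-sphere overlap $\sum ((3.0 - d)/3.0)^2$ over
  ligand–receptor pairs below 3.0 Å;
* attraction: −(per-ligand-atom capped count of receptor contacts in the
  3.2–4.5 Å shell, cap 4);
* `total = w_rep·rep + w_att·att + w_cst·Σ restraint penalties`, defaults
  $w_{rep} = 1.0$, $w_{att} = 0.4$, $w_{cst} = 1.0$.

The *interface energy* is the repulsion+attraction of the carbocation body
alone, restraints excluded. **Absolute pose counts from force-field-based runs of this analysis are
therefore not reproducible here and are not asserted anywhere; the
procedure, its combinatorics and its filter arithmetic are.**

The filter cascade has three stages: (1) every
per-ligand constraint score < 1; (2) the lowest 10% of total scores,
$k_1 = \max(1, \lfloor 0.10\,n_1\rfloor)$; (3) the lowest 10% of
carbocation interface energies, $k_2 = \max(1, \lfloor 0.10\,k_1\rfloor)$.
The floor-with-minimum-one rule and the stable tie-break by pose id are
package choices made for exact reproducibility; the cascade output is
invariant to input order. The per-set RNG stream seed is a 32-bit FNV-1a
hash of `"<base seed>|<set id>"`, so adding constraint sets to a run never
perturbs the streams of existing sets.

## Classification and reports

Surviving poses are classified from *realized geometry*, not from the
hypothesis that generated them: the abstractable hydrogen nearest the base
hydroxyl oxygen, gated at O···H ≤ 2.8 Å and C–H···O ≥ 100°, maps through
the site → product registry; below-gate poses are "unassigned". The gate is
deliberately looser than the docking flat bottom so near-miss poses are
still attributed, and it is configurable. The generating hypothesis is
recorded alongside and an agreement rate reported — realized geometry is
authoritative because it is what the mechanism claims. Water-carrying poses
are additionally labeled by the nearest labeled pyrophosphate oxygen within
3.5 Å ({bridging, terminal, none}) and, for species B, by the prochiral
face of C13 the water occupies (epimer "6a"/"6b"). Tallies render counts in
the "k/n" style with a strict-majority flag.

## The synthetic test system

Nothing in the test suite downloads a structure. Two generators stand in
for the crystal receptor:

* `make_toy_receptor()` — a spherical pseudo-atom shell with an
  inward-pointing residue-723 probe (A/S/T selectable) and the labeled
  7-point pyrophosphate–Mg cluster. Used for I/O, grafting and placement
  tests.
* `make_consistent_pocket()` — a *snug* pocket built around a reference
  conformer of the docked species, the way a closed active site hugs its
  substrate: a two-layer molecular-surface wall of carbon pseudo-atoms
  offset 3.0 Å from the ligand surface (≈1.5 Å spacing, second layer 1.9 Å
  further out closing the gaps), the hydroxyl probe seated on the extension
  of a C7–H bond, the cluster anchor 3.5 Å beyond C16 with the wall hugging
  the cluster tightly, and a water-sized bulge carved on the alpha face of
  C13. Because the anchor flat bottom tolerates a band of rotations about
  the probe axis, the bulge is carved along the arc the face point traces
  under that rotation family (±60°), not at a single spot. In this pocket
  the reactant-water restraints are sterically satisfiable mainly for
  orientations in the reference family — the feature the with-water
  docking experiments probe.

`plant_poses()` constructs pose sets with exact planted outcome mixtures
(largest-remainder apportionment, seeded shuffle) whose designated hydrogen
satisfies the classification gate by construction, with per-ligand
constraint scores, totals and interface energies drawn from controllable
distributions. Planted-truth recovery is exact at zero noise; positional
jitter (`geom_noise_sd`) degrades it monotonically.

What passing tests on these fixtures do **not** show: real protein
flexibility, electrostatics (including Mg²⁺), solvation, or the energetics
of a genuine force field. They validate the combinatorial, geometric and
procedural content of the analysis — site enumeration, restraint
mathematics, filter arithmetic, classification rules, determinism — and the
qualitative mechanism that water-consistency constraints concentrate the
passing population on one reactive orientation.

## Problem sizes and determinism

The full production budget (4000 poses per constraint set; 40,000 pooled for
the ten-set deprotonation scan, 8000 for the two-set wild-type runs) runs in
minutes with the surrogate scorer and is exercised for the pooling
arithmetic. The directional water check deserves a note on design: rerunning
the docking with the water restraints added (the production form of the
experiment)
shifts the fraction of constraint-passing poses classified "7" by about
+0.03 on this fixture — real but small, so an unpaired rerun comparison
needs on the order of 50,000 poses per condition before the shift clears
sampling noise. The suite therefore evaluates the *paired* form of the same
question: the identical constraint-passing poses are re-scored with the
water restraints added (`augment_pose_with_water()`), which measures
"adding the constraint" directly with the sampling noise cancelled; the
paired shift is consistently positive (≈+0.03 to +0.05) across seeds at 800
poses per set. Other distribution-level checks use 600–2000 poses per set
over several seeds — sizes chosen to give adequate counts at the cascade
output while keeping the whole suite fast; they are package choices, stated
here once. Every
experiment writes a manifest (config, set ids, per-set stream seeds,
library provenance) sufficient to reproduce its report byte-for-byte.

## Known limitations

* The scorer is a geometric surrogate; its pose populations are not
  force-field populations, and no claim is made about absolute pass counts.
* The receptor is rigid; the 723 graft uses ideal internal coordinates and
  does not repack neighbors.
* The A → B rearrangement itself (1,4-proton transfer, 1,2-methyl shift) is
  not modeled; A and B are docked as separate species.
* The distance-geometry conformers are sanity-gated (bonded distances
  0.7–1.9 Å) but not energy-minimized structures; users wanting QM-grade
  conformers should supply their own library via `conformer_library()` /
  `energy_table_fn()`.
* Per-set pose budgets for the wild-type water docking are sometimes quoted
  as 2500 and sometimes as 4000 in accounts of such workflows;
  `n_poses_per_set` is config and either is just a caller default.
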