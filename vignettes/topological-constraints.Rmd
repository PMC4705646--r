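---
title: "Topological constraints on RNA tertiary folding: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological constraints on RNA tertiary folding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the model answers

An RNA with folded secondary structure is a set of stiff A-form helices
joined by short flexible linkers. Even before any tertiary interaction
forms, chain connectivity and excluded volume ("topological constraints")
already restrict how those helices can arrange in space — and therefore how
hard or easy it is to bring any two residues close enough to form a
tertiary contact. `rnatopo` quantifies exactly that contribution and
nothing else: the model deliberately contains no electrostatics, no base
stacking, no sequence-dependent attraction. Whatever free-energy
differences the ensemble shows are attributable to connectivity and sterics
alone.

The package was built around the 195-nt *Azoarcus* group I ribozyme
(shipped as a data fixture) and an isolated tetraloop/receptor reference
system, but every stage works on any pseudoknotted secondary structure
supplied as dot-bracket or pair-list input.

## The coarse-grained model

Each nucleotide is three beads: P (phosphate), S (sugar, anchored at C1'),
B (base, at the glycosidic nitrogen N9/N1). Canonical base pairs are
permanent: every maximal stack of consecutive canonical pairs becomes one
rigid body with ideal A-form geometry (fiber-type parameters, rise 2.81 A,
twist 32.7 deg; the emergent template has ~5.9 A P-P spacing along a
strand and ~10.4 A S-S separation across a pair). All other nucleotides
are freely rotatable chains: harmonic bonds along P-S-P-S, *no* angle or
torsion potentials on unpaired residues. Paired residues carry backbone
angle and dihedral potentials; in practice only the terms that bridge two
rigid bodies survive (everything inside one body is constant), e.g. the two
backbone dihedrals separating two directly bonded helices such as P4 and
P6.

Noncanonical internal-loop pairs are treated as annotations, not helices:
the two residues stay flexible but receive (i) a steric filler bead bonded
to one base (the purine when exactly one member is a purine, else the
5'-most residue), (ii) a weak Gaussian attraction between their base beads
(0.3 kcal/mol deep, under the 0.5 kcal/mol cap), (iii) backbone dihedrals
at one-fourth canonical strength, and (iv) two fixed flat-bottom
restraints: B-B within 5.5-7.5 A and S-S within 11-14 A at
`f_max = k_min = k_max = 2` kcal/mol/A^2.

Excluded volume is a purely repulsive soft sphere, `E = k/2 (sigma - r)^2`
for `r < sigma`, with per-type radii (P 2.0, S 2.4, B/B2 2.2 A) chosen so
that the ideal duplex template itself is exactly overlap-free while two
duplexes cannot pass through one another. Pairs separated by at most one
residue along the chain, and pairs inside the same rigid body, are
excluded.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k_bond` | 20 | kcal/mol/A^2 | backbone bond stiffness (E = k/2 dx^2) |
| `k_angle` | 5 | kcal/mol/rad^2 | backbone bending, paired residues only |
| `k_dihedral` | 8 | kcal/mol | backbone torsion, paired residues (noncanonical: 1/4) |
| `k_ev` | 20 | kcal/mol/A^2 | soft-sphere repulsion |
| `attr_eps` | 0.3 | kcal/mol | paired-base attraction depth |
| contact cutoff | 14 | A | S-S distance defining a contact (about one base-pair span) |
| analysis T | 300 | K | temperature for all dG values |

The exact force-field constants of the original coarse-grained
implementation are not published in the sources this package works from;
the defaults above are chosen once on geometric/physical grounds. Two
choices deserve comment. First, paired residues carry substantial backbone
angle and torsion potentials (`k_angle = 5`, `k_dihedral = 8`,
corresponding to ~20-degree bending and ~16-degree torsional
fluctuations): in the original model those potentials are what hold the
A-form duplex geometry, and although rigid bodies make them redundant
inside a helix here, they remain the physics of every junction where two
helices abut — in particular they are what lets "restrain the two backbone
dihedrals separating two stacked helices" actually enforce a coaxial
stack, since the third inter-body torsion is held by the force field
itself. Second, unpaired residues carry no bending or torsion potential at
all — this is the literal reading of "freely rotatable", and it makes the
single-stranded linkers freely jointed chains of ~5.4 A virtual bonds.
All constants are overridable via `forceFieldParams()`.

## Sampling

Equilibrium observables depend only on the Boltzmann distribution, so the
dynamics engine of the original study is replaced by Metropolis Monte
Carlo — every analysis in the package is a functional of the equilibrium
ensemble, which both samplers target. "Moves" are MC proposals, and the
published step counts are treated as guidance for sampling effort, not as
unit-for-unit equivalents.

Four proposal types:

* **subtree pivots** — rotation of everything on one side of a flexible
  bond whose removal disconnects the molecule (arms, hairpins, tails),
  about a random axis through the hinge bead. Hinges are chosen with
  probability proportional to the square root of the moved-set size, so
  arm reorientations (which decorrelate interhelical angles) are proposed
  often; the angle is uniform within +/-180 deg, so a single accepted arm
  pivot fully randomizes that arm's orientation.
* **segment rotations** — generalized crankshaft about the axis through
  two flexible cut points; a candidate is valid only when every rigid body
  lies wholly inside or outside the moved span. These moves turn entire
  junction arms (e.g. the P4-P5-P6 arm between J3/4 and J6/7) without
  breaking any bond.
* **rigid-body helix perturbations** — small rotation/translation of one
  helix body. Its attachment bonds stretch slightly and the move is
  accepted or rejected through the energy; this is the only move class
  that relaxes the internal degrees of freedom of pseudoknots, whose
  cycles admit no bond-preserving concerted rotation.
* **local bead displacements** for flexible beads.

Rigid bodies are never split by a proposal, so helix geometry is exact by
construction; bodies are additionally re-snapped onto their templates at
every energy resync, which removes floating-point drift from composed
rotations. Detailed balance holds per move type (all proposals are
symmetric), verified on closed-form toy systems in the test suite.

Replica exchange uses the study ladder: eight exponentially spaced
temperatures spanning 300-400 K, neighbour swaps on alternating even/odd
sweeps every 500 moves with acceptance
`min(1, exp[(beta_i - beta_j)(E_i - E_j)])`. Analysis uses the frames
recorded from whichever replica holds the lowest rung (300 K), after
discarding an equilibration prefix (1% of frames by default; the
longer-run analyses in this package use 10%). With this energy function
the neighbour acceptance rates on the ribozyme fixture come out around
0.6-0.7 — higher than the 0.32-0.36 of the original molecular-dynamics
setup, as expected for a model with fewer effective degrees of freedom;
exchange rates are diagnostics, not calibration targets.

### Initial conformations

Chains are assembled by a sequential layout (helices instantiated as whole
rigid duplexes, loops arced between their anchors, pseudoknot partner
strands aimed at their already-placed partners) followed by staged
relaxation: the chain is first closed without sterics at descending
temperature, then the repulsion is ramped in. A build is accepted when
every bond is within 1.2 A of its rest length and no bead pair
interpenetrates by more than 1.2 A (about a quarter of a bead diameter —
soft spheres at 300 K tolerate grazing contact); otherwise the layout
retries with a new seed. Restrained runs (triple helix, L9/J5) start from
a docked conformation produced by `syntheticNativeReference()`, a short
funnel-restrained quench that stands in for crystal-structure coordinates
when none are available offline; it is labelled synthetic wherever it
appears.

## Analysis stack

**Euler angles.** Each helix of >= 2 pairs carries a body frame: z along
the helix axis oriented 5'-3' of the reference strand (the first range in
the regions file), x towards the reference 5' sugar. Because helices are
rigid, the frame is obtained exactly by fitting the helix template to each
frame. The relative rotation between two frames is decomposed in the ZYZ
convention into (alpha_h, beta_h, gamma_h) — twist, bend, twist — with
gamma set to 0 at the gimbal singularities. The absolute angle values
depend on this convention; the occupied-bin fractions and mutual
information below do not (a convention change relabels bins).

**Fractions of conformational space.** `fractionSampled()` discretizes
(alpha, beta, gamma) on a regular grid (10-deg bins: 36 x 18 x 36 = 23328
cells; bin edges start at -180/0 deg, samples on an edge belong to the
higher bin) and reports occupied cells over total cells, with no sin(beta)
correction — the statistic is the raw occupied fraction, and any reference
constant must use the same convention. Joint fractions over k helix pairs
(`fractionJoint()`, 30- or 60-deg bins) divide by the k-th power of the
per-pair cell count: 746496 for 2 x 30-deg, 1259712 for 3 x 60-deg.
`fractionNorm()` subsamples the pool to a fixed conformations-per-bin
density (499000 at 108^3 joint bins; 4621 for a two-pair junction) before
normalizing by a user-supplied reference fraction; that reference value is
an external input and is never defaulted.

**Mutual information.** `miNorm()` uses 45-deg bins (256 cells per
variable), plug-in entropies, `MI = H(X) + H(Y) - H(X,Y)` and
`MI_norm = MI / H(X,Y)`. The plug-in estimator is biased upward by
approximately `(M_xy - M_x - M_y + 1) / (2 N ln 2)` bits (occupied-cell
counts M); the estimate carries this analytic term as an attribute so that
near-zero values can be judged against it. Serial correlation between
recorded frames inflates MI beyond the iid bias term, which is why
near-zero targets are only approached at generous run lengths.

**Free energies.** A contact is `>= min_pairs` S-bead pairs within 14 A
(1 for residue-residue cells, 2 for tetraloop/receptor and J6/P3-type
interfaces). From the contact probability over post-equilibration 300 K
frames, `dG_topo = -RT ln(p/(1-p))`. Uncertainty comes from a seeded
block bootstrap over contiguous frame blocks (50 blocks, 1000 resamples by
default), which is robust to frame autocorrelation at the block scale.
When p hits 0 or 1, the value is reported as a one-sided bound from the
pseudocount `1/(N+1)` and flagged; bounds never mix silently with values.
Cooperativities are differences of conditional and unconditional
penalties, `ddG_coop(x, y) = dG_topo(x | y) - dG_topo(x)`, computed either
from a restrained ensemble or by masking the unrestrained ensemble with
the P4/P6 coaxial-stacking proxy.

The triple-helix restraint set (`makeRestraints("TH")`) carries the
printed roster — eight sugar-bead flat-bottom restraints at +/-1 A of the
reference distances with `f_max = k_min = k_max = 2` kcal/mol/A^2, plus
the two backbone dihedrals separating P4 and P6 at K = 50 kcal/mol — and
supplements it with five auxiliary distance restraints (tagged `stack` in
the table, against `roster`) between the junction base pairs' far-strand
beads and the two cross-junction diagonals, with targets measured exactly
on the ideal A-form continuation template. The supplement is needed
because with rigid helices the relative orientation across a direct
junction has six degrees of freedom and the two printed dihedrals pin only
part of them; in a model whose paired-residue backbone potentials
themselves hold A-form, the remainder is held by the force field, and the
auxiliary restraints reproduce exactly that role. The enforced-stack state
then sits at an interhelical bend near 140 degrees with a one-rise end
gap; accordingly the stacking-proxy thresholds are configurable, and
restrained-vs-unrestrained ensembles separate cleanly at `betaMin = 130`,
`gapMax = 7.5` (bend > 150 deg between the helix frames
and facing-end sugar centroids closer than 7 A; thresholds configurable —
the original study's exact stacking criteria are not printed, so these are
a documented stand-in). `dG_fold = dG_fold_ref - dG_topo_ref + dG_topo`
transfers an experimental reference folding free energy (defaults -0.3
and 2.9 kcal/mol) under the assumption that all non-topological terms are
constant across architectures.

**Pivot counting.** For the freely-jointed-chain rationalization of
native-contact preference, `countFlexiblePivots()` takes the shortest path
through the helix/linker graph and scores each traversed linker
`ceiling(L/2)` pivots (L single-stranded nucleotides), direct bonded
junctions 1, the regions' own units 0. On the ribozyme fixture this gives
2 pivots for L2-J8 and 4 for L9-J8; the Gaussian-chain estimate
`-RT (3/2) ln(n_b/n_a)` then yields -0.62 kcal/mol in favour of the
2-pivot path. The supplementary analysis of the original study quotes
-0.5 kcal/mol for this quantity; the package implements the standard
Gaussian-chain form and records the discrepancy rather than adjusting to
it.

## The fixtures and the synthetic generators

The ribozyme fixture is data (pair list, regions, restraint rosters in
crystal-style numbering 12-206), shipped under `inst/extdata/` and marked
in its headers as a reconstruction: the published architecture and every
printed residue anchor (the triple-helix and L9/J5 rosters, the GAAA
identities of L2 and L9, the pseudoknotted junction layout, the linker
lengths) are honoured, while pair-level detail away from those anchors is
the implementer's transcription. The code treats all of it as input and
hard-codes none of it. The tetraloop/receptor reference fixture is a GAAA
hairpin joined by a 9-U tether to an 11-nt-receptor hairpin whose
residues 26-50 are held by backbone dihedral restraints (K = 50 kcal/mol)
during production.

Three generators make every analysis stage testable without simulation:
ideal freely-jointed chains (`<R_ee^2> = n b^2` embedded as ground truth),
rotation pairs with a tunable correlation parameter (uniform and
independent at 0, identical at 1), and two-bead ensembles whose contact
indicator is an exact Bernoulli draw. Each embeds its spec and seed in the
trajectory metadata. What the generators do *not* emulate: real ensembles
have serially correlated frames, non-uniform orientation distributions and
state-dependent contact geometry, so passing the generator-based tests
validates the estimators, not the sampler — the sampler is validated
separately against closed-form toys (harmonic dimer variance, two-state
occupancy, freely jointed chains) and the fixture-level ordering checks.

## Problem sizes used by the shipped analyses

The packaged test-suite ensembles use moderate sampling (2-4 x 10^5 moves
per replica; a few thousand decorrelated frames), chosen as the scale at
which the qualitative claims — orderings of occupied fractions across
junction classes, signs of cooperativities, native-vs-non-native gaps —
are stable. The acceptance script runs 1.5-2 x 10^6 moves per replica.
Quantities that need the full published sampling depth (absolute occupied
fractions of pseudoknots, two-decimal mutual-information values, the
cooperativity magnitudes) converge much more slowly; `scripts/paper_repro.R`
runs that tier (hours on one CPU) with the documented tolerances. Mean
radius of gyration converges quickly and is reliable at the desk scale.

## Known limitations

* The model measures topological constraints only; dG_topo underestimates
  the true cost of forming an interaction because it ignores interaction
  geometry, and no electrostatic or ion effects are present by design.
* The fixture is a reconstruction at pair-level detail (see above); the
  restraint target distances derive from a synthetic docked reference, not
  a crystal structure.
* The Monte Carlo sampler's exchange rates and correlation times are not
  comparable to the original dynamics engine; only equilibrium averages
  are.
* Occupied-bin fractions are bounded above by the number of distinct
  frames; comparisons across runs are only meaningful at matched sampling
  density (which is exactly what `fractionNorm()` enforces).
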