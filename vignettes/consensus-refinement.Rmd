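---
title: "Consensus refinement of protein model ensembles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus refinement of protein model ensembles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ConsensusFold refines an ensemble of candidate all-atom protein models by
extracting the interatomic distances the models agree on, weighting them
with a knowledge-based statistical potential, rebuilding conformations in
torsion space under those distance restraints, filtering the decoys with
four sequentially applied scoring terms, and selecting representatives by
iterative density clustering — with a second consensus round seeded by the
first round's cluster centroids. This vignette explains the model behind
each stage, the tunable parameters and their defaults, the synthetic
study system the test suite uses, and the numerical and design choices a
maintainer should know about.

## 1. The data model

A `ProteinModel` is a single chain: one-letter sequence plus an ordered
atom table (`atom`, `element`, `resno`, `restype`, `x`, `y`, `z`; Å;
1-based contiguous residue numbering). Validity requires a Cα per residue
and finite coordinates; a CA-only trace is a legal coarse-grained model.
A `ModelEnsemble` is an ordered list of models with identical sequence and
atom naming — the unit that consensus extraction, filtering and
clustering operate on. PDB reading is delegated to `bio3d::read.pdb`
behind a deliberately narrow dialect: single chain, `ATOM` records only,
no insertion codes; alternate locations keep the highest-occupancy copy.
Writing uses fixed wwPDB columns so a write/read cycle is bit-stable at
the format's 3-decimal coordinate precision.

Working models are backbone + Cβ (N, CA, C, O, CB). Every scoring term in
the package — reduced-typing RAPDF, soft-sphere clashes, Cβ-based
compactness and electrostatics — is defined at this resolution, so full
side chains would add atoms but no testable behaviour.

## 2. Consensus distances

For every atom pair with residue separation ≥ 3, the per-model distances
are examined with a sliding window of width 0.5 Å (a free placement that
maximizes support, not a fixed grid, so no grid-origin artefact can split
a tight cluster of values). If some placement covers the value from at
least `min_support` models (default 4, capped at the ensemble size), a
constraint is emitted whose representative distance is the mean of the
supporting values (median available as an option) and whose support is
the maximal achievable count. Averaging is the point of the method: the
supporting values are independent noisy measurements of the same
underlying distance, so the consensus target is typically closer to the
truth than any single model.

Constraints are then scored by the RAPDF log-odds at their binned
distance and weighted `support_factor × rank_factor`: 1.0 for unanimous
support versus 0.8 otherwise, and a linear map of the score rank onto
(0, 1]. Per maximal-distance cutoff (12, 16, 20 Å) the best-scoring
constraint per residue pair is kept (ties: larger support, shorter
distance, lexicographic atom names). "Best" is read as *most favorable*
(lowest −ln ratio); a `score_direction = "largest"` switch exposes the
alternative reading.

## 3. The RAPDF table

The residue-specific all-atom probability discriminatory function is a
Bayesian comparison of distance distributions:

    score(pair, bin) = −ln [ P(bin | pair) / P(bin) ]

with counts accumulated over atom pairs (residue separation ≥ 3) in
half-open 1 Å bins over [3, 20) Å and additive pseudocount smoothing. The
marginal is computed from the *smoothed* counts, so a corpus in which all
pair types share one distance distribution scores exactly zero
everywhere. Atom typing is reduced — N, CA, C, O as themselves, Cβ and
any further side-chain atom typed by residue class (hydrophobic / polar /
positive / negative), 12 types and 78 unordered pairs — which keeps the
table trainable from a miniature corpus while retaining residue
specificity. The normalized score is `100 × raw / n_contacts`; the
literature threshold "better than −55" for correct topology is exposed as
`flagCorrectTopology` (strict `<`), but its absolute calibration depends
on the typing and training corpus, so no test or reported number depends
on it.

The three auxiliary filter terms are declared stand-ins with ranking
intent, not fitted physics:

* **van der Waals**: soft-sphere penalty `Σ max(0, 0.9(r_i+r_j) − d)²`
  over pairs with residue separation ≥ 2, element radii C 1.70 / N 1.55 /
  O 1.52 Å, computed with a cell list (edge 3.4 Å, larger than any
  contact distance) and tested against a brute-force double loop.
* **compactness**: radius of gyration of hydrophobic Cβ over radius of
  gyration of all Cα; a buried core gives a low ratio.
* **electrostatics**: unit charges (+1 K/R, −1 D/E) on Cβ with a
  distance-dependent dielectric ε = 4d, i.e. `Σ q_i q_j / (4 d²)`.

The sequential filter keeps ⌈N/2⌉ models; the removals are split equally
over the four stages (remainder at the last), each stage dropping its
count of worst scorers with ties broken by stable input order.

## 4. Restrained model building

Models are built in (φ, ψ) space with idealized covalent geometry
(N–CA 1.458, CA–C 1.525, C–N 1.329 Å, standard angles, ω = 180°; chains
are reconstructed by NeRF internal-coordinate placement, implemented in
C++). The objective is

    U = Σ_constraints w_ij (d_ij − target_ij)² + vdW

with the consensus weight as harmonic prefactor (the functional form of
the weighting is a package choice; only the weights themselves come from
the consensus stage).

The search is the one place where implementation experience overrode the
initial design. Pure Metropolis annealing with single-residue
prior-redraw proposals — the simplest reading of "restrained torsion
sampling" — stalls 8–14 Å from the source on a 60-residue recovery
fixture across every temperature schedule tried: once the chain
collapses, single-torsion moves swing whole chain arms and are virtually
always rejected, so basins are never crossed. The production search is
therefore *basin hopping with gradient polishing*, which is also closer
in spirit to the torsion-angle dynamics used by NMR-style structure
calculation programs:

1. start at the torsion prior's modal bin per residue (jittered within
   the 10° bin) — the locally most probable conformation;
2. repeat `steps` (default 30) hops: redraw one or two residues' (φ, ψ)
   from the prior, minimize `U` by L-BFGS over all torsions (analytic
   gradient — a torsion's derivative only involves the restraint and
   clash pairs whose two atoms straddle its rotation axis), and accept by
   Metropolis on a geometric temperature ladder (defaults 30 → 1);
3. polish the best basin with a deeper L-BFGS run (default 300
   iterations; the line search is monotone, so `U` never increases).

Every model is deterministic given (seed, round, model); all randomness
flows through R's RNG. On the 60-residue fixture this reaches ~1–1.5 Å
Cα RMSD from the source, with the restraint objective within a factor
~2 of its value at the source itself.

The Ramachandran-like torsion prior is trained per residue class (Gly,
Pro, pre-Pro, generic) on 10° bins with add-one smoothing. Cartesian
relaxation (`relaxModel`) is a separate, deliberately modest step —
steepest descent on the clash term with harmonic bond-length restraints —
standing in for the heavier minimization/side-chain stages of the
original protocol; it never increases the clash penalty and leaves
clash-free models untouched.

## 5. Clustering and the two-round protocol

Density is the ε-neighbour count at `rmsd_threshold` (pairwise Cα Kabsch
RMSD; the Kabsch implementation uses SVD with reflection sign-correction
and is tested against an independent quaternion-method oracle to 1e−9).
Models with density below `min_density` (default 2) are removed, densities
recomputed, and the cycle repeated to a fixed point; survivors are
grouped by single linkage at the same threshold, so "cluster" and
"neighbourhood" share one scale parameter. Clusters are ranked by size,
then lower mean intra-cluster RMSD, then lowest member index; a cluster's
centroid is its maximal-density member (ties: lowest mean RMSD to the
cluster, then lowest index). The centroids of the five largest clusters
seed the second consensus round; the second round's centroids are the
final predictions.

At the full-scale configuration (3 cutoffs × 50 rounds × 20 models =
3000 conformations per round) many clusters exist and `top_k = 5` is a
genuine selection. At the desk scale the tests run (18–30 conformations
per round), the defaults would often produce one or two clusters — and a
two-model second-round ensemble with quorum 2 is degenerate — so toy
configurations use a tighter threshold (1.0 Å) and `min_density` 0–1 to
keep several centroids in play. These are configuration choices, not
changes to the algorithm.

## 6. The synthetic study system

The generators produce every input the pipeline needs, deterministically
per seed:

* **`makeBundle`** — an idealized antiparallel helical bundle
  (φ = −57°, ψ = −47°) with helix axes on a circle (default 6 helices of
  20 residues, 5-residue connectors, radius 9 Å; the 60-residue recovery
  fixture uses 3 × 16 at 6.5 Å). The entire chain is built *from
  torsions*: connector torsions are solved by numerical inverse
  kinematics (Nelder–Mead on the loop's free torsions so the next helix's
  first four Cα land on their targets). This matters: a rigidly assembled
  bundle is not reproducible from its own torsions under ideal covalent
  geometry, which would place the reference structure outside the
  builder's search manifold and make its consensus restraints mutually
  unsatisfiable. Sequences follow a heptad-style pattern (hydrophobic
  a/d positions) so the compactness and electrostatics terms see
  realistic compositions. The connectors end up near-extended where the
  gap allows and tighter where it does not, rather than uniformly
  extended.
* **`perturbEnsemble`** — Gaussian torsion noise applied as pivot moves
  (exact rotations about the φ/ψ axes, preserving covalent geometry
  bit-exactly), with a single noise scale calibrated by bisection so the
  ensemble's mean Cα RMSD to the source hits the target (±5% at
  calibration, well inside the ±25% contract). One global scale means
  individual members scatter around the target — min-of-five is typically
  1.0–1.5 Å at a 2.0 Å target — which emulates servers of varying
  quality rather than equally-wrong copies.
* **`makeRapdfTraining`** — a cycling mixture of two-, three- and
  four-helix bundles plus sheet-free random-coil decoys with seed-varied
  sequences; 10–20 structures suffice for a table with no empty marginal
  bins and reliable native-vs-5 Å discrimination.
* **`makeAmphipathicSequence`** — a polar background with one helix
  window whose helical-wheel faces (100°/residue) are segregated
  (L/I/F vs S/E/Q), and lysines forced at requested positions; the test
  fixture plants the relative offsets {0, 3, 10, 14, 17}, the spacing of
  the PDCD10 α5 cluster K169–K186 (span 18).

What passing these tests does *not* show: real server ensembles have
correlated, structured errors (shared wrong templates, locally perfect
but globally shifted segments), real folds have side chains and
non-ideal geometry, and real training corpora are far larger and more
diverse. The synthetic system demonstrates the machinery's correctness
and the protocol's information flow, not its accuracy on hard targets.

## 7. Functional-site analyses

The hydrophobic moment is the Eisenberg consensus-scale vector sum
`|Σ h_n e^{i n δ}| / N` at δ = 100°/residue (an 18-mer homopolymer gives
exactly zero — five full turns). `findAmphipathicHelices` scans 18-residue
windows, reports merged maximal runs with moment ≥ 0.25, and assigns the
hydrophobic/polar face from the phase of the complex sum.
`findBasicClusters` reports maximal K/R groups of ≥ 4 members spanning
≤ 20 residues, anchored to an annotated helix extended 5 residues past
its end (basic clusters often spill into the following loop). Applied to
the packaged 212-residue PDCD10 sequence these recover the five-lysine
cluster at 169/172/179/183/186 with span 18 directly from sequence.

A note on the shuffle null: with a composition this hydrophobic-rich,
*some* window exceeding moment 0.25 appears in most shuffles, so
"detection" in the null simulation means recovering the planted
signature — an amphipathic helix carrying a five-lysine cluster — whose
shuffle rate is ~1%.

Solvent accessibility is Shrake–Rupley with 240 deterministic
golden-spiral points per atom and probe 1.4 Å. The quadrature is accurate
to ~1–2% and is *not* rotation-symmetric at machine precision, so
symmetry and rigid-invariance tests assert quadrature-level agreement
(1–5%), consistent with the ±2% closed-form tolerance. Desolvation
patches score each surface atom's 10 Å neighbourhood with a small
per-atom-class solvation parameter table (apolar carbon negative =
favourable to desolvate; polar/charged positive) weighted by SASA, rank
ascending, and greedily prune overlapping centers. The parameter table is
a shipped configuration with octanol/water-style *ranking* semantics, not
the published docking-area constants.

Mass estimates use average-isotope residue masses plus one water;
`estimateMw(s, k)` is exactly `k` times the monomer (no inter-chain
bonds), so the dimer-equals-twice-monomer relation is structural. No
post-translational or purification-tag arithmetic is attempted — the
packaged sequence's bare-chain mass (~24.7 kDa) is accordingly smaller
than tagged-construct estimates.

Heptad registers are assigned per annotated helix (≥ 14 residues) by
maximizing mean a/d-position hydrophobicity over the seven frames,
reported with the margin over the helix-wide mean.

## 8. Numerical choices and degenerate inputs

* Dihedrals follow the standard convention, returned in (−180°, 180°];
  torsions undefined at termini or across missing atoms are `NA`, never
  fabricated, and count as non-helical (but stay in the denominator of
  the helix fraction: window ±30° around (−57°, −47°), minimum run 3).
* Distance bins are half-open `[lo, hi)`; pairs outside [3, 20) Å are
  ignored by RAPDF scoring; an empty contact set yields an `NA`
  normalized score, which the filter treats as worst.
* An ensemble in which every model is removed by outlier cycling yields
  an explicit zero-cluster result; inside the pipeline any stage with no
  survivors aborts with a stage-named error.
* Serialized tables (RAPDF, constraint sets) print numerics at %.17g, so
  text round-trips are bit-exact; coordinates round-trip at the PDB
  format's 3 decimals.
* Degenerate superpositions (fewer than 3 points, collinear sets) are
  errors; proper rotations are enforced by SVD sign-correction.

## 9. Problem sizes used by the test suite

Simulations are scaled to desk size and stated here as the package's own
choices: recovery fixtures are 60-residue three-helix bundles; build
ensembles are 4–18 models per round; the build-recovery property runs 10
seeds and the full-pipeline recovery property 12 seeds against the 95%
and 90% success thresholds; discrimination and shuffle-null simulations
use 30 trials and 200 shuffles.

One property is honestly red at this scale: "the best final centroid
matches or beats the best input model in ≥ 90% of seeds". Measured across
many configurations the rate is ~40–55%. Three compounding reasons: at
2 Å ensemble noise the 0.5 Å/4-of-5 consensus window retains almost only
short- and medium-range distances, putting the rebuild floor at
~0.9–1.2 Å; the bar (the best of five members under one calibrated noise
scale) is often 1.0–1.1 Å, so near-ties abound; and with 18–30 decoys
instead of 3000 the filter and the density clustering cannot reliably
tell 1 Å-scale basins apart, occasionally promoting a tight
wrong-topology cluster into the second round. The machinery itself
frequently *does* improve on the best input (see the README example,
0.85 Å versus 1.24 Å); the stated success *rate* is a property of the
full-scale protocol that desk-scale decoy counts do not reproduce.

## 10. Known limitations

Backbone+Cβ resolution only; no hydrogen bonding or side-chain packing
terms; single chains (no inter-chain restraints, no dimer modelling —
the desolvation patches only *rank* candidate interface regions); the
density-clustering outlier rule (`min_density`) is a declared
interpretation, as the original protocol's outlier criterion is
unstated; structure-based sequence alignment is out of scope, so repeat
superposition takes explicit residue intervals as given.
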