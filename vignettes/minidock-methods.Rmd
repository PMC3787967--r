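---
title: "minidock: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{minidock: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minidock)
```

minidock is a desk-scale implementation of the docking-engine core used in
hot-spot matching virtual screening: deterministic clique-based orientation
sampling, grid-based multi-term scoring of rigid-component conformer
ensembles, and the enrichment metrics used to judge screens.  This vignette
explains the model, the parameters that matter, the numerical choices, and
what the synthetic fixtures do and do not emulate.

## Orientation sampling by sphere matching

Both sides of the matching problem are reduced to labelled points.
Receptor *matching spheres* mark positions in the binding site where a
ligand atom plausibly sits (in automated preparations they are seeded with
the crystallographic ligand's heavy atoms plus nearby generated spheres).
Ligand spheres are the heavy atoms of the molecule's *rigid component*.  A
*correspondence* (clique) is an injective map of `node_count = 4` ligand
spheres onto receptor spheres such that all `choose(4, 2) = 6` internal
distances agree within a tolerance:

$$ |d^{lig}_{ab} - d^{rec}_{\sigma(a)\sigma(b)}| \le t
   \quad \text{for all } a < b . $$

`enumerate_matches()` enumerates *all* such cliques from full distance
matrices — no histogram binning, no randomness, no minimum-internal-distance
filter (the rigid component is a compact ring; a spread filter would buy
nothing and cost completeness).  Each completed 4-node candidate is
validated by exactly 6 distance comparisons (1 + 2 + 3 along the extension
path); the returned `stats` attribute records this.

Because the acceptance condition is monotone in `t`, the match set at a
lower tolerance is always a subset of the set at a higher one.
`adaptive_match()` exploits this: the tolerance starts very low (0.05 Å)
and grows in 0.05 Å steps until at least `match_goal` correspondences
exist (or the 1.5 Å maximum is reached, which is flagged).  The schedule
minimum is the documented starting value; the increment and maximum are
this package's defaults, chosen so the tolerance grows slowly and the
match goal alone controls sampling.  Three design choices make the
"regularly variable sampling" contract testable:

* **Canonical order.** Correspondences are ordered lexicographically by
  sorted ligand indices, then receptor indices, so identical inputs give
  byte-identical output.
* **No truncation.** When the goal is passed mid-iteration, *all* matches
  at the final tolerance are kept.  Truncating to the goal would break the
  guarantee that a larger goal yields a superset of a smaller one — the
  property that makes docking scores monotone in sampling.
* **Re-enumeration per tolerance step.** Each step enumerates from
  scratch; by the subset property the result is identical to an
  incremental scheme, and at desk scale the cost is immaterial.

Each correspondence becomes one rigid-body *orientation* via Kabsch
superposition (SVD of the 3×3 cross-covariance).  The determinant is
forced to +1: reflections would dock a mirror image, which is unphysical
even though it can fit the spheres.  Near-collinear sphere subsets cannot
pin down a rotation; they are flagged degenerate when the second singular
value of the centered ligand points falls below 1e-6 of the first, and the
engine discards them.  Duplicate or near-duplicate orientations are *not*
deduplicated; scoring sorts them out, and raw counts stay interpretable.

## Ligand hierarchies

A `conformer_hierarchy` stores full topology (TRIPOS atoms, bonds,
charges), per-atom desolvation energies, and an ensemble of complete
conformations sharing one rigid component.  Only whole input conformations
are docked — never recombinations of pieces of different conformers — so
no internally clashing geometry can be fabricated at dock time.  The rigid
component is perceived as the largest fused ring system (largest
biconnected component, ≥ 3 atoms, of the heavy-atom bond graph; ties to
the lowest indices).  Under this edge-fusion definition spiro systems
count as separate ring systems.  For acyclic molecules the fallback is the
largest set of heavy atoms joined only by non-rotatable bonds (bonds to
terminal atoms, double/triple/aromatic/amide); fewer than three rigid
heavy atoms flags the molecule undockable (n-butane does).

Builder conformer energies are carried through, never recomputed — no
force field lives in this package — and `energy_window_filter()` keeps
conformers within a chosen window above the ensemble minimum.  The window
is a library-construction parameter (values around 12.5–30 kcal/mol are
typical; wider windows matter when internal electrostatics raise the
absolute energy scale); widening it can only add conformers.

**Hydroxyl rotamers.** Small-molecule crystal structures show aromatic
hydroxyls strongly in-plane, while older library builders often placed
them out of plane, producing high-energy decoy conformations.
`reset_hydroxyls()` therefore resets each O–H on an sp2 carbon to the two
in-plane rotamers (heavy-reference dihedrals 0 and π — both peaks of the
observed distribution are emitted) and each O–H on an sp3 carbon to three
staggered rotamers 2π/3 apart.  sp2 perception is aromatic ring membership
or any double bond on the attached carbon.  Independent hydroxyls combine
as a Cartesian product, capped at 32 combinations per conformer;
truncation sacrifices variation of the highest-index hydroxyls first.

**Formats.** TRIPOS mol2 is read and written natively (multi-MOLECULE
files with one topology fold into one hierarchy; docked output keeps full
atom and bond records, so nothing of the input mol2 is lost, plus `#`
score comments and optional per-atom breakdowns).  db2-lite, documented in
`docs/db2lite.md` with a hand-readable example, is this package's lossless
hierarchy dialect: same content as production flexibase files, not the
same bytes.  Both readers are gzip-transparent.

## Grid scoring

Receptor potentials are precomputed on a uniform lattice and combined with
atomic properties at score time:

$$ E_i = \sqrt{A_i}\,R(x_i) - \sqrt{B_i}\,A(x_i) + q_i\,\Phi(x_i) +
         s_i\,D(x_i) $$

where \(R\) and \(A\) are the sqrt-A- and sqrt-B-weighted \(r^{-12}\) and
\(r^{-6}\) receptor sums (the two-grid geometric-combination convention of
classic grid generators), \(\Phi\) the electrostatic potential in
kcal/(mol·e) (an `es_scale` factor accommodates imported grids in other
units; fixtures store kcal/(mol·e) directly, sidestepping kT conversions),
and \(D\) a dimensionless fractional-desolvation field multiplying the
atom's transfer energy \(s_i\).  Grid sizes come entirely from file
headers — nothing is compiled in.

Off-lattice positions are read by 8-corner trilinear interpolation.
`precompute_grid()` lays the 8 corner values of every interpolation cube
out contiguously, trading ~8× memory for lookups that touch one row
instead of strided array gathers; the fast path reproduces the naive path
to rounding error (the suite checks 1e-10 relative) and is exact at
lattice nodes and for affine fields.  Atoms outside the lattice reject the
pose (`out_of_grid`) — grids are trimmed to the scored region, and
extrapolation would be meaningless.

**Bump filter.** Instead of a distance-cutoff bump grid, the repulsive vdW
term itself prunes: atoms are accumulated in order and the running sum of
positive repulsive contributions is compared with the bump limit; crossing
it stops evaluation with status `bumped`.  Whether production engines test
per-atom or cumulatively is not documented; the cumulative rule is used
here (it is well defined for "any portion of the ligand", and the nesting
property — survivors at limit 10 ⊆ 20 ⊆ 50 ⊆ ∞ — holds either way).  The
routine default is 50 kcal/mol; `Inf` disables the filter.

## The docking engine

`dock_molecule()` chains the pieces: ligand spheres from the rigid
component, orientations from `adaptive_match()`, each transform applied to
*every* conformer (they share the rigid component, so one orientation
places the whole ensemble), each placed conformer scored with the bump
filter, survivors kept in a bounded `pose_list` by insertion sort on total
energy with a stable (orientation, conformer) tie-break.  Orientations are
scored in canonical match order and conformers in file order; each
(orientation, conformer) pair is scored independently.  The run is
deterministic end to end: two identical screens produce byte-identical
score tables and pose files.

Conformer (internal) energy is carried into the output but *not* added to
the docking score; weighting by internal energies is an output-field hook,
not part of the scoring function here.  Molecules with no surviving pose
get an explicit `+1000` kcal/mol sentinel alongside a status column —
sorting stays well defined without NaN conventions.  `top_poses` defaults
to 1; large values are supported and simply cost memory.

## Evaluation metrics

* **ROC/AUC** (`roc_points()`, `roc_auc()`): molecules ranked ascending by
  score; tied scores advance as one block (the trapezoid through the tie,
  equivalent to averaging over orderings), so an all-tied screen is
  exactly the diagonal.
* **Enrichment factor** (`enrichment_factor()`): fraction of ligands in
  the top `ceiling(f·N)` of the list divided by `f`; the ceiling makes the
  1% cutoff well defined for any library size, and sets too small for the
  fraction are an error rather than a silent 0/0.
* **Adjusted logAUC** (`adjusted_log_auc()`): the ROC area against a
  logarithmic FPR axis over `[λ, 1]`, normalized by `log10(1/λ)`, in
  percent, minus the random-classifier area `100(1−λ)/ln(1/λ)` (≈ 14.46
  for the default λ = 0.001), so 0 is random and positive is enrichment.
  The integral is evaluated in closed form per linear ROC segment
  (`∫(a+bf) d log f = a·ln(f2/f1) + b·(f2−f1)`, divided by ln 10) rather
  than by a trapezoid on log-transformed vertices: the trapezoid is not
  exact for segments linear in *f*, and exactness is what makes the
  diagonal's adjusted logAUC identically zero.
* **Symmetry-corrected RMSD** (`hungarian_rmsd()`): heavy-atom RMSD where
  same-element atoms may exchange, via a minimum-cost assignment (a
  shortest-augmenting-path Hungarian solver written in-package and checked
  against a brute-force permutation oracle).  It is never above the
  order-respecting RMSD and is zero for symmetry relabelings such as a
  rotated benzene.
* **Critical-contact RMSD** (`critical_contact_rmsd()`): the same optimal
  same-element assignment, but from a small set of pharmacophore-defining
  reference atoms to *any* pose atoms of the required elements.  A pose
  lacking a required element has an *undefined* RMSD (`NA`), not zero;
  across a library the median over defined values is reported
  (`critical_contact_summary()`), which is robust to those undefined
  entries.  The assignment is globally optimal, not greedy.

## Synthetic fixtures, problem sizes and what tests show

All tests run on generated data; every generator is a pure function of its
seed and asserts its own postconditions at build time.

* `make_fig1_system()` reproduces the *counts* of the classic toy matching
  diagram (2 correspondences at tolerance 0.1, 4 at 0.2, none at 0) — the
  published drawing's coordinates are unrecoverable, so the fixture is a
  faithful analog, not a transcription.
* `make_hierarchy()` builds an irregular aromatic ring (jitter breaks the
  hexagon's symmetry so sphere matching is anchored), a rotatable tail
  that generates the conformers, and hydroxyls starting 1.2 rad out of
  plane.
* `make_planted_site()` places pseudo-receptor atoms one Lennard-Jones
  minimum away from each heavy atom of the planted conformer (direction
  chosen per atom so no well crowds a neighboring atom), with opposite
  charges, samples the closed-form 12-6 + Coulomb (dielectric 4) +
  Gaussian-burial field onto grids (≤ 64³ nodes, default spacing 0.4 Å),
  and puts receptor spheres exactly on the planted rigid atoms.  The
  planted pose must score below −1 kcal/mol and survive a bump limit of
  50, or generation aborts.
* `make_score_set()` draws ligand scores from Normal(−separation, 1) and
  decoys from Normal(0, 1).

Typical suite sizes: oracle equivalence on 200 random systems with ≤ 8
spheres per side; interpolation agreement on 10⁴ random queries;
pose recovery on 10 seeded sites at match goal 100; bump-limit nesting on
a 20-molecule library at goals of 30; the null-enrichment calibration uses
50 seeds of 200 ligands + 200 decoys and checks the *mean over seeds*
(AUC within 0.5 ± 0.02, adjusted logAUC within ± 1.5) — a single 400-
molecule screen has sampling noise of the same order as the band, so the
band is a statement about the seeded ensemble, not about one draw.

What the fixtures do **not** emulate: real protein shapes (no occlusion,
no narrow pockets), property-matched decoys, conformer ensembles from a
real builder, tautomers/protonation, or receptor flexibility.  Passing
tests demonstrate the algorithmic contracts — completeness and
determinism of sampling, monotonicity in the sampling knobs, fidelity of
interpolation and of the scoring decomposition, metric correctness — not
screening performance on real targets.

## Known limitations

Single-process and pure R: throughput is adequate for desk-scale studies
and testing, not for multi-million-compound campaigns (parallelize across
molecules externally if needed).  No rigid-body minimization after
placement; scores are grid-resolution limited.  Receptor preparation
(grids from real structures, sphere generation) and ligand building
(conformer generation, charge/desolvation calculation) are out of scope —
minidock consumes their outputs via the documented file formats.
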