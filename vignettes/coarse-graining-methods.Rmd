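---
title: "Sparsity-preserving coarse-graining of spring-network Hessians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparsity-preserving coarse-graining of spring-network Hessians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Normal mode analysis (NMA) describes the thermal motions of a molecule
near its native state by the eigenpairs of the Hessian matrix **H** (the
3N x 3N second-derivative matrix of the potential).  For large complexes
an all-atom Hessian is too expensive to diagonalize, so practitioners
reduce the structure to a subset of sites — usually one C-alpha per
residue — and build an elastic network on those sites.  The catch is that
simple site-level spring rules lose the physics of the atoms that were
removed.

The Schur complement solves this exactly.  Partition the all-atom Hessian
into kept (c) and removed (r) blocks; then

$$\tilde H_{cc} = H_{cc} - H_{cr} H_{rr}^{-1} H_{cr}^\top$$

is the *exact* effective Hessian of the kept sites: every element of
$\tilde H_{cc}^{-1}$ equals the corresponding element of $H^{-1}$, so
mean-square fluctuations (MSF) and cross-correlations of the kept sites
are preserved bit-for-bit.  `schur_project_exact()` implements this
directly; it is the package's oracle, but its cost is cubic in the
removed size.

## The iterative algorithm

For spring-based models the Hessian is sparse (~99% zeros), and the
projection can be done group by group: remove one spatial group of atoms
at a time, each elimination adding the correction $B D^{-1} B^\top$ to
the surviving block ($B$ the coupling to the group, $D$ the group's
diagonal block).  Because Schur complements compose (a stepwise
elimination equals the one-shot elimination), the result with no
thresholding is exactly $\tilde H_{cc}$ — `coarse_grain_iterative()` with
`xi = 0` reproduces the oracle to roundoff, which the test suite checks
for randomized groupings.

Sparsity is maintained by hard-thresholding: couplings below `xi` are
zeroed before each elimination, the correction term is thresholded at
`xi/m` (it is accumulated over the m groups), and the final matrix is
thresholded at `xi` once more.  Groups are formed by binning the removed
atoms into 18 A cubic cells, merging the small tail of the cell-size
distribution up to a 500-atom cap, and eliminating smallest-first;
reverse Cuthill-McKee ordering within groups keeps each $D$ compact.
With these defaults the construction cost grows near-linearly with
system size while dense diagonalization grows cubically — the package's
benchmark verb reproduces that contrast.

## The spring models

`preset_rules()` ships four models.  The `ssnma_like` preset mirrors the
simplified spring-based family: one uniform constant per interaction
class — bonds 100, bond angles 20, torsions 5 (energy/A^2 or /rad^2) —
plus nonbonded springs $k = \max(0, V''_{LJ}(d))$ from a 12-6 potential
with a single per-element radius set (well depth 0.2), truncated at the
inflection distance $r_m (13/7)^{1/6}$ so springs are never negative, and
at an 8 A cutoff.  `eanm_like` and `atomic_anm` are distance-spring
elastic networks; `calpha_anm` is the textbook C-alpha network (13 A).

Angle and torsion terms act on the internal coordinate itself: each
contributes $k\, \nabla q \nabla q^\top$ with $q$ the bending or dihedral
angle.  An earlier draft used surrogate 1-3/1-4 *distance* springs
instead, but a distance spring has zero first-order stiffness wherever
the distance is extremal in the coordinate — exactly the situation at
trans/cis dihedrals and for sp2 out-of-plane motion — and peptide
fixtures then carry spurious zero modes.  The gradient outer-product form
preserves all the properties that matter here (3x3 block sparsity
limited to 1-2/1-3/1-4 neighbours, positive semidefiniteness, an exact
six-dimensional rigid-body null space; the dihedral gradient is validated
against finite differences in the tests) and is the faithful reading of a
"spring on every internal coordinate" model.

Thresholds are interpreted on raw Hessian entries in these units, so the
usable range of `xi` is about 1e-4 to 1e-1: at 0.01 the dropped entries
sit far below both the bonded couplings (~10-100) and the smallest
non-rigid eigenvalues of a well-packed structure (~0.05-1), which is why
accuracy is fully preserved there and degrades at 0.1.

## What the synthetic fixtures emulate — and what they do not

All tests run on generated structures (`make_peptide()`), not downloads.
The generator builds idealized peptides with standard stereochemistry
(N-CA 1.458, CA-C 1.525, C-N 1.329 A; helix phi/psi -57/-47), three
side-chain options, and seeded, bit-reproducible randomness.

The `compact-globule` geometry is an idealized helix bundle: helical rows
packed on a hexagonal serpentine grid (10.2 A axis spacing for
leucine-sized `stub3` side chains), connected by short turns whose
torsions are solved by seeded multistart optimization against the next
row's helix tube, with steric screens throughout.  Optionally backbone
amide hydrogens are added (`hydrogens = TRUE`); this matters because
real spring-model inputs are prepared structures with hydrogens, and the
N-H...O hydrogen-bond network supplies stiff short-range contact springs
that dominate the cohesion of a folded protein.  Without them a
heavy-atom random coil is orders of magnitude softer than any folded
protein and no threshold below the bonded scale preserves its soft
spectrum — an early all-coil version of the generator failed exactly this
way.

Because the growth is stochastic and greedy it occasionally mis-packs.
The generator therefore validates each globule before returning it:
non-hydrogenated builds must stay inside their design envelope (radius of
gyration within 1.28x of the guide's box), and prepared-structure builds
must pass a mechanical-stability screen — the lowest non-rigid eigenvalue
of the default spring network, coarse-grained to C-alpha sites, must be
at least 0.04.  Failing draws are re-sampled (up to seven attempts)
inside the same seed, mirroring the fact that experimentally solved folds
are mechanically stable minima while bad decoys are not.  A green
accuracy test therefore establishes that the algorithm preserves the
dynamics of *cohesive, protein-like* spring networks; it does not say
anything about intrinsically floppy chains, and the `xi = 0.1` row of the
replication table shows what breakage looks like.

Fixture termini are overgrown by three residues and trimmed so that the
returned chain ends sit in packed, hydrogen-bonded positions (dangling
helix ends otherwise add soft local modes no real minimized structure
has).

## Mode statistics

* `msf()` sums $\lambda_j^{-1} |m_j|^2$ over all non-rigid modes — equal
  to the diagonal blocks of the pseudo-inverse (checked against a dense
  oracle).  For thresholded Hessians of connected structures pass
  `n_rigid = 6` explicitly: thresholding shifts the six rigid eigenvalues
  slightly off zero and an automatic relative tolerance would misclassify
  them.
* `weighted_mode_overlap()` is the eigenvalue-weighted same-index overlap
  $\sum_{i\ge 7} (w_i/w) |m_i \cdot \hat m_i|$, $w_i = 1/\lambda_i$ from
  the reference model; same-index pairing (not best-match) so that mode
  reordering is penalized.  Degenerate eigenvalues make same-index
  pairing unstable in principle; the fixtures used here have
  non-degenerate low spectra, and the plain value is what the replication
  reports.
* `cooperativity()` is the normalized cross-correlation map over the
  first k non-rigid modes (default 15), unweighted as the definition
  states; a 1/lambda-weighted variant sits behind a flag since many ENM
  codes weight modes.
* `transition_overlap()` superposes the end conformation by a
  least-squares rigid fit (the superposition method is a choice this
  package makes; it is not dictated by the statistic) and reports
  $|m_i \cdot d|/\|d\|$; over all non-rigid modes these overlaps square-sum
  to 1.
* `sse_preservation()` scales a mode to a 1 A global RMSD, then measures
  each helix/strand segment's internal RMSD after independently
  superposing it back — low values mean the mode moves secondary
  structure rigidly.

## Numerical choices

* Symmetrization `(A + A^T)/2` after projection and after each
  elimination kills roundoff drift; the algorithm assumes symmetry.
* Each group block $D$ is factorized by dense Cholesky; failure means a
  removed component has no kept site (an input error, reported as such).
* The tethered-inverse identity test adds `tau = 1e-3 * mean(diag(H))`
  to make H invertible and compares `(H^-1)_cc` with the inverse of the
  projected matrix *relative to the block magnitude*: the identity is
  algebraically exact, and an absolute tolerance would only measure the
  conditioning of the tether.
* Fluctuation identities for singular Hessians are gauge questions: the
  Moore-Penrose pseudo-inverse fixes the rigid-motion gauge over whatever
  index set it is computed on, so `[pinv(H)]_cc` and `pinv(H_cg)` differ
  by a rigid field.  The exact identity — used by the conservation test —
  is `pinv(H_cg) = R [pinv(H)]_cc R^T`, with `R` projecting out rigid
  motions of the kept sites.  For invertible (tethered) matrices the
  plain elementwise identity holds and is tested as such.
* Rigid modes are counted with a relative eigenvalue tolerance (1e-8 of
  the largest) for exact models; thresholded models use the relaxed
  1e-4 tolerance consistent with the perturbation that thresholding
  introduces.
* Tie-breaks in the spatial partition (equal cell sizes) are resolved by
  lattice coordinates, making removal plans deterministic.

## Scaled-down checks

The replication ensemble (ten 80-120-residue globules) stands in for the
published 177-protein study; the benchmark runs at 1k-4k atoms rather
than the hundreds of thousands of the original application.  Both
substitutions are about compute budgets, not method limits: every
operation is identical at scale, only n changes.

## Known limitations

* Only spring-based (sparse) models are supported; potentials with
  long-range electrostatics produce dense Hessians for which the
  thresholded elimination is knowingly inaccurate — the replication
  table's dense-model column in the source material shows the same.
* The ssnma_like constants are plausible uniform values, not a fitted
  force field; all accuracy statements here are about reproducing the
  exact projection of the *same* model, which is invariant to that
  choice provided the structure is cohesive at the chosen unit scale.
* The turn solver optimizes geometry, not energetics; fixture turns are
  protein-like in shape but not Ramachandran-statistical.
* `read_pdb()` handles the common fixed-column records (ATOM/HETATM/TER/
  HELIX/SHEET, altloc, MODEL); mmCIF and residue-template topologies are
  out of scope.
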