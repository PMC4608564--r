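# cgnma — coarse-grained normal mode analysis with all-atom accuracy

Protein dynamics near the native state is routinely studied through
normal mode analysis (NMA): the eigenvectors of the Hessian **H** (the
3N x 3N second-derivative matrix of the potential) are the collective
motions, the eigenvalues their stiffness.  For large assemblies an
all-atom Hessian cannot be diagonalized, so structures are coarse-grained
to one site per residue — at the cost of replacing atomic physics with
ad-hoc site springs.

`cgnma` removes that trade-off for sparse spring-network models.  The
Schur complement

    H~cc = Hcc − Hcr Hrr⁻¹ Hcrᵀ

is the *exact* effective Hessian of the kept sites c (every element of
`H~cc⁻¹` equals the corresponding element of `H⁻¹`, so mean-square
fluctuations and cross-correlations of the kept sites are untouched).
The package provides

* the exact direct projection (`schur_project_exact()`), cubic cost,
  used as the oracle;
* an iterative, sparsity-preserving elimination
  (`coarse_grain_iterative()`): removed atoms are grouped by 18 Å spatial
  cells (≤ 500 atoms per group), eliminated group by group, with
  couplings below a threshold `ξ` zeroed along the way — near-linear cost
  in system size, and identical to the oracle when `ξ = 0`;
* sparse all-atom spring models (`preset_rules()`: an ssNMA-like model
  with internal-coordinate bond/angle/torsion springs plus truncated
  Lennard-Jones contacts, and eANM/ANM-style distance-spring networks);
* the validation statistics of the field: MSF, B-factor scaling,
  eigenvalue-weighted mode overlap, best-match mode tables,
  cooperativity (cross-correlation) maps, mode–transition overlaps and
  secondary-structure preservation;
* deterministic protein-like synthetic structures (helix-bundle
  globules, multimer rings, seeded perturbations) so everything is
  testable offline;
* a CLI (`exec/cgnma`) with verbs `coarsegrain`, `analyze`, `bench`,
  `fixture`, plus PDB and MatrixMarket I/O.

## Worked example

```r
library(cgnma)

# a 100-residue synthetic globule emulating a prepared (hydrogenated)
# structure, and its sparse all-atom spring Hessian
st    <- make_peptide(fixture_spec(100, "compact-globule", "stub3",
                                   seed = 0, hydrogens = TRUE))
rules <- preset_rules("ssnma_like")
topo  <- infer_topology(st, nonbonded_cutoff = rules$cutoff)
H     <- build_hessian(st, topo, rules)
sparseness(H)
#> [1] 0.9794917

# coarse-grain to the C-alpha sites: exact oracle vs iterative at xi=0.01
K    <- select_sites(st, "calpha")
ex   <- schur_project_exact(H, K)
plan <- spatial_partition(st, K, cg_config(xi = 0.01))
it   <- coarse_grain_iterative(H, plan, cg_config(xi = 0.01))

ref  <- eig_modes(ex); tst <- eig_modes(it)
cor(as.numeric(msf(ref, n_rigid = 6)), as.numeric(msf(tst, n_rigid = 6)))
#> [1] 0.9999532
weighted_mode_overlap(ref, tst)
#> [1] 0.9880794
```

The correlation compares per-residue mean-square fluctuations from the
two coarse-grained models over all non-rigid modes; the weighted overlap
is the 1/λ-weighted same-index mode agreement (1 = every mode and its
ordering preserved).  Values this close to 1 mean the thresholded
iterative elimination lost essentially nothing relative to the exact
projection, at a fraction of the cost.

The same pipeline from the shell:

```sh
cgnma coarsegrain --n-residues 100 --geometry compact-globule \
      --model ssnma_like --xi 0.01 --compare-exact --out run/
cgnma analyze --input run/cg_hessian.mtx --analyses msf,cooperativity \
      --out run/
```

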