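test_that("decoupled subsystems project to the plain kept block", {
  # two dumbbells far apart: eliminating one (H_cr = 0) leaves the other
  # unchanged; the removed block needs a pseudo-inverse since it carries
  # its own rigid modes
  atoms <- data.frame(serial = 1:4, name = paste0("C", 1:4), element = "C",
                      res_index = 1:4, res_name = "LIG", chain = "A",
                      x = c(0, 1.5, 100, 101.5), y = 0, z = 0)
  st <- atomic_structure(atoms)
  rules <- preset_rules("atomic_anm")
  H <- build_hessian(st, infer_topology(st), rules)
  cg <- schur_project_exact(H, c(1L, 2L), pinv = TRUE)
  expect_equal(as.matrix(cg$M), as.matrix(H$M[1:6, 1:6]),
               ignore_attr = TRUE)
})

test_that("eliminating the middle of a 3-spring chain gives the series spring", {
  atoms <- data.frame(serial = 1:3, name = paste0("C", 1:3), element = "C",
                      res_index = 1:3, res_name = "LIG", chain = "A",
                      x = c(0, 1.5, 3.0), y = 0, z = 0)
  st <- atomic_structure(atoms)
  rules <- preset_rules("atomic_anm")   # unit springs; 1-3 pair also within cutoff
  rules$k_angle <- 0                    # keep only the two 1-2 springs
  topo <- infer_topology(st, nonbonded_cutoff = 2)  # excludes the 1-3 pair
  H <- build_hessian(st, topo, rules)
  cg <- schur_project_exact(H, c(1L, 3L), pinv = TRUE)
  xs <- c(1, 4)                          # x dof of the two kept atoms
  expect_equal(as.matrix(cg$M[xs, xs]),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("tethered inverse identity: (H^-1)_cc = (projected tethered H)^-1", {
  md <- build_model(small_globule(n = 12, seed = 3))
  K <- select_sites(md$structure, "calpha")
  tau <- 1e-3 * mean(Matrix::diag(md$hessian$M))
  Ht <- md$hessian
  Ht$M <- Ht$M + tau * Matrix::Diagonal(nrow(Ht$M))
  cg <- schur_project_exact(Ht, K)
  dof <- cgnma:::dof_of(K$kept)
  inv_cc <- solve(as.matrix(Ht$M))[dof, dof]
  inv_cg <- solve(as.matrix(cg$M))
  expect_lt(max(abs(inv_cc - inv_cg)) / max(abs(inv_cc)), 1e-8)
})

test_that("spatial partition covers all removed atoms with capped groups", {
  st <- small_globule(n = 80, seed = 1)
  K <- select_sites(st, "calpha")
  cfg <- cg_config(cell_size = 8, max_group = 120)
  plan <- spatial_partition(st, K, cfg)
  got <- sort(unlist(plan$groups))
  expect_equal(got, setdiff(seq_len(n_atoms(st)), K$kept))
  expect_false(any(duplicated(got)))
  expect_true(all(diff(lengths(plan$groups)) <= 0))   # descending sizes
  # merged tail respects the cap (initial cells may exceed it)
  expect_true(plan$m >= 1)
  # all atoms in one cell -> one group
  plan1 <- spatial_partition(st, K, cg_config(cell_size = 1000))
  expect_equal(plan1$m, 1L)
})

test_that("reordering is a symmetric permutation and involution", {
  md <- build_model(small_globule(n = 20, seed = 2))
  K <- select_sites(md$structure, "calpha")
  plan <- spatial_partition(md$structure, K, cg_config(cell_size = 10))
  Hr <- reorder_for_elimination(md$hessian, plan, cg_config())
  p <- cgnma:::dof_of(Hr$atom_order)
  back <- Hr$M
  back[p, p] <- Hr$M            # undo the permutation
  expect_equal(as.matrix(back), as.matrix(md$hessian$M), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_identical(max(abs(Hr$M - Matrix::t(Hr$M))), 0)
})

test_that("Cuthill-McKee ordering does not increase group bandwidth on a chain", {
  st <- make_peptide(fixture_spec(30, "extended", "none", seed = 0))
  md <- build_model(st)
  K <- select_sites(st, "custom", indices = which(st$atoms$name == "CA")[1:2])
  plan <- spatial_partition(st, K, cg_config(cell_size = 1e4))
  bw <- function(H, plan, ordering) {
    cfg <- cg_config(ordering = ordering)
    Hr <- reorder_for_elimination(H, plan, cfg)
    nk <- 3 * length(plan$K)
    sub <- Hr$M[-(1:nk), -(1:nk), drop = FALSE]
    tr <- Matrix::mat2triplet(Matrix::drop0(sub))
    max(abs(tr$i - tr$j))
  }
  expect_lte(bw(md$hessian, plan, "cuthill_mckee"),
             bw(md$hessian, plan, "input"))
})

test_that("sparsify hard-thresholds entries", {
  A <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(2, 1, 3),
                            x = c(0.5, 0.5, -0.001), dims = c(3, 3))
  expect_equal(as.matrix(sparsify(A, 0)), as.matrix(A))
  s <- sparsify(A, 0.01)
  expect_equal(Matrix::nnzero(s), 2)
  expect_equal(Matrix::nnzero(sparsify(A, 1)), 0)
  # dense input path
  expect_equal(sparsify(matrix(c(1, 0.001), 1), 0.01),
               matrix(c(1, 0), 1))
})

test_that("iterative elimination with xi = 0 matches the exact oracle", {
  for (seed in c(0, 4)) {
    md <- build_model(small_globule(n = 25, seed = seed))
    K <- select_sites(md$structure, "calpha")
    ex <- schur_project_exact(md$hessian, K)
    for (cell in c(6, 12, 1e4)) {
      plan <- spatial_partition(md$structure, K,
                                cg_config(cell_size = cell, max_group = 40))
      it <- coarse_grain_iterative(md$hessian, plan, cg_config(xi = 0))
      expect_lt(max(abs(it$M - ex$M)), 1e-8 * max(abs(ex$M)))
    }
  }
})

test_that("random groupings also satisfy oracle equivalence", {
  md <- build_model(small_globule(n = 20, seed = 9))
  K <- select_sites(md$structure, "calpha")
  ex <- schur_project_exact(md$hessian, K)
  removed <- setdiff(seq_len(n_atoms(md$structure)), K$kept)
  set.seed(42)
  for (rep in 1:3) {
    m <- sample(2:5, 1)
    lab <- sample(rep_len(seq_len(m), length(removed)))
    groups <- unname(split(removed, lab))
    groups <- groups[order(-lengths(groups))]
    plan <- structure(list(K = K$kept, groups = groups, m = length(groups)),
                      class = "RemovalPlan")
    it <- coarse_grain_iterative(md$hessian, plan, cg_config(xi = 0))
    expect_lt(max(abs(it$M - ex$M)), 1e-8 * max(abs(ex$M)))
  }
})

test_that("degenerate site sets are handled", {
  md <- build_model(small_globule(n = 6, seed = 0))
  all_sites <- seq_len(n_atoms(md$structure))
  cg <- schur_project_exact(md$hessian, all_sites)
  expect_equal(as.matrix(cg$M), as.matrix(md$hessian$M))
  expect_error(schur_project_exact(md$hessian, integer(0)))
})

test_that("a removed component with no kept site raises a clear error", {
  # two far-apart dumbbells, keep only atoms of the first
  atoms <- data.frame(serial = 1:4, name = paste0("C", 1:4), element = "C",
                      res_index = 1:4, res_name = "LIG", chain = "A",
                      x = c(0, 1.5, 100, 101.5), y = 0, z = 0)
  st <- atomic_structure(atoms)
  H <- build_hessian(st, infer_topology(st), preset_rules("atomic_anm"))
  expect_error(schur_project_exact(H, c(1L, 2L)), "singular|no kept")
})

test_that("power-law fits recover known exponents", {
  n <- c(100, 200, 400, 800)
  expect_equal(fit_power_law(n, n)[["b"]], 1, tolerance = 1e-10)
  expect_equal(fit_power_law(n, n^3)[["b"]], 3, tolerance = 1e-10)
  set.seed(1)
  noisy <- 2 * n^1.1 * exp(rnorm(4, 0, 0.05))
  b <- fit_power_law(n, noisy)[["b"]]
  expect_gt(b, 0.9); expect_lt(b, 1.3)
  expect_error(fit_power_law(n, -n))
})
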