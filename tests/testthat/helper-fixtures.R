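# Shared fixture builders for the test suite.  Everything is generated in
# code at test time; nothing is read from disk.

small_globule <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 30, seed = 0, sidechain = "cbeta", hydrogens = FALSE) {
    key <- paste(n, seed, sidechain, hydrogens)
    if (is.null(cache[[key]]))
      cache[[key]] <- make_peptide(fixture_spec(n, "compact-globule",
                                                sidechain, seed = seed,
                                                hydrogens = hydrogens))
    cache[[key]]
  }
})

build_model <- function(structure, preset = "ssnma_like") {
  rules <- preset_rules(preset)
  topo <- infer_topology(structure, nonbonded_cutoff = rules$cutoff)
  list(structure = structure, rules = rules, topology = topo,
       hessian = build_hessian(structure, topo, rules))
}

# two atoms on the x-axis joined by one unit spring: the canonical
# closed-form system (eigenvalues 2k and five zeros)
dumbbell_hessian <- function(k = 1) {
  atoms <- data.frame(serial = 1:2, name = c("C1", "C2"),
                      element = "C", res_index = 1:2, res_name = "LIG",
                      chain = "A", x = c(0, 1.5), y = 0, z = 0)
  st <- atomic_structure(atoms)
  topo <- infer_topology(st)
  rules <- preset_rules("atomic_anm")
  rules$k_bond <- k
  list(structure = st, hessian = build_hessian(st, topo, rules))
}

rigid_space <- function(structure) {
  # 6 orthonormal rigid-body vectors (3 translations + 3 rotations about
  # the centroid) in the 3n-dimensional coordinate space
  xyz <- sweep(coords(structure), 2, colMeans(coords(structure)))
  n <- nrow(xyz)
  basis <- matrix(0, 3 * n, 6)
  for (d in 1:3) basis[seq(d, 3 * n, by = 3), d] <- 1
  for (i in seq_len(n)) {
    r <- xyz[i, ]
    basis[(3 * i - 2):(3 * i), 4] <- c(0, -r[3], r[2])
    basis[(3 * i - 2):(3 * i), 5] <- c(r[3], 0, -r[1])
    basis[(3 * i - 2):(3 * i), 6] <- c(-r[2], r[1], 0)
  }
  qr.Q(qr(basis))
}
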