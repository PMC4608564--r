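test_that("pair super-element is k r r^T", {
  b <- pair_super_element(1, c(0, 0, 0), c(2, 0, 0))
  expect_equal(b, diag(c(1, 0, 0)))
  expect_equal(pair_super_element(0, c(0, 0, 0), c(1, 1, 1)),
               matrix(0, 3, 3))
  set.seed(7)
  xi <- rnorm(3); xj <- rnorm(3)
  g <- pair_super_element(2.5, xi, xj)
  expect_equal(sum(diag(g)), 2.5)
  expect_equal(qr(g)$rank, 1L)
  expect_error(pair_super_element(1, xi, xi), "coincident")
})

test_that("truncated Lennard-Jones spring constant follows V''", {
  rules <- preset_rules("ssnma_like")
  rm_cc <- 2 * 1.70
  # numeric second derivative of V(r) = eps[(rm/r)^12 - 2 (rm/r)^6]
  V <- function(r) rules$epsilon * ((rm_cc / r)^12 - 2 * (rm_cc / r)^6)
  h <- 1e-5
  for (d in c(3.0, rm_cc, 3.6)) {
    vpp <- (V(d + h) - 2 * V(d) + V(d - h)) / h^2
    expect_equal(vdw_spring_constant("C", "C", d, rules), max(vpp, 0),
                 tolerance = 1e-5)
  }
  # at the minimum: k = 72 eps / rm^2 (= 57.146 eps/sigma^2)
  expect_equal(vdw_spring_constant("C", "C", rm_cc, rules),
               72 * rules$epsilon / rm_cc^2, tolerance = 1e-6)
  # zero beyond the inflection and continuous approaching it
  infl <- rm_cc * (13 / 7)^(1 / 6)
  expect_equal(vdw_spring_constant("C", "C", 2 * infl, rules), 0)
  expect_equal(vdw_spring_constant("C", "C", infl + 1e-9, rules), 0)
  expect_lt(vdw_spring_constant("C", "C", infl - 1e-3, rules), 1e-2)
  # unknown element falls back to the default radius
  expect_equal(vdw_spring_constant("XX", "XX", 3.4, rules),
               vdw_spring_constant("C", "C", 3.4, rules))
})

test_that("internal-coordinate gradients match finite differences", {
  ang_of <- function(x) {
    u <- x[1, ] - x[2, ]; v <- x[3, ] - x[2, ]
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  dih_of <- function(x) {
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    b1 <- x[2, ] - x[1, ]; b2 <- x[3, ] - x[2, ]; b3 <- x[4, ] - x[3, ]
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
    atan2(sum(m1 * n2), sum(n1 * n2))
  }
  numgrad <- function(f, x, h = 1e-6) {
    gr <- x * 0
    for (i in seq_len(nrow(x))) for (j in 1:3) {
      xp <- x; xm <- x
      xp[i, j] <- xp[i, j] + h; xm[i, j] <- xm[i, j] - h
      gr[i, j] <- (f(xp) - f(xm)) / (2 * h)
    }
    gr
  }
  set.seed(11)
  for (rep in 1:5) {
    x3 <- matrix(rnorm(9, sd = 2), 3, 3)
    ga <- cgnma:::angle_gradients(x3[1, , drop = FALSE], x3[2, , drop = FALSE],
                                  x3[3, , drop = FALSE])
    expect_equal(rbind(ga$gi, ga$gj, ga$gk), numgrad(ang_of, x3),
                 tolerance = 1e-5, ignore_attr = TRUE)
    x4 <- matrix(rnorm(12, sd = 2), 4, 3)
    gd <- cgnma:::dihedral_gradients(x4[1, , drop = FALSE], x4[2, , drop = FALSE],
                                     x4[3, , drop = FALSE], x4[4, , drop = FALSE])
    G <- rbind(gd$gi, gd$gj, gd$gk, gd$gl)
    Gn <- numgrad(dih_of, x4)
    # dihedral sign convention may flip the gradient globally
    if (sum(G * Gn) < 0) Gn <- -Gn
    expect_equal(G, Gn, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("the one-spring dumbbell has eigenvalues {2k, 0 x 5}", {
  db <- dumbbell_hessian(k = 1)
  ev <- eigen(as.matrix(db$hessian$M), symmetric = TRUE)$values
  expect_equal(sort(ev), c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
})

test_that("rigid translations and rotations are in the null space", {
  for (preset in c("ssnma_like", "eanm_like")) {
    md <- build_model(small_globule(n = 15, seed = 2), preset)
    R <- rigid_space(md$structure)
    resid <- md$hessian$M %*% R
    expect_lt(max(abs(resid)), 1e-8 * max(abs(md$hessian$M)))
  }
})

test_that("Hessians are symmetric, PSD, with exactly 6 near-zero modes", {
  for (seed in c(1, 5)) {
    md <- build_model(small_globule(n = 25, seed = seed, sidechain = "stub3",
                                    hydrogens = TRUE))
    M <- md$hessian$M
    expect_identical(max(abs(M - Matrix::t(M))), 0)
    ev <- eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
    expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6L)
  }
})

test_that("sparseness counts exactly-zero entries", {
  db <- dumbbell_hessian()
  # x-axis dumbbell: each 3x3 block is diag(k,0,0) -> 4 nonzeros of 36
  expect_equal(sparseness(db$hessian), 32 / 36)
  md <- build_model(small_globule(n = 60, seed = 4))
  expect_gte(sparseness(md$hessian), 0.9)
})

test_that("sparseness grows with system size at fixed cutoff", {
  sp <- vapply(c(20, 40, 80), function(n)
    sparseness(build_model(small_globule(n = n, seed = 6))$hessian), 0)
  expect_true(all(diff(sp) > 0))
})

test_that("presets expose the documented structure", {
  a <- preset_rules("atomic_anm")
  expect_equal(a$k_bond, a$k_nonbonded)
  expect_equal(preset_rules("calpha_anm")$cutoff, 13)
  expect_error(preset_rules("nope"))
  expect_equal(preset_rules("ssnma_like")$bonded, "internal")
})

test_that("calpha_anm equals a brute-force ANM on a CA-only structure", {
  st <- small_globule(n = 20, seed = 8)
  K <- select_sites(st, "calpha")
  ca <- atomic_structure(st$atoms[K$kept, ])
  rules <- preset_rules("calpha_anm")
  topo <- infer_topology(ca, nonbonded_cutoff = rules$cutoff)
  H <- build_hessian(ca, topo, rules)
  # independent textbook construction
  xyz <- coords(ca)
  n <- nrow(xyz)
  ref <- matrix(0, 3 * n, 3 * n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- xyz[j, ] - xyz[i, ]
    dn <- sqrt(sum(d^2))
    if (dn <= 13) {
      blk <- tcrossprod(d / dn)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      ref[ii, jj] <- ref[ii, jj] - blk
      ref[jj, ii] <- ref[jj, ii] - blk
      ref[ii, ii] <- ref[ii, ii] + blk
      ref[jj, jj] <- ref[jj, jj] + blk
    }
  }
  expect_equal(as.matrix(H$M), ref, tolerance = 1e-12, ignore_attr = TRUE)
})
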