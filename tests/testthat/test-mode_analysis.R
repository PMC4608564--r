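test_that("eig_modes returns ascending orthonormal modes with 6 rigid", {
  md <- build_model(small_globule(n = 15, seed = 1))
  m <- eig_modes(md$hessian)
  expect_false(is.unsorted(m$values))
  expect_equal(m$n_rigid, 6L)
  G <- crossprod(m$vectors)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  db <- dumbbell_hessian(k = 3)
  expect_equal(eig_modes(db$hessian)$values, c(0, 0, 0, 0, 0, 6),
               tolerance = 1e-12)
  expect_error(eig_modes(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("MSF equals the diagonal blocks of the dense pseudo-inverse", {
  md <- build_model(small_globule(n = 12, seed = 5))
  m <- eig_modes(md$hessian)
  prof <- msf(m)
  Hp <- as.matrix(md$hessian$M)
  e <- eigen(Hp, symmetric = TRUE)
  keep <- e$values > 1e-8 * max(e$values)
  pinv <- e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])
  ref <- vapply(seq_len(n_atoms(md$structure)),
                function(i) sum(diag(pinv)[(3 * i - 2):(3 * i)]), 0)
  expect_equal(as.numeric(prof), ref, tolerance = 1e-8)
  # scaling H by c scales MSF by 1/c
  H2 <- md$hessian; H2$M <- 2 * H2$M
  expect_equal(as.numeric(msf(eig_modes(H2))), ref / 2, tolerance = 1e-8)
})

test_that("B-factor scaling minimizes RMSD and reports Pearson r", {
  md <- build_model(small_globule(n = 12, seed = 2))
  prof <- as.numeric(msf(eig_modes(md$hessian)))
  fit <- fit_bfactor_scale(prof, 2 * prof)
  expect_equal(fit$scale, 2)
  expect_equal(fit$pearson_r, 1)
  expect_equal(fit_bfactor_scale(prof, -prof)$pearson_r, -1)
  set.seed(3)
  b <- prof + rnorm(length(prof), 0, sd(prof))
  fit <- fit_bfactor_scale(prof, b)
  expect_equal(fit$pearson_r, cor(prof, b))
  # the returned scale is the least-squares optimum
  rss <- function(s) sum((s * prof - b)^2)
  expect_lt(rss(fit$scale), min(rss(fit$scale * 1.01), rss(fit$scale * 0.99)))
  expect_error(fit_bfactor_scale(rep(1, 5), rep(2, 5)), "variance")
})

test_that("weighted mode overlap: self = 1, swaps penalized, signs ignored", {
  md <- build_model(small_globule(n = 10, seed = 7))
  K <- select_sites(md$structure, "calpha")
  cg <- schur_project_exact(md$hessian, K)
  m <- eig_modes(cg)
  expect_equal(weighted_mode_overlap(m, m), 1.0)
  # sign flips are invisible
  flip <- m
  flip$vectors <- m$vectors %*% diag(sign(rnorm(ncol(m$vectors))))
  expect_equal(weighted_mode_overlap(m, flip), 1.0)
  # swapping modes 7 and 8 gives the hand-computable value
  sw <- m
  sw$vectors[, 7:8] <- m$vectors[, 8:7]
  w <- 1 / m$values[7:length(m$values)]
  d78 <- abs(sum(m$vectors[, 7] * m$vectors[, 8]))
  expected <- (sum(w[-(1:2)]) + (w[1] + w[2]) * d78) / sum(w)
  expect_equal(weighted_mode_overlap(m, sw), expected, tolerance = 1e-12)
  expect_lt(weighted_mode_overlap(m, sw), 1.0)
})

test_that("best-match overlaps recover identity and permutations", {
  md <- build_model(small_globule(n = 10, seed = 4))
  K <- select_sites(md$structure, "calpha")
  m <- eig_modes(schur_project_exact(md$hessian, K))
  bm <- best_match_overlaps(m, m, n_list = 5)
  expect_equal(bm$mode_b, 1:5)
  expect_equal(bm$overlap, rep(1, 5), tolerance = 1e-10)
  perm <- m
  idx <- m$n_rigid + 1:4
  perm$vectors[, idx] <- m$vectors[, idx[c(2, 1, 4, 3)]]
  bm2 <- best_match_overlaps(m, perm, n_list = 4)
  expect_equal(bm2$mode_b, c(2, 1, 4, 3))
})

test_that("cooperativity matches Eq-6 hand computation and its identities", {
  md <- build_model(small_globule(n = 8, seed = 6))
  K <- select_sites(md$structure, "calpha")
  m <- eig_modes(schur_project_exact(md$hessian, K))
  C <- cooperativity(m, k = 2)
  expect_equal(diag(C), rep(1, 8))
  expect_equal(C, t(C))
  expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
  # manual average over the two modes
  v1 <- matrix(m$vectors[, m$n_rigid + 1], nrow = 3)
  v2 <- matrix(m$vectors[, m$n_rigid + 2], nrow = 3)
  num <- (crossprod(v1) + crossprod(v2)) / 2
  ref <- num / sqrt(outer(diag(num), diag(num)))
  expect_equal(C, ref, tolerance = 1e-12, ignore_attr = TRUE)
  # k = 1 reduces to the cosine between displacement vectors
  C1 <- cooperativity(m, k = 1)
  cosij <- sum(v1[, 1] * v1[, 2]) /
    sqrt(sum(v1[, 1]^2) * sum(v1[, 2]^2))
  expect_equal(C1[1, 2], cosij, tolerance = 1e-12)
  # invariant to a global mode sign flip
  flip <- m; flip$vectors[, m$n_rigid + 1] <- -m$vectors[, m$n_rigid + 1]
  expect_equal(cooperativity(flip, k = 2), C, tolerance = 1e-12)
})

test_that("transition overlap is exact for single-mode displacements", {
  md <- build_model(small_globule(n = 10, seed = 3))
  K <- select_sites(md$structure, "calpha")
  m <- eig_modes(schur_project_exact(md$hessian, K))
  X <- coords(md$structure)[K$kept, ]
  d7 <- matrix(m$vectors[, m$n_rigid + 1], ncol = 3, byrow = TRUE)
  tr <- transition_overlap(X, X + 0.8 * d7, m, n_list = 3)
  expect_equal(tr$mode[1], 1L)
  expect_gt(tr$overlap[1], 0.99)
  expect_lt(tr$overlap[2], 0.2)
})

test_that("transition overlap is rigid-motion invariant and complete", {
  md <- build_model(small_globule(n = 10, seed = 3))
  K <- select_sites(md$structure, "calpha")
  m <- eig_modes(schur_project_exact(md$hessian, K))
  X <- coords(md$structure)[K$kept, ]
  set.seed(9)
  Y <- X + matrix(rnorm(length(X), 0, 0.3), ncol = 3)
  tr <- transition_overlap(X, Y, m)
  # completeness: the displacement lives in the span of all modes; after
  # superposition the non-rigid modes carry almost all of it
  ov <- attr(tr, "all_overlaps")
  expect_equal(sum(ov^2), 1, tolerance = 1e-6)
  # rigid rotation + translation of the end structure changes nothing
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Y2 <- Y %*% R + matrix(5, nrow(Y), 3)
  tr2 <- transition_overlap(X, Y2, m)
  expect_equal(tr$overlap, tr2$overlap, tolerance = 1e-8)
  # pure rigid motion -> zero displacement error
  expect_error(transition_overlap(X, X %*% R + 2, m), "zero displacement")
})

test_that("SSE preservation is zero for rigid modes and localized for stretches", {
  st <- make_peptide(fixture_spec(24, "helix", "cbeta", seed = 0))
  st$sse <- data.frame(kind = "helix", chain = "A",
                       first = c(1L, 13L), last = c(12L, 24L),
                       stringsAsFactors = FALSE)
  K <- select_sites(st, "calpha")
  n <- length(K$kept)
  # synthetic mode set: one rigid translation and one stretch of segment 1
  stretch <- matrix(0, ncol = 3, nrow = n)
  stretch[1:12, 1] <- seq(-1, 1, length.out = 12)      # stretch helix 1
  modes <- structure(list(
    values = c(rep(0, 6), 1, 2),
    vectors = cbind(matrix(rnorm(3 * n * 6), ncol = 6),
                    rep(c(1, 0, 0), n) / sqrt(n),
                    as.vector(t(stretch)) / sqrt(sum(stretch^2))),
    n_rigid = 6L, n_sites = n), class = "ModeSet")
  res <- sse_preservation(st, K$kept, modes, rmsd_target = 1, n_modes = 2)
  # mode 1 (translation): all segments rigid
  expect_lt(res$per_mode$mean_sse_rmsd[1], 1e-10)
  # mode 2 stretches helix 1 only
  expect_gt(res$per_mode$mean_sse_rmsd[2], 0.1)
  res0 <- sse_preservation(st, K$kept, modes, rmsd_target = 0, n_modes = 2)
  expect_equal(res0$per_mode$mean_sse_rmsd, c(0, 0), tolerance = 1e-12)
  st2 <- st; st2$sse <- st$sse[0, ]
  expect_error(sse_preservation(st2, K$kept, modes), "SSE")
})
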