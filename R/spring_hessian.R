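# Sparse all-atom spring-network Hessians.  Every interaction contributes
# a rank-1 pair "super-element" k * r_hat r_hat^T: subtracted on the
# off-diagonal 3x3 block and added to both diagonal blocks, which places
# rigid translations (and, for central pair springs, rotations) in the
# null space by construction.

DEFAULT_VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
DEFAULT_VDW_RADIUS <- 1.70

#' Spring-rule presets
#'
#' @param name one of `"ssnma_like"` (uniform bond / angle / torsion
#'   spring constants on internal coordinates + truncated Lennard-Jones
#'   nonbonded springs), `"eanm_like"` (two-tier distance springs: stiff
#'   bonded 1-2/1-3, uniform weak nonbonded), `"atomic_anm"` (one uniform
#'   distance spring for every pair within the cutoff) or `"calpha_anm"`
#'   (uniform springs, 13 A cutoff, intended for CA-only structures).
#' @return list of class `SpringRules` with fields `k_bond`, `k_angle`,
#'   `k_torsion`, `bonded` (`"internal"`: angle/torsion terms act on the
#'   bending/dihedral coordinate; `"pairs"`: plain 1-3/1-4 distance
#'   springs), `nonbonded` (`"lj"` or `"uniform"`), `k_nonbonded`,
#'   `epsilon`, `radii`, `cutoff`, `model_label`.
#' @export
preset_rules <- function(name = c("ssnma_like", "eanm_like", "atomic_anm",
                                  "calpha_anm")) {
  name <- match.arg(name)
  r <- switch(name,
    ssnma_like = list(k_bond = 100, k_angle = 20, k_torsion = 5,
                      bonded = "internal", nonbonded = "lj",
                      k_nonbonded = NA_real_, epsilon = 0.2, cutoff = 8),
    eanm_like  = list(k_bond = 100, k_angle = 100, k_torsion = 0,
                      bonded = "pairs", nonbonded = "uniform",
                      k_nonbonded = 1, epsilon = NA_real_, cutoff = 8),
    atomic_anm = list(k_bond = 1, k_angle = 1, k_torsion = 0,
                      bonded = "pairs", nonbonded = "uniform",
                      k_nonbonded = 1, epsilon = NA_real_, cutoff = 8),
    calpha_anm = list(k_bond = 1, k_angle = 1, k_torsion = 0,
                      bonded = "pairs", nonbonded = "uniform",
                      k_nonbonded = 1, epsilon = NA_real_, cutoff = 13))
  r$radii <- DEFAULT_VDW_RADII
  r$model_label <- name
  class(r) <- "SpringRules"
  r
}

#' Pair spring super-element
#'
#' The 3x3 block `k * r_hat r_hat^T` for a spring of stiffness `k`
#' between positions `xi` and `xj` (r_hat the unit inter-atom vector).
#' It has trace `k` and rank 1; the caller subtracts it off-diagonal and
#' adds it to both diagonal blocks.
#'
#' @param k spring constant (energy/A^2), `>= 0`.
#' @param xi,xj 3-vectors, Angstrom.
#' @return 3x3 numeric matrix.
#' @export
pair_super_element <- function(k, xi, xj) {
  stopifnot(k >= 0)
  d <- xj - xi
  dn <- sqrt(sum(d^2))
  if (dn < 1e-8) stop("coincident atoms in pair spring")
  u <- d / dn
  k * tcrossprod(u)
}

#' Truncated Lennard-Jones spring constant
#'
#' Second derivative of the 12-6 potential with well minimum at
#' `r_min = R_i + R_j` (single per-element radius set) and depth
#' `epsilon`, clamped at zero beyond the inflection distance
#' `r_min * (13/7)^(1/6)` (equivalently `sigma * (26/7)^(1/6)`) and
#' beyond the cutoff, so nonbonded springs are never negative.
#'
#' @param el_i,el_j element symbols.
#' @param d pair distance, Angstrom (> 0).
#' @param rules a `SpringRules` (uses `epsilon`, `radii`, `cutoff`).
#' @return spring constant `>= 0`.
#' @export
vdw_spring_constant <- function(el_i, el_j, d, rules) {
  stopifnot(all(d > 0))
  ri <- rules$radii[el_i]; ri[is.na(ri)] <- DEFAULT_VDW_RADIUS
  rj <- rules$radii[el_j]; rj[is.na(rj)] <- DEFAULT_VDW_RADIUS
  rm <- unname(ri + rj)
  # V(r) = eps[(rm/r)^12 - 2 (rm/r)^6]; V''(r) = (12 eps/r^2)[13 q^12 - 7 q^6]
  q6 <- (rm / d)^6
  k <- 12 * rules$epsilon / d^2 * (13 * q6^2 - 7 * q6)
  k[d > rm * (13 / 7)^(1 / 6)] <- 0
  k[d > rules$cutoff] <- 0
  pmax(k, 0)
}

# Gradients of the bond angle i-j-k (radians) w.r.t. the three positions.
# Rows of xi/xj/xk are angle instances; returns list(gi, gj, gk), each A x 3.
angle_gradients <- function(xi, xj, xk) {
  u <- xi - xj; v <- xk - xj
  nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
  uh <- u / nu; vh <- v / nv
  ct <- rowSums(uh * vh)
  st <- sqrt(pmax(1 - ct^2, 1e-12))
  gi <- (ct * uh - vh) / (nu * st)
  gk <- (ct * vh - uh) / (nv * st)
  list(gi = gi, gj = -gi - gk, gk = gk)
}

row_cross <- function(a, b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])

# Gradients of the dihedral i-j-k-l (radians); returns list of T x 3.
dihedral_gradients <- function(xi, xj, xk, xl) {
  b1 <- xj - xi; b2 <- xk - xj; b3 <- xl - xk
  n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
  n1sq <- pmax(rowSums(n1^2), 1e-12)
  n2sq <- pmax(rowSums(n2^2), 1e-12)
  nb2 <- sqrt(rowSums(b2^2))
  gi <- -(nb2 / n1sq) * n1
  gl <- (nb2 / n2sq) * n2
  c12 <- rowSums(b1 * b2) / nb2^2
  c32 <- rowSums(b3 * b2) / nb2^2
  gj <- -(1 + c12) * gi + c32 * gl
  gk <- c12 * gi - (1 + c32) * gl
  list(gi = gi, gj = gj, gk = gk, gl = gl)
}

# triplets for sum over instances of k * g g^T, g the stacked gradient over
# `p` atoms; atoms is a list of index vectors, grads a list of n x 3 blocks.
internal_triplets <- function(atoms, grads, k) {
  p <- length(atoms)
  n <- length(atoms[[1]])
  kv <- rep_len(k, n)
  ii <- list(); jj <- list(); xx <- list()
  t <- 0L
  for (a in seq_len(p)) for (b in seq_len(p)) {
    ba <- 3 * (atoms[[a]] - 1L); bb <- 3 * (atoms[[b]] - 1L)
    for (r in 1:3) for (cc in 1:3) {
      t <- t + 1L
      ii[[t]] <- ba + r
      jj[[t]] <- bb + cc
      xx[[t]] <- kv * grads[[a]][, r] * grads[[b]][, cc]
    }
  }
  list(i = unlist(ii), j = unlist(jj), x = unlist(xx))
}

# triplets for pair super-elements over pair lists (i, j, k)
pair_triplets <- function(pi_, pj, pk, xyz) {
  dx <- xyz[pj, 1] - xyz[pi_, 1]
  dy <- xyz[pj, 2] - xyz[pi_, 2]
  dz <- xyz[pj, 3] - xyz[pi_, 3]
  d2 <- dx * dx + dy * dy + dz * dz
  if (any(d2 < 1e-12)) stop("coincident interacting atoms")
  s <- pk / d2
  bxx <- s * dx * dx; byy <- s * dy * dy; bzz <- s * dz * dz
  bxy <- s * dx * dy; bxz <- s * dx * dz; byz <- s * dy * dz
  # 9 entries per pair for block (i,j); symmetric partner and the two
  # diagonal accumulations reuse the same values.
  bi <- 3 * (pi_ - 1); bj <- 3 * (pj - 1)
  comp_r <- c(1, 1, 1, 2, 2, 2, 3, 3, 3)
  comp_c <- c(1, 2, 3, 1, 2, 3, 1, 2, 3)
  vals <- cbind(bxx, bxy, bxz, bxy, byy, byz, bxz, byz, bzz)
  np <- length(pi_)
  rI <- rep(bi, times = 9) + rep(comp_r, each = np)
  cJ <- rep(bj, times = 9) + rep(comp_c, each = np)
  v <- as.vector(vals)
  i_all <- c(rI, cJ, rep(bi, times = 9) + rep(comp_r, each = np),
             rep(bj, times = 9) + rep(comp_r, each = np))
  j_all <- c(cJ, rI, rep(bi, times = 9) + rep(comp_c, each = np),
             rep(bj, times = 9) + rep(comp_c, each = np))
  x_all <- c(-v, -v, v, v)
  list(i = i_all, j = j_all, x = x_all)
}

#' Build the sparse all-atom Hessian
#'
#' Bonds contribute pair super-elements (`k_bond`); angle and torsion
#' terms contribute either internal-coordinate springs
#' `k * grad(q) grad(q)^T` on the bending / dihedral coordinate
#' (`rules$bonded = "internal"`, the spring-based NMA form) or plain
#' 1-3 / 1-4 distance springs (`"pairs"`, the elastic-network form).
#' Nonbonded pairs get truncated Lennard-Jones or uniform springs per
#' `rules$nonbonded`; 1-4 pairs receive both the torsion term and the
#' nonbonded spring.  Rigid translations and rotations are in the null
#' space by construction in either form.
#'
#' @param structure an `AtomicStructure`.
#' @param topology a [infer_topology()] result (its nonbonded list must
#'   have been built with a cutoff `>= rules$cutoff`).
#' @param rules a [preset_rules()] object (or modified copy).
#' @return list of class `SparseHessian`: `M` (dgCMatrix, 3N x 3N),
#'   `atom_order` (block-position -> atom-index permutation),
#'   `model_label`, `n_atoms`.
#' @export
build_hessian <- function(structure, topology, rules) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  el <- structure$atoms$element
  pi_ <- integer(0); pj <- integer(0); pk <- numeric(0)
  add <- function(mat, k) {
    if (!is.null(mat) && nrow(mat) && any(k != 0)) {
      pi_ <<- c(pi_, mat[, 1]); pj <<- c(pj, mat[, 2])
      pk <<- c(pk, rep_len(k, nrow(mat)))
    }
  }
  add(topology$bonds, rules$k_bond)
  internal <- identical(rules$bonded, "internal")
  if (!internal) {
    add(topology$pairs13, rules$k_angle)
    add(topology$pairs14, rules$k_torsion)
  }
  nb <- topology$nonbonded
  if (nrow(nb)) {
    d <- nb[, "d"]
    within <- d <= rules$cutoff
    nb <- nb[within, , drop = FALSE]
    if (nrow(nb)) {
      kv <- if (rules$nonbonded == "uniform") rep(rules$k_nonbonded, nrow(nb))
            else vdw_spring_constant(el[nb[, "i"]], el[nb[, "j"]], nb[, "d"], rules)
      nz <- kv > 0
      add(nb[nz, c("i", "j"), drop = FALSE], kv[nz])
    }
  }
  trip <- list()
  if (length(pi_)) trip[[1]] <- pair_triplets(pi_, pj, pk, xyz)
  if (internal && rules$k_angle != 0 && nrow(topology$angles)) {
    an <- topology$angles
    g <- angle_gradients(xyz[an[, 1], , drop = FALSE],
                         xyz[an[, 2], , drop = FALSE],
                         xyz[an[, 3], , drop = FALSE])
    trip[[length(trip) + 1L]] <-
      internal_triplets(list(an[, 1], an[, 2], an[, 3]), g, rules$k_angle)
  }
  if (internal && rules$k_torsion != 0 && nrow(topology$torsions)) {
    to <- topology$torsions
    g <- dihedral_gradients(xyz[to[, 1], , drop = FALSE],
                            xyz[to[, 2], , drop = FALSE],
                            xyz[to[, 3], , drop = FALSE],
                            xyz[to[, 4], , drop = FALSE])
    trip[[length(trip) + 1L]] <-
      internal_triplets(list(to[, 1], to[, 2], to[, 3], to[, 4]), g,
                        rules$k_torsion)
  }
  M <- if (length(trip))
    Matrix::sparseMatrix(i = unlist(lapply(trip, `[[`, "i")),
                         j = unlist(lapply(trip, `[[`, "j")),
                         x = unlist(lapply(trip, `[[`, "x")),
                         dims = c(3 * n, 3 * n))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(3 * n, 3 * n))
  M <- Matrix::drop0((M + Matrix::t(M)) / 2)   # exact symmetry
  structure(list(M = M, atom_order = seq_len(n),
                 model_label = rules$model_label, n_atoms = n),
            class = "SparseHessian")
}

#' @export
print.SparseHessian <- function(x, ...) {
  cat(sprintf("SparseHessian: %d atoms (%d dof), %s, sparseness %.3f\n",
              x$n_atoms, nrow(x$M), x$model_label, sparseness(x)))
  invisible(x)
}

#' Fraction of exactly-zero entries
#' @param H a `SparseHessian` (or `CGHessian`).
#' @return value in `[0, 1]`.
#' @export
sparseness <- function(H) {
  M <- Matrix::drop0(H$M)
  1 - Matrix::nnzero(M) / prod(dim(M))
}
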