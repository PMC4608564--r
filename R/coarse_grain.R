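# Schur-complement coarse-graining: the exact direct projection
# H_cc - H_cr H_rr^-1 H_cr^T used as oracle, and the iterative
# sparsity-preserving group elimination that computes the same matrix in
# near-linear time by removing one spatial group of atoms at a time and
# hard-thresholding small couplings.

#' Coarse-graining configuration
#'
#' @param xi hard threshold applied to couplings between the surviving
#'   block and each eliminated group (0 = lossless elimination).
#' @param cell_size edge of the cubic spatial cells used to form removal
#'   groups, Angstrom (default 18).
#' @param max_group merge cap on group size in atoms (default 500).
#' @param ordering atom ordering inside each group: `"cuthill_mckee"`
#'   (reverse Cuthill-McKee on the group interaction subgraph) or
#'   `"input"`.
#' @param pinv_tol relative eigenvalue tolerance used when diagnosing a
#'   singular removed block.
#' @return list of class `CoarseGrainConfig`.
#' @export
cg_config <- function(xi = 0.01, cell_size = 18, max_group = 500L,
                      ordering = c("cuthill_mckee", "input"),
                      pinv_tol = 1e-8) {
  ordering <- match.arg(ordering)
  stopifnot(xi >= 0, cell_size > 0, max_group >= 1)
  structure(list(xi = xi, cell_size = cell_size,
                 max_group = as.integer(max_group),
                 ordering = ordering, pinv_tol = pinv_tol),
            class = "CoarseGrainConfig")
}

dof_of <- function(atoms) {
  b <- 3 * (rep(atoms, each = 3) - 1)
  b + rep(1:3, times = length(atoms))
}

sites_of <- function(K) {
  if (inherits(K, "SiteSelection")) K$kept else as.integer(K)
}

#' Exact Schur-complement projection
#'
#' Direct computation of the coarse-grained Hessian
#' `H_cc - H_cr H_rr^-1 H_cr^T` by sparse Cholesky factorization of the
#' removed block; exact but cubic in the removed size. The result is
#' symmetrized `(A + A^T)/2` to kill roundoff.
#'
#' @param H a `SparseHessian`.
#' @param K a `SiteSelection` or integer vector of kept atom indices.
#' @param pinv use a pseudo-inverse for a singular removed block instead
#'   of erroring (default FALSE: a singular block normally signals a
#'   removed component with no kept site, i.e. a modelling error).
#' @param pinv_tol relative eigenvalue tolerance of the pseudo-inverse.
#' @return list of class `CGHessian`: `M` (3|K| x 3|K| dgCMatrix),
#'   `sites`, `provenance`.
#' @export
schur_project_exact <- function(H, K, pinv = FALSE, pinv_tol = 1e-10) {
  kept <- sites_of(K)
  n <- H$n_atoms
  stopifnot(length(kept) >= 1, all(kept >= 1 & kept <= n))
  removed <- setdiff(seq_len(n), kept)
  ck <- dof_of(kept)
  if (!length(removed)) {
    return(structure(list(M = H$M[ck, ck, drop = FALSE], sites = kept,
                          provenance = list(method = "exact", xi = 0,
                                            model = H$model_label)),
                     class = "CGHessian"))
  }
  cr <- dof_of(removed)
  Hcc <- H$M[ck, ck, drop = FALSE]
  Hcr <- H$M[ck, cr, drop = FALSE]
  Hrr <- Matrix::forceSymmetric(H$M[cr, cr, drop = FALSE])
  X <- if (pinv) {
    e <- eigen(as.matrix(Hrr), symmetric = TRUE)
    keep_ev <- e$values > pinv_tol * max(abs(e$values))
    e$vectors[, keep_ev, drop = FALSE] %*%
      ((t(e$vectors[, keep_ev, drop = FALSE]) %*% as.matrix(Matrix::t(Hcr))) /
         e$values[keep_ev])
  } else tryCatch(suppressWarnings({
    ch <- Matrix::Cholesky(Hrr, LDL = FALSE, perm = TRUE)
    Matrix::solve(ch, Matrix::t(Hcr))
  }), error = function(e)
    stop("removed block is singular (a removed connected component has no ",
         "kept site): ", conditionMessage(e)))
  S <- Hcc - Hcr %*% X
  S <- Matrix::drop0((S + Matrix::t(S)) / 2)
  structure(list(M = methods::as(S, "CsparseMatrix"), sites = kept,
                 provenance = list(method = "exact", xi = 0,
                                   model = H$model_label)),
            class = "CGHessian")
}

#' @export
print.CGHessian <- function(x, ...) {
  cat(sprintf("CGHessian: %d sites, method=%s, xi=%g, model=%s\n",
              length(x$sites), x$provenance$method, x$provenance$xi,
              x$provenance$model))
  invisible(x)
}

#' Spatial grouping of the atoms to eliminate
#'
#' Non-kept atoms are binned into cubic cells (`cell_size`, anchored at
#' the bounding-box minimum); cells are sorted by atom count descending
#' and the small tail is repeatedly merged (smallest with next smallest)
#' while the merged size stays within `max_group`. Groups are returned in
#' descending-size order; the elimination loop removes the last (hence
#' smallest) group first.
#'
#' @param structure an `AtomicStructure`.
#' @param K a `SiteSelection` or integer vector of kept atom indices.
#' @param cfg a [cg_config()].
#' @return list of class `RemovalPlan`: `K` (kept indices), `groups`
#'   (list of integer vectors), `m`.
#' @export
spatial_partition <- function(structure, K, cfg = cg_config()) {
  kept <- sites_of(K)
  n <- n_atoms(structure)
  removed <- setdiff(seq_len(n), kept)
  if (!length(removed))
    return(structure(list(K = kept, groups = list(), m = 0L),
                     class = "RemovalPlan"))
  xyz <- coords(structure)[removed, , drop = FALSE]
  lo <- apply(xyz, 2, min)
  ci <- floor(sweep(xyz, 2, lo) / cfg$cell_size)
  key <- paste(ci[, 1], ci[, 2], ci[, 3])
  cells <- split(removed, key)
  # deterministic order: size descending, then lattice coordinates
  lat <- do.call(rbind, lapply(strsplit(names(cells), " "), as.integer))
  sz <- lengths(cells)
  ord <- order(-sz, lat[, 1], lat[, 2], lat[, 3])
  groups <- unname(cells[ord])
  # merge the small end: smallest + next smallest while within cap
  repeat {
    g <- length(groups)
    if (g < 2L) break
    if (length(groups[[g]]) + length(groups[[g - 1L]]) > cfg$max_group) break
    groups[[g - 1L]] <- c(groups[[g - 1L]], groups[[g]])
    groups[[g]] <- NULL
    groups <- groups[order(-lengths(groups))]
  }
  structure(list(K = kept, groups = groups, m = length(groups)),
            class = "RemovalPlan")
}

#' @export
print.RemovalPlan <- function(x, ...) {
  cat(sprintf("RemovalPlan: %d kept sites, %d group(s) (sizes %s)\n",
              length(x$K), x$m,
              paste(lengths(x$groups), collapse = ", ")))
  invisible(x)
}

# reverse Cuthill-McKee on an adjacency list restricted to `nodes`
# (local indices 1..length(nodes)); returns permutation of local indices.
rcm_order <- function(adj) {
  n <- length(adj)
  if (n <= 2L) return(seq_len(n))
  deg <- lengths(adj)
  visited <- logical(n)
  out <- integer(0)
  while (length(out) < n) {
    start <- which(!visited)[which.min(deg[!visited])]
    queue <- start; visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      out <- c(out, v)
      nb <- adj[[v]]
      nb <- nb[!visited[nb]]
      if (length(nb)) {
        nb <- nb[order(deg[nb])]
        visited[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
  }
  rev(out)
}

atom_adjacency <- function(M, nodes) {
  # adjacency among `nodes` from the nonzero 3x3 block pattern of M
  sub <- M[dof_of(nodes), dof_of(nodes), drop = FALSE]
  tr <- Matrix::mat2triplet(Matrix::drop0(sub))
  ai <- (tr$i - 1L) %/% 3L + 1L
  aj <- (tr$j - 1L) %/% 3L + 1L
  keep <- ai != aj
  split(aj[keep], factor(ai[keep], levels = seq_along(nodes))) |>
    lapply(unique)
}

#' Symmetric permutation into elimination order
#'
#' Permutes a Hessian so kept sites come first, followed by the removal
#' groups in plan order, optionally with reverse Cuthill-McKee ordering
#' of the atoms inside each group (concentrates each group's couplings
#' near the diagonal).
#'
#' @param H a `SparseHessian`.
#' @param plan a [spatial_partition()] result.
#' @param cfg a [cg_config()].
#' @return a `SparseHessian` whose `atom_order[p]` is the original index
#'   of the atom at block position `p`.
#' @export
reorder_for_elimination <- function(H, plan, cfg = cg_config()) {
  groups <- plan$groups
  if (cfg$ordering == "cuthill_mckee") {
    groups <- lapply(groups, function(g) {
      if (length(g) <= 2L) return(g)
      g[rcm_order(atom_adjacency(H$M, g))]
    })
  }
  perm <- c(plan$K, unlist(groups, use.names = FALSE))
  stopifnot(length(perm) == H$n_atoms)
  pd <- dof_of(perm)
  structure(list(M = H$M[pd, pd, drop = FALSE],
                 atom_order = as.integer(perm),
                 model_label = H$model_label, n_atoms = H$n_atoms),
            class = "SparseHessian")
}

#' Hard-threshold a sparse matrix
#'
#' Sets to zero every stored entry with `|entry| < b`; preserves symmetry
#' of symmetric inputs.
#'
#' @param A a sparse `Matrix` (or base matrix).
#' @param b threshold `>= 0`.
#' @return thresholded matrix of the same class family.
#' @export
sparsify <- function(A, b) {
  stopifnot(b >= 0)
  if (b == 0) return(A)
  if (is.matrix(A)) { A[abs(A) < b] <- 0; return(A) }
  A <- methods::as(A, "CsparseMatrix")
  A@x[abs(A@x) < b] <- 0
  Matrix::drop0(A)
}

#' Iterative sparsity-preserving coarse-graining
#'
#' Eliminates the removal groups one at a time, smallest first.  At each
#' step, with `k` surviving atoms and group `R_i` of size `r - k`:
#' `B <- sparsify(H[1..k, k+1..r], xi)`; `D <- H[k+1..r, k+1..r]`;
#' `E <- sparsify(B D^-1 B^T, xi/m)`; `H[1..k,1..k] <- H[..] - E`.
#' The final kept-block is thresholded at `xi` once more and symmetrized.
#' With `xi = 0` this reproduces [schur_project_exact()] to roundoff
#' (stepwise Schur elimination equals one-shot elimination).
#'
#' @param H a `SparseHessian` (any atom order; reordered internally).
#' @param plan a [spatial_partition()] result.
#' @param cfg a [cg_config()]; `cfg$xi` is the threshold.
#' @return a `CGHessian` over the kept sites (rows/cols in `plan$K`
#'   order), with provenance `method = "iterative"`.
#' @export
coarse_grain_iterative <- function(H, plan, cfg = cg_config()) {
  kept <- plan$K
  if (!length(plan$groups)) {
    ck <- dof_of(kept)
    return(structure(list(M = H$M[ck, ck, drop = FALSE], sites = kept,
                          provenance = list(method = "exact", xi = cfg$xi,
                                            model = H$model_label)),
                     class = "CGHessian"))
  }
  Hr <- reorder_for_elimination(H, plan, cfg)
  M <- Hr$M
  m <- plan$m
  gsizes <- lengths(plan$groups)
  nK <- length(kept)
  for (i in m:1) {
    k <- nK + if (i > 1L) sum(gsizes[seq_len(i - 1L)]) else 0L
    r <- k + gsizes[i]
    rows <- seq_len(3 * k)
    gcols <- (3 * k + 1L):(3 * r)
    B <- sparsify(M[rows, gcols, drop = FALSE], cfg$xi)
    D <- as.matrix(M[gcols, gcols, drop = FALSE])
    if (any(!is.finite(D))) stop("non-finite entries in group ", i)
    R <- tryCatch(chol(D), error = function(e)
      stop("singular diagonal block for group ", i,
           " (group decoupled from the rest): ", conditionMessage(e)))
    # restrict to the atoms that actually couple to the group
    nzr <- unique((Matrix::mat2triplet(B)$i - 1L) %/% 3L + 1L)
    if (length(nzr)) {
      srows <- dof_of(sort(nzr))
      Bs <- as.matrix(B[srows, , drop = FALSE])
      X <- backsolve(R, forwardsolve(t(R), t(Bs)))
      E <- Bs %*% X
      E[abs(E) < cfg$xi / m] <- 0
      M[srows, srows] <- M[srows, srows, drop = FALSE] - E
    }
  }
  ck <- seq_len(3 * nK)
  S <- sparsify(M[ck, ck, drop = FALSE], cfg$xi)
  S <- Matrix::drop0((S + Matrix::t(S)) / 2)
  if (any(!is.finite(S@x))) stop("non-finite entries in coarse-grained result")
  structure(list(M = methods::as(S, "CsparseMatrix"), sites = kept,
                 provenance = list(method = "iterative", xi = cfg$xi,
                                   model = H$model_label)),
            class = "CGHessian")
}

#' Power-law fit of timings
#'
#' Least-squares fit of `log t = log a + b log n`, the standard check
#' that coarse-graining time grows near-linearly while dense
#' diagonalization grows near-cubically.
#'
#' @param sizes positive problem sizes.
#' @param times positive timings.
#' @return named vector `c(a, b)`.
#' @export
fit_power_law <- function(sizes, times) {
  stopifnot(length(sizes) == length(times), length(sizes) >= 3,
            all(sizes > 0), all(times > 0))
  fit <- stats::lm(log(times) ~ log(sizes))
  cf <- stats::coef(fit)
  c(a = unname(exp(cf[1])), b = unname(cf[2]))
}
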