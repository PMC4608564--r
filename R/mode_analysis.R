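# Normal-mode statistics: eigenmodes, mean-square fluctuations, B-factor
# agreement, eigenvalue-weighted mode overlap, cooperativity maps,
# best-match and transition overlaps, secondary-structure preservation.

hessian_matrix <- function(H) {
  if (inherits(H, c("SparseHessian", "CGHessian"))) as.matrix(H$M)
  else as.matrix(H)
}

#' Eigenmodes of a Hessian
#'
#' Full (or lowest-`n_modes`) symmetric eigendecomposition, eigenvalues
#' ascending.  Modes with eigenvalue below `rigid_tol` times the largest
#' are classed as rigid-body modes (6 for a connected 3-D structure).
#'
#' @param H a `SparseHessian`, `CGHessian` or symmetric matrix.
#' @param n_modes number of lowest modes to return (default all).
#' @param rigid_tol relative rigid-mode tolerance (default 1e-8).
#' @return list of class `ModeSet`: `values` (ascending), `vectors`
#'   (orthonormal columns), `n_rigid`, `n_sites`.
#' @export
eig_modes <- function(H, n_modes = NULL, rigid_tol = 1e-8) {
  M <- hessian_matrix(H)
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1e-300))
    stop("Hessian is not symmetric")
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  n_rigid <- sum(values < rigid_tol * max(abs(values)))
  if (!is.null(n_modes)) {
    n_modes <- min(n_modes, length(values))
    values <- values[seq_len(n_modes)]
    vectors <- vectors[, seq_len(n_modes), drop = FALSE]
  }
  structure(list(values = values, vectors = vectors,
                 n_rigid = as.integer(n_rigid),
                 n_sites = nrow(M) %/% 3L),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  cat(sprintf("ModeSet: %d sites, %d modes (%d rigid), lambda in [%.3g, %.3g]\n",
              x$n_sites, length(x$values), x$n_rigid,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Mean-square fluctuations
#'
#' `MSF_i = sum_{j > n_rigid} (1/lambda_j) |m_j(site i)|^2`, the trace of
#' site i's 3x3 block of the Hessian pseudo-inverse when all non-rigid
#' modes are supplied.
#'
#' @param modes a [eig_modes()] result.
#' @param n_rigid override the auto-detected rigid-mode count (pass 6 for
#'   a connected structure whose Hessian was hard-thresholded: the
#'   thresholding shifts the six rigid eigenvalues slightly off zero, and
#'   treating them as physical would swamp the fluctuations).
#' @return numeric vector of per-site MSF (class `MSFProfile`).
#' @export
msf <- function(modes, n_rigid = NULL) {
  nr <- if (is.null(n_rigid)) modes$n_rigid else as.integer(n_rigid)
  nm <- length(modes$values)
  if (nr >= nm) stop("no non-rigid modes available")
  idx <- (nr + 1L):nm
  V2 <- modes$vectors[, idx, drop = FALSE]^2
  w <- 1 / modes$values[idx]
  per_dof <- as.vector(V2 %*% w)
  out <- per_dof[c(TRUE, FALSE, FALSE)] + per_dof[c(FALSE, TRUE, FALSE)] +
    per_dof[c(FALSE, FALSE, TRUE)]
  class(out) <- "MSFProfile"
  out
}

#' Scale fluctuations onto experimental B-factors
#'
#' Least-RMSD scaling `s = (msf . b) / (msf . msf)` plus the
#' scale-invariant Pearson correlation.
#'
#' @param msf_profile per-site MSF.
#' @param bfactors experimental B-factors, same length (>= 3).
#' @return list `scale`, `pearson_r`, `scaled` (s * msf).
#' @export
fit_bfactor_scale <- function(msf_profile, bfactors) {
  m <- as.numeric(msf_profile); b <- as.numeric(bfactors)
  stopifnot(length(m) == length(b), length(m) >= 3)
  if (stats::sd(m) == 0 || stats::sd(b) == 0)
    stop("zero-variance input")
  s <- sum(m * b) / sum(m * m)
  list(scale = s, pearson_r = stats::cor(m, b), scaled = s * m)
}

#' Eigenvalue-weighted mode overlap
#'
#' `sum_{i=7}^{3n} (w_i / w) |m_i . m_hat_i|` with `w_i = 1/lambda_i`
#' taken from the reference set and `w = sum w_i`; same-index pairing so
#' that mode-order scrambling is penalized.  1.0 means the test model
#' reproduces every reference mode in order (up to sign).
#'
#' @param ref reference `ModeSet` (weights come from its eigenvalues).
#' @param test test `ModeSet`, same dimension.
#' @param first first mode index included (default 7, skipping the six
#'   rigid-body modes).
#' @return scalar in `[0, 1]`.
#' @export
weighted_mode_overlap <- function(ref, test, first = 7L) {
  nm <- length(ref$values)
  if (nm != length(test$values) || nrow(ref$vectors) != nrow(test$vectors))
    stop("mode sets have different dimensions")
  idx <- first:nm
  w <- 1 / ref$values[idx]
  dots <- abs(colSums(ref$vectors[, idx, drop = FALSE] *
                      test$vectors[, idx, drop = FALSE]))
  sum(w * dots) / sum(w)
}

#' Best-matching mode table
#'
#' For each of the first `n_list` non-rigid modes of `A`, the mode of `B`
#' with the largest absolute dot product.
#'
#' @param A,B `ModeSet`s of equal dimension.
#' @param n_list number of A-modes to report.
#' @return data.frame `mode_a`, `mode_b`, `overlap` (indices counted from
#'   the first non-rigid mode).
#' @export
best_match_overlaps <- function(A, B, n_list = 10L) {
  if (nrow(A$vectors) != nrow(B$vectors))
    stop("mode sets have different dimensions")
  ia <- A$n_rigid + seq_len(min(n_list, length(A$values) - A$n_rigid))
  ib <- (B$n_rigid + 1L):length(B$values)
  G <- abs(crossprod(B$vectors[, ib, drop = FALSE],
                     A$vectors[, ia, drop = FALSE]))   # |B . A|
  best <- apply(G, 2, which.max)
  data.frame(mode_a = seq_along(ia),
             mode_b = as.integer(best),
             overlap = G[cbind(best, seq_along(ia))])
}

#' Cooperativity (cross-correlation) map
#'
#' `C_ij = <r_i . r_j> / sqrt(<r_i . r_i><r_j . r_j>)` where `r_i` is
#' site i's displacement 3-vector in a mode and `< >` averages
#' (unweighted by default) over the first `k` non-rigid modes.
#'
#' @param modes a `ModeSet`.
#' @param k number of low-frequency modes to average (default 15).
#' @param weighted if TRUE, weight each mode by 1/lambda (the common ENM
#'   convention); default FALSE, plain average.
#' @return n x n matrix with unit diagonal, values in `[-1, 1]`.
#' @export
cooperativity <- function(modes, k = 15L, weighted = FALSE) {
  nr <- modes$n_rigid
  k <- min(k, length(modes$values) - nr)
  stopifnot(k >= 1)
  n <- modes$n_sites
  acc <- matrix(0, n, n)
  for (j in seq_len(k)) {
    v <- matrix(modes$vectors[, nr + j], nrow = 3)   # 3 x n
    wj <- if (weighted) 1 / modes$values[nr + j] else 1
    acc <- acc + wj * crossprod(v)                   # <r_i . r_j>
  }
  d <- diag(acc)
  if (any(d <= 0)) stop("site with zero displacement in all selected modes")
  C <- acc / sqrt(outer(d, d))
  diag(C) <- 1
  C
}

kabsch_fit <- function(X, Y) {
  # rotate+translate Y onto X (rows are sites); returns fitted Y
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  s <- svd(crossprod(Y0, X0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(Y0 %*% t(R), 2, cx, "+")
}

#' Overlap of a conformational transition with normal modes
#'
#' Superposes the end coordinates onto the start by least-squares
#' rigid-body fit, forms the displacement vector `d`, and reports the
#' per-mode overlaps `|m_i . d| / (|m_i||d|)` for the top `n_list`
#' non-rigid modes.
#'
#' @param start,end site coordinate matrices (n x 3) or
#'   `AtomicStructure`s with matching site sets.
#' @param modes `ModeSet` computed on the start structure's sites.
#' @param n_list number of top overlaps to report (default 3).
#' @return data.frame `mode` (non-rigid index), `overlap`, sorted
#'   descending; attribute `"displacement_rmsd"`.
#' @export
transition_overlap <- function(start, end, modes, n_list = 3L) {
  X <- if (inherits(start, "AtomicStructure")) coords(start) else as.matrix(start)
  Y <- if (inherits(end, "AtomicStructure")) coords(end) else as.matrix(end)
  if (!all(dim(X) == dim(Y))) stop("mismatched site sets")
  if (nrow(X) < 3) stop("need at least 3 shared sites")
  if (3 * nrow(X) != nrow(modes$vectors)) stop("modes do not match sites")
  Yf <- kabsch_fit(X, Y)
  d <- as.vector(t(Yf - X))              # (x1,y1,z1,x2,...) matches dof order
  dn <- sqrt(sum(d^2))
  if (dn < 1e-8) stop("zero displacement after superposition")
  nr <- modes$n_rigid
  idx <- (nr + 1L):length(modes$values)
  ov <- abs(crossprod(modes$vectors[, idx, drop = FALSE], d)) / dn
  ord <- order(-ov)
  out <- data.frame(mode = seq_along(idx)[ord[seq_len(min(n_list, length(ov)))]],
                    overlap = ov[ord[seq_len(min(n_list, length(ov)))]])
  attr(out, "displacement_rmsd") <- dn / sqrt(nrow(X))
  attr(out, "all_overlaps") <- as.vector(ov)
  out
}

#' Secondary-structure preservation along modes
#'
#' Each of the first `n_modes` non-rigid modes is scaled so the global
#' site RMSD from the start equals `rmsd_target`; every SSE segment of
#' the deformed structure is then independently superposed back onto its
#' undeformed self and its internal RMSD recorded.  Low per-mode averages
#' mean the mode bends the protein between, not inside, its helices and
#' strands.
#'
#' @param structure an `AtomicStructure` carrying SSE segments.
#' @param sites integer atom indices the modes live on (e.g. the CA
#'   selection used for coarse-graining).
#' @param modes `ModeSet` on those sites.
#' @param rmsd_target global RMSD amplitude in Angstrom (default 1).
#' @param n_modes number of non-rigid modes to scan (default 100).
#' @return list `per_mode` (data.frame mode, mean_sse_rmsd), `slope` and
#'   `intercept` of the least-squares line over mode index.
#' @export
sse_preservation <- function(structure, sites, modes, rmsd_target = 1.0,
                             n_modes = 100L) {
  if (!nrow(structure$sse)) stop("structure has no SSE segments")
  X <- coords(structure)[sites, , drop = FALSE]
  a <- structure$atoms[sites, ]
  nr <- modes$n_rigid
  n_modes <- min(n_modes, length(modes$values) - nr)
  segs <- lapply(seq_len(nrow(structure$sse)), function(s) {
    which(a$chain == structure$sse$chain[s] &
          a$res_index >= structure$sse$first[s] &
          a$res_index <= structure$sse$last[s])
  })
  segs <- segs[lengths(segs) >= 3L]
  if (!length(segs)) stop("no SSE segment covers >= 3 sites")
  n <- nrow(X)
  res <- numeric(n_modes)
  for (j in seq_len(n_modes)) {
    v <- matrix(modes$vectors[, nr + j], ncol = 3, byrow = TRUE)
    s <- rmsd_target * sqrt(n) / sqrt(sum(v^2))   # unit vector: sqrt(n)
    Y <- X + s * v
    rr <- vapply(segs, function(ix) {
      Yf <- kabsch_fit(X[ix, , drop = FALSE], Y[ix, , drop = FALSE])
      sqrt(mean(rowSums((Yf - X[ix, , drop = FALSE])^2)))
    }, 0)
    res[j] <- mean(rr)
  }
  fit <- stats::lm(res ~ seq_len(n_modes))
  list(per_mode = data.frame(mode = seq_len(n_modes), mean_sse_rmsd = res),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}
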