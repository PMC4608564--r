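# MatrixMarket export/import of (coarse-grained) Hessians with a JSON
# sidecar carrying site identities and provenance.

#' Write a Hessian to MatrixMarket + JSON sidecar
#'
#' @param H a `SparseHessian` or `CGHessian`.
#' @param path output `.mtx` path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return invisibly, the mtx path.
#' @export
write_hessian <- function(H, path) {
  Matrix::writeMM(methods::as(H$M, "generalMatrix"), path)
  meta <- if (inherits(H, "CGHessian"))
    list(kind = "CGHessian", sites = H$sites, provenance = H$provenance)
  else
    list(kind = "SparseHessian", atom_order = H$atom_order,
         model_label = H$model_label, n_atoms = H$n_atoms)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a Hessian written by [write_hessian()]
#'
#' @param path `.mtx` path with a `<path>.json` sidecar.
#' @return a `SparseHessian` or `CGHessian`, per the sidecar.
#' @export
read_hessian <- function(path) {
  M <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  M <- (M + Matrix::t(M)) / 2
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(meta$kind, "CGHessian")) {
    structure(list(M = M, sites = as.integer(meta$sites),
                   provenance = as.list(meta$provenance)),
              class = "CGHessian")
  } else {
    structure(list(M = M, atom_order = as.integer(meta$atom_order),
                   model_label = meta$model_label,
                   n_atoms = as.integer(meta$n_atoms)),
              class = "SparseHessian")
  }
}

#' Export a mode set in NMD format
#'
#' Minimal NMD (normal-mode data) writer for external visualizers: one
#' `coordinates` line and one `mode` line per requested mode.
#'
#' @param modes a `ModeSet`.
#' @param xyz n x 3 site coordinates.
#' @param path output path.
#' @param n_modes number of non-rigid modes to export (default 10).
#' @return invisibly, the path.
#' @export
write_nmd <- function(modes, xyz, path, n_modes = 10L) {
  nr <- modes$n_rigid
  n_modes <- min(n_modes, length(modes$values) - nr)
  lines <- c("nmwiz_load generated.nmd",
             paste("coordinates", paste(sprintf("%.3f", t(xyz)), collapse = " ")))
  for (j in seq_len(n_modes)) {
    lines <- c(lines, paste("mode", j,
                            sprintf("%.6g", 1 / sqrt(modes$values[nr + j])),
                            paste(sprintf("%.5f", modes$vectors[, nr + j]),
                                  collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}
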