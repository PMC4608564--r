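# Atomic structures, PDB I/O, covalent topology and site selection.

COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                    P = 1.07, SE = 1.20)
DEFAULT_COVALENT_RADIUS <- 0.77

#' Construct an atomic structure
#'
#' An `AtomicStructure` is the container every other module consumes: an
#' ordered atom table (one row per atom, coordinates in Angstrom) plus
#' optional secondary-structure segments.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `res_index`, `res_name`, `chain`, `x`, `y`, `z` and optionally
#'   `bfactor`, `occupancy`.
#' @param sse optional data.frame of secondary-structure segments with
#'   columns `kind` ("helix" or "strand"), `chain`, `first`, `last`
#'   (residue indices, inclusive).
#' @return object of class `AtomicStructure`.
#' @export
atomic_structure <- function(atoms, sse = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  needed <- c("serial", "name", "element", "res_index", "res_name",
              "chain", "x", "y", "z")
  miss <- setdiff(needed, names(atoms))
  if (length(miss))
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial))
    stop("atom serials must be unique")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols")
  if (any(!nzchar(as.character(atoms$chain))))
    stop("empty chain identifiers")
  if (is.null(atoms$bfactor)) atoms$bfactor <- NA_real_
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1.0
  rownames(atoms) <- NULL
  if (!is.null(sse) && nrow(sse)) {
    stopifnot(all(c("kind", "chain", "first", "last") %in% names(sse)))
    stopifnot(all(sse$kind %in% c("helix", "strand")))
  } else {
    sse <- data.frame(kind = character(), chain = character(),
                      first = integer(), last = integer(),
                      stringsAsFactors = FALSE)
  }
  structure(list(atoms = atoms, sse = sse), class = "AtomicStructure")
}

#' @export
print.AtomicStructure <- function(x, ...) {
  cat(sprintf("AtomicStructure: %d atoms, %d chain(s), %d residues, %d SSE segment(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)),
              nrow(unique(x$atoms[, c("chain", "res_index")])),
              nrow(x$sse)))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `AtomicStructure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Coordinate matrix of a structure
#' @param structure an `AtomicStructure`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(structure)
  cbind(x = structure$atoms$x, y = structure$atoms$y, z = structure$atoms$z)

`coords<-` <- function(structure, value) {
  stopifnot(nrow(value) == n_atoms(structure), ncol(value) == 3L)
  structure$atoms$x <- value[, 1]
  structure$atoms$y <- value[, 2]
  structure$atoms$z <- value[, 3]
  structure
}

guess_element <- function(name) {
  # PDB atom-name heuristics: strip digits/primes, two-letter elements only
  # when the name occupies column 13 (handled upstream via the raw field).
  nm <- gsub("[0-9']", "", trimws(name))
  if (!nzchar(nm)) return("C")
  two <- toupper(substr(nm, 1, 2))
  if (two %in% c("SE", "FE", "ZN", "MG", "MN", "CL", "NA", "CA") && nchar(nm) > 1 &&
      !grepl("^C[ABGDEZH]", toupper(nm)) && !grepl("^N[ABGDEZH]", toupper(nm)))
    return(two)
  toupper(substr(nm, 1, 1))
}

WATER_RES <- c("HOH", "WAT", "DOD", "TIP")

#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records plus HELIX/SHEET secondary
#' structure. One altloc per atom is retained (highest occupancy, ties to
#' 'A'/blank). Waters and non-polymer HETATM records are dropped unless
#' `keep_hetatm` is set.
#'
#' @param path PDB file path.
#' @param model model number to read (for multi-MODEL files); default 1.
#' @param keep_hydrogens keep hydrogen atoms (default FALSE).
#' @param keep_hetatm keep non-water HETATM records (default FALSE).
#' @return an [atomic_structure()].
#' @export
read_pdb <- function(path, model = 1L, keep_hydrogens = FALSE,
                     keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)

  # model selection: take lines between the model-th MODEL and its ENDMDL;
  # files without MODEL records are a single model.
  mstart <- which(trimws(rec) == "MODEL")
  if (length(mstart)) {
    if (model > length(mstart)) stop("model ", model, " not present")
    mend <- which(trimws(rec) == "ENDMDL")
    lo <- mstart[model]
    hi <- if (length(mend) >= model) mend[model] else length(lines)
    in_model <- seq_along(lines) >= lo & seq_along(lines) <= hi
  } else in_model <- rep(TRUE, length(lines))

  is_atom <- (rec == "ATOM  " | rec == "HETATM") & in_model
  al <- lines[is_atom]
  if (!length(al)) stop("no ATOM records in ", path)
  f <- function(a, b) substr(al, a, b)

  atoms <- data.frame(
    record    = trimws(f(1, 6)),
    serial    = as.integer(f(7, 11)),
    name      = trimws(f(13, 16)),
    altloc    = f(17, 17),
    res_name  = trimws(f(18, 20)),
    chain     = f(22, 22),
    res_seq   = as.integer(f(23, 26)),
    icode     = f(27, 27),
    x         = suppressWarnings(as.numeric(f(31, 38))),
    y         = suppressWarnings(as.numeric(f(39, 46))),
    z         = suppressWarnings(as.numeric(f(47, 54))),
    occupancy = suppressWarnings(as.numeric(f(55, 60))),
    bfactor   = suppressWarnings(as.numeric(f(61, 66))),
    element   = trimws(f(77, 78)),
    stringsAsFactors = FALSE)

  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("malformed coordinate fields in ", path)
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1.0
  noel <- !nzchar(atoms$element)
  if (any(noel))
    atoms$element[noel] <- vapply(atoms$name[noel], guess_element, "")
  atoms$element <- toupper(atoms$element)
  atoms$chain[atoms$chain == " "] <- "A"

  keep <- rep(TRUE, nrow(atoms))
  is_het <- atoms$record == "HETATM"
  keep[is_het & atoms$res_name %in% WATER_RES] <- FALSE
  if (!keep_hetatm) keep[is_het] <- FALSE
  if (!keep_hydrogens) keep <- keep & atoms$element != "H" & atoms$element != "D"
  atoms <- atoms[keep, , drop = FALSE]
  if (!nrow(atoms)) stop("zero atoms after filtering in ", path)

  # altloc: keep highest occupancy, tie broken toward ' ' then 'A'.
  key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$name)
  if (anyDuplicated(key)) {
    pref <- order(key, -atoms$occupancy, match(atoms$altloc, c(" ", LETTERS)))
    atoms <- atoms[pref, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$res_seq,
                                     atoms$icode, atoms$name)), , drop = FALSE]
    atoms <- atoms[order(match(atoms$serial, sort(atoms$serial))), , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
  }

  # residue index: PDB numbering with insertion-code ordering preserved by
  # file order; res_index is the PDB res_seq (unique per chain+icode in
  # practice for our inputs).
  atoms$res_index <- atoms$res_seq

  sse <- NULL
  hx <- lines[rec == "HELIX "]
  sh <- lines[rec == "SHEET "]
  seg <- list()
  if (length(hx))
    seg[[1]] <- data.frame(kind = "helix",
                           chain = substr(hx, 20, 20),
                           first = as.integer(substr(hx, 22, 25)),
                           last = as.integer(substr(hx, 34, 37)),
                           stringsAsFactors = FALSE)
  if (length(sh))
    seg[[2]] <- data.frame(kind = "strand",
                           chain = substr(sh, 22, 22),
                           first = as.integer(substr(sh, 23, 26)),
                           last = as.integer(substr(sh, 34, 37)),
                           stringsAsFactors = FALSE)
  if (length(seg)) sse <- do.call(rbind, seg)

  atoms$record <- NULL; atoms$altloc <- NULL; atoms$res_seq <- NULL
  atoms$icode <- NULL
  atomic_structure(atoms, sse)
}

#' Write a structure to a PDB file
#'
#' Fixed-column ATOM records (coordinates at 3 decimals), TER records
#' between chains, and HELIX/SHEET records for any stored SSE segments.
#'
#' @param structure an `AtomicStructure`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  out <- character(0)
  s <- structure$sse
  if (nrow(s)) {
    for (i in seq_len(nrow(s))) {
      if (s$kind[i] == "helix")
        out <- c(out, sprintf("HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d  1%30s",
                              i, sprintf("%3d", i), "ALA", s$chain[i], s$first[i],
                              "ALA", s$chain[i], s$last[i], ""))
      else
        out <- c(out, sprintf("SHEET  %3d %3s 1 %3s %1s%4d  %3s %1s%4d  0",
                              i, sprintf("%3s", "S"), "ALA", s$chain[i], s$first[i],
                              "ALA", s$chain[i], s$last[i]))
    }
  }
  fmt_name <- function(nm, el) {
    # element right-justified in cols 13-14 for 1-letter elements
    if (nchar(el) == 1 && nchar(nm) <= 3) sprintf(" %-3s", nm) else sprintf("%-4s", nm)
  }
  occ <- ifelse(is.finite(a$occupancy), a$occupancy, 1.0)
  bf <- ifelse(is.finite(a$bfactor), a$bfactor, 0.0)
  ser <- a$serial %% 100000L
  recs <- sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  ser,
                  vapply(seq_len(nrow(a)), function(i) fmt_name(a$name[i], a$element[i]), ""),
                  substr(a$res_name, 1, 3), substr(a$chain, 1, 1),
                  a$res_index %% 10000L, a$x, a$y, a$z, occ, bf,
                  substr(a$element, 1, 2))
  # TER between chains
  ch <- a$chain
  brk <- which(ch[-1] != ch[-length(ch)])
  pieces <- character(0)
  last <- 0L
  for (b in c(brk, length(ch))) {
    pieces <- c(pieces, recs[(last + 1L):b], "TER")
    last <- b
  }
  writeLines(c(out, pieces, "END"), path)
  invisible(path)
}

cell_pairs <- function(xyz, cutoff) {
  # all unordered atom pairs with distance <= cutoff, via cell binning
  n <- nrow(xyz)
  if (n < 2L) return(cbind(i = integer(), j = integer(), d = numeric()))
  lo <- apply(xyz, 2, min)
  cs <- max(cutoff, 1e-6)
  ci <- floor(sweep(xyz, 2, lo) / cs)
  nx <- max(ci[, 1]) + 1L; ny <- max(ci[, 2]) + 1L; nz <- max(ci[, 3]) + 1L
  code <- ci[, 1] + nx * (ci[, 2] + ny * ci[, 3])
  ord <- order(code)
  codes <- code[ord]
  # map cell code -> atom indices
  cell_of <- split(ord, codes)
  ucodes <- as.numeric(names(cell_of))
  # neighbor offsets
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- vector("list", length(cell_of)); out_j <- out_i; out_d <- out_i
  keyset <- new.env(hash = TRUE)
  for (k in seq_along(ucodes)) assign(as.character(ucodes[k]), k, envir = keyset)
  for (k in seq_along(cell_of)) {
    a_idx <- cell_of[[k]]
    cz <- ucodes[k] %/% (nx * ny)
    cy <- (ucodes[k] - cz * nx * ny) %/% nx
    cx <- ucodes[k] - cz * nx * ny - cy * nx
    nb <- integer(0)
    for (o in seq_len(nrow(offs))) {
      if (offs[o, 1] == 0 && offs[o, 2] == 0 && offs[o, 3] == 0) next
      ex <- cx + offs[o, 1]; ey <- cy + offs[o, 2]; ez <- cz + offs[o, 3]
      # bounds check prevents index aliasing on small grids
      if (ex < 0 || ex >= nx || ey < 0 || ey >= ny || ez < 0 || ez >= nz) next
      nc <- ex + nx * (ey + ny * ez)
      kk <- mget(as.character(nc), envir = keyset, ifnotfound = list(NULL))[[1]]
      # only count each cell pair once
      if (!is.null(kk) && nc > ucodes[k]) nb <- c(nb, cell_of[[kk]])
    }
    cand_j <- c(a_idx, nb)
    # pairs within own cell
    if (length(a_idx) > 1L) {
      cp <- utils::combn(a_idx, 2L)
      ii <- cp[1, ]; jj <- cp[2, ]
    } else { ii <- integer(0); jj <- integer(0) }
    if (length(nb)) {
      ii <- c(ii, rep(a_idx, each = length(nb)))
      jj <- c(jj, rep(nb, times = length(a_idx)))
    }
    if (!length(ii)) next
    dd <- sqrt((xyz[ii, 1] - xyz[jj, 1])^2 + (xyz[ii, 2] - xyz[jj, 2])^2 +
               (xyz[ii, 3] - xyz[jj, 3])^2)
    sel <- dd <= cutoff
    out_i[[k]] <- ii[sel]; out_j[[k]] <- jj[sel]; out_d[[k]] <- dd[sel]
  }
  i <- unlist(out_i); j <- unlist(out_j); d <- unlist(out_d)
  if (is.null(i)) return(cbind(i = integer(), j = integer(), d = numeric()))
  sw <- i > j
  tmp <- i[sw]; i[sw] <- j[sw]; j[sw] <- tmp
  cbind(i = i, j = j, d = d)
}

#' Infer covalent and nonbonded topology
#'
#' Bonds are detected by distance against the sum of covalent radii times
#' `(1 + bond_tolerance)`. Angles (1-3) and torsions (1-4) are enumerated
#' from the bond graph; nonbonded pairs are all pairs within
#' `nonbonded_cutoff` that are not 1-2 or 1-3 connected (1-4 pairs remain
#' in the nonbonded set).
#'
#' @param structure an `AtomicStructure`.
#' @param bond_tolerance fractional slack on covalent radii sums (default 0.15).
#' @param nonbonded_cutoff nonbonded distance cutoff in Angstrom (default 8).
#' @return a list of class `Topology`: `bonds` (2-col matrix), `angles`
#'   (3-col), `torsions` (4-col), `pairs13`, `pairs14`, `nonbonded` (2-col
#'   matrices with a distance column).
#' @export
infer_topology <- function(structure, bond_tolerance = 0.15,
                           nonbonded_cutoff = 8.0) {
  stopifnot(bond_tolerance > 0, nonbonded_cutoff > 0)
  xyz <- coords(structure)
  el <- structure$atoms$element
  rad <- COVALENT_RADII[el]
  rad[is.na(rad)] <- DEFAULT_COVALENT_RADIUS
  maxbond <- (2 * max(rad)) * (1 + bond_tolerance)

  cand <- cell_pairs(xyz, max(maxbond, 0.1))
  if (nrow(cand)) {
    lim <- (rad[cand[, "i"]] + rad[cand[, "j"]]) * (1 + bond_tolerance)
    bonds <- cand[cand[, "d"] <= lim & cand[, "d"] > 1e-6, c("i", "j"), drop = FALSE]
  } else bonds <- cbind(i = integer(), j = integer())

  n <- nrow(xyz)
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }

  # angles: center j, neighbors i<k
  ang <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2L) {
      cp <- utils::combn(sort(nb), 2L)
      ang[[length(ang) + 1L]] <- cbind(cp[1, ], j, cp[2, ])
    }
  }
  angles <- if (length(ang)) do.call(rbind, ang) else
    cbind(integer(), integer(), integer())

  # torsions: bond (j,k), i in N(j)\{k}, l in N(k)\{j}, i != l
  tor <- list()
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      j <- bonds[r, 1]; k <- bonds[r, 2]
      is_ <- setdiff(adj[[j]], k); ls_ <- setdiff(adj[[k]], j)
      if (length(is_) && length(ls_)) {
        g <- expand.grid(i = is_, l = ls_)
        g <- g[g$i != g$l, , drop = FALSE]
        if (nrow(g)) tor[[length(tor) + 1L]] <- cbind(g$i, j, k, g$l)
      }
    }
  }
  torsions <- if (length(tor)) do.call(rbind, tor) else
    cbind(integer(), integer(), integer(), integer())

  pkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bkey <- if (nrow(bonds)) pkey(bonds[, 1], bonds[, 2]) else character(0)
  k13 <- if (nrow(angles)) unique(pkey(angles[, 1], angles[, 3])) else character(0)
  k13 <- setdiff(k13, bkey)
  k14 <- if (nrow(torsions)) unique(pkey(torsions[, 1], torsions[, 4])) else character(0)
  k14 <- setdiff(k14, c(bkey, k13))

  nb_cand <- cell_pairs(xyz, nonbonded_cutoff)
  if (nrow(nb_cand)) {
    nk <- pkey(nb_cand[, "i"], nb_cand[, "j"])
    keep <- !(nk %in% c(bkey, k13)) & nb_cand[, "d"] > 1e-6
    nonbonded <- nb_cand[keep, , drop = FALSE]
  } else nonbonded <- cbind(i = integer(), j = integer(), d = numeric())

  unpack <- function(keys) {
    if (!length(keys)) return(cbind(i = integer(), j = integer()))
    sp <- do.call(rbind, strsplit(keys, " "))
    cbind(i = as.integer(sp[, 1]), j = as.integer(sp[, 2]))
  }
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 pairs13 = unpack(k13), pairs14 = unpack(k14),
                 nonbonded = nonbonded,
                 bond_tolerance = bond_tolerance,
                 nonbonded_cutoff = nonbonded_cutoff),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d bonds, %d angles, %d torsions, %d nonbonded pairs\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions), nrow(x$nonbonded)))
  invisible(x)
}

#' Select coarse-grained sites
#'
#' @param structure an `AtomicStructure`.
#' @param scheme `"calpha"` (one CA per residue), `"backbone"`
#'   (N, CA, C, O) or `"custom"` with explicit `indices`.
#' @param indices custom 1-based atom indices (scheme = "custom").
#' @return list of class `SiteSelection` with ordered `kept` indices and
#'   the `scheme` label.
#' @export
select_sites <- function(structure, scheme = c("calpha", "backbone", "custom"),
                         indices = NULL) {
  scheme <- match.arg(scheme)
  a <- structure$atoms
  ord <- order(a$chain, a$res_index)
  if (scheme == "calpha") {
    sel <- which(a$name == "CA" & a$element == "C")
    sel <- sel[order(a$chain[sel], a$res_index[sel])]
    # one per residue: first CA wins
    key <- paste(a$chain[sel], a$res_index[sel])
    sel <- sel[!duplicated(key)]
  } else if (scheme == "backbone") {
    sel <- which(a$name %in% c("N", "CA", "C", "O"))
    sel <- sel[order(a$chain[sel], a$res_index[sel], sel)]
  } else {
    if (is.null(indices)) stop("custom scheme requires indices")
    if (anyDuplicated(indices)) stop("duplicate site indices")
    if (any(indices < 1L | indices > nrow(a))) stop("site index out of range")
    sel <- as.integer(indices)
    sel <- sel[order(a$chain[sel], a$res_index[sel], sel)]
  }
  if (!length(sel)) stop("site scheme '", scheme, "' selects no atoms")
  structure(list(kept = as.integer(sel), scheme = scheme),
            class = "SiteSelection")
}

#' @export
print.SiteSelection <- function(x, ...) {
  cat(sprintf("SiteSelection(%s): %d sites\n", x$scheme, length(x$kept)))
  invisible(x)
}
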