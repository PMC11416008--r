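## Structure I/O and per-residue local frames.
##
## Parsing of PDB/mmCIF goes through bio3d; this layer normalizes atom tables,
## resolves alternate locations, splits polymer from hetero groups, and applies
## the solvent/ion exclusion list so that the remaining hetero groups can be
## treated as ligands.

#' Residue names excluded from ligand extraction
#'
#' Waters are always excluded; the default exclusion list additionally removes
#' common crystallization additives, buffers and monoatomic ions.
#'
#' @export
defaultHetExclusions <- function() {
  c(## waters
    "HOH", "DOD", "WAT", "H2O", "OH2",
    ## monoatomic ions
    "NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "FE2", "CU", "CO", "NI",
    "CD", "HG", "BR", "IOD", "I", "F", "CS", "LI", "SR", "BA", "NH4", "RB",
    ## buffers / cryoprotectants / additives
    "SO4", "PO4", "PO3", "NO3", "GOL", "EDO", "ACT", "DMS", "PEG", "PG4",
    "PGE", "MPD", "TRS", "FMT", "BME", "MES", "EPE", "IMD", "CIT", "TLA",
    "SCN", "AZI", "DTT", "BOG", "LDA")
}

.HYDROGEN <- c("H", "D", "T")

.normalizeElement <- function(elesy, elety) {
  ele <- toupper(trimws(as.character(elesy)))
  bad <- is.na(ele) | ele == ""
  if (any(bad)) {
    guess <- suppressWarnings(bio3d::atom2ele(as.character(elety[bad])))
    ele[bad] <- toupper(guess)
  }
  ele
}

## Keep the highest-occupancy alternate conformer per atom; ties and missing
## occupancies resolve to first-in-file order.
.resolveAltLoc <- function(df) {
  alt <- as.character(df$alt)
  alt[is.na(alt)] <- ""
  if (all(alt %in% c("", " ", "A"))) {
    return(df[alt %in% c("", " ", "A"), , drop = FALSE])
  }
  occ <- suppressWarnings(as.numeric(df$o))
  occ[is.na(occ)] <- 1
  key <- paste(df$chain, df$resno, df$insert, df$resid, df$elety, sep = "\r")
  ord <- seq_len(nrow(df))
  keep <- unlist(lapply(split(ord, factor(key, levels = unique(key))),
                        function(idx) idx[which.max(occ[idx])]),
                 use.names = FALSE)
  df[sort(keep), , drop = FALSE]
}

.atomTable <- function(df) {
  ins <- as.character(df$insert)
  ins[is.na(ins)] <- ""
  ele <- .normalizeElement(df$elesy, df$elety)
  data.frame(chain = as.character(df$chain),
             resno = as.integer(df$resno),
             insert = ins,
             resid = as.character(df$resid),
             elety = trimws(as.character(df$elety)),
             elesy = ele,
             x = as.numeric(df$x), y = as.numeric(df$y), z = as.numeric(df$z),
             isHeavy = !(ele %in% .HYDROGEN),
             stringsAsFactors = FALSE)
}

.buildProteinStructure <- function(id, atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  ukey <- unique(key)
  ridx <- match(key, ukey)
  first <- match(ukey, key)
  residues <- data.frame(chain = atoms$chain[first],
                         resno = atoms$resno[first],
                         insert = atoms$insert[first],
                         resid = atoms$resid[first],
                         stringsAsFactors = FALSE)
  atoms$residueIndex <- ridx
  new("ProteinStructure", id = id, atoms = atoms, residues = residues)
}

#' Read a macromolecular structure and extract ligands
#'
#' Parses a PDB or mmCIF file, resolves alternate locations (highest
#' occupancy, ties first-in-file), fills polymer residues into a
#' \linkS4class{ProteinStructure} and turns remaining hetero groups into
#' \linkS4class{Ligand} objects. Waters and entries on \code{exclude} are
#' dropped; hetero groups whose heavy-atom count is zero are dropped. Polymer
#' hydrogens are retained but flagged non-heavy.
#'
#' @param path file path.
#' @param dialect "auto" (by extension), "pdb" or "mmcif".
#' @param exclude hetero residue names never treated as ligands.
#' @param id complex identifier; defaults to the file base name.
#' @return a \linkS4class{ProteinComplex}.
#' @export
readStructure <- function(path, dialect = c("auto", "pdb", "mmcif"),
                          exclude = defaultHetExclusions(), id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (dialect == "mmcif") bio3d::read.cif(path, verbose = FALSE,
                                            rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                         rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", dialect, ": ",
                             conditionMessage(e), call. = FALSE))
  df <- .resolveAltLoc(pdb$atom)
  if (is.null(id)) id <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "",
                             basename(path), ignore.case = TRUE)

  poly <- df[df$type == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0)
    stop("empty structure: no polymer (ATOM) records in ", path)
  protein <- .buildProteinStructure(id, .atomTable(poly))

  het <- df[df$type == "HETATM", , drop = FALSE]
  ligands <- list()
  if (nrow(het) > 0) {
    at <- .atomTable(het)
    drop <- at$resid %in% c("HOH", "DOD", "WAT", "H2O", "OH2") |
      at$resid %in% exclude
    at <- at[!drop, , drop = FALSE]
    if (nrow(at) > 0) {
      key <- paste(at$resid, at$chain, at$resno, at$insert, sep = "\r")
      for (k in unique(key)) {
        grp <- at[key == k & at$isHeavy, , drop = FALSE]
        if (nrow(grp) == 0) next
        lid <- paste(grp$resid[1], grp$chain[1], grp$resno[1], sep = "_")
        ligands[[length(ligands) + 1L]] <- new("Ligand", id = lid, atoms = grp)
      }
    }
  }
  new("ProteinComplex", id = id, protein = protein, ligands = ligands)
}

#' @rdname accessors
#' @param x a package object.
#' @export
nResidues <- function(x) {
  if (is(x, "ProteinComplex")) x <- x@protein
  nrow(x@residues)
}

#' Accessors
#'
#' Small accessors for the S4 containers: residue/atom tables, coordinates,
#' ligand list and frame components.
#'
#' @name accessors
#' @export
residueTable <- function(x) {
  if (is(x, "ProteinComplex")) x <- x@protein
  x@residues
}

#' @rdname accessors
#' @param heavyOnly drop hydrogens.
#' @export
atomCoords <- function(x, heavyOnly = FALSE) {
  at <- if (is(x, "ProteinComplex")) x@protein@atoms else x@atoms
  if (heavyOnly) at <- at[at$isHeavy, , drop = FALSE]
  unname(as.matrix(at[, c("x", "y", "z")]))
}

#' @rdname accessors
#' @export
ligands <- function(x) x@ligands

#' @rdname accessors
#' @export
proteinStructure <- function(x) x@protein

#' @rdname accessors
#' @export
frameRotation <- function(x) x@rotation

#' @rdname accessors
#' @export
frameTranslation <- function(x) x@translation

#' Backbone coordinates of one residue
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param index residue index (1-based positional).
#' @return list with N, CA, C rows (or NULL entries when absent).
#' @export
backboneCoords <- function(structure, index) {
  at <- structure@atoms
  at <- at[at$residueIndex == index, , drop = FALSE]
  pick <- function(name) {
    i <- which(at$elety == name)
    if (length(i) == 0) NULL else as.numeric(at[i[1], c("x", "y", "z")])
  }
  list(N = pick("N"), CA = pick("CA"), C = pick("C"))
}

#' Build the local frame of a residue
#'
#' Gram-Schmidt on the backbone: e1 = normalize(C - CA); e2 = the component of
#' (N - CA) orthogonal to e1, normalized; e3 = e1 x e2. The rotation columns
#' are (e1, e2, e3) and the translation is the CA position, so the transform
#' maps residue-local coordinates to global ones.
#'
#' @param structure a \linkS4class{ProteinStructure} (or a list with N/CA/C
#'   numeric coordinates).
#' @param index residue index when a structure is given.
#' @param tol collinearity tolerance on the orthogonalized component norm.
#' @return a \linkS4class{LocalFrame}.
#' @export
buildFrame <- function(structure, index = NULL, tol = 1e-6) {
  bb <- if (is(structure, "ProteinStructure")) {
    backboneCoords(structure, index)
  } else structure
  if (is.null(bb$N) || is.null(bb$CA) || is.null(bb$C))
    stop("frame unbuildable: backbone N/CA/C incomplete")
  u <- bb$C - bb$CA
  nu <- sqrt(sum(u^2))
  if (nu < tol) stop("frame unbuildable: C coincides with CA")
  e1 <- u / nu
  v <- bb$N - bb$CA
  v <- v - sum(v * e1) * e1
  nv <- sqrt(sum(v^2))
  if (nv < tol) stop("frame unbuildable: backbone atoms collinear")
  e2 <- v / nv
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  new("LocalFrame", rotation = cbind(e1, e2, e3, deparse.level = 0),
      translation = as.numeric(bb$CA))
}

#' Build frames for all residues
#'
#' Residues with incomplete or collinear backbones yield NULL entries and a
#' single summarizing warning; downstream context selection skips them.
#'
#' @inheritParams buildFrame
#' @return list of \linkS4class{LocalFrame} or NULL, one per residue.
#' @export
buildFrames <- function(structure, tol = 1e-6) {
  n <- nResidues(structure)
  frames <- vector("list", n)
  failed <- 0L
  for (i in seq_len(n)) {
    frames[[i]] <- tryCatch(buildFrame(structure, i, tol = tol),
                            error = function(e) NULL)
    if (is.null(frames[[i]])) failed <- failed + 1L
  }
  if (failed > 0)
    warning(failed, " residue(s) without buildable frames were excluded")
  frames
}

## Minimum cross distance between two coordinate matrices (rows = points).
.minCrossDist <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(Inf)
  ## |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, computed blockwise via BLAS
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

#' Chains associated to a ligand
#'
#' A chain is associated to a ligand when some heavy-atom pair (one chain
#' atom, one ligand atom) is closer than \code{cutoff}.
#'
#' @param ligand a \linkS4class{Ligand}.
#' @param structure a \linkS4class{ProteinStructure}.
#' @param cutoff association distance in Angstrom.
#' @return character vector of chain ids (possibly empty).
#' @export
associatedChains <- function(ligand, structure, cutoff = 4.0) {
  lat <- atomCoords(ligand, heavyOnly = TRUE)
  at <- structure@atoms[structure@atoms$isHeavy, , drop = FALSE]
  chains <- unique(structure@residues$chain)
  hits <- vapply(chains, function(ch) {
    A <- as.matrix(at[at$chain == ch, c("x", "y", "z"), drop = FALSE])
    .minCrossDist(unname(A), lat) < cutoff
  }, logical(1))
  chains[hits]
}

#' Apply a rigid transform to a complex, structure, ligand or frame
#'
#' @param x object to transform.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 shift.
#' @return transformed object of the same class.
#' @export
rigidTransform <- function(x, rotation, translation = c(0, 0, 0)) {
  move <- function(at) {
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(rotation)
    at$x <- xyz[, 1] + translation[1]
    at$y <- xyz[, 2] + translation[2]
    at$z <- xyz[, 3] + translation[3]
    at
  }
  if (is(x, "ProteinComplex")) {
    x@protein@atoms <- move(x@protein@atoms)
    x@ligands <- lapply(x@ligands, function(l) { l@atoms <- move(l@atoms); l })
    x
  } else if (is(x, "ProteinStructure")) {
    x@atoms <- move(x@atoms)
    x
  } else if (is(x, "Ligand")) {
    x@atoms <- move(x@atoms)
    x
  } else if (is(x, "LocalFrame")) {
    new("LocalFrame", rotation = rotation %*% x@rotation,
        translation = as.numeric(rotation %*% x@translation) + translation)
  } else stop("cannot transform object of class ", class(x))
}

#' Export frames as a flat table
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param frames list from \code{\link{buildFrames}}.
#' @return data.frame with chain, resno, insert, the 3x3 rotation row-major
#'   (r11..r33) and the translation (tx, ty, tz); unbuildable residues omitted.
#' @export
framesTable <- function(structure, frames) {
  keep <- which(!vapply(frames, is.null, logical(1)))
  res <- structure@residues[keep, , drop = FALSE]
  mat <- t(vapply(frames[keep], function(f)
    c(as.vector(t(f@rotation)), f@translation), numeric(12)))
  colnames(mat) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                     "r31", "r32", "r33", "tx", "ty", "tz")
  cbind(res[, c("chain", "resno", "insert")], as.data.frame(mat),
        row.names = NULL)
}

#' Write a complex to a PDB file
#'
#' Polymer atoms are emitted as ATOM records and ligand atoms as HETATM
#' blocks, preserving chain/sequence identifiers.
#'
#' @param complex a \linkS4class{ProteinComplex}.
#' @param path output file.
#' @export
writeComplexPdb <- function(complex, path) {
  p <- complex@protein@atoms
  rows <- list(data.frame(type = "ATOM", p, stringsAsFactors = FALSE))
  for (l in complex@ligands) {
    la <- l@atoms
    la$residueIndex <- NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(type = "HETATM", la,
                                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = at$type,
                   resno = at$resno, resid = at$resid,
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = at$chain, insert = ifelse(at$insert == "", NA,
                                                    at$insert),
                   elesy = at$elesy, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  invisible(path)
}
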