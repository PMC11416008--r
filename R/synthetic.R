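## Synthetic fixtures: idealized poly-alanine helices with planted ligands,
## decoy candidate centers and synthetic alignments, so the whole pipeline
## (I/O included) is exercisable without any database download. Geometry is
## idealized, not physical: the helix uses the canonical 2.3 A radius,
## 100 degrees per residue and 1.5 A rise (consecutive CA-CA about 3.8 A),
## and ligands are small random heavy-atom clouds placed against the helix
## surface so the 4 A contact rule holds by construction.

.unit <- function(v) v / sqrt(sum(v^2))

.AA3 <- c("ALA", "GLY", "SER", "THR", "VAL", "LEU", "ILE", "PHE", "TYR",
          "ASP", "GLU", "LYS", "ARG", "ASN", "GLN", "MET", "TRP", "HIS",
          "PRO", "CYS")

#' Generate an idealized toy protein
#'
#' Poly-alanine helix with full N/CA/C/O/CB backbones so every residue has a
#' buildable local frame.
#'
#' @param nResidues number of residues (>= 3).
#' @param noise Gaussian coordinate noise (sd, Angstrom).
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @param id structure identifier.
#' @return a \linkS4class{ProteinStructure}.
#' @export
makeToyProtein <- function(nResidues = 40L, noise = 0.05, seed = 1L,
                           chain = "A", id = "toy") {
  if (nResidues < 3) stop("need at least 3 residues")
  set.seed(seed)
  i <- seq_len(nResidues)
  ang <- (i - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (i - 1))
  rows <- list()
  for (k in i) {
    prev <- ca[max(1, k - 1), ]; nxt <- ca[min(nResidues, k + 1), ]
    tang <- .unit(nxt - prev)
    rad <- .unit(c(ca[k, 1], ca[k, 2], 0))
    dN <- .unit(tang - 0.5 * rad); dC <- .unit(tang + 0.5 * rad)
    up <- .unit(c(tang[2] * rad[3] - tang[3] * rad[2],
                  tang[3] * rad[1] - tang[1] * rad[3],
                  tang[1] * rad[2] - tang[2] * rad[1]))
    pos <- rbind(N = ca[k, ] - 1.45 * dN,
                 CA = ca[k, ],
                 C = ca[k, ] + 1.52 * dC,
                 O = ca[k, ] + 1.52 * dC + 1.23 * rad,
                 CB = ca[k, ] + 1.53 * up)
    pos <- pos + matrix(stats::rnorm(15, sd = noise), 5, 3)
    rows[[k]] <- data.frame(
      chain = chain, resno = k, insert = "", resid = "ALA",
      elety = rownames(pos), elesy = c("N", "C", "C", "O", "C"),
      x = pos[, 1], y = pos[, 2], z = pos[, 3], isHeavy = TRUE,
      stringsAsFactors = FALSE)
  }
  .buildProteinStructure(id, do.call(rbind, c(rows, make.row.names = FALSE)))
}

.ligandNear <- function(structure, anchorIdx, nAtoms, ligId, chain, resno) {
  ca <- backboneCoords(structure, anchorIdx)$CA
  rad <- .unit(c(ca[1], ca[2], 0))
  center <- ca + 2.8 * rad
  off <- matrix(stats::runif(nAtoms * 3, -0.8, 0.8), nAtoms, 3)
  off[1, ] <- 0  # one atom exactly at the placement center
  xyz <- sweep(off, 2, center, "+")
  eles <- c("C", "O", "N", "C", "C", "O")[seq_len(nAtoms)]
  new("Ligand", id = ligId,
      atoms = data.frame(chain = chain, resno = resno, insert = "",
                         resid = "LIG", elety = paste0(eles, seq_len(nAtoms)),
                         elesy = eles, x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], isHeavy = TRUE,
                         stringsAsFactors = FALSE))
}

#' Generate a toy protein-ligand complex with candidates and labels
#'
#' Plants \code{nLigands} ligands against the helix surface, one candidate
#' center within 4 A DCA of each ligand, and \code{nDecoys} decoy centers at
#' least 10 A from every ligand atom; labels are derived through the 4 A
#' rule, so planted candidates are positive and decoys negative by
#' construction (verified, with bounded retries).
#'
#' @param nResidues,noise,seed,id as in \code{\link{makeToyProtein}}.
#' @param nLigands number of planted ligands.
#' @param nDecoys number of decoy candidates.
#' @return list with \code{complex} (a \linkS4class{ProteinComplex}),
#'   \code{candidates} (data.frame rank, id, x, y, z, positive) and
#'   \code{anchors} (anchor residue indices).
#' @export
makeToyComplex <- function(nResidues = 40L, nLigands = 1L, nDecoys = 3L,
                           noise = 0.05, seed = 1L, id = "toy") {
  protein <- makeToyProtein(nResidues, noise, seed, id = id)
  set.seed(seed + 10000L)
  anchors <- round(seq(0.25, 0.75, length.out = nLigands) * nResidues)
  ligs <- lapply(seq_len(nLigands), function(j)
    .ligandNear(protein, anchors[j], nAtoms = 4L + (j %% 3L),
                ligId = paste0("LIG_X_", j), chain = "X", resno = j))
  cx <- new("ProteinComplex", id = id, protein = protein, ligands = ligs)
  ligXyz <- do.call(rbind, lapply(ligs, atomCoords))

  centers <- list()
  ## planted candidate per ligand: perturbed ligand center of mass
  for (j in seq_len(nLigands)) {
    cen <- candidateCenter(ligs[[j]]@atoms) + stats::runif(3, -0.5, 0.5)
    if (!candidateIsPositive(cen, ligs))
      cen <- candidateCenter(ligs[[j]]@atoms)  # fallback: exact center
    centers[[j]] <- list(xyz = cen, positive = TRUE)
  }
  ## decoys: pushed off the surface of residues away from the ligands
  cas <- t(vapply(seq_len(nResidues), function(i)
    backboneCoords(protein, i)$CA, numeric(3)))
  for (j in seq_len(nDecoys)) {
    ok <- FALSE
    for (try in 1:200) {
      k <- sample.int(nResidues, 1)
      dir <- .unit(c(cas[k, 1], cas[k, 2], 0) + stats::rnorm(3, sd = 0.2))
      cand <- cas[k, ] + stats::runif(1, 8, 12) * dir
      dmin <- sqrt(min(colSums((t(ligXyz) - cand)^2)))
      dca_ <- sqrt(min(colSums((t(cas) - cand)^2)))
      if (dmin >= 10 && dca_ < 15) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place decoy candidate after bounded retries")
    centers[[nLigands + j]] <- list(xyz = cand, positive = FALSE)
  }
  tab <- data.frame(
    rank = seq_along(centers),
    id = paste0("cand", seq_along(centers)),
    x = vapply(centers, function(c) c$xyz[1], numeric(1)),
    y = vapply(centers, function(c) c$xyz[2], numeric(1)),
    z = vapply(centers, function(c) c$xyz[3], numeric(1)),
    stringsAsFactors = FALSE)
  ## self-consistent labels through the supervision rule
  tab$positive <- vapply(seq_len(nrow(tab)), function(j)
    candidateIsPositive(as.numeric(tab[j, c("x", "y", "z")]), ligs),
    logical(1))
  if (!all(tab$positive[seq_len(nLigands)]) ||
      any(tab$positive[-seq_len(nLigands)]))
    stop("toy complex construction produced inconsistent labels")
  list(complex = cx, candidates = tab, anchors = anchors)
}

#' Derive a homologous copy of a structure plus its alignment
#'
#' The target is a copy in which each residue is deleted with probability
#' \code{indelRate} and renamed with probability \code{mutationRate}; the
#' alignment maps surviving residues (identity alignment at zero rates).
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param mutationRate,indelRate per-residue probabilities in [0, 1).
#' @param seed RNG seed.
#' @param targetId identifier of the derived structure.
#' @return list(target, alignment).
#' @export
makeAlignmentPair <- function(structure, mutationRate = 0, indelRate = 0,
                              seed = 1L, targetId = NULL) {
  stopifnot(mutationRate >= 0, mutationRate < 1, indelRate >= 0, indelRate < 1)
  set.seed(seed)
  n <- nResidues(structure)
  keep <- which(stats::runif(n) >= indelRate)
  if (length(keep) < 3) keep <- sort(sample.int(n, 3))
  if (is.null(targetId)) targetId <- paste0(structure@id, "_hom")
  at <- structure@atoms[structure@atoms$residueIndex %in% keep, , drop = FALSE]
  newPos <- match(at$residueIndex, keep)
  at$resno <- newPos
  mut <- stats::runif(length(keep)) < mutationRate
  for (m in which(mut))
    at$resid[newPos == m] <- sample(.AA3, 1)
  at$residueIndex <- NULL
  target <- .buildProteinStructure(targetId, at)
  chain <- structure@residues$chain[1]
  list(target = target,
       alignment = alignmentRecord(structure@id, chain, targetId, chain,
                                   qpos = keep,
                                   tpos = seq_along(keep)))
}

#' Write a toy complex as an on-disk fixture directory
#'
#' Emits the real external formats so that I/O code paths are exercised:
#' \code{complex.pdb} (ATOM + HETATM), an Fpocket-style \code{fpocket/pockets/}
#' directory with one \code{pocket<N>_atm.pdb} per candidate (four carbon
#' pseudo-atoms placed symmetrically about the center, so the center of mass
#' recovers the candidate center), \code{centers.tsv}, and optionally
#' \code{alignment.tsv}.
#'
#' @param toy result of \code{\link{makeToyComplex}}.
#' @param dir output directory (created).
#' @param alignment optional \code{\link{alignmentRecord}} to include.
#' @return the directory path, invisibly.
#' @export
writeFixtureDir <- function(toy, dir, alignment = NULL) {
  dir.create(file.path(dir, "fpocket", "pockets"), recursive = TRUE,
             showWarnings = FALSE)
  writeComplexPdb(toy$complex, file.path(dir, "complex.pdb"))
  cand <- toy$candidates
  for (j in seq_len(nrow(cand))) {
    cen <- as.numeric(cand[j, c("x", "y", "z")])
    off <- rbind(c(0.5, 0, 0), c(-0.5, 0, 0), c(0, 0.5, 0), c(0, -0.5, 0))
    xyz <- sweep(off, 2, cen, "+")
    bio3d::write.pdb(
      file = file.path(dir, "fpocket", "pockets",
                       sprintf("pocket%d_atm.pdb", j)),
      xyz = as.vector(t(xyz)), type = rep("ATOM", 4),
      resno = rep(j, 4), resid = rep("STP", 4),
      eleno = 1:4, elety = paste0("C", 1:4), chain = rep("P", 4),
      elesy = rep("C", 4), o = rep(1, 4), b = rep(0, 4))
  }
  utils::write.table(cand[, c("id", "x", "y", "z")],
                     file.path(dir, "centers.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(alignment)) {
    tab <- data.frame(query_id = alignment$queryId,
                      query_chain = alignment$queryChain,
                      target_id = alignment$targetId,
                      target_chain = alignment$targetChain,
                      qpos = alignment$qpos, tpos = alignment$tpos,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, "alignment.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
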