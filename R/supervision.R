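## Ground-truth labeling: true binding residues and positive candidates via
## the 4 Angstrom heavy-atom rule (strict "<" at the boundary throughout),
## class-balancing loss weights, and the balanced candidate sampler.

#' True binding residues of a ligand
#'
#' A residue is a binding residue when any of its heavy atoms lies closer
#' than \code{cutoff} to any ligand heavy atom.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param ligand a \linkS4class{Ligand} (or heavy-atom coordinate matrix).
#' @param cutoff contact distance in Angstrom.
#' @return sorted integer vector of residue indices (possibly empty).
#' @export
trueBindingResidues <- function(structure, ligand, cutoff = 4.0) {
  lat <- if (is(ligand, "Ligand")) atomCoords(ligand, heavyOnly = TRUE)
         else as.matrix(ligand)
  at <- structure@atoms[structure@atoms$isHeavy, , drop = FALSE]
  if (nrow(at) == 0 || nrow(lat) == 0) return(integer(0))
  A <- as.matrix(at[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(lat^2), "+") - 2 * tcrossprod(A, lat)
  mind <- sqrt(pmax(0, apply(d2, 1, min)))
  sort(unique(at$residueIndex[mind < cutoff]))
}

#' Distance from a center to the nearest ligand heavy atom (DCA)
#'
#' @param center length-3 numeric.
#' @param ligand a \linkS4class{Ligand} or heavy-atom coordinate matrix.
#' @return distance in Angstrom.
#' @export
dca <- function(center, ligand) {
  lat <- if (is(ligand, "Ligand")) atomCoords(ligand, heavyOnly = TRUE)
         else as.matrix(ligand)
  if (nrow(lat) == 0) stop("dca: ligand has no heavy atoms")
  sqrt(min(colSums((t(lat) - as.numeric(center))^2)))
}

#' Is a candidate center a positive binding site?
#'
#' True when DCA to some ligand is smaller than \code{cutoff}.
#'
#' @param center length-3 numeric.
#' @param ligs list of \linkS4class{Ligand} (or coordinate matrices).
#' @param cutoff detection threshold in Angstrom.
#' @export
candidateIsPositive <- function(center, ligs, cutoff = 4.0) {
  if (length(ligs) == 0) stop("candidateIsPositive: no ligands")
  any(vapply(ligs, function(l) dca(center, l) < cutoff, logical(1)))
}

#' Class-balancing residue loss weights
#'
#' w_pos = 1/(2 n_pos) and w_neg = 1/(2 n_neg), so that the total weighted
#' mass is 1. When one class is absent its weight is 0 and the other is 1/n.
#'
#' @param labels numeric per-residue labels in [0,1] (>= 0.5 counts as
#'   positive) or a logical vector.
#' @return list(wPos, wNeg, nPos, nNeg).
#' @export
residueLossWeights <- function(labels) {
  pos <- as.numeric(labels) >= 0.5
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 && nNeg == 0) stop("no labeled residues")
  if (nPos == 0 || nNeg == 0) {
    n <- nPos + nNeg
    return(list(wPos = if (nPos > 0) 1 / n else 0,
                wNeg = if (nNeg > 0) 1 / n else 0,
                nPos = nPos, nNeg = nNeg))
  }
  list(wPos = 1 / (2 * nPos), wNeg = 1 / (2 * nNeg), nPos = nPos, nNeg = nNeg)
}

#' Balanced candidate sampler
#'
#' Draws candidate indices such that positives and negatives appear with
#' equal probability; the minority class is resampled with replacement.
#' Deterministic under \code{seed}.
#'
#' @param labels logical (or 0/1) vector of candidate labels.
#' @param nDraws number of indices to emit.
#' @param seed RNG seed.
#' @return integer vector of candidate indices of length \code{nDraws}.
#' @export
balancedCandidateSampler <- function(labels, nDraws, seed = 0L) {
  labels <- as.logical(labels)
  posIdx <- which(labels); negIdx <- which(!labels)
  if (length(posIdx) == 0 || length(negIdx) == 0)
    stop("balanced sampling requires both classes")
  set.seed(seed)
  cls <- sample(c(TRUE, FALSE), nDraws, replace = TRUE)
  out <- integer(nDraws)
  out[cls] <- posIdx[sample.int(length(posIdx), sum(cls), replace = TRUE)]
  out[!cls] <- negIdx[sample.int(length(negIdx), sum(!cls), replace = TRUE)]
  out
}

#' Write / read per-protein label files
#'
#' JSON layout: candidate id -> {positive, residues: {index: value}}.
#'
#' @param labels named list: per candidate, list(positive=, residues=named
#'   numeric of residue labels).
#' @param path file path.
#' @export
writeLabelFile <- function(labels, path) {
  jsonlite::write_json(labels, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLabelFile
#' @export
readLabelFile <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
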