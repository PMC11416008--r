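## Unified evaluation suite. Per protein i with n ligands and exactly n
## predictions (c_j, BR_j):
##   precision P = #{j : c_j detects some ligand} / n,   detection = DCA < 4 A
##   recall    R = #{k : l_k detected by some c_j} / n
##   success rate = weighted mean of F1(P, R), weights n
##   IOU          = sum_{i,j} |BR_j ^ TBR_phi(j)| / |BR_j v TBR_phi(j)| / sum n
##   cond. IOU    = same sum restricted to detected predictions j in S,
##                  denominator sum |S|
## phi(j) is the DCA-closest ligand (ties -> lowest index).

#' Evaluation record constructor
#'
#' @param id protein identifier.
#' @param ligandAtoms list of ligand heavy-atom coordinate matrices (or
#'   \linkS4class{Ligand} objects).
#' @param centers n x 3 matrix of predicted centers (one per ligand).
#' @param predictedResidues list of n integer vectors.
#' @param trueResidues list of n integer vectors (4 Angstrom rule); computed
#'   from \code{structure} when omitted.
#' @param structure optional \linkS4class{ProteinStructure} used to derive
#'   trueResidues.
#' @param cutoff contact distance for derived trueResidues.
#' @return an \linkS4class{EvalRecord}.
#' @export
evalRecord <- function(id, ligandAtoms, centers, predictedResidues,
                       trueResidues = NULL, structure = NULL, cutoff = 4.0) {
  ligandAtoms <- lapply(ligandAtoms, function(l)
    if (is(l, "Ligand")) atomCoords(l, heavyOnly = TRUE) else as.matrix(l))
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (is.null(trueResidues)) {
    if (is.null(structure))
      stop("either trueResidues or structure must be given")
    trueResidues <- lapply(ligandAtoms, function(l)
      trueBindingResidues(structure, l, cutoff))
  }
  new("EvalRecord", id = id, ligandAtoms = ligandAtoms, centers = centers,
      predictedResidues = lapply(predictedResidues, as.integer),
      trueResidues = lapply(trueResidues, as.integer))
}

#' Index of the DCA-closest ligand
#'
#' @param center length-3 numeric.
#' @param ligs list of ligands or coordinate matrices.
#' @return index of the closest ligand; ties break to the lowest index.
#' @export
closestLigand <- function(center, ligs) {
  d <- vapply(ligs, function(l) dca(center, l), numeric(1))
  which.min(d)  # which.min returns the first (lowest-index) minimum
}

.iou <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)  # both empty: vacuous perfection
  length(intersect(a, b)) / u
}

.recordTerms <- function(rec, cutoff = 4.0) {
  n <- length(rec@ligandAtoms)
  dcaMat <- matrix(0, n, n)  # predictions x ligands
  for (j in seq_len(n))
    for (k in seq_len(n))
      dcaMat[j, k] <- dca(rec@centers[j, ], rec@ligandAtoms[[k]])
  detected <- dcaMat < cutoff
  P <- sum(apply(detected, 1, any)) / n
  R <- sum(apply(detected, 2, any)) / n
  phi <- apply(dcaMat, 1, which.min)
  iou <- vapply(seq_len(n), function(j)
    .iou(rec@predictedResidues[[j]], rec@trueResidues[[phi[j]]]), numeric(1))
  S <- which(vapply(seq_len(n), function(j) dcaMat[j, phi[j]] < cutoff,
                    logical(1)))
  list(n = n, P = P, R = R,
       F1 = if (P + R == 0) 0 else 2 * P * R / (P + R),
       phi = phi, iou = iou, S = S)
}

.checkRecords <- function(records) {
  keep <- vapply(records, function(r) length(r@ligandAtoms) >= 1, logical(1))
  if (!all(keep))
    warning(sum(!keep), " record(s) without ligands excluded from metrics")
  records[keep]
}

#' Detection success rate (ligand-weighted F1)
#'
#' @param records list of \linkS4class{EvalRecord}.
#' @param cutoff detection threshold in Angstrom.
#' @return fraction in [0, 1].
#' @export
f1SuccessRate <- function(records, cutoff = 4.0) {
  records <- .checkRecords(records)
  terms <- lapply(records, .recordTerms, cutoff = cutoff)
  n <- vapply(terms, `[[`, numeric(1), "n")
  f1 <- vapply(terms, `[[`, numeric(1), "F1")
  sum(n * f1) / sum(n)
}

#' Average IOU of binding residues against the closest ligands
#'
#' @inheritParams f1SuccessRate
#' @return fraction in [0, 1].
#' @export
avgIou <- function(records, cutoff = 4.0) {
  records <- .checkRecords(records)
  terms <- lapply(records, .recordTerms, cutoff = cutoff)
  total <- sum(vapply(terms, function(t) sum(t$iou), numeric(1)))
  total / sum(vapply(terms, `[[`, numeric(1), "n"))
}

#' Conditional IOU: restricted to successfully detected predictions
#'
#' @inheritParams f1SuccessRate
#' @return fraction in [0, 1]; NaN (with a warning) when no prediction is
#'   detected anywhere.
#' @export
conditionalIou <- function(records, cutoff = 4.0) {
  records <- .checkRecords(records)
  terms <- lapply(records, .recordTerms, cutoff = cutoff)
  nS <- sum(vapply(terms, function(t) length(t$S), numeric(1)))
  if (nS == 0) {
    warning("no detected predictions; conditional IOU undefined")
    return(NaN)
  }
  total <- sum(vapply(terms, function(t) sum(t$iou[t$S]), numeric(1)))
  total / nS
}

#' Per-protein metric table
#'
#' @inheritParams f1SuccessRate
#' @return data.frame with one row per record (id, n, P, R, F1, meanIou,
#'   nDetected) plus an aggregate row.
#' @export
metricsTable <- function(records, cutoff = 4.0) {
  records <- .checkRecords(records)
  terms <- lapply(records, .recordTerms, cutoff = cutoff)
  per <- data.frame(
    id = vapply(records, function(r) r@id, character(1)),
    n = vapply(terms, `[[`, numeric(1), "n"),
    P = vapply(terms, `[[`, numeric(1), "P"),
    R = vapply(terms, `[[`, numeric(1), "R"),
    F1 = vapply(terms, `[[`, numeric(1), "F1"),
    meanIou = vapply(terms, function(t) mean(t$iou), numeric(1)),
    nDetected = vapply(terms, function(t) length(t$S), numeric(1)),
    stringsAsFactors = FALSE)
  agg <- data.frame(id = "ALL", n = sum(per$n), P = NA, R = NA,
                    F1 = f1SuccessRate(records, cutoff),
                    meanIou = avgIou(records, cutoff),
                    nDetected = sum(per$nDetected),
                    stringsAsFactors = FALSE)
  rbind(per, agg)
}

#' Probability that top-ranked sites fall among the most frequent ones
#'
#' The chance that \code{nTop} sites chosen uniformly at random out of
#' \code{nSites} all lie within a designated set of \code{nFrequent} sites:
#' C(nFrequent, nTop) / C(nSites, nTop).
#'
#' @param nSites total number of binding sites.
#' @param nTop number of top-scored sites.
#' @param nFrequent size of the designated frequent set.
#' @return probability in [0, 1].
#' @export
rankProbability <- function(nSites, nTop, nFrequent) {
  if (!(nTop <= nFrequent && nFrequent <= nSites) || nTop < 0)
    stop("require 0 <= nTop <= nFrequent <= nSites")
  choose(nFrequent, nTop) / choose(nSites, nTop)
}
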