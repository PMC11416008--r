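## Homology-based augmentation: transfer binding-site evidence from a seed
## database of complexes to unlabeled target chains through sequence
## alignments.
##
## Steps: (1) ligands associated to exactly one chain; (2) alignments (built
## externally, e.g. HHBlits; consumed here as pairwise aligned-position
## records); (3) a triplet (query chain x, ligand l, target chain y) is
## "preserving" when at least half of x's ligand-contact residues are aligned
## to y; (4) the proxy center on y is the mean CA position of the aligned
## partners of those contacts; (5) Fpocket candidates on y are labeled
## positive within 7.5 A of a proxy center, negative beyond 30 A of all, and
## excluded otherwise; (6) residue labels on y are vote fractions over the
## supporting triplets.

#' Pairwise alignment record
#'
#' Aligned position pairs between one seed-database chain (query) and one
#' target chain. Positions are 1-based within the chain's residue order.
#'
#' @param queryId,queryChain seed complex id and chain id.
#' @param targetId,targetChain target structure id and chain id.
#' @param qpos,tpos equal-length integer vectors of aligned positions;
#'   both must be strictly increasing (colinear alignment).
#' @return list of class "AlignmentRecord".
#' @export
alignmentRecord <- function(queryId, queryChain, targetId, targetChain,
                            qpos, tpos) {
  qpos <- as.integer(qpos); tpos <- as.integer(tpos)
  if (length(qpos) != length(tpos))
    stop("qpos and tpos must have equal length")
  if (length(qpos) > 1 &&
      (any(diff(qpos) <= 0) || any(diff(tpos) <= 0)))
    stop("alignment pairs must be strictly increasing in both coordinates")
  if (length(qpos) > 0 && (min(qpos) < 1 || min(tpos) < 1))
    stop("alignment positions must be >= 1")
  structure(list(queryId = queryId, queryChain = queryChain,
                 targetId = targetId, targetChain = targetChain,
                 qpos = qpos, tpos = tpos),
            class = "AlignmentRecord")
}

#' Read alignment records from a pair table
#'
#' TSV with columns query_id, query_chain, target_id, target_chain, qpos,
#' tpos; one record is emitted per (query, target) chain pair.
#'
#' @param path table file.
#' @return list of \code{\link{alignmentRecord}}.
#' @export
readAlignmentTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("query_id", "query_chain", "target_id", "target_chain",
            "qpos", "tpos")
  if (!all(need %in% names(tab)))
    stop("alignment table must have columns ", paste(need, collapse = ", "))
  key <- paste(tab$query_id, tab$query_chain, tab$target_id,
               tab$target_chain, sep = "\r")
  lapply(split(seq_len(nrow(tab)), factor(key, levels = unique(key))),
         function(idx) {
           idx <- idx[order(tab$qpos[idx])]
           alignmentRecord(tab$query_id[idx[1]], tab$query_chain[idx[1]],
                           tab$target_id[idx[1]], tab$target_chain[idx[1]],
                           tab$qpos[idx], tab$tpos[idx])
         })
}

#' Extract pairwise alignments from an A3M file
#'
#' The first sequence is the query; each subsequent entry yields one record.
#' Uppercase letters are match states (consume a query column and a target
#' residue), lowercase letters are insertions in the target (no query
#' column), and "-" is a deletion (query column without target residue).
#' Sequence names are parsed as "id_chain" (a trailing "_X" suffix; a name
#' without a suffix gets chain "A").
#'
#' @param path A3M file.
#' @param queryId,queryChain identity of the query chain (defaults parsed
#'   from the first header).
#' @return list of \code{\link{alignmentRecord}}.
#' @export
readA3m <- function(path, queryId = NULL, queryChain = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) < 2) stop("A3M must contain a query and >= 1 aligned entry")
  getSeq <- function(k) {
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    paste(lines[(hdr[k] + 1):to], collapse = "")
  }
  splitName <- function(h) {
    nm <- sub("^>\\s*", "", h)
    nm <- strsplit(nm, "\\s+")[[1]][1]
    if (grepl("_[A-Za-z0-9]+$", nm))
      list(id = sub("_[A-Za-z0-9]+$", "", nm),
           chain = sub("^.*_", "", nm))
    else list(id = nm, chain = "A")
  }
  qn <- splitName(lines[hdr[1]])
  if (is.null(queryId)) queryId <- qn$id
  if (is.null(queryChain)) queryChain <- qn$chain
  out <- list()
  for (k in 2:length(hdr)) {
    tn <- splitName(lines[hdr[k]])
    s <- strsplit(getSeq(k), "")[[1]]
    qp <- 0L; tp <- 0L
    qpos <- integer(0); tpos <- integer(0)
    for (ch in s) {
      if (ch == "-") {
        qp <- qp + 1L
      } else if (ch %in% letters) {
        tp <- tp + 1L
      } else {
        qp <- qp + 1L; tp <- tp + 1L
        qpos <- c(qpos, qp); tpos <- c(tpos, tp)
      }
    }
    out[[length(out) + 1L]] <- alignmentRecord(queryId, queryChain,
                                               tn$id, tn$chain, qpos, tpos)
  }
  out
}

## residue indices (global) of a chain, in order; chain position p maps to
## .chainResidueIndices(structure, chain)[p]
.chainResidueIndices <- function(structure, chain) {
  which(structure@residues$chain == chain)
}

#' Ligands associated to exactly one chain
#'
#' @param complex a \linkS4class{ProteinComplex}.
#' @param cutoff association distance in Angstrom.
#' @return list of entries \code{list(chain, ligand)}; a chain can appear in
#'   several entries.
#' @export
singleChainLigands <- function(complex, cutoff = 4.0) {
  out <- list()
  for (lig in complex@ligands) {
    ch <- associatedChains(lig, complex@protein, cutoff)
    if (length(ch) == 1)
      out[[length(out) + 1L]] <- list(chain = ch, ligand = lig)
  }
  out
}

#' Contact residues of a chain with a ligand
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param chain chain id.
#' @param ligand a \linkS4class{Ligand}.
#' @param cutoff contact distance in Angstrom.
#' @return integer vector of chain positions (1-based within the chain).
#' @export
contactResidues <- function(structure, chain, ligand, cutoff = 4.0) {
  global <- trueBindingResidues(structure, ligand, cutoff)
  chainIdx <- .chainResidueIndices(structure, chain)
  which(chainIdx %in% global)
}

#' Is a (query chain, ligand, target chain) triplet preserving?
#'
#' Preserving means at least half of the query chain's ligand-contact
#' residues are aligned with a residue of the target.
#'
#' @param seedStructure the query \linkS4class{ProteinStructure}.
#' @param chain query chain id.
#' @param ligand the associated \linkS4class{Ligand}.
#' @param alignment an \code{\link{alignmentRecord}} joining the query chain
#'   to the target chain.
#' @param cutoff contact distance in Angstrom.
#' @return list(preserving, contacts, alignedContacts, targetPositions):
#'   chain positions of contacts, the aligned subset, and their partner
#'   positions on the target.
#' @export
isPreserving <- function(seedStructure, chain, ligand, alignment,
                         cutoff = 4.0) {
  contacts <- contactResidues(seedStructure, chain, ligand, cutoff)
  if (length(contacts) == 0)
    return(list(preserving = FALSE, contacts = integer(0),
                alignedContacts = integer(0), targetPositions = integer(0)))
  hit <- match(contacts, alignment$qpos)
  aligned <- contacts[!is.na(hit)]
  tgt <- alignment$tpos[hit[!is.na(hit)]]
  list(preserving = length(aligned) >= length(contacts) / 2,
       contacts = contacts, alignedContacts = aligned,
       targetPositions = tgt)
}

#' Proxy center of a transferred binding site
#'
#' Unweighted mean of the alpha-carbon coordinates of the target residues
#' aligned to the query's ligand-contact residues.
#'
#' @param targetStructure the target \linkS4class{ProteinStructure}.
#' @param targetChain target chain id.
#' @param targetPositions chain positions on the target (from
#'   \code{\link{isPreserving}}).
#' @return length-3 numeric center.
#' @export
proxyCenter <- function(targetStructure, targetChain, targetPositions) {
  chainIdx <- .chainResidueIndices(targetStructure, targetChain)
  idx <- chainIdx[targetPositions]
  cas <- lapply(idx, function(i) backboneCoords(targetStructure, i)$CA)
  cas <- cas[!vapply(cas, is.null, logical(1))]
  if (length(cas) == 0) stop("proxyCenter: no aligned CA on target")
  colMeans(do.call(rbind, cas))
}

#' Label candidate centers against proxy centers
#'
#' Positive when the distance to some proxy center is below \code{lower};
#' negative when the distance to every proxy center exceeds \code{upper};
#' otherwise excluded from the dataset.
#'
#' @param centers m x 3 matrix of candidate centers.
#' @param proxies k x 3 matrix of proxy centers.
#' @param lower,upper thresholds in Angstrom (lower < upper).
#' @return data.frame with columns label ("positive"/"negative"/"excluded")
#'   and a list-column supporting of proxy indices within \code{lower}.
#' @export
labelSiteCandidates <- function(centers, proxies, lower = 7.5, upper = 30.0) {
  if (lower >= upper) stop("lower threshold must be smaller than upper")
  centers <- matrix(as.numeric(centers), ncol = 3)
  proxies <- matrix(as.numeric(proxies), ncol = 3)
  m <- nrow(centers)
  d <- sqrt(pmax(outer(rowSums(centers^2), rowSums(proxies^2), "+") -
                   2 * tcrossprod(centers, proxies), 0))
  label <- character(m)
  supporting <- vector("list", m)
  for (j in seq_len(m)) {
    mind <- min(d[j, ])
    if (mind < lower) {
      label[j] <- "positive"
      supporting[[j]] <- which(d[j, ] < lower)
    } else if (mind > upper) {
      label[j] <- "negative"
    } else {
      label[j] <- "excluded"
    }
  }
  out <- data.frame(label = label, stringsAsFactors = FALSE)
  out$supporting <- supporting
  out
}

#' Residue vote labels for a positive site
#'
#' Each residue covered by at least one supporting triplet's aligned contact
#' image receives the fraction of supporting triplets whose image contains
#' it; uncovered residues receive no label.
#'
#' @param alignedContactSets list with one element per supporting triplet:
#'   the target residues (chain positions or residue names) aligned to that
#'   triplet's ligand-contact residues.
#' @return named numeric vector of vote fractions in (0, 1].
#' @export
voteResidueLabels <- function(alignedContactSets) {
  k <- length(alignedContactSets)
  if (k < 1) stop("at least one supporting triplet is required")
  all <- unlist(lapply(alignedContactSets, function(s) unique(as.character(s))))
  tab <- table(all)
  votes <- as.numeric(tab) / k
  names(votes) <- names(tab)
  votes[order(names(votes))]
}

#' Read printed residue-correspondence sets
#'
#' Reads a TSV with columns triplet, query_chain, query_res, target_res --
#' the form in which ligand-binding residue correspondences of preserving
#' triplets are published -- and returns, per triplet, the target residues
#' aligned to its ligand-contact residues, ready for
#' \code{\link{voteResidueLabels}}.
#'
#' @param path TSV file.
#' @return named list of character vectors (one per triplet).
#' @export
readCorrespondenceSets <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("triplet", "target_res")
  if (!all(need %in% names(tab)))
    stop("correspondence table must have columns ",
         paste(need, collapse = ", "))
  lapply(split(tab$target_res, factor(tab$triplet,
                                      levels = unique(tab$triplet))),
         unique)
}

#' Build the augmented dataset (steps 1-6)
#'
#' @param seedComplexes list of \linkS4class{ProteinComplex} (the seed DB).
#' @param targets named list of target \linkS4class{ProteinStructure}
#'   (names = target ids).
#' @param alignments list of \code{\link{alignmentRecord}}.
#' @param candidateFun function(targetStructure) returning a candidate table
#'   (columns id, x, y, z), e.g. from Fpocket output.
#' @param contactCutoff,lower,upper distance parameters in Angstrom.
#' @return named list per target id: \code{sites} (candidate table with a
#'   label column) and \code{residues} (per positive candidate id, named
#'   vote-fraction vector over target chain positions). Targets without a
#'   preserving triplet are omitted; per-chain failures are skipped with a
#'   warning.
#' @export
buildAugmentedDataset <- function(seedComplexes, targets, alignments,
                                  candidateFun, contactCutoff = 4.0,
                                  lower = 7.5, upper = 30.0) {
  ## deterministic processing order regardless of input order
  ord <- order(vapply(alignments, function(a)
    paste(a$targetId, a$targetChain, a$queryId, a$queryChain, sep = "\r"),
    character(1)))
  alignments <- alignments[ord]
  seedIds <- vapply(seedComplexes, function(s) s@id, character(1))

  ## step 1 per seed complex: single-chain ligands
  seedLigands <- lapply(seedComplexes, singleChainLigands,
                        cutoff = contactCutoff)

  ## steps 3-4: preserving triplets grouped by target
  triplets <- list()
  for (al in alignments) {
    si <- match(al$queryId, seedIds)
    if (is.na(si)) next
    tgt <- targets[[al$targetId]]
    if (is.null(tgt)) next
    for (cl in seedLigands[[si]]) {
      if (cl$chain != al$queryChain) next
      pres <- tryCatch(
        isPreserving(seedComplexes[[si]]@protein, cl$chain, cl$ligand, al,
                     cutoff = contactCutoff),
        error = function(e) {
          warning("skipping triplet (", al$queryId, ",", cl$ligand@id, ",",
                  al$targetId, "): ", conditionMessage(e))
          NULL
        })
      if (is.null(pres) || !pres$preserving) next
      proxy <- tryCatch(
        proxyCenter(tgt, al$targetChain, pres$targetPositions),
        error = function(e) {
          warning("skipping triplet on ", al$targetId, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(proxy)) next
      triplets[[length(triplets) + 1L]] <- list(
        targetId = al$targetId, targetChain = al$targetChain,
        queryId = al$queryId, queryChain = al$queryChain,
        ligandId = cl$ligand@id, proxy = proxy,
        targetPositions = pres$targetPositions)
    }
  }
  if (length(triplets) == 0) return(list())

  ## steps 5-6 per involved target
  byTarget <- split(seq_along(triplets),
                    vapply(triplets, function(t) t$targetId, character(1)))
  out <- list()
  for (tid in sort(names(byTarget))) {
    trs <- triplets[byTarget[[tid]]]
    tgt <- targets[[tid]]
    cand <- tryCatch(candidateFun(tgt), error = function(e) {
      warning("candidate generation failed on ", tid, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(cand) || nrow(cand) == 0) next
    proxies <- do.call(rbind, lapply(trs, function(t) t$proxy))
    lab <- labelSiteCandidates(as.matrix(cand[, c("x", "y", "z")]), proxies,
                               lower, upper)
    sites <- cbind(cand, label = lab$label, stringsAsFactors = FALSE)
    residues <- list()
    for (j in which(lab$label == "positive")) {
      sets <- lapply(trs[lab$supporting[[j]]],
                     function(t) t$targetPositions)
      residues[[as.character(cand$id[j])]] <- voteResidueLabels(sets)
    }
    out[[tid]] <- list(sites = sites, residues = residues)
  }
  out
}
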