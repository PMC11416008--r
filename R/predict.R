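## The inference pipeline: candidates -> BSD druggability ranking -> top-n ->
## BRI residue sets; plus evaluation wiring from prediction records to the
## metric suite.

#' Predict binding sites of a protein
#'
#' Scores every candidate center with the BSD model, ranks them by
#' druggability (ties preserve the candidate source order), and runs the BRI
#' model on the top \code{n} to produce predicted binding residue sets
#' (logit > 0).
#'
#' @param complex a \linkS4class{ProteinComplex} (ligands, if any, are
#'   ignored at inference).
#' @param candidates data.frame with columns rank, id, x, y, z (see
#'   \code{\link{candidateCenters}}).
#' @param bsdModel,briModel trained \linkS4class{BspModel}s.
#' @param n number of sites to emit; when fewer candidates score (e.g. empty
#'   contexts), all are emitted with a warning.
#' @param threshold context radius in Angstrom.
#' @return list of predictions: \code{list(id, center, score, residues)},
#'   sorted by decreasing druggability score.
#' @export
predictSites <- function(complex, candidates, bsdModel, briModel, n = 1L,
                         threshold = 17.0) {
  stopifnot(n >= 1)
  protein <- complex@protein
  frames <- buildFrames(protein)
  spec <- bsdModel@gridSpec
  feats <- vector("list", nrow(candidates))
  scores <- rep(NA_real_, nrow(candidates))
  for (j in seq_len(nrow(candidates))) {
    center <- as.numeric(candidates[j, c("x", "y", "z")])
    feat <- tryCatch(
      featurizeCandidate(protein, frames, center, spec, threshold),
      error = function(e) {
        warning("candidate ", candidates$id[j], " skipped: ",
                conditionMessage(e))
        NULL
      })
    if (is.null(feat)) next
    feats[[j]] <- feat
    scores[j] <- bsdForward(bsdModel, feat$grids, feat$frames)
  }
  scored <- which(!is.na(scores))
  if (length(scored) < n) {
    warning("only ", length(scored), " scorable candidates for n = ", n)
    n <- length(scored)
  }
  if (n == 0) return(list())
  ord <- scored[order(-scores[scored], candidates$rank[scored])]
  top <- ord[seq_len(n)]
  lapply(top, function(j) {
    feat <- feats[[j]]
    logits <- briForward(briModel, feat$grids, feat$frames)
    list(id = as.character(candidates$id[j]),
         center = as.numeric(candidates[j, c("x", "y", "z")]),
         score = druggability(scores[j]),
         residues = feat$indices[logits > 0])
  })
}

#' Write predictions as JSON records
#'
#' @param predictions result of \code{\link{predictSites}}.
#' @param proteinId protein identifier to embed.
#' @param path output file.
#' @export
writePredictionsJson <- function(predictions, proteinId, path) {
  recs <- lapply(predictions, function(p)
    list(protein = proteinId, candidate = p$id, center = p$center,
         score = p$score, residues = as.integer(p$residues)))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePredictionsJson
#' @export
readPredictionsJson <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Evaluate predictions against a labeled complex
#'
#' Builds the \linkS4class{EvalRecord} (n predictions against n ligands,
#' true binding residues by the 4 Angstrom rule) for one protein.
#'
#' @param complex a labeled \linkS4class{ProteinComplex}.
#' @param predictions list as returned by \code{\link{predictSites}}, of
#'   length equal to the ligand count.
#' @param cutoff contact distance in Angstrom.
#' @return an \linkS4class{EvalRecord}.
#' @export
predictionRecord <- function(complex, predictions, cutoff = 4.0) {
  n <- length(complex@ligands)
  if (n == 0) stop("complex ", complex@id, " has no ligands to evaluate")
  if (length(predictions) != n)
    stop("need exactly ", n, " predictions for ", complex@id,
         " (got ", length(predictions), ")")
  evalRecord(id = complex@id, ligandAtoms = complex@ligands,
             centers = do.call(rbind, lapply(predictions, `[[`, "center")),
             predictedResidues = lapply(predictions, `[[`, "residues"),
             structure = complex@protein, cutoff = cutoff)
}

#' Evaluate a set of labeled complexes end to end
#'
#' Runs \code{\link{predictSites}} with n = ligand count on each complex and
#' aggregates the metric table.
#'
#' @param toys list of entries with \code{complex} and \code{candidates}.
#' @param bsdModel,briModel trained models.
#' @param threshold context radius in Angstrom.
#' @return list(records, table): the \linkS4class{EvalRecord}s and the
#'   per-protein + aggregate metric table.
#' @export
evaluatePredictions <- function(toys, bsdModel, briModel, threshold = 17.0) {
  records <- list()
  for (toy in toys) {
    n <- length(toy$complex@ligands)
    preds <- predictSites(toy$complex, toy$candidates, bsdModel, briModel,
                          n = n, threshold = threshold)
    records[[length(records) + 1L]] <- predictionRecord(toy$complex, preds)
  }
  list(records = records, table = metricsTable(records))
}
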