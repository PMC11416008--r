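## Training harnesses: BRI pretraining on positive candidates, inter-
## resolution transfer to BSD with partial freezing, balanced sampling for
## BSD, and the auxiliary loss from the augmented dataset.

#' Training configuration constructor
#'
#' @param stage "bri" or "bsd_finetune".
#' @param lr Adam learning rate.
#' @param batchSize items per gradient step.
#' @param freezeSteps initial steps with the shared trunk frozen
#'   (bsd_finetune only).
#' @param auxWeight weight of the augmented-data auxiliary loss.
#' @param seed RNG seed for sampling.
#' @param maxSteps gradient steps.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(stage = c("bri", "bsd_finetune"), lr = 1e-3,
                        batchSize = 4L, freezeSteps = 0L, auxWeight = 1.0,
                        seed = 0L, maxSteps = 100L) {
  stage <- match.arg(stage)
  new("TrainConfig", stage = stage, lr = as.numeric(lr),
      batchSize = as.integer(batchSize), freezeSteps = as.integer(freezeSteps),
      auxWeight = as.numeric(auxWeight), seed = as.integer(seed),
      maxSteps = as.integer(maxSteps))
}

#' Read / write a training configuration as YAML
#'
#' @param path YAML file.
#' @export
readTrainConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(trainConfig, y)
}

#' @rdname readTrainConfig
#' @param config a \linkS4class{TrainConfig}.
#' @export
writeTrainConfig <- function(config, path) {
  yaml::write_yaml(list(stage = config@stage, lr = config@lr,
                        batchSize = config@batchSize,
                        freezeSteps = config@freezeSteps,
                        auxWeight = config@auxWeight, seed = config@seed,
                        maxSteps = config@maxSteps), path)
  invisible(path)
}

#' Weighted BRI loss over context residues
#'
#' Weighted binary cross-entropy: residues with label >= 0.5 count as
#' positives for the 1/(2 n_pos), 1/(2 n_neg) weights; soft labels (e.g.
#' augmentation vote fractions) enter the cross-entropy as targets directly.
#'
#' @param logits per-residue logits.
#' @param labels per-residue targets in [0, 1].
#' @param mask optional logical vector of labeled residues; unlabeled
#'   residues contribute neither loss nor weight mass.
#' @return scalar loss.
#' @export
briLoss <- function(logits, labels, mask = NULL) {
  .briLossGrad(logits, labels, mask)$loss
}

.briLossGrad <- function(logits, labels, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(labels))
  if (length(logits) != length(labels) || length(mask) != length(labels))
    stop("logits, labels and mask must be aligned")
  if (!any(mask)) stop("no labeled residues")
  z <- logits[mask]; y <- labels[mask]
  lw <- residueLossWeights(y)
  w <- ifelse(y >= 0.5, lw$wPos, lw$wNeg)
  dz <- numeric(length(logits))
  dz[mask] <- w * .bceGrad(z, y)
  list(loss = sum(w * .bceWithLogits(z, y)), dLogits = dz)
}

#' BSD loss for one candidate
#'
#' Binary cross-entropy between the druggability logit and the candidate
#' label.
#'
#' @param logit scalar logit.
#' @param label 0/1 (or soft) target.
#' @return scalar loss.
#' @export
bsdLoss <- function(logit, label) .bceWithLogits(logit, label)

#' Initialize a BSD model from a trained BRI model (transfer learning)
#'
#' Copies the shared trunk (CNN + attention layers 1..L-1) exactly; the
#' task-specific final attention layer and head keep the BSD model's own
#' initialization.
#'
#' @param briModel trained \linkS4class{BspModel} with task "bri" (or a
#'   checkpoint path).
#' @param bsdModel \linkS4class{BspModel} with task "bsd" to initialize.
#' @return list(model, copied): the updated model and the manifest of copied
#'   parameter names.
#' @export
transferInit <- function(briModel, bsdModel) {
  if (is.character(briModel)) briModel <- loadCheckpoint(briModel)
  stopifnot(briModel@task == "bri", bsdModel@task == "bsd")
  shared <- sharedParameterNames(bsdModel@config, bsdModel@params)
  for (nm in shared) {
    src <- briModel@params[[nm]]
    dst <- bsdModel@params[[nm]]
    if (is.null(src) || length(src) != length(dst) ||
        !identical(dim(src), dim(dst)))
      stop("shared parameter shape mismatch for group: ", nm)
    bsdModel@params[[nm]] <- src
  }
  list(model = bsdModel, copied = shared)
}

## loss + gradient of one training item under the current model
.itemLossGrad <- function(model, item) {
  fwd <- .modelForward(model, item$grids, item$frames, withCache = TRUE)
  if (model@task == "bri") {
    lg <- .briLossGrad(fwd$out, item$labels, item$mask)
    list(loss = lg$loss, grads = .modelBackward(model, fwd$cache, lg$dLogits))
  } else {
    loss <- .bceWithLogits(fwd$out, item$label)
    dOut <- .bceGrad(fwd$out, item$label)
    list(loss = loss, grads = .modelBackward(model, fwd$cache, dOut))
  }
}

.itemLoss <- function(model, item) {
  out <- .modelForward(model, item$grids, item$frames)$out
  if (model@task == "bri") briLoss(out, item$labels, item$mask)
  else .bceWithLogits(out, item$label)
}

#' Mean validation loss over items
#'
#' @param model a \linkS4class{BspModel}.
#' @param items list of training items.
#' @return mean loss (forward only).
#' @export
validationLoss <- function(model, items) {
  mean(vapply(items, function(it) .itemLoss(model, it), numeric(1)))
}

#' Train one stage
#'
#' Runs Adam over the dataset. For the "bsd_finetune" stage, candidates are
#' drawn with balanced positive/negative sampling and the shared trunk is
#' frozen (parameters untouched, no optimizer state) for the first
#' \code{freezeSteps} steps. When \code{augItems} are provided and
#' \code{auxWeight > 0}, each step adds \code{auxWeight} times the mean loss
#' of an equally-sized draw from the augmented items.
#'
#' @param model a \linkS4class{BspModel} matching the stage.
#' @param items training items: for BRI, \code{list(grids, frames, labels,
#'   mask)} (positive candidates only); for BSD, \code{list(grids, frames,
#'   label)}.
#' @param config a \linkS4class{TrainConfig}.
#' @param valItems optional held-out items; validation loss is recorded
#'   every \code{valEvery} steps.
#' @param augItems optional augmented-data items (same shape as items, soft
#'   labels allowed).
#' @param valEvery validation period in steps.
#' @return list(model, curve): the trained model and a data.frame with
#'   columns step, loss, valLoss (NA between validations).
#' @export
trainStage <- function(model, items, config, valItems = NULL,
                       augItems = NULL, valEvery = 25L) {
  if (length(items) == 0) stop("empty training dataset")
  isBsd <- config@stage == "bsd_finetune"
  if (isBsd && model@task != "bsd") stop("bsd_finetune stage needs a bsd model")
  if (!isBsd && model@task != "bri") stop("bri stage needs a bri model")
  if (isBsd) {
    labs <- vapply(items, function(it) as.numeric(it$label), numeric(1)) >= 0.5
    posIdx <- which(labs); negIdx <- which(!labs)
    if (length(posIdx) == 0 || length(negIdx) == 0)
      stop("bsd training requires both positive and negative candidates")
  }
  useAux <- !is.null(augItems) && length(augItems) > 0 && config@auxWeight > 0
  shared <- sharedParameterNames(model@config, model@params)
  state <- .adamInit()
  set.seed(config@seed)
  B <- config@batchSize
  steps <- config@maxSteps
  curve <- data.frame(step = seq_len(steps), loss = NA_real_,
                      valLoss = NA_real_)
  for (step in seq_len(steps)) {
    idx <- if (isBsd) {
      cls <- sample(c(TRUE, FALSE), B, replace = TRUE)
      pdraw <- posIdx[sample.int(length(posIdx), B, replace = TRUE)]
      ndraw <- negIdx[sample.int(length(negIdx), B, replace = TRUE)]
      ifelse(cls, pdraw, ndraw)
    } else {
      sample(seq_along(items), B, replace = length(items) < B)
    }
    gr <- .gnew()
    loss <- 0
    for (i in idx) {
      lg <- .itemLossGrad(model, items[[i]])
      loss <- loss + lg$loss / B
      for (nm in names(lg$grads)) .gadd(gr, nm, lg$grads[[nm]] / B)
    }
    if (useAux) {
      aidx <- sample(seq_along(augItems), B, replace = length(augItems) < B)
      for (i in aidx) {
        lg <- .itemLossGrad(model, augItems[[i]])
        loss <- loss + config@auxWeight * lg$loss / B
        for (nm in names(lg$grads))
          .gadd(gr, nm, config@auxWeight * lg$grads[[nm]] / B)
      }
    }
    if (!is.finite(loss))
      stop("training diverged at step ", step, " (non-finite loss)")
    frozen <- if (isBsd && step <= config@freezeSteps) shared else character(0)
    model@params <- .adamStep(model@params, .gcollect(gr), state, config@lr,
                              frozen = frozen)
    curve$loss[step] <- loss
    if (!is.null(valItems) && (step %% valEvery == 0 || step == steps))
      curve$valLoss[step] <- validationLoss(model, valItems)
  }
  list(model = model, curve = curve)
}

#' Inter-resolution transfer-learning experiment on synthetic complexes
#'
#' Pretrains a BRI model, then fine-tunes two BSD models with identical
#' initialization and sampling: one whose shared trunk is initialized from
#' the BRI model (with the trunk frozen for the first quarter of the run)
#' and one trained from scratch. Accelerated convergence shows up as a lower
#' validation loss for the transfer run at the fixed final step.
#'
#' @param nTrain,nVal number of training / validation toy complexes.
#' @param spec grid specification.
#' @param config model configuration.
#' @param seed base seed; all RNG (data, init, sampling) derives from it.
#' @param briSteps,bsdSteps gradient steps for the two stages.
#' @param threshold context radius in Angstrom.
#' @return list(transfer, scratch, briLoss): validation-loss curves (step,
#'   valLoss) of the two BSD runs and the final BRI training loss.
#' @export
runTransferExperiment <- function(nTrain = 20L, nVal = 6L,
                                  spec = gridSpec(8L, 1.5),
                                  config = modelConfig(
                                    dHidden = 16L, nHeads = 2L, nPoints = 2L,
                                    nAttnLayers = 2L,
                                    cnnChannels = c(8L, 16L), headWidth = 16L),
                                  seed = 1L, briSteps = 200L, bsdSteps = 80L,
                                  threshold = 12.0) {
  toys <- lapply(seq_len(nTrain), function(s)
    makeToyComplex(nResidues = 30L, nLigands = 1L, nDecoys = 2L,
                   seed = seed * 1000L + s))
  valToys <- lapply(seq_len(nVal), function(s)
    makeToyComplex(nResidues = 30L, nLigands = 1L, nDecoys = 2L,
                   seed = seed * 1000L + 500L + s))
  briItems <- makeBriItems(toys, spec, threshold)
  bsdItems <- makeBsdItems(toys, spec, threshold)
  bsdVal <- makeBsdItems(valToys, spec, threshold)
  briModel <- initModel("bri", config, spec, seed = seed + 11L)
  briRes <- trainStage(briModel, briItems,
                       trainConfig("bri", lr = 3e-3, batchSize = 4L,
                                   seed = seed + 42L, maxSteps = briSteps))
  bsdInit <- initModel("bsd", config, spec, seed = seed + 12L)
  freeze <- as.integer(bsdSteps %/% 4L)
  cfgT <- trainConfig("bsd_finetune", lr = 1e-3, batchSize = 4L,
                      freezeSteps = freeze, seed = seed + 43L,
                      maxSteps = bsdSteps)
  cfgS <- trainConfig("bsd_finetune", lr = 1e-3, batchSize = 4L,
                      freezeSteps = 0L, seed = seed + 43L,
                      maxSteps = bsdSteps)
  resT <- trainStage(transferInit(briRes$model, bsdInit)$model, bsdItems,
                     cfgT, valItems = bsdVal, valEvery = bsdSteps %/% 4L)
  resS <- trainStage(bsdInit, bsdItems, cfgS, valItems = bsdVal,
                     valEvery = bsdSteps %/% 4L)
  keep <- function(cv) cv[!is.na(cv$valLoss), c("step", "valLoss")]
  list(transfer = keep(resT$curve), scratch = keep(resS$curve),
       briLoss = mean(utils::tail(briRes$curve$loss, 5)))
}

#' Build BRI training items from synthetic (or parsed) complexes
#'
#' One item per positive candidate: the featurized context plus per-residue
#' binary labels (membership in the true binding residues of the DCA-closest
#' ligand).
#'
#' @param toys list of complexes as returned by \code{\link{makeToyComplex}}
#'   (entries with \code{complex} and \code{candidates}).
#' @param spec a \linkS4class{GridSpec}.
#' @param threshold context radius in Angstrom.
#' @param cutoff contact distance for labels.
#' @return list of BRI training items.
#' @export
makeBriItems <- function(toys, spec = gridSpec(), threshold = 17.0,
                         cutoff = 4.0) {
  items <- list()
  for (toy in toys) {
    cx <- toy$complex
    frames <- buildFrames(cx@protein)
    cand <- toy$candidates
    for (j in which(cand$positive)) {
      center <- as.numeric(cand[j, c("x", "y", "z")])
      feat <- tryCatch(
        featurizeCandidate(cx@protein, frames, center, spec, threshold),
        error = function(e) NULL)
      if (is.null(feat)) next
      lig <- cx@ligands[[closestLigand(center, cx@ligands)]]
      tbr <- trueBindingResidues(cx@protein, lig, cutoff)
      items[[length(items) + 1L]] <- list(
        grids = feat$grids, frames = feat$frames,
        labels = as.numeric(feat$indices %in% tbr),
        mask = rep(TRUE, length(feat$indices)))
    }
  }
  items
}

#' Build BSD training items (one per candidate, positive or negative)
#'
#' @inheritParams makeBriItems
#' @return list of BSD training items.
#' @export
makeBsdItems <- function(toys, spec = gridSpec(), threshold = 17.0) {
  items <- list()
  for (toy in toys) {
    cx <- toy$complex
    frames <- buildFrames(cx@protein)
    cand <- toy$candidates
    for (j in seq_len(nrow(cand))) {
      center <- as.numeric(cand[j, c("x", "y", "z")])
      feat <- tryCatch(
        featurizeCandidate(cx@protein, frames, center, spec, threshold),
        error = function(e) NULL)
      if (is.null(feat)) next
      items[[length(items) + 1L]] <- list(
        grids = feat$grids, frames = feat$frames,
        label = as.numeric(cand$positive[j]))
    }
  }
  items
}
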