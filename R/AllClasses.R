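#' @import methods
NULL

## Central S4 containers. Atom tables are plain data.frames with a fixed
## column set; the classes add identity, validity and stable residue ordering
## on top.

.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "isHeavy")

.checkAtomTable <- function(atoms) {
  missing <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing) > 0)
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) > 0 && !all(is.finite(xyz)))
    return("atom coordinates must be finite")
  TRUE
}

#' Protein structure
#'
#' Polymer chains of a macromolecular structure: a flat atom table plus a
#' residue table whose row order (the residue index, 1-based) is the stable
#' positional order of residues in the source file.
#'
#' @slot id structure identifier.
#' @slot atoms data.frame with columns chain, resno, insert, resid, elety,
#'   elesy, x, y, z, isHeavy, residueIndex.
#' @slot residues data.frame with columns chain, resno, insert, resid; row
#'   \code{i} is residue index \code{i}.
#' @export
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame",
                 residues = "data.frame"),
  validity = function(object) {
    msg <- .checkAtomTable(object@atoms)
    if (!isTRUE(msg)) return(msg)
    if (!"residueIndex" %in% names(object@atoms))
      return("atom table lacks residueIndex")
    n <- nrow(object@residues)
    if (nrow(object@atoms) > 0 &&
        (min(object@atoms$residueIndex) < 1 ||
         max(object@atoms$residueIndex) > n))
      return("residueIndex out of range")
    TRUE
  })

#' Ligand
#'
#' A hetero group treated as a ligand. Only heavy atoms are retained; all
#' downstream computations (association, contacts, DCA) are heavy-atom based.
#'
#' @slot id identifier (component code + chain + sequence number).
#' @slot atoms data.frame of heavy atoms (same columns as
#'   \linkS4class{ProteinStructure} atoms, without residueIndex).
#' @export
setClass("Ligand",
  representation(id = "character", atoms = "data.frame"),
  validity = function(object) {
    msg <- .checkAtomTable(object@atoms)
    if (!isTRUE(msg)) return(msg)
    if (nrow(object@atoms) < 1) return("ligand must have at least 1 heavy atom")
    if (!all(object@atoms$isHeavy)) return("ligand atoms must all be heavy")
    TRUE
  })

#' Protein-ligand complex
#'
#' A parsed structure file: the polymer part plus the hetero groups that
#' survived solvent/ion filtering.
#'
#' @slot id complex identifier.
#' @slot protein a \linkS4class{ProteinStructure}.
#' @slot ligands list of \linkS4class{Ligand}.
#' @export
setClass("ProteinComplex",
  representation(id = "character", protein = "ProteinStructure",
                 ligands = "list"),
  validity = function(object) {
    if (!all(vapply(object@ligands, is, logical(1), "Ligand")))
      return("ligands must be a list of Ligand")
    TRUE
  })

#' Per-residue local frame
#'
#' Rigid transform T = (R, t) mapping residue-local coordinates to global
#' coordinates: x_global = R x_local + t, with t the alpha-carbon position.
#'
#' @slot rotation 3x3 rotation matrix (orthonormal, det +1).
#' @slot translation length-3 numeric, the CA position in Angstrom.
#' @export
setClass("LocalFrame",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (length(object@translation) != 3) return("translation must be length 3")
    if (!all(is.finite(R)) || !all(is.finite(object@translation)))
      return("frame entries must be finite")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      return("rotation must be orthonormal (tol 1e-6)")
    if (abs(det(R) - 1) > 1e-6) return("rotation must have det +1")
    TRUE
  })

#' Voxel grid specification
#'
#' Geometry and channel scheme of per-residue local grids. The grid is a cube
#' of \code{edgeVoxels^3} voxels of side \code{voxelSize} Angstrom, centered
#' on the residue alpha carbon, axes aligned with the residue local frame.
#'
#' @slot edgeVoxels even integer, voxels per edge.
#' @slot voxelSize voxel edge length in Angstrom.
#' @slot channelScheme name of a registered channel scheme.
#' @slot channels channel names (derived from the scheme).
#' @export
setClass("GridSpec",
  representation(edgeVoxels = "integer", voxelSize = "numeric",
                 channelScheme = "character", channels = "character"),
  validity = function(object) {
    if (object@edgeVoxels < 2 || object@edgeVoxels %% 2 != 0)
      return("edgeVoxels must be a positive even integer")
    if (object@voxelSize <= 0) return("voxelSize must be > 0")
    if (length(object@channels) < 1) return("at least one channel required")
    TRUE
  })

#' Model configuration
#'
#' Architecture hyper-parameters of the shared trunk and task heads.
#'
#' @slot dHidden hidden width of residue embeddings.
#' @slot nHeads attention heads; must divide dHidden.
#' @slot nPoints attention points per head.
#' @slot nAttnLayers number of geometric attention layers L; layers 1..L-1
#'   form the shared trunk together with the CNN.
#' @slot cnnChannels output channels of each CNN stage (stride-2 bottleneck
#'   residual blocks).
#' @slot headWidth hidden width of the pointwise feed-forward head.
#' @slot squaredDistance use squared point distances in the geometric
#'   attention weight instead of plain norms.
#' @export
setClass("ModelConfig",
  representation(dHidden = "integer", nHeads = "integer", nPoints = "integer",
                 nAttnLayers = "integer", cnnChannels = "integer",
                 headWidth = "integer", squaredDistance = "logical"),
  validity = function(object) {
    vals <- c(object@dHidden, object@nHeads, object@nPoints,
              object@nAttnLayers, object@cnnChannels, object@headWidth)
    if (any(vals < 1)) return("all sizes must be positive")
    if (object@dHidden %% object@nHeads != 0)
      return("dHidden must be divisible by nHeads")
    TRUE
  })

#' Model: parameters + configuration for one task
#'
#' @slot task "bri" (per-residue logits) or "bsd" (pooled druggability logit).
#' @slot config a \linkS4class{ModelConfig}.
#' @slot gridSpec the \linkS4class{GridSpec} the CNN expects.
#' @slot params named list of parameter arrays (flat checkpoint layout).
#' @export
setClass("BspModel",
  representation(task = "character", config = "ModelConfig",
                 gridSpec = "GridSpec", params = "list"),
  validity = function(object) {
    if (!object@task %in% c("bri", "bsd")) return("task must be bri or bsd")
    TRUE
  })

#' Training configuration
#'
#' @slot stage "bri" or "bsd_finetune".
#' @slot lr Adam learning rate.
#' @slot batchSize items per gradient step.
#' @slot freezeSteps number of initial steps during which shared-trunk
#'   parameters are frozen (bsd_finetune stage).
#' @slot auxWeight weight of the auxiliary loss from augmented data.
#' @slot seed RNG seed fixing sampling and initialization.
#' @slot maxSteps gradient steps to run.
#' @export
setClass("TrainConfig",
  representation(stage = "character", lr = "numeric", batchSize = "integer",
                 freezeSteps = "integer", auxWeight = "numeric",
                 seed = "integer", maxSteps = "integer"),
  validity = function(object) {
    if (!object@stage %in% c("bri", "bsd_finetune"))
      return("stage must be bri or bsd_finetune")
    if (object@freezeSteps < 0) return("freezeSteps must be >= 0")
    if (object@auxWeight < 0) return("auxWeight must be >= 0")
    TRUE
  })

#' Per-protein evaluation record
#'
#' One protein's ground-truth ligands and the model's predictions, as consumed
#' by the evaluation metrics. The task definition fixes the number of
#' predictions to the number of ligands n.
#'
#' @slot id protein identifier.
#' @slot ligandAtoms list of n matrices of ligand heavy-atom coordinates.
#' @slot centers n x 3 matrix of predicted binding-site centers.
#' @slot predictedResidues list of n integer vectors (predicted residue sets).
#' @slot trueResidues list of n integer vectors (true binding residues per
#'   ligand, 4 Angstrom heavy-atom rule).
#' @export
setClass("EvalRecord",
  representation(id = "character", ligandAtoms = "list", centers = "matrix",
                 predictedResidues = "list", trueResidues = "list"),
  validity = function(object) {
    n <- length(object@ligandAtoms)
    if (n < 1) return("record must have at least one ligand")
    if (nrow(object@centers) != n)
      return("number of predictions must equal number of ligands")
    if (length(object@predictedResidues) != n ||
        length(object@trueResidues) != n)
      return("residue set lists must have one entry per ligand")
    TRUE
  })

setMethod("show", "ProteinStructure", function(object) {
  cat("ProteinStructure", object@id, "\n",
      " residues:", nrow(object@residues),
      " atoms:", nrow(object@atoms),
      " chains:", paste(unique(object@residues$chain), collapse = ","), "\n")
})

setMethod("show", "Ligand", function(object) {
  cat("Ligand", object@id, "with", nrow(object@atoms), "heavy atoms\n")
})

setMethod("show", "ProteinComplex", function(object) {
  cat("ProteinComplex", object@id, "\n")
  show(object@protein)
  cat("  ligands:", length(object@ligands), "\n")
})

setMethod("show", "LocalFrame", function(object) {
  cat("LocalFrame at CA", sprintf("(%.2f, %.2f, %.2f)\n",
      object@translation[1], object@translation[2], object@translation[3]))
})

setMethod("show", "BspModel", function(object) {
  cat(sprintf("BspModel [%s] dHidden=%d heads=%d points=%d layers=%d (%d params)\n",
              object@task, object@config@dHidden, object@config@nHeads,
              object@config@nPoints, object@config@nAttnLayers,
              sum(vapply(object@params, length, integer(1)))))
})
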