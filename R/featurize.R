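## Residue-local voxelization.
##
## For a candidate center, the residues whose alpha carbon lies within the
## context threshold are selected; each one contributes a cubic occupancy grid
## of the surrounding heavy atoms expressed in that residue's local frame.
## Because binning happens in local coordinates, the grids (and hence the
## model) are invariant under rigid motions of the whole structure.

.BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## Bin edges are displaced by a fixed 1e-6 A. Atoms of the frame's own
## residue lie exactly on the local axes (zero components), i.e. exactly on
## voxel edges; without the displacement their bin would depend on the
## floating-point noise of the global pose. 1e-6 A is far below structural
## coordinate precision (1e-3 A in PDB files) and far above rigid-motion
## round-off (~1e-12 A), so binning is pose-independent.
.BIN_EPS <- 1e-6

.channelSchemes <- new.env(parent = emptyenv())

.registerScheme <- function(name, channels, assign) {
  assign_fun <- assign
  .channelSchemes[[name]] <- list(channels = channels, assign = assign_fun)
}

## default8: element one-hots {C,N,O,S,other} + backbone/sidechain flags + CA
.registerScheme("default8",
  c("elem.C", "elem.N", "elem.O", "elem.S", "elem.other",
    "backbone", "sidechain", "isCA"),
  function(atoms) {
    n <- nrow(atoms)
    M <- matrix(0, n, 8)
    ele <- atoms$elesy
    M[, 1] <- ele == "C"
    M[, 2] <- ele == "N"
    M[, 3] <- ele == "O"
    M[, 4] <- ele == "S"
    M[, 5] <- !(ele %in% c("C", "N", "O", "S"))
    bb <- atoms$elety %in% .BACKBONE_ATOMS
    M[, 6] <- bb
    M[, 7] <- !bb
    M[, 8] <- atoms$elety == "CA"
    M
  })

## elements5: pure one-hot; exactly one channel per atom
.registerScheme("elements5",
  c("elem.C", "elem.N", "elem.O", "elem.S", "elem.other"),
  function(atoms) {
    n <- nrow(atoms)
    M <- matrix(0, n, 5)
    ele <- atoms$elesy
    M[, 1] <- ele == "C"
    M[, 2] <- ele == "N"
    M[, 3] <- ele == "O"
    M[, 4] <- ele == "S"
    M[, 5] <- !(ele %in% c("C", "N", "O", "S"))
    M
  })

#' Grid specification constructor
#'
#' @param edgeVoxels even number of voxels per edge (default 16).
#' @param voxelSize voxel edge in Angstrom (default 1.0).
#' @param channelScheme registered channel scheme name ("default8" or
#'   "elements5").
#' @return a \linkS4class{GridSpec}.
#' @export
gridSpec <- function(edgeVoxels = 16L, voxelSize = 1.0,
                     channelScheme = "default8") {
  scheme <- .channelSchemes[[channelScheme]]
  if (is.null(scheme)) stop("unknown channel scheme: ", channelScheme)
  new("GridSpec", edgeVoxels = as.integer(edgeVoxels),
      voxelSize = as.numeric(voxelSize), channelScheme = channelScheme,
      channels = scheme$channels)
}

#' Select context residues around a candidate center
#'
#' Residues whose alpha carbon lies closer than \code{threshold} to the
#' center, in structure order; residues without buildable frames (NULL entries
#' in \code{frames}) are excluded.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param frames list from \code{\link{buildFrames}}.
#' @param center length-3 candidate center.
#' @param threshold context radius in Angstrom.
#' @return integer vector of residue indices; error when empty.
#' @export
selectContext <- function(structure, frames, center, threshold = 17.0) {
  ok <- which(!vapply(frames, is.null, logical(1)))
  if (length(ok) == 0) stop("no frame-buildable residues in structure")
  ca <- t(vapply(frames[ok], function(f) f@translation, numeric(3)))
  d <- sqrt(colSums((t(ca) - center)^2))
  sel <- ok[d < threshold]
  if (length(sel) == 0)
    stop("empty context: no residue CA within ", threshold,
         " Angstrom of the candidate center")
  sel
}

#' Voxelize the environment of one residue
#'
#' Each heavy atom whose local-frame coordinates fall inside the cube
#' \code{[-D*s/2, D*s/2)^3} increments its channels' containing voxel
#' (half-open bins, nearest-voxel counting); atoms outside are ignored.
#'
#' @param structure a \linkS4class{ProteinStructure} (its heavy atoms are
#'   deposited).
#' @param frame the residue's \linkS4class{LocalFrame}.
#' @param spec a \linkS4class{GridSpec}.
#' @return numeric array of dim (channels, D, D, D).
#' @export
voxelize <- function(structure, frame, spec) {
  D <- spec@edgeVoxels
  s <- spec@voxelSize
  half <- D * s / 2
  at <- structure@atoms[structure@atoms$isHeavy, , drop = FALSE]
  nC <- length(spec@channels)
  vals <- array(0, dim = c(nC, D, D, D))
  if (nrow(at) > 0) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    ## cheap prefilter: bounding sphere of the cube
    d2 <- colSums((t(xyz) - frame@translation)^2)
    near <- d2 <= 3 * half * half + 1e-9
    at <- at[near, , drop = FALSE]
    xyz <- xyz[near, , drop = FALSE]
    if (nrow(at) > 0) {
      local <- (xyz - matrix(frame@translation, nrow(xyz), 3, byrow = TRUE)) %*%
        frame@rotation
      idx <- floor((local + .BIN_EPS) / s) + D / 2   # 0-based voxel index
      inside <- idx[, 1] >= 0 & idx[, 1] < D &
                idx[, 2] >= 0 & idx[, 2] < D &
                idx[, 3] >= 0 & idx[, 3] < D
      if (any(inside)) {
        idx <- idx[inside, , drop = FALSE]
        chan <- .channelSchemes[[spec@channelScheme]]$assign(
          at[inside, , drop = FALSE])
        flat <- idx[, 1] + D * idx[, 2] + D * D * idx[, 3] + 1
        agg <- rowsum(chan, group = flat)
        M <- matrix(0, nC, D^3)
        M[, as.integer(rownames(agg))] <- t(agg)
        vals <- array(M, dim = c(nC, D, D, D))
      }
    }
  }
  vals
}

#' Featurize a candidate binding site
#'
#' Selects the context residues around the center and voxelizes each one in
#' its own local frame.
#'
#' @inheritParams selectContext
#' @param spec a \linkS4class{GridSpec}.
#' @return list with \code{indices} (residue indices), \code{grids} (list of
#'   channel x D x D x D arrays) and \code{frames} (matching LocalFrames).
#' @export
featurizeCandidate <- function(structure, frames, center, spec = gridSpec(),
                               threshold = 17.0) {
  idx <- selectContext(structure, frames, center, threshold)
  list(indices = idx,
       grids = lapply(idx, function(i) voxelize(structure, frames[[i]], spec)),
       frames = frames[idx])
}
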