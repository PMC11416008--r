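## Candidate binding-site centers.
##
## Candidates normally come from Fpocket: each pocket is a set of heavy atoms
## and the candidate center is the (mass-weighted) mean of their coordinates.
## A plain (id, x, y, z) table is accepted as an alternative source so that
## any external pocket generator can be used.

#' Parse an Fpocket output directory
#'
#' Reads the per-pocket atom files (\code{pocket<N>_atm.pdb}) from an Fpocket
#' run, either directly in \code{path} or in its \code{pockets/} subdirectory.
#'
#' @param path Fpocket output directory.
#' @return list of entries \code{list(id, atoms)} ordered by pocket number;
#'   unparseable pocket files are skipped with a warning.
#' @export
parseFpocketDir <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  dirs <- c(file.path(path, "pockets"), path)
  files <- character(0)
  for (d in dirs) {
    if (!dir.exists(d)) next
    files <- list.files(d, pattern = "^pocket[0-9]+_atm\\.(pdb|pqr)$",
                        full.names = TRUE)
    if (length(files) > 0) break
  }
  if (length(files) == 0)
    stop("no Fpocket pocket atom files found under ", path)
  num <- as.integer(sub("^pocket([0-9]+)_atm\\..*$", "\\1", basename(files)))
  files <- files[order(num)]
  num <- sort(num)
  out <- list()
  for (i in seq_along(files)) {
    at <- tryCatch({
      pdb <- bio3d::read.pdb(files[i], verbose = FALSE, multi = FALSE)
      .atomTable(pdb$atom)
    }, error = function(e) {
      warning("skipping unparseable pocket file ", basename(files[i]), ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(at)) next
    out[[length(out) + 1L]] <- list(id = num[i], atoms = at)
  }
  out
}

#' Read a plain candidate-center table
#'
#' Alternative to Fpocket output: a whitespace- or comma-delimited table with
#' columns id, x, y, z.
#'
#' @param path table file.
#' @return data.frame with columns id, x, y, z.
#' @export
readCenterTable <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("center table must have columns id, x, y, z")
  tab[, need]
}

.massEnv <- new.env(parent = emptyenv())

## standard atomic masses looked up from bio3d's periodic table
.elementMass <- function(symbols) {
  if (is.null(.massEnv$tab)) {
    e <- new.env()
    utils::data("elements", package = "bio3d", envir = e)
    .massEnv$tab <- stats::setNames(e$elements$mass,
                                    toupper(as.character(e$elements$symb)))
  }
  unname(.massEnv$tab[toupper(symbols)])
}

#' Candidate center of a pocket atom set
#'
#' The center of mass of the pocket's heavy atoms; with
#' \code{weighting = "uniform"} the unweighted barycenter is used instead.
#'
#' @param atoms atom data.frame (as in \linkS4class{ProteinStructure}).
#' @param weighting "mass" or "uniform".
#' @return length-3 numeric center.
#' @export
candidateCenter <- function(atoms, weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  at <- atoms[atoms$isHeavy, , drop = FALSE]
  if (nrow(at) == 0) stop("candidateCenter: no heavy atoms")
  w <- if (weighting == "mass") {
    m <- .elementMass(at$elesy)
    m[is.na(m)] <- 12.011  # unknown elements fall back to carbon
    m
  } else rep(1, nrow(at))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  as.numeric(colSums(xyz * w) / sum(w))
}

#' Candidate centers from any supported source
#'
#' @param source an Fpocket directory, a center-table path, or the list
#'   returned by \code{\link{parseFpocketDir}}.
#' @param weighting passed to \code{\link{candidateCenter}}.
#' @return data.frame with columns rank, id, x, y, z; rank is the source
#'   ordering (Fpocket pocket number order or table row order).
#' @export
candidateCenters <- function(source, weighting = c("mass", "uniform")) {
  weighting <- match.arg(weighting)
  if (is.character(source) && length(source) == 1 && dir.exists(source))
    source <- parseFpocketDir(source)
  if (is.character(source) && length(source) == 1 && file.exists(source)) {
    tab <- readCenterTable(source)
    return(data.frame(rank = seq_len(nrow(tab)), id = tab$id,
                      x = tab$x, y = tab$y, z = tab$z,
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.list(source))
  centers <- t(vapply(source, function(p)
    candidateCenter(p$atoms, weighting), numeric(3)))
  data.frame(rank = seq_along(source),
             id = vapply(source, function(p) as.character(p$id), character(1)),
             x = centers[, 1], y = centers[, 2], z = centers[, 3],
             stringsAsFactors = FALSE)
}
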