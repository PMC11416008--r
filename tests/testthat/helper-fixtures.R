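# Shared fixtures and small helpers; everything is generated in code.

randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  Q <- Q %*% diag(d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

tinySpec <- function() gridSpec(8L, 1.5)

tinyConfig <- function(nAttnLayers = 2L)
  modelConfig(dHidden = 16L, nHeads = 2L, nPoints = 2L,
              nAttnLayers = nAttnLayers, cnnChannels = c(8L, 16L),
              headWidth = 16L)

# one cached toy complex + frames + featurized planted candidate
.fixtureEnv <- new.env()
toyFixture <- function() {
  if (is.null(.fixtureEnv$fx)) {
    toy <- makeToyComplex(nResidues = 30L, nLigands = 1L, nDecoys = 2L,
                          seed = 3L)
    frames <- buildFrames(toy$complex@protein)
    center <- as.numeric(toy$candidates[1, c("x", "y", "z")])
    feat <- featurizeCandidate(toy$complex@protein, frames, center,
                               tinySpec(), threshold = 12)
    .fixtureEnv$fx <- list(toy = toy, frames = frames, center = center,
                           feat = feat)
  }
  .fixtureEnv$fx
}

# a tiny hand-built two-chain structure with a placed hetero group, for
# association / contact tests with exactly known distances
twoChainStructure <- function(dAB = 20) {
  mkres <- function(chain, resno, origin) {
    data.frame(chain = chain, resno = resno, insert = "", resid = "GLY",
               elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
               x = origin[1] + c(0, 1.45, 2.0),
               y = origin[2] + c(1.0, 0, 0),
               z = origin[3], isHeavy = TRUE, stringsAsFactors = FALSE)
  }
  at <- rbind(mkres("A", 1, c(0, 0, 0)), mkres("A", 2, c(3.8, 0, 0)),
              mkres("B", 1, c(dAB, 0, 0)))
  GeoPocket:::.buildProteinStructure("twochain", at)
}

mkLigandAt <- function(xyz, id = "LIG_L_1") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  new("Ligand", id = id,
      atoms = data.frame(chain = "L", resno = 1, insert = "", resid = "LIG",
                         elety = paste0("C", seq_len(n)),
                         elesy = rep("C", n), x = xyz[, 1], y = xyz[, 2],
                         z = xyz[, 3], isHeavy = TRUE,
                         stringsAsFactors = FALSE))
}
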