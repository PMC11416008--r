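test_that("readStructure counts polymer residues and hetero ligands", {
  toy <- makeToyComplex(nResidues = 12L, nLigands = 1L, nDecoys = 0L,
                        seed = 7L)
  path <- file.path(tempdir(), "rs1.pdb")
  writeComplexPdb(toy$complex, path)
  cx <- readStructure(path)
  expect_s4_class(cx, "ProteinComplex")
  expect_equal(nResidues(cx), 12L)
  expect_length(ligands(cx), 1L)
  expect_equal(nrow(ligands(cx)[[1]]@atoms),
               nrow(toy$complex@ligands[[1]]@atoms))
})

test_that("waters and excluded solvents never become ligands", {
  toy <- makeToyComplex(nResidues = 8L, nLigands = 1L, nDecoys = 0L,
                        seed = 8L)
  cx <- toy$complex
  # relabel the only hetero group as water
  cx@ligands[[1]]@atoms$resid <- "HOH"
  path <- file.path(tempdir(), "rs2.pdb")
  writeComplexPdb(cx, path)
  expect_length(ligands(readStructure(path)), 0L)
  # same for a buffer on the default exclusion list
  cx@ligands[[1]]@atoms$resid <- "GOL"
  writeComplexPdb(cx, path)
  expect_length(ligands(readStructure(path)), 0L)
})

test_that("write + read round-trips coordinates to 1e-3 Angstrom", {
  toy <- makeToyComplex(nResidues = 15L, nLigands = 1L, nDecoys = 1L,
                        seed = 9L)
  path <- file.path(tempdir(), "rs3.pdb")
  writeComplexPdb(toy$complex, path)
  cx <- readStructure(path)
  expect_lt(max(abs(atomCoords(cx) - atomCoords(toy$complex))), 1e-3 + 1e-9)
  expect_lt(max(abs(atomCoords(ligands(cx)[[1]]) -
                    atomCoords(toy$complex@ligands[[1]]))), 1e-3 + 1e-9)
})

test_that("readStructure rejects missing and polymer-free files", {
  expect_error(readStructure(file.path(tempdir(), "nope.pdb")), "no such")
})

test_that("axis-aligned backbone gives the identity frame and translation
           equivariance holds", {
  f <- buildFrame(list(CA = c(0, 0, 0), C = c(1, 0, 0), N = c(0, 1, 0)))
  expect_equal(frameRotation(f), diag(3), tolerance = 1e-12)
  expect_equal(frameTranslation(f), c(0, 0, 0))
  f2 <- buildFrame(list(CA = c(1, 2, 3), C = c(2, 2, 3), N = c(1, 3, 3)))
  expect_equal(frameRotation(f2), diag(3), tolerance = 1e-12)
  expect_equal(frameTranslation(f2), c(1, 2, 3))
})

test_that("frames are equivariant under rigid motions and stay in SO(3)", {
  set.seed(41)
  for (rep in 1:40) {
    bb <- list(CA = rnorm(3), C = rnorm(3), N = rnorm(3))
    f <- tryCatch(buildFrame(bb), error = function(e) NULL)
    if (is.null(f)) next
    Q <- randomRotation(); tr <- runif(3, -10, 10)
    bb2 <- lapply(bb, function(v) as.numeric(Q %*% v) + tr)
    f2 <- buildFrame(bb2)
    expect_lt(max(abs(frameRotation(f2) - Q %*% frameRotation(f))), 1e-6)
    expect_lt(max(abs(frameTranslation(f2) -
                      (as.numeric(Q %*% frameTranslation(f)) + tr))), 1e-6)
  }
  # orthonormality, det +1 on many random synthetic residues
  set.seed(42)
  worstOrtho <- 0; worstDet <- 0
  for (rep in 1:1000) {
    f <- tryCatch(buildFrame(list(CA = rnorm(3), C = rnorm(3), N = rnorm(3))),
                  error = function(e) NULL)
    if (is.null(f)) next
    R <- frameRotation(f)
    worstOrtho <- max(worstOrtho, max(abs(crossprod(R) - diag(3))))
    worstDet <- max(worstDet, abs(det(R) - 1))
  }
  expect_lt(worstOrtho, 1e-6)
  expect_lt(worstDet, 1e-6)
})

test_that("frame construction fails on incomplete or collinear backbones", {
  expect_error(buildFrame(list(CA = c(0, 0, 0), C = c(1, 0, 0), N = NULL)),
               "unbuildable")
  expect_error(buildFrame(list(CA = c(0, 0, 0), C = c(1, 0, 0),
                               N = c(2, 0, 0))), "collinear")
})

test_that("associatedChains applies the 4 Angstrom heavy-atom rule", {
  s <- twoChainStructure(dAB = 30)
  # chain A CA of residue 1 is at (1.45, 0, 0); place a ligand atom 3.9 away
  lig <- mkLigandAt(c(1.45 + 3.9, 0, 0) + c(0, 0, 0))
  # nearest A atom: C of residue 1 at (2.0,0,0) -> 3.35; within 4
  expect_equal(associatedChains(lig, s), "A")
  # 4.1 Angstrom away from everything in either chain
  lig2 <- mkLigandAt(c(3.8 + 2.0 + 4.1, 8, 0))
  expect_length(associatedChains(lig2, s), 0L)
  # ligand between two chains at ~3 each -> both chains
  s2 <- twoChainStructure(dAB = 10)
  # A's rightmost atom: C of res2 at (5.8, 0, 0); B's leftmost: N at (10,1,0)
  lig3 <- mkLigandAt(c(8, 0.6, 0))
  expect_setequal(associatedChains(lig3, s2), c("A", "B"))
})

test_that("associatedChains agrees with an all-pairs brute-force oracle", {
  set.seed(13)
  for (rep in 1:10) {
    toy <- makeToyComplex(nResidues = 20L, nLigands = 1L, nDecoys = 0L,
                          seed = 100L + rep)
    s <- toy$complex@protein
    lig <- mkLigandAt(matrix(rnorm(9, sd = 8), 3, 3) +
                        matrix(colMeans(atomCoords(s)), 3, 3, byrow = TRUE))
    cutoff <- runif(1, 3, 8)
    got <- associatedChains(lig, s, cutoff)
    # oracle: loop every atom pair
    A <- s@atoms[s@atoms$isHeavy, ]
    L <- atomCoords(lig, heavyOnly = TRUE)
    oracle <- character(0)
    for (ch in unique(A$chain)) {
      B <- as.matrix(A[A$chain == ch, c("x", "y", "z")])
      mind <- Inf
      for (i in seq_len(nrow(B))) for (j in seq_len(nrow(L)))
        mind <- min(mind, sqrt(sum((B[i, ] - L[j, ])^2)))
      if (mind < cutoff) oracle <- c(oracle, ch)
    }
    expect_setequal(got, oracle)
  }
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  # two conformers of one atom; B has higher occupancy
  lines <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       5.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   GLY A   1       2.000   1.000   0.000  1.00  0.00           C",
    "END")
  path <- file.path(tempdir(), "alt.pdb")
  writeLines(lines, path)
  cx <- readStructure(path)
  at <- proteinStructure(cx)@atoms
  expect_equal(sum(at$elety == "N"), 1L)
  expect_equal(at$x[at$elety == "N"], 5.0)
})
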