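test_that("alignment records enforce colinearity", {
  expect_error(alignmentRecord("q", "A", "t", "A", c(1, 3, 2), c(1, 2, 3)),
               "strictly increasing")
  expect_error(alignmentRecord("q", "A", "t", "A", c(1, 2), c(2, 2)),
               "strictly increasing")
  a <- alignmentRecord("q", "A", "t", "A", c(1, 5, 9), c(2, 6, 7))
  expect_s3_class(a, "AlignmentRecord")
})

test_that("A3M parsing yields the match-state pairwise alignments", {
  path <- file.path(tempdir(), "toy.a3m")
  writeLines(c(">seed_A", "MKLV", ">tgt_B", "M-lKV"), path)
  # columns: M (match q1,t1), - (deletion, q2), l (insertion, t2),
  #          K (q3,t3), V (q4,t4)
  als <- readA3m(path)
  expect_length(als, 1L)
  a <- als[[1]]
  expect_equal(a$queryId, "seed")
  expect_equal(a$targetChain, "B")
  expect_equal(a$qpos, c(1L, 3L, 4L))
  expect_equal(a$tpos, c(1L, 3L, 4L))
})

test_that("singleChainLigands keeps exactly-one-chain associations", {
  s <- twoChainStructure(dAB = 10)
  near_A <- mkLigandAt(c(2, 0, 3), id = "LA")      # 3 A from A only
  between <- mkLigandAt(c(8, 0.6, 0), id = "LAB")  # ~3 A from both chains
  cx <- new("ProteinComplex", id = "m", protein = s,
            ligands = list(near_A, between))
  scl <- singleChainLigands(cx)
  expect_length(scl, 1L)
  expect_equal(scl[[1]]$chain, "A")
  expect_equal(scl[[1]]$ligand@id, "LA")
  # a chain can carry several single-chain ligands
  near_A2 <- mkLigandAt(c(5.8, 0, 3), id = "LA2")
  cx2 <- new("ProteinComplex", id = "m2", protein = s,
             ligands = list(near_A, near_A2))
  expect_length(singleChainLigands(cx2), 2L)
})

test_that("isPreserving applies the at-least-half rule at the boundary", {
  toy <- makeToyComplex(nResidues = 24L, nLigands = 1L, nDecoys = 0L,
                        seed = 31L)
  s <- toy$complex@protein
  lig <- toy$complex@ligands[[1]]
  contacts <- contactResidues(s, "A", lig, cutoff = 6)
  expect_gt(length(contacts), 1L)
  # align exactly ceiling(half) of the contacts -> preserving
  half <- ceiling(length(contacts) / 2)
  al <- alignmentRecord(s@id, "A", "t", "A", sort(contacts)[1:half],
                        seq_len(half))
  pres <- isPreserving(s, "A", lig, al, cutoff = 6)
  expect_true(pres$preserving)
  expect_equal(sort(pres$alignedContacts), sort(contacts)[1:half])
  # one fewer -> not preserving (when that drops below half)
  if (half - 1 < length(contacts) / 2 && half > 1) {
    al2 <- alignmentRecord(s@id, "A", "t", "A", sort(contacts)[1:(half - 1)],
                           seq_len(half - 1))
    expect_false(isPreserving(s, "A", lig, al2, cutoff = 6)$preserving)
  }
  # all contacts aligned -> preserving with full subset
  al3 <- alignmentRecord(s@id, "A", "t", "A", contacts,
                         seq_along(contacts))
  pres3 <- isPreserving(s, "A", lig, al3, cutoff = 6)
  expect_true(pres3$preserving)
  expect_equal(pres3$alignedContacts, contacts)
})

test_that("proxyCenter is the mean target CA and is rigidly equivariant", {
  toy <- makeToyComplex(nResidues = 10L, nLigands = 1L, nDecoys = 0L,
                        seed = 33L)
  s <- toy$complex@protein
  cas <- t(vapply(1:3, function(i) backboneCoords(s, i)$CA, numeric(3)))
  expect_equal(proxyCenter(s, "A", 1:3), colMeans(cas))
  expect_equal(proxyCenter(s, "A", 2L),
               backboneCoords(s, 2)$CA)
  set.seed(44)
  Q <- randomRotation(); tr <- runif(3, -10, 10)
  s2 <- rigidTransform(s, Q, tr)
  expect_equal(proxyCenter(s2, "A", 1:3),
               as.numeric(Q %*% proxyCenter(s, "A", 1:3)) + tr,
               tolerance = 1e-10)
})

test_that("site candidates are labeled by the 7.5/30 Angstrom thresholds", {
  proxy <- matrix(c(0, 0, 0), 1, 3)
  centers <- rbind(c(5, 0, 0), c(15, 0, 0), c(40, 0, 0))
  lab <- labelSiteCandidates(centers, proxy)
  expect_equal(lab$label, c("positive", "excluded", "negative"))
  expect_equal(lab$supporting[[1]], 1L)
  expect_error(labelSiteCandidates(centers, proxy, lower = 30, upper = 7.5),
               "lower threshold")
})

test_that("vote fractions reproduce the two-triplet worked example", {
  sets <- readCorrespondenceSets(
    system.file("extdata", "q9vc32_correspondences.tsv", package = "GeoPocket"))
  expect_length(sets, 2L)
  votes <- voteResidueLabels(sets)
  expect_equal(unname(votes["ASP248"]), 1.0)
  expect_equal(unname(votes["PHE156"]), 0.5)
  expect_equal(unname(votes["GLY112"]), 0.5)
  # every residue shared by both correspondences is 1.0, the rest 0.5
  purple <- c("ALA119", "VAL132", "LYS134", "VAL165", "MET181", "GLU182",
              "TYR183", "ALA184", "PHE237", "ASP248")
  expect_equal(unname(votes[purple]), rep(1.0, 10))
  expect_true(all(votes[setdiff(names(votes), purple)] == 0.5))
})

test_that("vote fraction edge cases: single triplet and 1-of-4 coverage", {
  v1 <- voteResidueLabels(list(c(3, 5, 9)))
  expect_equal(unname(v1), c(1, 1, 1))
  v2 <- voteResidueLabels(list(c(1, 2), c(2, 3), c(2, 4), c(2, 5)))
  expect_equal(unname(v2["1"]), 0.25)
  expect_equal(unname(v2["2"]), 1.0)
  expect_true(all(v2 > 0 & v2 <= 1))
})

test_that("augmentation closure: an identity alignment recovers the seed's
           own labels", {
  toy <- makeToyComplex(nResidues = 28L, nLigands = 1L, nDecoys = 2L,
                        seed = 35L)
  cx <- toy$complex
  pair <- makeAlignmentPair(cx@protein, 0, 0, seed = 1L)
  expect_equal(pair$alignment$qpos, pair$alignment$tpos)
  targets <- list()
  targets[[pair$target@id]] <- pair$target
  candFun <- function(tgt) toy$candidates[, c("id", "x", "y", "z")]
  aug <- buildAugmentedDataset(list(cx), targets, list(pair$alignment),
                               candFun)
  expect_length(aug, 1L)
  res <- aug[[pair$target@id]]
  # the planted candidate is positive, decoys are not positive
  expect_equal(res$sites$label[1], "positive")
  expect_false(any(res$sites$label[-1] == "positive"))
  # vote labels 1.0 exactly on the contact residues
  votes <- res$residues[[as.character(toy$candidates$id[1])]]
  contacts <- contactResidues(cx@protein, "A", cx@ligands[[1]])
  expect_setequal(as.integer(names(votes)), contacts)
  expect_true(all(votes == 1.0))
})

test_that("the augmented dataset is empty without alignments and is
           independent of alignment input order", {
  toy <- makeToyComplex(nResidues = 20L, nLigands = 1L, nDecoys = 1L,
                        seed = 36L)
  cx <- toy$complex
  expect_length(buildAugmentedDataset(list(cx), list(), list(),
                                      function(t) toy$candidates), 0L)
  p1 <- makeAlignmentPair(cx@protein, 0, 0.2, seed = 2L)
  p2 <- makeAlignmentPair(cx@protein, 0, 0.2, seed = 3L,
                          targetId = "homB")
  targets <- list(); targets[[p1$target@id]] <- p1$target
  targets[["homB"]] <- p2$target
  candFun <- function(tgt) toy$candidates[, c("id", "x", "y", "z")]
  a12 <- buildAugmentedDataset(list(cx), targets,
                               list(p1$alignment, p2$alignment), candFun)
  a21 <- buildAugmentedDataset(list(cx), targets,
                               list(p2$alignment, p1$alignment), candFun)
  expect_identical(a12, a21)
})
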