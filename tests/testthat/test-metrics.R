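test_that("dca is the minimum center-to-heavy-atom distance", {
  lig <- mkLigandAt(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(dca(c(0, 0, 0), lig), 0)
  expect_equal(dca(c(5, 0, 0), lig), 2)
  set.seed(61)
  for (rep in 1:20) {
    L <- matrix(rnorm(15), 5, 3); cen <- rnorm(3)
    expect_equal(dca(cen, L),
                 min(apply(L, 1, function(a) sqrt(sum((a - cen)^2)))))
  }
})

test_that("closestLigand breaks ties toward the lowest index", {
  l1 <- mkLigandAt(c(2, 0, 0)); l2 <- mkLigandAt(c(-2, 0, 0))
  expect_equal(closestLigand(c(0, 0, 0), list(l1, l2)), 1L)
  expect_equal(closestLigand(c(0, 0, 0), list(l1)), 1L)
  expect_equal(closestLigand(c(-1, 0, 0), list(l1, l2)), 2L)
})

test_that("success rate reproduces hand-computed F1 examples", {
  # perfect detection -> 1.0
  rec <- evalRecord("a", list(matrix(c(0, 0, 0), 1, 3)),
                    matrix(c(1, 0, 0), 1, 3), list(1:3), list(1:3))
  expect_equal(f1SuccessRate(list(rec)), 1.0)
  # one protein, 2 ligands, both predictions detect only ligand 1:
  # P = 1, R = 1/2, F1 = 2/3
  rec2 <- evalRecord("b",
                     list(matrix(c(0, 0, 0), 1, 3),
                          matrix(c(100, 0, 0), 1, 3)),
                     rbind(c(1, 0, 0), c(0, 1, 0)),
                     list(integer(0), integer(0)),
                     list(integer(0), integer(0)))
  expect_equal(f1SuccessRate(list(rec2)), 2 / 3)
  # two proteins with n = 1 (F1 = 1) and n = 3 (F1 = 0): weighted 1/4
  rec3 <- evalRecord("c", list(matrix(c(0, 0, 0), 1, 3)),
                     matrix(c(0, 0, 0), 1, 3), list(1L), list(1L))
  far <- lapply(1:3, function(k) matrix(c(100 * k, 0, 0), 1, 3))
  rec4 <- evalRecord("d", far, matrix(0, 3, 3),
                     list(1L, 2L, 3L), list(1L, 2L, 3L))
  expect_equal(f1SuccessRate(list(rec3, rec4)), 0.25)
})

test_that("IOU examples: equality, half-overlap, disjoint, both-empty", {
  mkRec <- function(br, tbr) {
    evalRecord("x", list(matrix(c(0, 0, 0), 1, 3)), matrix(c(1, 0, 0), 1, 3),
               list(br), list(tbr))
  }
  expect_equal(avgIou(list(mkRec(1:3, 1:3))), 1.0)
  expect_equal(avgIou(list(mkRec(1:3, 2:4))), 0.5)
  expect_equal(avgIou(list(mkRec(1:3, 4:6))), 0.0)
  expect_equal(avgIou(list(mkRec(integer(0), integer(0)))), 1.0)
  expect_equal(avgIou(list(mkRec(integer(0), 1:2))), 0.0)
})

test_that("conditional IOU keeps only detected predictions", {
  # ligand 1 detected (iou 0.6), ligand 2 prediction 10 A away (iou 0.1)
  rec <- evalRecord("y",
                    list(matrix(c(0, 0, 0), 1, 3),
                         matrix(c(50, 0, 0), 1, 3)),
                    rbind(c(1, 0, 0), c(60, 0, 0)),
                    list(1:5, 1:10),
                    list(c(1:3, 11:12), 10:19))
  # iou_1 = |{1,2,3}|/|{1..5,11,12}| = 3/7? recompute: pred 1:5, true {1,2,3,11,12}
  # int = 3, union = 7 -> 3/7; detected
  # pred2 1:10 vs true 10:19 -> int 1, union 19 -> 1/19; NOT detected (10 A)
  expect_equal(conditionalIou(list(rec)), 3 / 7)
  expect_equal(avgIou(list(rec)), (3 / 7 + 1 / 19) / 2)
  # no detections -> NaN with warning
  recFar <- evalRecord("z", list(matrix(c(0, 0, 0), 1, 3)),
                       matrix(c(50, 0, 0), 1, 3), list(1L), list(1L))
  expect_warning(v <- conditionalIou(list(recFar)), "undefined")
  expect_true(is.nan(v))
})

test_that("aggregate metrics match the naive oracle on 200 random records", {
  records <- randomRecords(200, seed = 71)
  oracle <- naiveMetrics(records)
  expect_equal(f1SuccessRate(records), oracle$f1, tolerance = 1e-12)
  expect_equal(avgIou(records), oracle$iou, tolerance = 1e-12)
  expect_equal(conditionalIou(records), oracle$condIou, tolerance = 1e-12)
  expect_true(f1SuccessRate(records) >= 0 && f1SuccessRate(records) <= 1)
  expect_true(avgIou(records) >= 0 && avgIou(records) <= 1)
})

test_that("metrics are invariant under a global rigid motion", {
  records <- randomRecords(20, seed = 73)
  set.seed(74)
  Q <- randomRotation(); tr <- runif(3, -20, 20)
  moved <- lapply(records, function(r) {
    r@ligandAtoms <- lapply(r@ligandAtoms, function(L)
      sweep(L %*% t(Q), 2, tr, "+"))
    r@centers <- sweep(r@centers %*% t(Q), 2, tr, "+")
    r
  })
  expect_equal(f1SuccessRate(moved), f1SuccessRate(records),
               tolerance = 1e-10)
  expect_equal(avgIou(moved), avgIou(records), tolerance = 1e-10)
  expect_equal(conditionalIou(moved), conditionalIou(records),
               tolerance = 1e-10)
})

test_that("restricting records to detected predictions equates the two IOU
           metrics", {
  records <- randomRecords(50, seed = 75)
  # records whose predictions are all detected: avgIou equals conditionalIou
  recs2 <- list()
  for (r in records) {
    terms <- GeoPocket:::.recordTerms(r)
    if (length(terms$S) != length(r@ligandAtoms)) next
    recs2[[length(recs2) + 1L]] <- r
  }
  if (length(recs2) > 0)
    expect_equal(avgIou(recs2), conditionalIou(recs2), tolerance = 1e-12)
})

test_that("rank probability equals the combinatorial closed form and its
           exhaustive enumeration", {
  expect_equal(rankProbability(15, 5, 6), 6 / 3003)
  expect_equal(round(100 * rankProbability(15, 5, 6), 1), 0.2)
  expect_equal(rankProbability(7, 7, 7), 1.0)
  expect_error(rankProbability(5, 6, 6), "require")
  # exhaustive enumeration over all C(15,5) subsets
  combs <- utils::combn(15, 5)
  inside <- sum(apply(combs, 2, function(s) all(s <= 6)))
  expect_equal(rankProbability(15, 5, 6), inside / ncol(combs))
})
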