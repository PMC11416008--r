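# Independent dense re-computation of one geometric attention layer, written
# naively with explicit loops; used as the oracle for the package's
# implementation.
naiveAttention <- function(params, l, config, X, frames) {
  n <- nrow(X); d <- config@dHidden; H <- config@nHeads; P <- config@nPoints
  dh <- d / H
  pre <- sprintf("attn%d.", l)
  gamma <- log(1 + exp(params[[paste0(pre, "rho")]])) # softplus
  out <- matrix(0, n, d)
  applyT <- function(i, v) as.numeric(frames[[i]]@rotation %*% v +
                                        frames[[i]]@translation)
  invT <- function(i, v) as.numeric(t(frames[[i]]@rotation) %*%
                                      (v - frames[[i]]@translation))
  Q <- X %*% params[[paste0(pre, "Wq")]]
  K <- X %*% params[[paste0(pre, "Wk")]]
  V <- X %*% params[[paste0(pre, "Wv")]]
  QP <- X %*% params[[paste0(pre, "Wqp")]]
  KP <- X %*% params[[paste0(pre, "Wkp")]]
  VP <- X %*% params[[paste0(pre, "Wvp")]]
  pt <- function(M, i, h, p) M[i, ((h - 1) * P + p - 1) * 3 + 1:3]
  concat <- matrix(0, n, H * (dh + 4 * P))
  for (h in 1:H) {
    sc <- (h - 1) * dh + 1:dh
    for (i in 1:n) {
      logits <- numeric(n)
      for (j in 1:n) {
        wstd <- sum(Q[i, sc] * K[j, sc]) / sqrt(d)
        wgeo <- 0
        for (p in 1:P) {
          dv <- applyT(i, pt(QP, i, h, p)) - applyT(j, pt(KP, j, h, p))
          dd <- sum(dv^2)
          wgeo <- wgeo + if (config@squaredDistance) dd else sqrt(dd + 1e-12)
        }
        wgeo <- wgeo / sqrt(P)
        logits[j] <- (wstd - log(1 + gamma[h]) * wgeo) / sqrt(2)
      }
      w <- exp(logits - max(logits)); w <- w / sum(w)
      osc <- numeric(dh)
      for (j in 1:n) osc <- osc + w[j] * V[j, sc]
      base <- (h - 1) * (dh + 4 * P)
      concat[i, base + 1:dh] <- osc
      for (p in 1:P) {
        s <- c(0, 0, 0)
        for (j in 1:n) s <- s + w[j] * applyT(j, pt(VP, j, h, p))
        op <- invT(i, s)
        concat[i, base + dh + (p - 1) * 3 + 1:3] <- op
        concat[i, base + dh + 3 * P + p] <- sqrt(sum(op^2) + 1e-12)
      }
    }
  }
  sweep(concat %*% params[[paste0(pre, "Wf")]], 2,
        params[[paste0(pre, "bf")]], "+")
}

test_that("attention layer matches an independent dense recomputation", {
  fx <- toyFixture()
  model <- initModel("bri", tinyConfig(), tinySpec(), seed = 4L)
  set.seed(55)
  n <- 6
  X <- matrix(rnorm(n * 16), n, 16)
  frames <- fx$feat$frames[1:n]
  for (l in 1:2) {
    got <- attentionLayer(model, l, X, frames)
    expected <- naiveAttention(model@params, l, model@config, X, frames)
    expect_equal(got, expected, tolerance = 1e-10)
  }
  # squared-distance variant too
  m2 <- initModel("bri", tinyConfig(), tinySpec(), seed = 4L)
  m2@config@squaredDistance <- TRUE
  expect_equal(attentionLayer(m2, 1, X, frames),
               naiveAttention(m2@params, 1, m2@config, X, frames),
               tolerance = 1e-10)
})

test_that("attention weights row-normalize and a single token gets weight 1", {
  fx <- toyFixture()
  model <- initModel("bri", tinyConfig(), tinySpec(), seed = 6L)
  set.seed(8)
  X <- matrix(rnorm(5 * 16), 5, 16)
  W <- attentionWeights(model, 1, 1, X, fx$feat$frames[1:5])
  expect_equal(unname(rowSums(W)), rep(1, 5), tolerance = 1e-6)
  W1 <- attentionWeights(model, 1, 2, X[1, , drop = FALSE],
                         fx$feat$frames[1])
  expect_equal(as.numeric(W1), 1)
})

test_that("with gamma = 0 the weights reduce to standard scaled dot-product
           attention", {
  fx <- toyFixture()
  model <- initModel("bri", tinyConfig(), tinySpec(), seed = 9L)
  model@params[["attn1.rho"]][] <- -40          # softplus(-40) ~ 0
  model@params[["attn1.Wqp"]][] <- 0
  model@params[["attn1.Wkp"]][] <- 0
  set.seed(10)
  X <- matrix(rnorm(6 * 16), 6, 16)
  W <- attentionWeights(model, 1, 1, X, fx$feat$frames[1:6])
  d <- 16; dh <- 8
  Q <- X %*% model@params[["attn1.Wq"]][, 1:dh]
  K <- X %*% model@params[["attn1.Wk"]][, 1:dh]
  S <- tcrossprod(Q, K) / (sqrt(d) * sqrt(2))
  ref <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  expect_equal(W, ref, tolerance = 1e-10)
})

test_that("token-independent geometric offsets cancel in the softmax", {
  # identity frames at the origin and zero k-point maps: the geometric term
  # is constant across j for each i, so weights equal the standard-only case
  model <- initModel("bri", tinyConfig(), tinySpec(), seed = 12L)
  model@params[["attn1.Wkp"]][] <- 0
  idFrames <- replicate(6, new("LocalFrame", rotation = diag(3),
                               translation = c(0, 0, 0)), simplify = FALSE)
  set.seed(11)
  X <- matrix(rnorm(6 * 16), 6, 16)
  W <- attentionWeights(model, 1, 1, X, idFrames)
  d <- 16; dh <- 8
  Q <- X %*% model@params[["attn1.Wq"]][, 1:dh]
  K <- X %*% model@params[["attn1.Wk"]][, 1:dh]
  S <- tcrossprod(Q, K) / (sqrt(d) * sqrt(2))
  ref <- t(apply(S, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  expect_equal(W, ref, tolerance = 1e-10)
})

test_that("cnnExtract shares weights: identical grids give identical
           embeddings, order permutes with the input", {
  fx <- toyFixture()
  model <- initModel("bri", tinyConfig(), tinySpec(), seed = 3L)
  grids <- fx$feat$grids[1:4]
  E <- cnnExtract(model, grids)
  expect_identical(E[1, ], cnnExtract(model, grids[1])[1, ])
  E2 <- cnnExtract(model, grids[c(3, 1, 4, 2)])
  expect_equal(E2, E[c(3, 1, 4, 2), ])
  # byte-identical grids -> identical rows
  E3 <- cnnExtract(model, list(grids[[2]], grids[[2]]))
  expect_identical(E3[1, ], E3[2, ])
})

test_that("zero and nonzero grids embed differently under random weights", {
  fx <- toyFixture()
  spec <- tinySpec()
  zero <- array(0, dim = c(length(spec@channels), 8, 8, 8))
  nz <- fx$feat$grids[[1]]
  for (seed in 1:10) {
    model <- initModel("bri", tinyConfig(), spec, seed = seed)
    E <- cnnExtract(model, list(zero, nz))
    expect_gt(max(abs(E[1, ] - E[2, ])), 1e-8)
  }
})

test_that("BSD score is permutation- and duplication-invariant over the
           context", {
  fx <- toyFixture()
  model <- initModel("bsd", tinyConfig(), tinySpec(), seed = 14L)
  grids <- fx$feat$grids[1:6]; frames <- fx$feat$frames[1:6]
  s0 <- bsdForward(model, grids, frames)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(bsdForward(model, grids[perm], frames[perm]), s0,
               tolerance = 1e-10)
  dup <- rep(seq_len(6), 2)
  expect_equal(bsdForward(model, grids[dup], frames[dup]), s0,
               tolerance = 1e-10)
})

test_that("BRI threshold semantics: logit sign determines the predicted set", {
  fx <- toyFixture()
  model <- initModel("bri", tinyConfig(), tinySpec(), seed = 15L)
  z <- briForward(model, fx$feat$grids, fx$feat$frames)
  expect_length(z, length(fx$feat$grids))
  # shifting the head bias far down empties the predicted set
  model@params[["head.b2"]][] <- -1e3
  z2 <- briForward(model, fx$feat$grids, fx$feat$frames)
  expect_length(fx$feat$indices[z2 > 0], 0L)
})

test_that("BRI and BSD trunks with identical shared weights produce
           identical penultimate features", {
  fx <- toyFixture()
  cfg <- tinyConfig()
  bri <- initModel("bri", cfg, tinySpec(), seed = 16L)
  bsd <- initModel("bsd", cfg, tinySpec(), seed = 17L)
  bsd <- transferInit(bri, bsd)$model
  trunkFeatures <- function(m) {
    X <- cnnExtract(m, fx$feat$grids)
    for (l in seq_len(cfg@nAttnLayers - 1L))
      X <- attentionLayer(m, l, X, fx$feat$frames)
    X
  }
  expect_equal(trunkFeatures(bri), trunkFeatures(bsd), tolerance = 1e-12)
})

test_that("checkpoints round-trip through the archive format", {
  model <- initModel("bsd", tinyConfig(), tinySpec(), seed = 18L)
  path <- file.path(tempdir(), "ckpt.json")
  saveCheckpoint(model, path)
  m2 <- loadCheckpoint(path)
  expect_equal(m2@task, "bsd")
  expect_equal(m2@params, model@params, tolerance = 1e-12)
  fx <- toyFixture()
  expect_equal(bsdForward(m2, fx$feat$grids, fx$feat$frames),
               bsdForward(model, fx$feat$grids, fx$feat$frames),
               tolerance = 1e-10)
})

test_that("model gradients match central finite differences", {
  fx <- toyFixture()
  spec <- gridSpec(4L, 2.0)
  cfg <- modelConfig(dHidden = 8L, nHeads = 2L, nPoints = 2L,
                     nAttnLayers = 2L, cnnChannels = c(4L, 8L),
                     headWidth = 6L)
  frames <- buildFrames(fx$toy$complex@protein)
  feat <- featurizeCandidate(fx$toy$complex@protein, frames, fx$center,
                             spec, threshold = 10)
  model <- initModel("bri", cfg, spec, seed = 7L)
  set.seed(99)  # move biases off the ReLU kinks of empty voxels
  for (nm in names(model@params))
    model@params[[nm]] <- model@params[[nm]] +
      rnorm(length(model@params[[nm]]), sd = 0.05)
  mf <- GeoPocket:::.modelForward
  lossOf <- function(m) sum(sin(mf(m, feat$grids, feat$frames)$out))
  fwd <- mf(model, feat$grids, feat$frames, withCache = TRUE)
  grads <- GeoPocket:::.modelBackward(model, fwd$cache, cos(fwd$out))
  set.seed(31)
  for (nm in c("cnn.s1.conv2.W", "cnn.proj.W", "attn1.Wqp", "attn1.rho",
               "attn2.Wf", "head.W1")) {
    i <- sample(length(model@params[[nm]]), 1)
    m2 <- model; m2@params[[nm]][i] <- m2@params[[nm]][i] + 1e-5
    m3 <- model; m3@params[[nm]][i] <- m3@params[[nm]][i] - 1e-5
    num <- (lossOf(m2) - lossOf(m3)) / 2e-5
    expect_equal(grads[[nm]][i], num, tolerance = 1e-3)
  }
})
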