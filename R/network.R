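## The model: a per-residue 3D bottleneck-ResNet feature extractor over local
## grids, a stack of geometric self-attention layers over residue frames, and
## task heads -- a pointwise feed-forward head with mean reduction for binding
## site detection (BSD, one druggability logit per candidate) and without the
## reduction for binding residue identification (BRI, one logit per residue).
##
## Geometric attention (per head h, point p):
##   w_std[i,j]  = q_i . k_j / sqrt(dHidden)
##   w_geo[i,j]  = (1/sqrt(P)) sum_p || T_i q_i^p - T_j k_j^p ||
##   w[i,j]      = softmax_j( (w_std - log(1+gamma) * w_geo) / sqrt(2) )
##   o_i         = sum_j w[i,j] v_j
##   o_i^p       = T_i^-1( sum_j w[i,j] T_j v_j^p )
##   x_i'        = f_final( concat_h,p(o_i, o_i^p, ||o_i^p||) )
## gamma is stored through a softplus so log(1+gamma) stays positive; the
## frames T_i are inputs, not parameters, which makes every output invariant
## under rigid motions of the structure (the grids are built in local frames
## and the o^p sums are pulled back into local coordinates).

.NORM_EPS <- 1e-12

#' Model configuration constructor
#'
#' @param dHidden embedding width (divisible by nHeads).
#' @param nHeads attention heads.
#' @param nPoints attention points per head.
#' @param nAttnLayers attention layers L (1..L-1 shared between tasks).
#' @param cnnChannels per-stage CNN output channels; each stage halves the
#'   grid edge, so the grid edge must be divisible by 2^length(cnnChannels).
#' @param headWidth hidden width of the pointwise head.
#' @param squaredDistance use squared distances in the geometric weight.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(dHidden = 128L, nHeads = 8L, nPoints = 4L,
                        nAttnLayers = 4L, cnnChannels = c(32L, 64L, 128L),
                        headWidth = 128L, squaredDistance = FALSE) {
  new("ModelConfig", dHidden = as.integer(dHidden), nHeads = as.integer(nHeads),
      nPoints = as.integer(nPoints), nAttnLayers = as.integer(nAttnLayers),
      cnnChannels = as.integer(cnnChannels), headWidth = as.integer(headWidth),
      squaredDistance = isTRUE(squaredDistance))
}

#' Initialize a model
#'
#' @param task "bri" or "bsd".
#' @param config a \linkS4class{ModelConfig}.
#' @param spec the \linkS4class{GridSpec} the CNN will consume.
#' @param seed RNG seed for the parameter draw.
#' @return a \linkS4class{BspModel}.
#' @export
initModel <- function(task = c("bri", "bsd"), config = modelConfig(),
                      spec = gridSpec(), seed = 0L) {
  task <- match.arg(task)
  nStages <- length(config@cnnChannels)
  if (spec@edgeVoxels %% (2^nStages) != 0)
    stop("grid edge ", spec@edgeVoxels, " not divisible by 2^", nStages)
  set.seed(seed)
  p <- list()
  cIn <- length(spec@channels)
  for (i in seq_len(nStages)) {
    cOut <- config@cnnChannels[i]
    mid <- max(1L, cOut %/% 4L)
    pre <- sprintf("cnn.s%d.", i)
    p[[paste0(pre, "conv1.W")]] <- .initW(cIn, mid)
    p[[paste0(pre, "conv1.b")]] <- numeric(mid)
    p[[paste0(pre, "conv2.W")]] <- .initW(27L * mid, mid)
    p[[paste0(pre, "conv2.b")]] <- numeric(mid)
    p[[paste0(pre, "conv3.W")]] <- .initW(mid, cOut)
    p[[paste0(pre, "conv3.b")]] <- numeric(cOut)
    p[[paste0(pre, "skip.W")]] <- .initW(cIn, cOut)
    p[[paste0(pre, "skip.b")]] <- numeric(cOut)
    cIn <- cOut
  }
  d <- config@dHidden
  p[["cnn.proj.W"]] <- .initW(cIn, d)
  p[["cnn.proj.b"]] <- numeric(d)
  H <- config@nHeads; P <- config@nPoints; dh <- d %/% H
  for (l in seq_len(config@nAttnLayers)) {
    pre <- sprintf("attn%d.", l)
    p[[paste0(pre, "Wq")]] <- .initW(d, d)
    p[[paste0(pre, "Wk")]] <- .initW(d, d)
    p[[paste0(pre, "Wv")]] <- .initW(d, d)
    p[[paste0(pre, "Wqp")]] <- .initW(d, 3L * H * P)
    p[[paste0(pre, "Wkp")]] <- .initW(d, 3L * H * P)
    p[[paste0(pre, "Wvp")]] <- .initW(d, 3L * H * P)
    ## log(1 + gamma) initialized to 1
    p[[paste0(pre, "rho")]] <- rep(.softplusInv(exp(1) - 1), H)
    p[[paste0(pre, "Wf")]] <- .initW(H * (dh + 4L * P), d)
    p[[paste0(pre, "bf")]] <- numeric(d)
  }
  w <- config@headWidth
  p[["head.W1"]] <- .initW(d, w)
  p[["head.b1"]] <- numeric(w)
  p[["head.W2"]] <- .initW(w, 1L)
  p[["head.b2"]] <- numeric(1L)
  new("BspModel", task = task, config = config, gridSpec = spec, params = p)
}

#' Names of the shared-trunk parameter groups
#'
#' The CNN and attention layers 1..L-1 are shared between the BRI and BSD
#' models; the final attention layer and the pointwise head are task-specific.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param params optional parameter list to subset names from.
#' @return character vector of shared parameter names (prefix-expanded when
#'   \code{params} is given, prefixes otherwise).
#' @export
sharedParameterNames <- function(config, params = NULL) {
  prefixes <- c("cnn.",
                if (config@nAttnLayers > 1)
                  sprintf("attn%d.", seq_len(config@nAttnLayers - 1L)))
  if (is.null(params)) return(prefixes)
  nm <- names(params)
  nm[Reduce(`|`, lapply(prefixes, function(px) startsWith(nm, px)))]
}

## grid array (C x D x D x D) -> (D^3 x C) matrix, x-fastest voxel order
.gridToMat <- function(grid) {
  nC <- dim(grid)[1]
  t(matrix(grid, nC, length(grid) / nC))
}

.cnnForwardOne <- function(X, params, config, D, withCache = FALSE) {
  nStages <- length(config@cnnChannels)
  caches <- if (withCache) vector("list", nStages)
  curD <- D
  for (i in seq_len(nStages)) {
    pre <- sprintf("cnn.s%d.", i)
    Xin <- X
    f1 <- .conv3dF(Xin, params[[paste0(pre, "conv1.W")]],
                   params[[paste0(pre, "conv1.b")]], curD, 1L, 1L, 0L)
    r1 <- .reluF(f1$Y)
    f2 <- .conv3dF(r1$Y, params[[paste0(pre, "conv2.W")]],
                   params[[paste0(pre, "conv2.b")]], curD, 3L, 2L, 1L)
    r2 <- .reluF(f2$Y)
    f3 <- .conv3dF(r2$Y, params[[paste0(pre, "conv3.W")]],
                   params[[paste0(pre, "conv3.b")]], curD %/% 2L, 1L, 1L, 0L)
    fs <- .conv3dF(Xin, params[[paste0(pre, "skip.W")]],
                   params[[paste0(pre, "skip.b")]], curD, 1L, 2L, 0L)
    ro <- .reluF(f3$Y + fs$Y)
    if (withCache)
      caches[[i]] <- list(Xin = Xin, f1 = f1, r1 = r1, f2 = f2, r2 = r2,
                          f3 = f3, fs = fs, ro = ro, D = curD)
    X <- ro$Y
    curD <- curD %/% 2L
  }
  hpre <- colMeans(X)
  emb <- as.numeric(hpre %*% params[["cnn.proj.W"]]) + params[["cnn.proj.b"]]
  list(emb = emb, hpre = hpre, nVox = nrow(X),
       caches = if (withCache) caches)
}

.cnnBackwardOne <- function(dEmb, fw, params, config, gr) {
  .gadd(gr, "cnn.proj.W", outer(fw$hpre, dEmb))
  .gadd(gr, "cnn.proj.b", dEmb)
  dHpre <- as.numeric(params[["cnn.proj.W"]] %*% dEmb)
  dX <- matrix(dHpre, fw$nVox, length(dHpre), byrow = TRUE) / fw$nVox
  for (i in rev(seq_along(config@cnnChannels))) {
    pre <- sprintf("cnn.s%d.", i)
    cc <- fw$caches[[i]]
    dSum <- dX * cc$ro$M
    b3 <- .conv3dB(dSum, cc$f3, params[[paste0(pre, "conv3.W")]],
                   cc$D %/% 2L, ncol(cc$r2$Y))
    bs <- .conv3dB(dSum, cc$fs, params[[paste0(pre, "skip.W")]],
                   cc$D, ncol(cc$Xin))
    .gadd(gr, paste0(pre, "conv3.W"), b3$dW)
    .gadd(gr, paste0(pre, "conv3.b"), b3$db)
    .gadd(gr, paste0(pre, "skip.W"), bs$dW)
    .gadd(gr, paste0(pre, "skip.b"), bs$db)
    dR2 <- b3$dX * cc$r2$M
    b2 <- .conv3dB(dR2, cc$f2, params[[paste0(pre, "conv2.W")]],
                   cc$D, ncol(cc$r1$Y))
    .gadd(gr, paste0(pre, "conv2.W"), b2$dW)
    .gadd(gr, paste0(pre, "conv2.b"), b2$db)
    dR1 <- b2$dX * cc$r1$M
    b1 <- .conv3dB(dR1, cc$f1, params[[paste0(pre, "conv1.W")]],
                   cc$D, ncol(cc$Xin))
    .gadd(gr, paste0(pre, "conv1.W"), b1$dW)
    .gadd(gr, paste0(pre, "conv1.b"), b1$db)
    dX <- b1$dX + bs$dX
  }
  dX  # gradient wrt the input grid matrix (unused upstream)
}

## gradient accumulator helpers over an environment
.gnew <- function() new.env(parent = emptyenv())
.gadd <- function(gr, nm, val) {
  cur <- gr[[nm]]
  gr[[nm]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}
.gcollect <- function(gr) as.list(gr)

#' Extract residue embeddings from grids with the CNN
#'
#' Runs the shared 3D bottleneck-ResNet feature extractor independently (with
#' shared weights) on each grid.
#'
#' @param model a \linkS4class{BspModel}.
#' @param grids list of channel x D x D x D arrays.
#' @return matrix (n grids x dHidden).
#' @export
cnnExtract <- function(model, grids) {
  spec <- model@gridSpec
  nC <- length(spec@channels)
  D <- spec@edgeVoxels
  out <- matrix(0, length(grids), model@config@dHidden)
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    if (!all(dim(g) == c(nC, D, D, D)))
      stop("grid ", i, " has shape (", paste(dim(g), collapse = ","),
           "), expected (", paste(c(nC, D, D, D), collapse = ","), ")")
    out[i, ] <- .cnnForwardOne(.gridToMat(g), model@params, model@config,
                               D)$emb
  }
  out
}

.framesToArrays <- function(frames) {
  n <- length(frames)
  Rl <- vector("list", n)
  Tm <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    Rl[[i]] <- frames[[i]]@rotation
    Tm[i, ] <- frames[[i]]@translation
  }
  list(R = Rl, T = Tm)
}

## One geometric attention layer. X: (n x d). fr: list(R=, T=).
.attnForward <- function(X, fr, params, l, config, withCache = FALSE) {
  n <- nrow(X)
  if (n < 1) stop("attention layer requires at least one token")
  d <- config@dHidden; H <- config@nHeads; P <- config@nPoints
  dh <- d %/% H
  pre <- sprintf("attn%d.", l)
  Wq <- params[[paste0(pre, "Wq")]]; Wk <- params[[paste0(pre, "Wk")]]
  Wv <- params[[paste0(pre, "Wv")]]
  Q <- X %*% Wq; K <- X %*% Wk; V <- X %*% Wv
  QP <- X %*% params[[paste0(pre, "Wqp")]]
  KP <- X %*% params[[paste0(pre, "Wkp")]]
  VP <- X %*% params[[paste0(pre, "Wvp")]]
  HP <- H * P
  ## global coordinates of the projected points: T_i applied per token
  toGlobal <- function(M) {
    G <- array(0, c(n, 3, HP))
    for (i in seq_len(n))
      G[i, , ] <- fr$R[[i]] %*% matrix(M[i, ], 3, HP) + fr$T[i, ]
    G
  }
  GQ <- toGlobal(QP); GK <- toGlobal(KP); GV <- toGlobal(VP)
  rho <- params[[paste0(pre, "rho")]]
  gamma <- .softplus(rho)
  gcoef <- log1p(gamma)
  sqd <- sqrt(d); sqP <- sqrt(P)
  heads <- vector("list", H)
  concat <- matrix(0, n, H * (dh + 4L * P))
  for (h in seq_len(H)) {
    sc <- (h - 1L) * dh + seq_len(dh)
    pc <- (h - 1L) * P + seq_len(P)
    Sstd <- tcrossprod(Q[, sc, drop = FALSE], K[, sc, drop = FALSE]) / sqd
    dists <- vector("list", P)
    Wgeo <- matrix(0, n, n)
    for (p in seq_len(P)) {
      A <- GQ[, , pc[p], drop = FALSE]; dim(A) <- c(n, 3)
      B <- GK[, , pc[p], drop = FALSE]; dim(B) <- c(n, 3)
      D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      D2 <- pmax(D2, 0)
      if (config@squaredDistance) {
        dists[[p]] <- list(A = A, B = B, D2 = D2)
        Wgeo <- Wgeo + D2
      } else {
        dst <- sqrt(D2 + .NORM_EPS)
        dists[[p]] <- list(A = A, B = B, dst = dst)
        Wgeo <- Wgeo + dst
      }
    }
    Wgeo <- Wgeo / sqP
    L <- (Sstd - gcoef[h] * Wgeo) / sqrt(2)
    L <- L - apply(L, 1, max)
    Wm <- exp(L)
    Wm <- Wm / rowSums(Wm)
    Osc <- Wm %*% V[, sc, drop = FALSE]
    Sp <- vector("list", P); Op <- vector("list", P)
    nrm <- matrix(0, n, P)
    for (p in seq_len(P)) {
      GVp <- GV[, , pc[p], drop = FALSE]; dim(GVp) <- c(n, 3)
      S <- Wm %*% GVp
      Loc <- matrix(0, n, 3)
      for (i in seq_len(n))
        Loc[i, ] <- crossprod(fr$R[[i]], S[i, ] - fr$T[i, ])
      Sp[[p]] <- S; Op[[p]] <- Loc
      nrm[, p] <- sqrt(rowSums(Loc^2) + .NORM_EPS)
    }
    base <- (h - 1L) * (dh + 4L * P)
    concat[, base + seq_len(dh)] <- Osc
    for (p in seq_len(P))
      concat[, base + dh + (p - 1L) * 3L + 1:3] <- Op[[p]]
    concat[, base + dh + 3L * P + seq_len(P)] <- nrm
    heads[[h]] <- list(Sstd = Sstd, Wgeo = Wgeo, Wm = Wm, dists = dists,
                       Osc = Osc, Sp = Sp, Op = Op, nrm = nrm)
  }
  Wf <- params[[paste0(pre, "Wf")]]
  Y <- concat %*% Wf
  Y <- sweep(Y, 2, params[[paste0(pre, "bf")]], "+")
  res <- list(Y = Y)
  if (withCache)
    res$cache <- list(X = X, Q = Q, K = K, V = V, QP = QP, KP = KP, VP = VP,
                      GQ = GQ, GK = GK, GV = GV, heads = heads,
                      concat = concat, gamma = gamma, gcoef = gcoef,
                      rho = rho, fr = fr, n = n)
  res
}

.attnBackward <- function(dY, cache, params, l, config, gr) {
  n <- cache$n; d <- config@dHidden; H <- config@nHeads; P <- config@nPoints
  dh <- d %/% H; HP <- H * P
  pre <- sprintf("attn%d.", l)
  Wf <- params[[paste0(pre, "Wf")]]
  .gadd(gr, paste0(pre, "Wf"), crossprod(cache$concat, dY))
  .gadd(gr, paste0(pre, "bf"), colSums(dY))
  dCat <- dY %*% t(Wf)
  fr <- cache$fr
  sqd <- sqrt(d); sqP <- sqrt(P)
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  dGQ <- array(0, c(n, 3, HP)); dGK <- array(0, c(n, 3, HP))
  dGV <- array(0, c(n, 3, HP))
  dRho <- numeric(H)
  for (h in seq_len(H)) {
    hc <- cache$heads[[h]]
    sc <- (h - 1L) * dh + seq_len(dh)
    pc <- (h - 1L) * P + seq_len(P)
    base <- (h - 1L) * (dh + 4L * P)
    dOsc <- dCat[, base + seq_len(dh), drop = FALSE]
    dWm <- matrix(0, n, n)
    ## scalar aggregation: Osc = Wm %*% V_h
    dWm <- dWm + tcrossprod(dOsc, cache$V[, sc, drop = FALSE])
    dV[, sc] <- dV[, sc] + crossprod(hc$Wm, dOsc)
    for (p in seq_len(P)) {
      dOp <- dCat[, base + dh + (p - 1L) * 3L + 1:3, drop = FALSE]
      dNrm <- dCat[, base + dh + 3L * P + p]
      dOp <- dOp + hc$Op[[p]] * (dNrm / hc$nrm[, p])
      ## local pullback: Op_i = R_i^T (S_i - t_i)  =>  dS_i = R_i dOp_i
      dS <- matrix(0, n, 3)
      for (i in seq_len(n)) dS[i, ] <- fr$R[[i]] %*% dOp[i, ]
      GVp <- cache$GV[, , pc[p], drop = FALSE]; dim(GVp) <- c(n, 3)
      dWm <- dWm + tcrossprod(dS, GVp)
      dGV[, , pc[p]] <- dGV[, , pc[p]] + crossprod(hc$Wm, dS)
    }
    ## softmax
    dL <- hc$Wm * (dWm - rowSums(hc$Wm * dWm))
    dSstd <- dL / sqrt(2)
    dWgeo <- -(cache$gcoef[h] / sqrt(2)) * dL
    dGcoef <- -sum(dL * hc$Wgeo) / sqrt(2)
    dRho[h] <- dGcoef * .sigmoid(cache$rho[h]) / (1 + cache$gamma[h])
    dQ[, sc] <- dQ[, sc] + dSstd %*% cache$K[, sc, drop = FALSE] / sqd
    dK[, sc] <- dK[, sc] + crossprod(dSstd, cache$Q[, sc, drop = FALSE]) / sqd
    for (p in seq_len(P)) {
      dd <- hc$dists[[p]]
      if (config@squaredDistance) {
        dD2 <- dWgeo / sqP
      } else {
        dD2 <- dWgeo / sqP * 0.5 / dd$dst
      }
      dA <- 2 * (rowSums(dD2) * dd$A - dD2 %*% dd$B)
      dB <- 2 * (colSums(dD2) * dd$B - crossprod(dD2, dd$A))
      dGQ[, , pc[p]] <- dGQ[, , pc[p]] + dA
      dGK[, , pc[p]] <- dGK[, , pc[p]] + dB
    }
  }
  .gadd(gr, paste0(pre, "rho"), dRho)
  ## global points back to the linear projections: G_i = R_i M_i + t_i
  toLocalGrad <- function(dG) {
    dM <- matrix(0, n, 3L * HP)
    for (i in seq_len(n)) {
      g <- dG[i, , ]; dim(g) <- c(3, HP)
      dM[i, ] <- as.vector(crossprod(fr$R[[i]], g))
    }
    dM
  }
  dQP <- toLocalGrad(dGQ); dKP <- toLocalGrad(dGK); dVP <- toLocalGrad(dGV)
  X <- cache$X
  .gadd(gr, paste0(pre, "Wq"), crossprod(X, dQ))
  .gadd(gr, paste0(pre, "Wk"), crossprod(X, dK))
  .gadd(gr, paste0(pre, "Wv"), crossprod(X, dV))
  .gadd(gr, paste0(pre, "Wqp"), crossprod(X, dQP))
  .gadd(gr, paste0(pre, "Wkp"), crossprod(X, dKP))
  .gadd(gr, paste0(pre, "Wvp"), crossprod(X, dVP))
  dQ %*% t(params[[paste0(pre, "Wq")]]) +
    dK %*% t(params[[paste0(pre, "Wk")]]) +
    dV %*% t(params[[paste0(pre, "Wv")]]) +
    dQP %*% t(params[[paste0(pre, "Wqp")]]) +
    dKP %*% t(params[[paste0(pre, "Wkp")]]) +
    dVP %*% t(params[[paste0(pre, "Wvp")]])
}

#' Apply one geometric attention layer
#'
#' Exposed mainly for testing the attention mechanism in isolation.
#'
#' @param model a \linkS4class{BspModel}.
#' @param layer layer index (1..nAttnLayers).
#' @param x embedding matrix (n x dHidden).
#' @param frames list of \linkS4class{LocalFrame}, one per row of x.
#' @return updated embedding matrix.
#' @export
attentionLayer <- function(model, layer, x, frames) {
  fr <- .framesToArrays(frames)
  .attnForward(x, fr, model@params, layer, model@config)$Y
}

#' Attention weights of one layer and head
#'
#' @inheritParams attentionLayer
#' @param head head index.
#' @return n x n row-stochastic attention weight matrix.
#' @export
attentionWeights <- function(model, layer, head, x, frames) {
  fr <- .framesToArrays(frames)
  res <- .attnForward(x, fr, model@params, layer, model@config,
                      withCache = TRUE)
  res$cache$heads[[head]]$Wm
}

.headForward <- function(Xtok, params, withCache = FALSE) {
  A <- Xtok %*% params[["head.W1"]]
  A <- sweep(A, 2, params[["head.b1"]], "+")
  r <- .reluF(A)
  z <- as.numeric(r$Y %*% params[["head.W2"]]) + params[["head.b2"]]
  list(z = z, cache = if (withCache) list(Xtok = Xtok, r = r))
}

.headBackward <- function(dz, cache, params, gr) {
  dz <- matrix(dz, ncol = 1)
  .gadd(gr, "head.W2", crossprod(cache$r$Y, dz))
  .gadd(gr, "head.b2", sum(dz))
  dA <- (dz %*% t(params[["head.W2"]])) * cache$r$M
  .gadd(gr, "head.W1", crossprod(cache$Xtok, dA))
  .gadd(gr, "head.b1", colSums(dA))
  dA %*% t(params[["head.W1"]])
}

## Full forward pass. Returns task output and (optionally) all caches.
.modelForward <- function(model, grids, frames, withCache = FALSE) {
  if (length(grids) == 0) stop("empty context: no grids")
  if (length(grids) != length(frames))
    stop("grids and frames must have equal length")
  spec <- model@gridSpec; config <- model@config
  nC <- length(spec@channels); D <- spec@edgeVoxels
  n <- length(grids)
  E <- matrix(0, n, config@dHidden)
  cnnCaches <- if (withCache) vector("list", n)
  for (i in seq_len(n)) {
    g <- grids[[i]]
    if (!all(dim(g) == c(nC, D, D, D)))
      stop("grid shape mismatch with model GridSpec")
    fwd <- .cnnForwardOne(.gridToMat(g), model@params, config, D,
                          withCache = withCache)
    E[i, ] <- fwd$emb
    if (withCache) cnnCaches[[i]] <- fwd
  }
  fr <- .framesToArrays(frames)
  attnCaches <- if (withCache) vector("list", config@nAttnLayers)
  X <- E
  for (l in seq_len(config@nAttnLayers)) {
    res <- .attnForward(X, fr, model@params, l, config, withCache = withCache)
    if (withCache) attnCaches[[l]] <- res$cache
    X <- res$Y
  }
  hd <- .headForward(X, model@params, withCache = withCache)
  out <- if (model@task == "bsd") mean(hd$z) else hd$z
  list(out = out, tokens = X,
       cache = if (withCache) list(cnn = cnnCaches, attn = attnCaches,
                                   head = hd$cache, n = n))
}

## dOut: scalar (bsd) or per-token vector (bri). Returns named gradient list.
.modelBackward <- function(model, cache, dOut) {
  config <- model@config
  gr <- .gnew()
  n <- cache$n
  dz <- if (model@task == "bsd") rep(dOut / n, n) else dOut
  dX <- .headBackward(dz, cache$head, model@params, gr)
  for (l in rev(seq_len(config@nAttnLayers)))
    dX <- .attnBackward(dX, cache$attn[[l]], model@params, l, config, gr)
  for (i in seq_len(n))
    .cnnBackwardOne(dX[i, ], cache$cnn[[i]], model@params, config, gr)
  .gcollect(gr)
}

#' BSD forward pass: druggability logit of a candidate
#'
#' @param model a \linkS4class{BspModel} with task "bsd".
#' @param grids per-context-residue grids.
#' @param frames matching \linkS4class{LocalFrame}s.
#' @return scalar logit; druggability probability is its sigmoid.
#' @export
bsdForward <- function(model, grids, frames) {
  stopifnot(model@task == "bsd")
  .modelForward(model, grids, frames)$out
}

#' BRI forward pass: per-residue binding logits
#'
#' Residues with logit > 0 constitute the predicted binding residue set.
#'
#' @param model a \linkS4class{BspModel} with task "bri".
#' @inheritParams bsdForward
#' @return numeric vector of logits, one per context residue.
#' @export
briForward <- function(model, grids, frames) {
  stopifnot(model@task == "bri")
  .modelForward(model, grids, frames)$out
}

#' Sigmoid druggability probability
#' @param logit scalar or vector of logits.
#' @export
druggability <- function(logit) .sigmoid(logit)

#' Save / load a model checkpoint
#'
#' Flat named-parameter archive (JSON) with the embedded model and grid
#' configuration.
#'
#' @param model a \linkS4class{BspModel}.
#' @param path output file.
#' @export
saveCheckpoint <- function(model, path) {
  cfg <- model@config; spec <- model@gridSpec
  obj <- list(
    task = model@task,
    config = list(dHidden = cfg@dHidden, nHeads = cfg@nHeads,
                  nPoints = cfg@nPoints, nAttnLayers = cfg@nAttnLayers,
                  cnnChannels = cfg@cnnChannels, headWidth = cfg@headWidth,
                  squaredDistance = cfg@squaredDistance),
    gridSpec = list(edgeVoxels = spec@edgeVoxels, voxelSize = spec@voxelSize,
                    channelScheme = spec@channelScheme),
    params = lapply(model@params, function(p)
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- modelConfig(dHidden = obj$config$dHidden, nHeads = obj$config$nHeads,
                     nPoints = obj$config$nPoints,
                     nAttnLayers = obj$config$nAttnLayers,
                     cnnChannels = obj$config$cnnChannels,
                     headWidth = obj$config$headWidth,
                     squaredDistance = obj$config$squaredDistance)
  spec <- gridSpec(obj$gridSpec$edgeVoxels, obj$gridSpec$voxelSize,
                   obj$gridSpec$channelScheme)
  params <- lapply(obj$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  new("BspModel", task = obj$task, config = cfg, gridSpec = spec,
      params = params)
}
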