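## Minimal reverse-mode building blocks for the models in this package:
## 3D convolution via im2col + BLAS matrix products, dense layers, ReLU and
## an Adam optimizer over flat named parameter lists. Feature maps are stored
## as (voxels x channels) matrices with x-fastest voxel flattening; gradients
## are hand-derived per layer.

.im2colCache <- new.env(parent = emptyenv())

## Index table mapping (kernel offset u, output voxel o) -> flat input voxel
## (1-based, 0 = zero pad). Cached per geometry.
.im2colIdx <- function(D, k, stride, pad) {
  key <- paste(D, k, stride, pad, sep = "_")
  hit <- .im2colCache[[key]]
  if (!is.null(hit)) return(hit)
  Do <- (D + 2 * pad - k) %/% stride + 1
  ov <- as.matrix(expand.grid(0:(Do - 1), 0:(Do - 1), 0:(Do - 1)))
  kv <- as.matrix(expand.grid(0:(k - 1), 0:(k - 1), 0:(k - 1)))
  IDX <- matrix(0L, nrow(kv), nrow(ov))
  for (u in seq_len(nrow(kv))) {
    ix <- ov[, 1] * stride - pad + kv[u, 1]
    iy <- ov[, 2] * stride - pad + kv[u, 2]
    iz <- ov[, 3] * stride - pad + kv[u, 3]
    ok <- ix >= 0 & ix < D & iy >= 0 & iy < D & iz >= 0 & iz < D
    flat <- ix + D * iy + D * D * iz + 1L
    flat[!ok] <- 0L
    IDX[u, ] <- flat
  }
  res <- list(IDX = IDX, Do = Do, k3 = nrow(kv))
  .im2colCache[[key]] <- res
  res
}

## X: (D^3 x Cin). Returns patches P: (Do^3 x (k^3*Cin)), u fastest then c.
.im2col <- function(X, info) {
  Cin <- ncol(X)
  Xz <- rbind(0, X)                       # row 1 = zero pad
  Q <- Xz[as.vector(info$IDX) + 1L, , drop = FALSE]   # (k3*Do^3) x Cin
  dim(Q) <- c(info$k3, ncol(info$IDX), Cin)
  Q <- aperm(Q, c(2, 1, 3))
  dim(Q) <- c(ncol(info$IDX), info$k3 * Cin)
  Q
}

.col2im <- function(dP, info, D, Cin) {
  dim(dP) <- c(ncol(info$IDX), info$k3, Cin)
  dP <- aperm(dP, c(2, 1, 3))
  dim(dP) <- c(info$k3 * ncol(info$IDX), Cin)
  grp <- as.vector(info$IDX)
  rs <- rowsum(dP, group = grp)
  dX <- matrix(0, D^3, Cin)
  rows <- as.integer(rownames(rs))
  keep <- rows > 0
  dX[rows[keep], ] <- rs[keep, , drop = FALSE]
  dX
}

## W: ((k^3*Cin) x Cout), b: Cout
.conv3dF <- function(X, W, b, D, k, stride, pad) {
  info <- .im2colIdx(D, k, stride, pad)
  P <- .im2col(X, info)
  Y <- P %*% W
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, P = P, info = info, Do = info$Do)
}

.conv3dB <- function(dY, fw, W, D, Cin) {
  list(dX = .col2im(dY %*% t(W), fw$info, D, Cin),
       dW = crossprod(fw$P, dY),
       db = colSums(dY))
}

.reluF <- function(X) {
  M <- X > 0
  list(Y = X * M, M = M)
}

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
.softplusInv <- function(y) ifelse(y > 30, y, log(expm1(y)))
.sigmoid <- function(x) 1 / (1 + exp(-x))

## Glorot-normal init
.initW <- function(dIn, dOut) {
  matrix(stats::rnorm(dIn * dOut, sd = sqrt(2 / (dIn + dOut))), dIn, dOut)
}

.adamInit <- function() new.env(parent = emptyenv())

## One Adam update in place on a named parameter list. Frozen parameters are
## left untouched and accumulate no optimizer state.
.adamStep <- function(params, grads, state, lr, frozen = character(0),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state$t)) state$t <- 0L
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state[[nm]])) state[[nm]] <- list(m = g * 0, v = g * 0, n = 0L)
    st <- state[[nm]]
    st$n <- st$n + 1L
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[nm]] <- st
    mh <- st$m / (1 - beta1^st$n)
    vh <- st$v / (1 - beta2^st$n)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  params
}

## Stable binary cross-entropy with logits and its gradient wrt logits.
.bceWithLogits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}
.bceGrad <- function(z, y) .sigmoid(z) - y
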