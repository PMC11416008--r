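# Independent naive implementations of the three aggregate metrics, coded
# directly from the definitions with explicit loops.
naiveMetrics <- function(records, cutoff = 4.0) {
  sumN <- 0; sumF1 <- 0; sumIou <- 0; sumIouS <- 0; nS <- 0
  for (rec in records) {
    n <- length(rec@ligandAtoms)
    det <- matrix(FALSE, n, n)
    for (j in 1:n) for (k in 1:n) {
      dmin <- Inf
      for (a in seq_len(nrow(rec@ligandAtoms[[k]])))
        dmin <- min(dmin, sqrt(sum((rec@centers[j, ] -
                                      rec@ligandAtoms[[k]][a, ])^2)))
      det[j, k] <- dmin < cutoff
    }
    P <- 0; for (j in 1:n) if (any(det[j, ])) P <- P + 1
    R <- 0; for (k in 1:n) if (any(det[, k])) R <- R + 1
    P <- P / n; R <- R / n
    F1 <- if (P + R == 0) 0 else 2 / (1 / P + 1 / R)
    sumN <- sumN + n; sumF1 <- sumF1 + n * F1
    for (j in 1:n) {
      dcas <- sapply(1:n, function(k) {
        min(sapply(seq_len(nrow(rec@ligandAtoms[[k]])), function(a)
          sqrt(sum((rec@centers[j, ] - rec@ligandAtoms[[k]][a, ])^2))))
      })
      phi <- which.min(dcas)
      A <- rec@predictedResidues[[j]]; B <- rec@trueResidues[[phi]]
      iou <- if (length(union(A, B)) == 0) 1
             else length(intersect(A, B)) / length(union(A, B))
      sumIou <- sumIou + iou
      if (dcas[phi] < cutoff) { sumIouS <- sumIouS + iou; nS <- nS + 1 }
    }
  }
  list(f1 = sumF1 / sumN, iou = sumIou / sumN,
       condIou = if (nS == 0) NaN else sumIouS / nS)
}

randomRecords <- function(nRecords, seed) {
  set.seed(seed)
  lapply(seq_len(nRecords), function(i) {
    n <- sample(1:4, 1)
    ligs <- lapply(1:n, function(k)
      matrix(rnorm(3 * sample(2:6, 1), sd = 6), ncol = 3))
    centers <- do.call(rbind, lapply(1:n, function(j) {
      base <- ligs[[sample(n, 1)]][1, ]
      base + rnorm(3, sd = sample(c(0.5, 3, 10), 1))
    }))
    evalRecord(id = paste0("p", i), ligandAtoms = ligs, centers = centers,
               predictedResidues = lapply(1:n, function(j)
                 sample(1:30, sample(0:10, 1))),
               trueResidues = lapply(1:n, function(j)
                 sample(1:30, sample(0:10, 1))))
  })
}

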