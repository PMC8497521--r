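# Independent oracles used across the suite. Each is a deliberately naive
# implementation (explicit loops, sorting, exhaustive scans) kept free of
# the package's own code paths.

# 3x3x3 median by explicitly gathering each neighborhood with clamped
# (edge-replicated) indices and sorting.
bruteMedian3D <- function(x) {
  d <- dim(x)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- pmin(pmax((i - 1):(i + 1), 1), d[1])
    jj <- pmin(pmax((j - 1):(j + 1), 1), d[2])
    kk <- pmin(pmax((k - 1):(k + 1), 1), d[3])
    v <- sort(as.vector(x[ii, jj, kk]))
    out[i, j, k] <- v[14]
  }
  out
}

# Breadth-first flood fill labeling; seeds iterate in raster order so
# component numbers match a raster-scan first-encounter convention.
floodLabelOracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0L, d)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  K <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    K <- K + 1L
    lab[s] <- K
    queue <- s
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      ci <- arrayInd(cur, d)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 &
        nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- nb[, 1] + d[1] * ((nb[, 2] - 1L) + d[2] * (nb[, 3] - 1L))
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- K
      queue <- c(queue, lin)
    }
  }
  list(labels = lab, k = K)
}

# Exhaustive scan of all candidate cuts maximizing the between-class
# variance, computed naively per cut; returns the lowest maximizing cut.
otsuOracleCut <- function(counts, mids) {
  p <- counts / sum(counts)
  B <- length(p)
  best <- -Inf
  bestCut <- NA_integer_
  for (t in 1:(B - 1)) {
    w0 <- sum(p[1:t])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:t] * mids[1:t]) / w0
    mu1 <- sum(p[(t + 1):B] * mids[(t + 1):B]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) {
      best <- v
      bestCut <- t
    }
  }
  bestCut
}

# Naive evaluation of Yen's maximum-correlation criterion per cut.
yenOracleCut <- function(counts, mids) {
  p <- counts / sum(counts)
  B <- length(p)
  best <- -Inf
  bestCut <- NA_integer_
  for (t in 1:(B - 1)) {
    P <- sum(p[1:t])
    if (P <= 0 || P >= 1) next
    s1 <- sum(p[1:t]^2)
    s2 <- sum(p[(t + 1):B]^2)
    if (s1 <= 0 || s2 <= 0) next
    v <- -log(s1 * s2) + 2 * log(P * (1 - P))
    if (v > best + 1e-12) {
      best <- v
      bestCut <- t
    }
  }
  bestCut
}

# A random two-component intensity histogram with well-separated modes;
# returns the histogram plus the mode bin locations.
randomBimodalHistogram <- function(nBins = 256) {
  lowMode <- sample(10:60, 1)
  highMode <- sample(160:240, 1)
  xs <- seq_len(nBins)
  counts <- round(3000 * exp(-(xs - lowMode)^2 / (2 * runif(1, 3, 10)^2)) +
                    runif(1, 500, 3000) *
                      exp(-(xs - highMode)^2 / (2 * runif(1, 3, 12)^2)))
  list(counts = counts, mids = xs, lowMode = lowMode, highMode = highMode)
}

# Scalar iteration of the segregational-loss recursion, independent of the
# generator's implementation.
lossRecursionOracle <- function(f0, lambda, s, nGenerations) {
  f <- f0
  for (g in seq_len(nGenerations)) {
    grown <- f * (1 + s)
    f <- (grown + (1 - f) * lambda) / (grown + (1 - f))
  }
  f
}

# Small deterministic ZProfile builder.
makeProfile <- function(nFree, nCarrier) {
  data.frame(z = seq_along(nFree), nFree = nFree, nCarrier = nCarrier,
             biomass = nFree + nCarrier)
}

# A scaled-down run configuration for workflow tests.
smallRunConfig <- function() {
  config <- defaultRunConfig()
  config$flowcell$nLayers <- 16L
  config$flowcell$ny <- 48L
  config$flowcell$nx <- 48L
  config$flowcell$biomassPerLayer <- 400
  config$flowcell$nImages <- 1L
  config$flowcell$nReplicates <- 2L
  config$bead$radiusUm <- 50
  config$bead$nAggregates <- 12L
  config$bead$nBeads <- 2L
  config$facs$nControlEvents <- 2000L
  config$facs$nEvents <- 1000L
  config$facs$nBioReps <- 2L
  config$facs$nTechReps <- 2L
  config$facs$days <- 2L
  config
}
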