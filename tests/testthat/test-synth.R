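test_that("all generators are bit-identical under a fixed seed", {
  ftr <- flowcellTruth(nLayers = 8L, ny = 24L, nx = 24L,
                       biomassProfile = function(z) rep(60, length(z)),
                       seed = 101L)
  a <- simulateFlowcellStack(ftr)
  b <- simulateFlowcellStack(ftr)
  expect_identical(a, b)
  btr <- beadTruth(radiusUm = 40, nAggregates = 6L, seed = 102L)
  expect_identical(simulateBeadStack(btr), simulateBeadStack(btr))
  xtr <- facsTruth(nEvents = 500L, seed = 103L)
  expect_identical(simulateFacsEvents(xtr), simulateFacsEvents(xtr))
  ttr <- trajectoryTruth()
  expect_identical(simulateLossTimecourse(ttr, 1000L, seed = 104L),
                   simulateLossTimecourse(ttr, 1000L, seed = 104L))
})

test_that("true per-layer counts equal rendered foreground voxels before noise", {
  tr <- flowcellTruth(nLayers = 10L, ny = 32L, nx = 32L,
                      biomassProfile = function(z) rep(150, length(z)),
                      noiseMean = 0, noiseSd = 0, seed = 5L)
  sim <- simulateFlowcellStack(tr)
  g <- channelIntensity(sim$image, "green")
  r <- channelIntensity(sim$image, "red")
  expect_identical(apply(g > 0, 1, sum), as.integer(sim$truth$nFree))
  expect_identical(apply(r > 0, 1, sum), as.integer(sim$truth$nCarrier))
  expect_identical(sim$truth$nFree + sim$truth$nCarrier, rep(150L, 10L))
})

test_that("degenerate loss profiles put all signal in one channel", {
  base <- function(p, seed) flowcellTruth(
    nLayers = 6L, ny = 20L, nx = 20L, lossProfile = function(z) rep(p, length(z)),
    biomassProfile = function(z) rep(40, length(z)),
    noiseMean = 0, noiseSd = 0, seed = seed)
  allCarrier <- simulateFlowcellStack(base(0, 7L))
  expect_true(all(channelIntensity(allCarrier$image, "green") == 0))
  expect_identical(sum(allCarrier$truth$nFree), 0L)
  allFree <- simulateFlowcellStack(base(1, 8L))
  expect_true(all(channelIntensity(allFree$image, "red") == 0))
  expect_identical(sum(allFree$truth$nCarrier), 0L)
})

test_that("an all-zero biomass profile is rejected", {
  expect_error(
    flowcellTruth(biomassProfile = function(z) rep(0, length(z))))
})

test_that("a bead stack with no aggregates is noise-only with an empty truth table", {
  sim <- simulateBeadStack(beadTruth(radiusUm = 30, nAggregates = 0L,
                                     signalMean = 1000, seed = 9L))
  expect_identical(nrow(sim$truth), 0L)
  # nothing near the signal level anywhere
  expect_lt(max(channelIntensity(sim$image, "red")), 100)
  expect_lt(max(channelIntensity(sim$image, "green")), 100)
})

test_that("bead ground-truth centroids lie inside the bead and volumes obey the discretization bound", {
  sim <- simulateBeadStack(beadTruth(radiusUm = 60, nAggregates = 20L,
                                     noiseMean = 0, noiseSd = 0, seed = 21L))
  tt <- sim$truth
  expect_true(all(tt$distance <= 60 + 1e-9))
  expect_true(all(sqrt((tt$cz - sim$center[1])^2 + (tt$cy - sim$center[2])^2 +
                         (tt$cx - sim$center[3])^2) <= 60 + 1e-9))
  # per-aggregate: |rendered - requested| < voxel volume x surface voxels;
  # surface voxels counted on the noise-free rendering (6-neighbor boundary)
  vs <- c(2, 1, 1)
  for (ch in c("free", "carrier")) {
    arr <- channelIntensity(sim$image,
                            if (ch == "free") "green" else "red") > 0
    lm <- labelComponents(arr)
    lab <- labelArray(lm)
    sub <- tt[tt$channel == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      vox <- round(c(sub$cz[i] / vs[1], sub$cy[i] / vs[2],
                     sub$cx[i] / vs[3])) + 1
      lbl <- lab[vox[1], vox[2], vox[3]]
      idx <- which(lab == lbl)
      co <- arrayInd(idx, dim(lab))
      nSurface <- 0L
      for (v in seq_len(nrow(co))) {
        nb <- rbind(co[v, ] + c(1, 0, 0), co[v, ] - c(1, 0, 0),
                    co[v, ] + c(0, 1, 0), co[v, ] - c(0, 1, 0),
                    co[v, ] + c(0, 0, 1), co[v, ] - c(0, 0, 1))
        inB <- nb[, 1] >= 1 & nb[, 1] <= dim(lab)[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim(lab)[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim(lab)[3]
        vals <- lab[nb[inB, , drop = FALSE]]
        if (any(vals != lbl) || any(!inB)) nSurface <- nSurface + 1L
      }
      expect_lt(abs(sub$volumeRendered[i] - sub$volumeRequested[i]),
                prod(vs) * nSurface)
    }
  }
})

test_that("impossible aggregate packing fails with a clear error", {
  expect_error(
    simulateBeadStack(beadTruth(radiusUm = 15, nAggregates = 100L,
                                maxTries = 20L, seed = 3L)),
    "without overlap")
})

test_that("FACS generator honours degenerate mixtures and empty tables", {
  allCarrier <- simulateFacsEvents(facsTruth(nEvents = 300L, freeFraction = 0,
                                             debrisFraction = 0, seed = 31L))
  expect_true(all(allCarrier$trueClass == "carrier"))
  empty <- simulateFacsEvents(facsTruth(nEvents = 0L, seed = 32L))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("green", "red", "trueClass") %in% names(empty)))
})

test_that("the loss timecourse matches an independent scalar recursion oracle", {
  tr <- trajectoryTruth(lambdaSeg = 0.001, sCost = 0.05,
                        generationsPerDay = 10, days = 4L, f0 = 0)
  traj <- simulateLossTimecourse(tr, samplingN = 100L, seed = 41L)
  for (d in 0:4)
    expect_equal(traj$expectedFraction[traj$day == d],
                 lossRecursionOracle(0, 0.001, 0.05, 10 * d), tolerance = 1e-12)
})

test_that("no loss and no selection leaves the expected fraction at f0", {
  tr <- trajectoryTruth(lambdaSeg = 0, sCost = 0, days = 3L, f0 = 0.2)
  traj <- simulateLossTimecourse(tr, samplingN = 10000L, seed = 43L)
  expect_true(all(traj$expectedFraction == 0.2))
  tr0 <- trajectoryTruth(lambdaSeg = 0, sCost = 0.1, days = 3L, f0 = 0)
  traj0 <- simulateLossTimecourse(tr0, samplingN = 10000L, seed = 44L)
  expect_true(all(traj0$fraction == 0))
})

test_that("sampled fractions converge to the deterministic recursion at large n", {
  tr <- trajectoryTruth(lambdaSeg = 0.002, sCost = 0.05, days = 4L, f0 = 0.01)
  n <- 1e6
  traj <- simulateLossTimecourse(tr, samplingN = n, seed = 47L)
  mcSd <- sqrt(traj$expectedFraction * (1 - traj$expectedFraction) / n)
  expect_true(all(abs(traj$fraction - traj$expectedFraction) <=
                    pmax(3 * mcSd, 1e-9)))
})

test_that("expected loss fraction is non-decreasing when loss and cost are non-negative", {
  set.seed(53)
  for (i in 1:5) {
    tr <- trajectoryTruth(lambdaSeg = runif(1, 0, 0.01),
                          sCost = runif(1, 0, 0.2), days = 5L,
                          f0 = runif(1, 0, 0.5))
    traj <- simulateLossTimecourse(tr, samplingN = 100L, seed = 53L + i)
    expect_true(all(diff(traj$expectedFraction) >= -1e-12))
  }
})
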