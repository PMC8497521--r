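test_that("bead center is the median foreground position, robust to outliers", {
  # filled centered sphere in a 21^3 stack, unit voxels
  d <- c(21, 21, 21)
  m <- array(FALSE, d)
  co <- as.matrix(expand.grid(i = 1:21, j = 1:21, k = 1:21))
  inside <- (co[, 1] - 11)^2 + (co[, 2] - 11)^2 + (co[, 3] - 11)^2 <= 36
  m[co[inside, ]] <- TRUE
  ctr <- beadCenter(m, array(FALSE, d), c(1, 1, 1))
  expect_true(all(abs(ctr - 10) <= 0.5))  # voxel 11 -> 10 um at (i-1)*1
  # one distant outlier voxel must not move the median (the mean would move)
  m2 <- m
  m2[21, 21, 21] <- TRUE
  ctr2 <- beadCenter(m2, array(FALSE, d), c(1, 1, 1))
  expect_equal(as.numeric(ctr2), as.numeric(ctr))
  meanCtr <- colMeans((arrayInd(which(m2), d) - 1) * 1)
  expect_gt(max(abs(meanCtr - as.numeric(ctr))), 0)
  expect_error(beadCenter(array(FALSE, d), array(FALSE, d), c(1, 1, 1)),
               "no foreground")
})

test_that("bead center equals a sort-based per-axis median oracle", {
  set.seed(83)
  d <- c(12, 14, 16)
  m <- array(runif(prod(d)) < 0.2, d)
  vs <- c(2, 1, 0.5)
  ctr <- beadCenter(m, array(FALSE, d), vs)
  co <- arrayInd(which(m), d)
  oracle <- vapply(1:3, function(a) {
    v <- sort(co[, a])
    n <- length(v)
    mid <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    (mid - 1) * vs[a]
  }, numeric(1))
  expect_equal(as.numeric(ctr), oracle)
})

test_that("aggregate volumes are voxel count times voxel volume, exactly", {
  d <- c(8, 8, 8)
  m <- array(FALSE, d)
  m[3:4, 3:4, 3:4] <- TRUE  # a 2x2x2 block
  ctr <- c(0, 0, 0)
  tab <- detectAggregates(m, array(FALSE, d), c(1, 1, 1), ctr)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$volume, 8)
  expect_equal(tab$voxels, 8L)
  tabAniso <- detectAggregates(m, array(FALSE, d), c(1, 0.25, 0.25), ctr)
  expect_equal(tabAniso$volume, 0.5)
})

test_that("channels are detected independently", {
  d <- c(8, 8, 8)
  fm <- array(FALSE, d)
  fm[2:3, 2:3, 2:3] <- TRUE
  cm <- array(FALSE, d)
  cm[6, 6, 6] <- TRUE
  ctr <- c(3, 3, 3)
  before <- detectAggregates(fm, cm, c(1, 1, 1), ctr)
  cm2 <- cm
  cm2[7, 7, 7] <- TRUE  # grow the carrier channel only
  after <- detectAggregates(fm, cm2, c(1, 1, 1), ctr)
  expect_identical(before[before$channel == "free", ],
                   after[after$channel == "free", ])
  expect_identical(nrow(detectAggregates(array(FALSE, d), array(FALSE, d),
                                         c(1, 1, 1), ctr)), 0L)
})

makeAggRow <- function(volume, distance, bead = "b1", channel = "carrier") {
  data.frame(bead = bead, channel = channel, label = 1L,
             voxels = as.integer(volume), volume = volume, cz = 0, cy = 0,
             cx = 0, distance = distance, retained = NA,
             removalReason = NA_character_, normalizedDistance = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("the volume filter discards strictly below 50 cubic microns", {
  tab <- rbind(makeAggRow(49.9, 10), makeAggRow(50.0, 12),
               makeAggRow(50.1, 14))
  out <- filterAggregates(tab, minVolume = 50, beadRadius = 100)
  expect_identical(out$retained, c(FALSE, TRUE, TRUE))
  expect_identical(out$removalReason[1], "below minimum volume")
  expect_identical(nrow(filterAggregates(tab[0, ])), 0L)
})

test_that("aggregates beyond the exclusion radius are removed as outside", {
  tab <- rbind(makeAggRow(100, 50), makeAggRow(100, 130))  # radius 100
  out <- filterAggregates(tab, minVolume = 50, beadRadius = 100,
                          exclusionFactor = 1.1)
  expect_identical(out$retained, c(TRUE, FALSE))
  expect_identical(out$removalReason[2], "outside bead")
})

test_that("distance normalization maps the farthest aggregate to exactly 1, per bead", {
  tab <- rbind(makeAggRow(100, 100), makeAggRow(100, 200), makeAggRow(100, 400))
  tab <- filterAggregates(tab, minVolume = 50, beadRadius = 500)
  out <- normalizeDistances(tab)
  expect_equal(out$normalizedDistance, c(0.25, 0.5, 1))
  same <- normalizeDistances(filterAggregates(
    rbind(makeAggRow(80, 70), makeAggRow(90, 70)), beadRadius = 100))
  expect_equal(same$normalizedDistance, c(1, 1))
})

test_that("normalization is independent per bead and matches a groupwise max oracle", {
  set.seed(89)
  rows <- do.call(rbind, lapply(1:40, function(i)
    makeAggRow(runif(1, 60, 500), runif(1, 5, 90),
               bead = sample(c("b1", "b2"), 1))))
  rows <- filterAggregates(rows, minVolume = 50, beadRadius = 100)
  out <- normalizeDistances(rows)
  for (b in c("b1", "b2")) {
    sel <- out$bead == b & out$retained
    expect_equal(out$normalizedDistance[sel],
                 out$distance[sel] / max(out$distance[sel]))
  }
})

test_that("loss ratios count free vs carrier aggregates per bead and pooled", {
  tab <- rbind(
    do.call(rbind, replicate(5, makeAggRow(100, 10, channel = "free"),
                             simplify = FALSE)),
    do.call(rbind, replicate(20, makeAggRow(100, 10, channel = "carrier"),
                             simplify = FALSE)))
  tab$retained <- TRUE
  lr <- lossRatio(tab)
  expect_equal(lr$pooled, 0.25)
  expect_equal(lr$perBead$ratio, 0.25)
  tab0 <- tab[tab$channel == "carrier", ]
  expect_equal(lossRatio(tab0)$pooled, 0)
})

test_that("size-distance regression recovers an exact log-linear relation", {
  d <- seq(0.1, 1, length.out = 20)
  tab <- do.call(rbind, lapply(seq_along(d), function(i)
    makeAggRow(10^(2 + 0.8 * d[i]), d[i] * 100)))
  tab$retained <- TRUE
  tab$normalizedDistance <- d
  ## exact data: summary.lm warns about the perfect fit, which is the point
  reg <- suppressWarnings(sizeDistanceRegression(tab))
  expect_equal(reg$slope, 0.8, tolerance = 1e-9)
  expect_equal(reg$intercept, 2, tolerance = 1e-9)
  expect_lt(sum(resid(reg$fit)^2), 1e-18)
  tabC <- tab
  tabC$volume <- 100
  expect_equal(suppressWarnings(sizeDistanceRegression(tabC))$slope, 0,
               tolerance = 1e-9)
})

test_that("regression CIs have close to nominal coverage on simulated tables", {
  set.seed(97)
  hits <- 0L
  nSim <- 200L
  for (i in seq_len(nSim)) {
    d <- runif(60)
    vol <- 10^(2.8 + 0.8 * d + rnorm(60, 0, 0.15))
    tab <- makeAggRow(vol[1], d[1] * 100)[rep(1, 60), ]
    tab$volume <- vol
    tab$normalizedDistance <- d
    tab$retained <- TRUE
    reg <- sizeDistanceRegression(tab)
    if (reg$slopeCI[1] <= 0.8 && 0.8 <= reg$slopeCI[2]) hits <- hits + 1L
  }
  expect_gte(hits / nSim, 0.93)
})

test_that("the status mixed model matches the balanced closed form and collapses without between-bead variance", {
  ## balanced fixture: 2 beads x 10 aggregates per status, no bead effect
  set.seed(101)
  volumes <- c()
  status <- c()
  bead <- c()
  for (b in c("b1", "b2")) for (s in c("carrier", "free")) {
    volumes <- c(volumes, 10^(2.5 + 0.3 * (s == "free") + rnorm(10, 0, 0.1)))
    status <- c(status, rep(s, 10))
    bead <- c(bead, rep(b, 10))
  }
  tab <- makeAggRow(volumes[1], 10)[rep(1, 40), ]
  tab$volume <- volumes
  tab$channel <- status
  tab$bead <- bead
  tab$retained <- TRUE
  fit <- sizeByStatusLMM(tab)
  diffMeans <- mean(log10(volumes[status == "free"])) -
    mean(log10(volumes[status == "carrier"]))
  expect_equal(fit$estimate, diffMeans, tolerance = 1e-6)
  ols <- lm(log10(volumes) ~ factor(status, c("carrier", "free")))
  expect_equal(fit$estimate, unname(coef(ols)[2]), tolerance = 1e-6)
  ## single bead falls back to OLS with a warning
  one <- tab[tab$bead == "b1", ]
  expect_warning(fitOne <- sizeByStatusLMM(one), "single bead")
  expect_identical(fitOne$method, "OLS")
})

test_that("the pipeline order is filter then normalize, and the order matters", {
  tab <- rbind(makeAggRow(100, 50), makeAggRow(30, 90), makeAggRow(100, 60))
  pipelineOrder <- normalizeDistances(
    filterAggregates(tab, minVolume = 50, beadRadius = 100))
  ## the far aggregate (distance 90) is volume-filtered, so the max
  ## retained distance is 60 and the farthest retained maps to 1
  expect_equal(max(pipelineOrder$normalizedDistance[pipelineOrder$retained]), 1)
  expect_equal(pipelineOrder$normalizedDistance[1], 50 / 60)
  ## normalizing before filtering would have used 90 as the denominator
  wrongOrder <- tab
  wrongOrder$retained <- TRUE
  wrongOrder <- normalizeDistances(wrongOrder)
  expect_equal(wrongOrder$normalizedDistance[1], 50 / 90)
})

test_that("normalized distances are invariant to uniform voxel rescaling", {
  set.seed(103)
  d <- c(10, 12, 12)
  fm <- array(FALSE, d)
  fm[2:3, 2:3, 2:3] <- TRUE
  fm[7:9, 8:10, 8:10] <- TRUE
  cm <- array(FALSE, d)
  cm[5:6, 9:10, 2:3] <- TRUE
  for (scale in c(1, 3)) {
    vs <- c(2, 1, 1) * scale
    ctr <- beadCenter(fm, cm, vs)
    tab <- normalizeDistances(filterAggregates(
      detectAggregates(fm, cm, vs, ctr), minVolume = 0,
      beadRadius = 1000 * scale))
    if (scale == 1) ref <- tab$normalizedDistance
  }
  expect_equal(tab$normalizedDistance, ref)
})
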