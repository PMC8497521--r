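## Synthetic-data generators.
##
## The experiments these workflows target measure plasmid loss; they imply
## no generative model. Every distributional form here (binomial channel
## assignment per layer,
## log-linear aggregate size model, log-normal fluorescence mixture,
## segregational-loss recursion) is a package invention chosen to match the
## statistical structure the downstream analyses assume. Ground truth is
## always returned alongside the rendered data so each pipeline stage has a
## recoverable target.

.checkSeed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

## Draw integer intensities: signal + Gaussian detector noise, clipped at 0
## and rounded, emulating a 16-bit detector export.
.renderIntensity <- function(base, noiseMean, noiseSd) {
  pmin(pmax(round(base + rnorm(length(base), noiseMean, noiseSd)), 0), 65535) + 0
}

#' Flow-cell stack truth specification
#'
#' Parameters of a synthetic flow-cell biofilm stack: a depth-dependent
#' plasmid-loss profile and a biomass profile, plus imaging noise. The
#' defaults emulate a 48-h flow-cell biofilm imaged with a high-NA oil
#' objective: 40 optical sections of 128 x 128 pixels at
#' `(dz, dy, dx) = (0.5, 0.2, 0.2)` um, ~2000 biomass voxels per layer, and
#' a step loss profile (5% plasmid-free below mid-depth, 30% above) that
#' mimics elevated segregational loss among the actively growing top layers.
#'
#' @param nLayers number of z layers.
#' @param ny,nx lateral dimensions in voxels.
#' @param lossProfile function mapping layer index `z` (1-based) to the true
#'   plasmid-free proportion in `[0, 1]`.
#' @param biomassProfile function mapping layer index to the expected number
#'   of foreground (biomass) voxels in that layer.
#' @param voxelSize `(dz, dy, dx)` in micrometres.
#' @param signalMean,signalSd foreground intensity distribution.
#' @param noiseMean,noiseSd Gaussian background noise, clipped at zero.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @return an object of class `flowcellTruth`.
#' @export
flowcellTruth <- function(nLayers = 40L, ny = 128L, nx = 128L,
                          lossProfile = function(z)
                            ifelse(z <= nLayers / 2, 0.05, 0.30),
                          biomassProfile = function(z) rep(2000, length(z)),
                          voxelSize = c(dz = 0.5, dy = 0.2, dx = 0.2),
                          signalMean = 150, signalSd = 10,
                          noiseMean = 10, noiseSd = 3, seed = 1L) {
  z <- seq_len(nLayers)
  p <- lossProfile(z)
  B <- biomassProfile(z)
  stopifnot(all(is.finite(p)), all(p >= 0 & p <= 1),
            all(is.finite(B)), all(B >= 0), any(B > 0),
            all(B <= ny * nx), all(voxelSize > 0))
  structure(list(nLayers = as.integer(nLayers), ny = as.integer(ny),
                 nx = as.integer(nx), lossProfile = lossProfile,
                 biomassProfile = biomassProfile,
                 voxelSize = voxelSize, signalMean = signalMean,
                 signalSd = signalSd, noiseMean = noiseMean,
                 noiseSd = noiseSd, seed = seed),
            class = "flowcellTruth")
}

#' Generate a synthetic flow-cell stack
#'
#' Renders a two-channel stack in which layer `z` receives (exactly)
#' `round(B(z))` foreground voxels at random lateral positions, each
#' assigned to the green (plasmid-free) channel with probability
#' `p_loss(z)` and to the red (plasmid-carrying) channel otherwise.
#' Gaussian background noise is then added to both channels and intensities
#' are rounded to integers. The true per-layer counts are returned
#' alongside; before noise, they equal the rendered foreground voxels per
#' layer exactly.
#'
#' @param truth a [flowcellTruth()] specification.
#' @return list with elements `image` (a [VoxelImage-class]) and `truth`
#'   (data.frame: `z`, `nFree`, `nCarrier`, `pLoss`).
#' @export
simulateFlowcellStack <- function(truth) {
  stopifnot(inherits(truth, "flowcellTruth"))
  .checkSeed(truth$seed)
  nz <- truth$nLayers; ny <- truth$ny; nx <- truth$nx
  z <- seq_len(nz)
  B <- as.integer(round(truth$biomassProfile(z)))
  if (all(B == 0L)) stop("all-zero biomass profile")
  p <- truth$lossProfile(z)
  red <- array(0, c(nz, ny, nx))
  green <- array(0, c(nz, ny, nx))
  nFree <- integer(nz); nCarrier <- integer(nz)
  for (k in z) {
    if (B[k] == 0) next
    pos <- sample.int(ny * nx, B[k])           # distinct lateral positions
    isFree <- runif(B[k]) < p[k]
    nFree[k] <- sum(isFree)
    nCarrier[k] <- B[k] - nFree[k]
    sig <- rnorm(B[k], truth$signalMean, truth$signalSd)
    ## linear index of (k, pos) within the (z, y, x) array
    idx <- k + nz * (pos - 1L)
    green[idx[isFree]] <- sig[isFree]
    red[idx[!isFree]] <- sig[!isFree]
  }
  red <- array(.renderIntensity(red, truth$noiseMean, truth$noiseSd),
               c(nz, ny, nx))
  green <- array(.renderIntensity(green, truth$noiseMean, truth$noiseSd),
                 c(nz, ny, nx))
  list(image = VoxelImage(red = red, green = green,
                          voxelSize = truth$voxelSize),
       truth = data.frame(z = z, nFree = nFree, nCarrier = nCarrier,
                          pLoss = p))
}

#' Alginate-bead stack truth specification
#'
#' Parameters of a synthetic alginate-bead stack: discrete spherical
#' aggregates (microcolonies, one founder cell each) scattered inside a
#' spherical bead. Each aggregate draws a plasmid status (free with
#' probability `freeFraction`), a normalized radial distance, and a volume
#' from a log-linear size model `log10(volume um^3) = intercept(status) +
#' slope * distance + N(0, sigma)` - larger aggregates toward the bead
#' surface, plasmid-free aggregates larger at equal distance. Defaults
#' emulate a low-magnification bead scan with `(dz, dy, dx) = (2, 1, 1)` um.
#'
#' @param radiusUm bead radius in micrometres.
#' @param nAggregates number of aggregates to place.
#' @param interceptCarrier,interceptFree intercepts of the log10-volume
#'   model per plasmid status.
#' @param slope common slope of log10(volume) on normalized distance.
#' @param sigmaLog10 residual sd of log10(volume).
#' @param freeFraction probability an aggregate is plasmid-free.
#' @param voxelSize `(dz, dy, dx)` in micrometres.
#' @param margin voxels of empty border around the bead.
#' @param signalMean,signalSd,noiseMean,noiseSd as in [flowcellTruth()].
#' @param maxTries placement retries per aggregate before giving up.
#' @param seed integer seed.
#' @return an object of class `beadTruth`.
#' @export
beadTruth <- function(radiusUm = 150, nAggregates = 150L,
                      interceptCarrier = 2.8, interceptFree = 3.1,
                      slope = 0.8, sigmaLog10 = 0.15, freeFraction = 0.2,
                      voxelSize = c(dz = 2, dy = 1, dx = 1), margin = 4L,
                      signalMean = 150, signalSd = 10,
                      noiseMean = 10, noiseSd = 3,
                      maxTries = 200L, seed = 1L) {
  stopifnot(radiusUm > 0, nAggregates >= 0,
            freeFraction >= 0, freeFraction <= 1,
            sigmaLog10 >= 0, all(voxelSize > 0))
  structure(list(radiusUm = radiusUm, nAggregates = as.integer(nAggregates),
                 interceptCarrier = interceptCarrier,
                 interceptFree = interceptFree, slope = slope,
                 sigmaLog10 = sigmaLog10, freeFraction = freeFraction,
                 voxelSize = voxelSize, margin = as.integer(margin),
                 signalMean = signalMean, signalSd = signalSd,
                 noiseMean = noiseMean, noiseSd = noiseSd,
                 maxTries = as.integer(maxTries), seed = seed),
            class = "beadTruth")
}

## Voxel centers sit at (index - 1) * voxelSize micrometres, a convention
## shared with centroid and distance computations in the bead module.
## Returns the linear indices of the voxels whose centers fall inside the
## sphere, so the caller can fill them without copying whole arrays.
.sphereVoxels <- function(d, centerUm, radiusUm, voxelSize) {
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, floor(centerUm[a] / voxelSize[a] - radiusUm / voxelSize[a]))
    hi <- min(d[a], ceiling(centerUm[a] / voxelSize[a] + radiusUm / voxelSize[a]) + 1L)
    lo:hi
  })
  g <- expand.grid(i = rng[[1]], j = rng[[2]], k = rng[[3]])
  inside <- ((g$i - 1) * voxelSize[1] - centerUm[1])^2 +
    ((g$j - 1) * voxelSize[2] - centerUm[2])^2 +
    ((g$k - 1) * voxelSize[3] - centerUm[3])^2 <= radiusUm^2
  g$i[inside] + d[1] * ((g$j[inside] - 1L) + d[2] * (g$k[inside] - 1L))
}

#' Generate a synthetic alginate-bead stack
#'
#' Places non-overlapping voxelized spherical aggregates inside a spherical
#' bead (rejection-sampled positions; aggregates additionally keep a
#' two-voxel gap so 26-connected labeling cannot merge neighbors), renders
#' each into the channel of its plasmid status, adds background noise, and
#' returns the ground-truth table.
#'
#' @param truth a [beadTruth()] specification.
#' @param beadId identifier recorded in the truth table.
#' @return list with `image` (a [VoxelImage-class]), `truth` (data.frame:
#'   `bead`, `channel`, `volumeRequested`, `voxels`, `volumeRendered`,
#'   `cz`, `cy`, `cx` (um), `distance` (um), `normalizedDistance`), and
#'   `center` (bead center in um).
#' @export
simulateBeadStack <- function(truth, beadId = "bead1") {
  stopifnot(inherits(truth, "beadTruth"))
  .checkSeed(truth$seed)
  vs <- truth$voxelSize
  R <- truth$radiusUm
  d <- c(ceiling(2 * R / vs[1]) + 2 * truth$margin,
         ceiling(2 * R / vs[2]) + 2 * truth$margin,
         ceiling(2 * R / vs[3]) + 2 * truth$margin)
  centerUm <- (d - 1) / 2 * vs
  red <- array(0, d); green <- array(0, d)
  n <- truth$nAggregates
  rows <- vector("list", n)
  placed <- matrix(numeric(0), ncol = 4)  # cz, cy, cx, radius
  gap <- 2 * max(vs)
  for (i in seq_len(n)) {
    isFree <- runif(1) < truth$freeFraction
    intercept <- if (isFree) truth$interceptFree else truth$interceptCarrier
    ok <- FALSE
    ## rejection sampling: redraw distance, volume and direction until the
    ## aggregate fits inside the bead without touching a placed one
    for (try in seq_len(truth$maxTries)) {
      dNorm <- runif(1)
      vol <- 10^(intercept + truth$slope * dNorm +
                   rnorm(1, 0, truth$sigmaLog10))
      rAgg <- (3 * vol / (4 * pi))^(1 / 3)
      if (dNorm * R + rAgg > R) next          # must fit inside the bead
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      pos <- centerUm + dNorm * R * u
      if (nrow(placed)) {
        dd <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - pos)^2))
        if (any(dd < placed[, 4] + rAgg + gap)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf("could not place aggregate %d without overlap after %d tries",
                   i, truth$maxTries))
    placed <- rbind(placed, c(pos, rAgg))
    sig <- rnorm(1, truth$signalMean, truth$signalSd)
    idx <- .sphereVoxels(d, pos, rAgg, vs)
    if (isFree) green[idx] <- sig else red[idx] <- sig
    rows[[i]] <- data.frame(
      bead = beadId, channel = if (isFree) "free" else "carrier",
      volumeRequested = vol, voxels = length(idx),
      volumeRendered = length(idx) * prod(vs),
      cz = pos[1], cy = pos[2], cx = pos[3],
      distance = dNorm * R, normalizedDistance = dNorm,
      stringsAsFactors = FALSE)
  }
  red <- array(.renderIntensity(red, truth$noiseMean, truth$noiseSd), d)
  green <- array(.renderIntensity(green, truth$noiseMean, truth$noiseSd), d)
  tt <- if (n > 0) do.call(rbind, rows) else
    data.frame(bead = character(), channel = character(),
               volumeRequested = numeric(), voxels = integer(),
               volumeRendered = numeric(), cz = numeric(), cy = numeric(),
               cx = numeric(), distance = numeric(),
               normalizedDistance = numeric(), stringsAsFactors = FALSE)
  list(image = VoxelImage(red = red, green = green, voxelSize = vs),
       truth = tt, center = centerUm)
}

#' FACS event-table truth specification
#'
#' Mixture model for synthetic flow-cytometry events: plasmid-carrying
#' cells (red-bright, green-dim), plasmid-free cells (green-bright,
#' red-dim) and optional dim debris, each with log10-normal intensities in
#' both detectors. Defaults put the carrier and free populations 8 log-sd
#' apart, comfortably separable like a clean dual-reporter experiment.
#'
#' @param nEvents number of events.
#' @param freeFraction true plasmid-free fraction among cells (not debris).
#' @param debrisFraction fraction of all events that are debris.
#' @param carrier,free,debris per-class named vectors
#'   `c(gMean, gSd, rMean, rSd)` of log10-intensity parameters.
#' @param seed integer seed.
#' @return an object of class `facsTruth`.
#' @export
facsTruth <- function(nEvents = 10000L, freeFraction = 0.5,
                      debrisFraction = 0.05,
                      carrier = c(gMean = 1.2, gSd = 0.25, rMean = 3.2, rSd = 0.25),
                      free = c(gMean = 3.2, gSd = 0.25, rMean = 1.2, rSd = 0.25),
                      debris = c(gMean = 0.6, gSd = 0.3, rMean = 0.6, rSd = 0.3),
                      seed = 1L) {
  stopifnot(nEvents >= 0, freeFraction >= 0, freeFraction <= 1,
            debrisFraction >= 0, debrisFraction < 1,
            carrier[c("gSd", "rSd")] > 0, free[c("gSd", "rSd")] > 0,
            debris[c("gSd", "rSd")] > 0)
  structure(list(nEvents = as.integer(nEvents), freeFraction = freeFraction,
                 debrisFraction = debrisFraction, carrier = carrier,
                 free = free, debris = debris, seed = seed),
            class = "facsTruth")
}

#' Generate a synthetic FACS event table
#'
#' Draws `nEvents` events from the carrier/free/debris mixture with
#' log10-normal green and red intensities. The true class of each event is
#' stored in `trueClass` for validation of the gating stage.
#'
#' @param truth a [facsTruth()] specification.
#' @param strain,plasmid,day,bioRep,techRep metadata stamped on every event.
#' @return data.frame with columns `green`, `red`, `trueClass`, `strain`,
#'   `plasmid`, `day`, `bioRep`, `techRep`.
#' @export
simulateFacsEvents <- function(truth, strain = "WT", plasmid = "conjugative",
                               day = 0L, bioRep = 1L, techRep = 1L) {
  stopifnot(inherits(truth, "facsTruth"))
  .checkSeed(truth$seed)
  n <- truth$nEvents
  if (n == 0L)
    return(data.frame(green = numeric(), red = numeric(),
                      trueClass = character(), strain = character(),
                      plasmid = character(), day = integer(),
                      bioRep = integer(), techRep = integer(),
                      stringsAsFactors = FALSE))
  isDebris <- runif(n) < truth$debrisFraction
  isFree <- !isDebris & runif(n) < truth$freeFraction
  cls <- ifelse(isDebris, "debris", ifelse(isFree, "free", "carrier"))
  par <- rbind(carrier = truth$carrier, free = truth$free,
               debris = truth$debris)
  g <- 10^rnorm(n, par[cls, "gMean"], par[cls, "gSd"])
  r <- 10^rnorm(n, par[cls, "rMean"], par[cls, "rSd"])
  data.frame(green = g, red = r, trueClass = cls, strain = strain,
             plasmid = plasmid, day = as.integer(day),
             bioRep = as.integer(bioRep), techRep = as.integer(techRep),
             stringsAsFactors = FALSE)
}

#' Loss-trajectory truth specification
#'
#' Deterministic recursion for the plasmid-free fraction under
#' segregational loss and a selective cost of carriage. Per generation,
#' with free fraction `f`, segregational loss probability `lambdaSeg` and
#' per-generation selective advantage `sCost` of the plasmid-free type:
#' `f' = (f * (1 + sCost) + (1 - f) * lambdaSeg) /
#'       (f * (1 + sCost) + (1 - f))`.
#' The recursion is applied `generationsPerDay` times per day. No
#' quantitative loss rates are reported for the source system, so the
#' defaults are illustrative.
#'
#' @param lambdaSeg segregational loss probability per division in `[0,1]`.
#' @param sCost selective advantage of plasmid-free cells per generation.
#' @param generationsPerDay generations elapsed per day.
#' @param days number of days (day 0 = initial state is also reported).
#' @param f0 initial plasmid-free fraction.
#' @return an object of class `trajectoryTruth`.
#' @export
trajectoryTruth <- function(lambdaSeg = 0.001, sCost = 0.05,
                            generationsPerDay = 10, days = 4L, f0 = 0) {
  stopifnot(lambdaSeg >= 0, lambdaSeg <= 1, days >= 1, f0 >= 0, f0 <= 1,
            generationsPerDay > 0)
  structure(list(lambdaSeg = lambdaSeg, sCost = sCost,
                 generationsPerDay = generationsPerDay,
                 days = as.integer(days), f0 = f0),
            class = "trajectoryTruth")
}

.lossStep <- function(f, lambdaSeg, sCost) {
  num <- f * (1 + sCost) + (1 - f) * lambdaSeg
  den <- f * (1 + sCost) + (1 - f)
  num / den
}

#' Generate a multi-day plasmid-loss trajectory
#'
#' Iterates the segregational-loss recursion of [trajectoryTruth()]
#' `generationsPerDay` times per day, then emulates a daily FACS
#' measurement by sampling `samplingN` cells binomially at the expected
#' fraction. With `sCost >= 0` and `lambdaSeg >= 0` the expected fraction
#' is non-decreasing.
#'
#' @param truth a [trajectoryTruth()] specification.
#' @param samplingN cells sampled per measurement (>= 1).
#' @param seed integer seed for the binomial sampling.
#' @param strain,plasmid,bioRep metadata stamped on the trajectory.
#' @return data.frame with one row per day (0..days): `day`,
#'   `expectedFraction`, `fraction` (sampled), plus metadata columns.
#' @export
simulateLossTimecourse <- function(truth, samplingN = 10000L, seed = 1L,
                                   strain = "WT", plasmid = "conjugative",
                                   bioRep = 1L) {
  stopifnot(inherits(truth, "trajectoryTruth"), samplingN >= 1)
  .checkSeed(seed)
  f <- truth$f0
  expected <- numeric(truth$days + 1L)
  expected[1L] <- f
  for (d in seq_len(truth$days)) {
    for (g in seq_len(truth$generationsPerDay))
      f <- .lossStep(f, truth$lambdaSeg, truth$sCost)
    expected[d + 1L] <- f
  }
  sampled <- rbinom(length(expected), samplingN, expected) / samplingN
  data.frame(day = 0:truth$days, expectedFraction = expected,
             fraction = sampled, strain = strain, plasmid = plasmid,
             bioRep = as.integer(bioRep), stringsAsFactors = FALSE)
}
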