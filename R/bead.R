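## Alginate-bead aggregate quantification. Voxel centers sit at
## (index - 1) * voxelSize micrometres along each axis; all centroids and
## distances are physical (um) unless voxelUnits = TRUE is requested.

.foregroundCoords <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(NULL)
  arrayInd(idx, dim(mask))
}

#' Bead center as the median foreground position
#'
#' The bead center is the coordinate-wise median position of all
#' foreground voxels in the image (union of both channels), converted to
#' micrometres. The median makes the center robust to stray voxels far
#' from the bead, unlike the mean.
#'
#' @param freeMask,carrierMask [BinaryMask-class] objects (or logical 3D
#'   arrays) for the green and red channels.
#' @param voxelSize `(dz, dy, dx)` in micrometres.
#' @return named numeric `(z, y, x)` center in micrometres; attribute
#'   `nVoxels` gives the number of foreground voxels used.
#' @export
beadCenter <- function(freeMask, carrierMask, voxelSize) {
  fm <- if (is(freeMask, "BinaryMask")) maskArray(freeMask) else freeMask
  cm <- if (is(carrierMask, "BinaryMask")) maskArray(carrierMask) else carrierMask
  stopifnot(identical(dim(fm), dim(cm)))
  co <- .foregroundCoords(fm | cm)
  if (is.null(co)) stop("no foreground voxels: cannot locate bead center")
  ctr <- (apply(co, 2L, median) - 1) * voxelSize
  names(ctr) <- c("z", "y", "x")
  attr(ctr, "nVoxels") <- nrow(co)
  ctr
}

.channelAggregates <- function(mask, channelLabel, voxelSize, center,
                               beadId, connectivity) {
  lm <- labelComponents(mask, connectivity)
  K <- nComponents(lm)
  empty <- data.frame(bead = character(), channel = character(),
                      label = integer(), voxels = integer(),
                      volume = numeric(), cz = numeric(), cy = numeric(),
                      cx = numeric(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (K == 0L) return(empty)
  lab <- labelArray(lm)
  idx <- which(lab > 0L)
  lb <- lab[idx]
  co <- arrayInd(idx, dim(lab))
  nv <- tabulate(lb, K)
  cz <- (rowsum(co[, 1], lb)[, 1] / nv - 1) * voxelSize[1]
  cy <- (rowsum(co[, 2], lb)[, 1] / nv - 1) * voxelSize[2]
  cx <- (rowsum(co[, 3], lb)[, 1] / nv - 1) * voxelSize[3]
  data.frame(bead = beadId, channel = channelLabel, label = seq_len(K),
             voxels = nv, volume = nv * prod(voxelSize), cz = cz, cy = cy,
             cx = cx,
             distance = sqrt((cz - center[1])^2 + (cy - center[2])^2 +
                               (cx - center[3])^2),
             stringsAsFactors = FALSE)
}

#' Detect aggregates in bead masks
#'
#' Labels each channel independently under 26-connectivity ("grouping
#' adjacent voxels including diagonals"), then measures every component:
#' voxel count, physical volume (count x voxel volume, exactly), centroid
#' (unweighted mean voxel position in um) and Euclidean distance from the
#' centroid to the bead center.
#'
#' @param freeMask,carrierMask [BinaryMask-class] objects or logical arrays.
#' @param voxelSize `(dz, dy, dx)` in micrometres.
#' @param center bead center in um, e.g. from [beadCenter()].
#' @param beadId bead identifier for multi-bead tables.
#' @param connectivity voxel adjacency (default 26).
#' @return an AggregateTable: one row per aggregate with columns `bead`,
#'   `channel` (`"free"`/`"carrier"`), `label`, `voxels`, `volume` (um^3),
#'   `cz`, `cy`, `cx` (um), `distance` (um), plus `retained`,
#'   `removalReason`, `normalizedDistance` initialized for the filtering
#'   and normalization steps.
#' @export
detectAggregates <- function(freeMask, carrierMask, voxelSize, center,
                             beadId = "bead1", connectivity = 26L) {
  fm <- if (is(freeMask, "BinaryMask")) maskArray(freeMask) else freeMask
  cm <- if (is(carrierMask, "BinaryMask")) maskArray(carrierMask) else carrierMask
  if (!identical(dim(fm), dim(cm))) stop("masks must share shape")
  out <- rbind(
    .channelAggregates(fm, "free", voxelSize, center, beadId, connectivity),
    .channelAggregates(cm, "carrier", voxelSize, center, beadId, connectivity))
  out$retained <- rep(NA, nrow(out))
  out$removalReason <- rep(NA_character_, nrow(out))
  out$normalizedDistance <- rep(NA_real_, nrow(out))
  out
}

#' Filter aggregates by volume and bead membership
#'
#' Discards aggregates smaller than `minVolume` (strictly below; an
#' aggregate of exactly 50 um^3 is retained) and aggregates lying outside
#' the bead. "Outside" is automated as distance beyond
#' `exclusionFactor x bead radius`; the radius is taken from `beadRadius`
#' when known, otherwise estimated per bead as the 99th percentile of the
#' distances of volume-passing aggregates (robust to stragglers). Removals
#' are recorded in `removalReason`.
#'
#' @param table an AggregateTable from [detectAggregates()].
#' @param minVolume minimum aggregate volume in um^3 (default 50).
#' @param beadRadius known bead radius in um, or `NULL` to estimate.
#' @param exclusionFactor multiple of the radius beyond which aggregates
#'   are treated as outside the bead (default 1.1).
#' @param radiusQuantile quantile of distances used for the radius
#'   estimate (default 0.99).
#' @return the table with `retained` and `removalReason` filled in.
#' @export
filterAggregates <- function(table, minVolume = 50, beadRadius = NULL,
                             exclusionFactor = 1.1, radiusQuantile = 0.99) {
  if (!nrow(table)) return(table)
  stopifnot(all(c("bead", "volume", "distance") %in% names(table)))
  table$retained <- TRUE
  table$removalReason <- NA_character_
  small <- table$volume < minVolume
  table$retained[small] <- FALSE
  table$removalReason[small] <- "below minimum volume"
  for (b in unique(table$bead)) {
    sel <- table$bead == b
    radius <- if (!is.null(beadRadius)) beadRadius else {
      ds <- table$distance[sel & !small]
      if (!length(ds)) next
      quantile(ds, radiusQuantile, names = FALSE)
    }
    outside <- sel & table$distance > exclusionFactor * radius
    table$retained[outside] <- FALSE
    table$removalReason[outside] <- ifelse(
      small[outside], "below minimum volume; outside bead", "outside bead")
  }
  table
}

#' Normalize aggregate distances per bead
#'
#' Divides each retained aggregate's distance to the bead center by the
#' maximum retained distance of its bead, so the farthest aggregate maps
#' to exactly 1. Applied after filtering (the maximum is taken over
#' retained aggregates). A bead with a single retained aggregate gets
#' normalized distance 1.0 and a warning.
#'
#' @param table a filtered AggregateTable.
#' @return the table with `normalizedDistance` set for retained rows.
#' @export
normalizeDistances <- function(table) {
  if (!nrow(table)) return(table)
  if (!any(table$retained %in% TRUE))
    stop("no retained aggregates to normalize")
  for (b in unique(table$bead)) {
    sel <- which(table$bead == b & table$retained %in% TRUE)
    if (!length(sel)) next
    if (length(sel) == 1L)
      warning(sprintf("bead '%s' has a single retained aggregate; its normalized distance is set to 1", b))
    table$normalizedDistance[sel] <-
      table$distance[sel] / max(table$distance[sel])
  }
  table
}

#' Plasmid-loss ratio from aggregate counts
#'
#' Ratio of plasmid-free (green) to plasmid-carrying (red) retained
#' aggregate counts, reflecting the rate of plasmid loss. Both the pooled
#' ratio (all beads' aggregates pooled) and the per-bead ratios (for a
#' boxplot across beads) are returned; a bead without carrier aggregates
#' yields an infinite ratio with a flag.
#'
#' @param table a filtered AggregateTable.
#' @return list with `pooled` (single ratio), `perBead` (data.frame:
#'   `bead`, `nFree`, `nCarrier`, `ratio`, `infinite`).
#' @export
lossRatio <- function(table) {
  tab <- table[table$retained %in% TRUE, , drop = FALSE]
  perBead <- do.call(rbind, lapply(unique(tab$bead), function(b) {
    sub <- tab[tab$bead == b, , drop = FALSE]
    nF <- sum(sub$channel == "free")
    nC <- sum(sub$channel == "carrier")
    data.frame(bead = b, nFree = nF, nCarrier = nC, ratio = nF / nC,
               infinite = nC == 0 & nF > 0, stringsAsFactors = FALSE)
  }))
  nF <- sum(tab$channel == "free")
  nC <- sum(tab$channel == "carrier")
  list(pooled = nF / nC, perBead = perBead)
}

#' Regression of aggregate size on radial position
#'
#' Ordinary least squares of `log10(volume um^3)` on normalized distance
#' from the bead center, over retained aggregates, with a 95% confidence
#' band. A positive slope means aggregates grow larger toward the bead
#' surface.
#'
#' @param table a filtered, distance-normalized AggregateTable.
#' @param level confidence level for the interval (default 0.95).
#' @return list with `slope`, `intercept`, `slopeSE`, `slopeCI`, `fit`
#'   (the `lm` object), and `band` (data.frame of fitted values with
#'   confidence limits over the observed distance range).
#' @export
sizeDistanceRegression <- function(table, level = 0.95) {
  tab <- table[table$retained %in% TRUE, , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 retained aggregates")
  if (sd(tab$normalizedDistance) == 0)
    stop("zero variance in normalized distance")
  dat <- data.frame(logVol = log10(tab$volume), d = tab$normalizedDistance)
  fit <- lm(logVol ~ d, data = dat)
  sm <- summary(fit)
  ci <- confint(fit, "d", level = level)
  grid <- data.frame(d = seq(min(dat$d), max(dat$d), length.out = 50))
  pr <- predict(fit, grid, interval = "confidence", level = level)
  list(slope = unname(coef(fit)["d"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       slopeSE = sm$coefficients["d", "Std. Error"],
       slopeCI = c(ci[1], ci[2]), fit = fit,
       band = cbind(grid, as.data.frame(pr)))
}

#' Mixed-effects model of aggregate size by plasmid status
#'
#' Random-intercept model `log10(volume) ~ status + (1 | bead)` fitted by
#' REML, testing whether plasmid-free aggregates are larger than
#' plasmid-carrying ones at the same bead. The reported p-value uses a
#' normal approximation on estimate/SE (labelled as such); with a single
#' bead the model falls back to OLS with a warning.
#'
#' @param table a filtered AggregateTable with both statuses present.
#' @return list with `estimate` (free minus carrier, log10 units), `se`,
#'   `z`, `p` (normal approximation), `varBead`, `varResidual`, `nBeads`,
#'   `method` (`"REML"` or `"OLS"`), and `fit`.
#' @export
sizeByStatusLMM <- function(table) {
  tab <- table[table$retained %in% TRUE, , drop = FALSE]
  if (!all(c("free", "carrier") %in% tab$channel))
    stop("both plasmid statuses must be present")
  dat <- data.frame(logVol = log10(tab$volume),
                    status = factor(tab$channel, c("carrier", "free")),
                    bead = factor(tab$bead))
  nBeads <- nlevels(dat$bead)
  if (nBeads < 2L) {
    warning("single bead: falling back to OLS (no random intercept identifiable)")
    fit <- lm(logVol ~ status, data = dat)
    sm <- summary(fit)$coefficients
    est <- sm["statusfree", "Estimate"]; se <- sm["statusfree", "Std. Error"]
    return(list(estimate = est, se = se, z = est / se,
                p = 2 * pnorm(-abs(est / se)), varBead = 0,
                varResidual = summary(fit)$sigma^2, nBeads = nBeads,
                method = "OLS", fit = fit))
  }
  fit <- lme4::lmer(logVol ~ status + (1 | bead), data = dat, REML = TRUE)
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))["statusfree"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- unname(fe["statusfree"]); se <- unname(se)
  list(estimate = est, se = se, z = est / se, p = 2 * pnorm(-abs(est / se)),
       varBead = vc$vcov[vc$grp == "bead"],
       varResidual = vc$vcov[vc$grp == "Residual"],
       nBeads = nBeads, method = "REML", fit = fit)
}
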