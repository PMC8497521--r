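#' Per-layer voxel counts from segmented flow-cell masks
#'
#' Counts plasmid-free (green) and plasmid-carrying (red) foreground voxels
#' in every z layer of a segmented stack. Biomass per layer is their sum.
#'
#' @param freeMask [BinaryMask-class] of the green (plasmid-free) channel.
#' @param carrierMask [BinaryMask-class] of the red channel.
#' @return a ZProfile: data.frame with columns `z` (layer index, image
#'   order), `nFree`, `nCarrier`, `biomass`.
#' @export
layerProfile <- function(freeMask, carrierMask) {
  fm <- if (is(freeMask, "BinaryMask")) maskArray(freeMask) else freeMask
  cm <- if (is(carrierMask, "BinaryMask")) maskArray(carrierMask) else carrierMask
  if (!identical(dim(fm), dim(cm)))
    stop("free and carrier masks must share shape")
  nFree <- apply(fm, 1L, sum)
  nCarrier <- apply(cm, 1L, sum)
  data.frame(z = seq_len(dim(fm)[1]), nFree = nFree, nCarrier = nCarrier,
             biomass = nFree + nCarrier)
}

#' Recenter layer positions on the biomass-weighted mean
#'
#' Shifts z positions by subtracting the biomass-weighted average layer, so
#' corrected position 0 marks the biomass center of mass and stacks of
#' different total thickness become comparable. The layer with the most
#' biomass does not coincide with the weighted mean in general; its
#' corrected position is reported as the `modalZCorrected` attribute as a
#' diagnostic.
#'
#' @param profile a ZProfile data.frame (from [layerProfile()]).
#' @return the profile with a `zCorrected` column; attribute
#'   `modalZCorrected` gives the corrected position of the biomass mode.
#' @export
recenterZ <- function(profile) {
  stopifnot(all(c("z", "biomass") %in% names(profile)))
  tot <- sum(profile$biomass)
  if (tot <= 0) stop("zero total biomass: cannot recenter")
  shift <- sum(profile$z * profile$biomass) / tot
  profile$zCorrected <- profile$z - shift
  attr(profile, "modalZCorrected") <-
    profile$zCorrected[which.max(profile$biomass)]
  profile
}

#' Average aligned profiles across images of one biological replicate
#'
#' Corrected z positions are generally non-integer, so profiles from
#' different images are aligned by binning `zCorrected` to unit-layer bins
#' centered on integers (`round(zCorrected)`), then voxel counts are
#' averaged per bin across the images that cover it.
#'
#' @param profiles list of recentered ZProfiles (each with `zCorrected`).
#' @return averaged ZProfile with columns `zCorrected` (bin center),
#'   `nFree`, `nCarrier`, `biomass`, `nImages` (images covering the bin).
#' @export
averageReplicates <- function(profiles) {
  if (!length(profiles)) stop("empty profile group")
  stopifnot(all(vapply(profiles, function(p) "zCorrected" %in% names(p),
                       logical(1))))
  pooled <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    data.frame(img = i, bin = round(p$zCorrected), nFree = p$nFree,
               nCarrier = p$nCarrier)
  }))
  ## an image may contribute several layers to one bin: sum within image
  perImg <- aggregate(cbind(nFree, nCarrier) ~ img + bin, pooled, sum)
  avg <- aggregate(cbind(nFree, nCarrier) ~ bin, perImg, mean)
  nImg <- aggregate(img ~ bin, perImg, function(v) length(unique(v)))
  out <- data.frame(zCorrected = avg$bin, nFree = avg$nFree,
                    nCarrier = avg$nCarrier,
                    biomass = avg$nFree + avg$nCarrier,
                    nImages = nImg$img[match(avg$bin, nImg$bin)])
  out[order(out$zCorrected), , drop = FALSE]
}

#' Per-layer plasmid-loss proportion
#'
#' The proportion of plasmid-free biomass per layer,
#' `p(z) = nFree / (nFree + nCarrier)`. Layers without biomass are flagged
#' (`defined = FALSE`, proportion `NA`), never imputed.
#'
#' @param profile a ZProfile data.frame.
#' @return the profile with columns `pLoss` and `defined` added.
#' @export
lossProportion <- function(profile) {
  stopifnot(all(c("nFree", "nCarrier") %in% names(profile)))
  B <- profile$nFree + profile$nCarrier
  profile$pLoss <- ifelse(B > 0, profile$nFree / B, NA_real_)
  profile$defined <- B > 0
  profile
}

#' Biomass-weighted LOESS curve of plasmid loss
#'
#' Locally weighted polynomial regression (tricube kernel, degree 2 by
#' default) of the loss proportion on position, with the per-layer biomass
#' entering as prior weights so that dense layers dominate the fit. Points
#' with zero weight or undefined response are dropped before fitting;
#' fitted values are also reported clipped to `[0, 1]`, the range of a
#' proportion.
#'
#' @param x positions (e.g. corrected z).
#' @param y proportions at `x`.
#' @param w biomass weights, `>= 0`.
#' @param span LOESS span (fraction of points in each local window).
#' @param degree local polynomial degree (1 or 2).
#' @param at positions at which to evaluate the curve (default `x` with
#'   positive weight).
#' @return a LossCurve data.frame: `position`, `fitted`, `clipped`;
#'   attributes `span` and `degree`.
#' @export
weightedLoess <- function(x, y, w, span = 0.75, degree = 2, at = NULL) {
  keep <- is.finite(x) & is.finite(y) & is.finite(w) & w > 0
  if (!any(keep)) stop("all weights are zero or non-finite")
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 3L)
    stop("need at least 3 points with positive weight")
  if (is.null(at)) at <- x
  fit <- loess(y ~ x, weights = w, span = span, degree = degree,
               surface = "direct",
               control = loess.control(statistics = "exact"))
  f <- predict(fit, data.frame(x = at))
  out <- data.frame(position = at, fitted = f,
                    clipped = pmin(pmax(f, 0), 1))
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  out
}

#' Split a recentered profile into top and bottom strata
#'
#' Bottom = layers with corrected z below 0, top = layers at or above 0
#' (the boundary layer, if any lands exactly on 0, goes to the top). With
#' recentering on the biomass-weighted mean, each stratum holds half the
#' biomass up to the discretization limit of the boundary layer. The
#' per-stratum statistic is the ratio of plasmid-free to plasmid-carrying
#' voxels aggregated over the stratum (equivalent to a biomass-weighted
#' average of per-layer ratios); a stratum without carrier voxels yields an
#' infinite ratio with a flag.
#'
#' @param profile recentered ZProfile (needs `zCorrected`).
#' @param perLayerMean alternatively average the per-layer free:carrier
#'   ratios unweighted (sensitivity option; default `FALSE` aggregates
#'   counts first).
#' @return StratifiedRatios data.frame: `stratum` (`"bottom"`, `"top"`),
#'   `nFree`, `nCarrier`, `biomass`, `ratio`, `infinite`.
#' @export
splitTopBottom <- function(profile, perLayerMean = FALSE) {
  if (!"zCorrected" %in% names(profile))
    stop("profile must be recentered first (see recenterZ())")
  used <- profile[profile$biomass > 0, , drop = FALSE]
  strata <- ifelse(used$zCorrected < 0, "bottom", "top")
  out <- do.call(rbind, lapply(c("bottom", "top"), function(s) {
    sub <- used[strata == s, , drop = FALSE]
    nF <- sum(sub$nFree); nC <- sum(sub$nCarrier)
    ratio <- if (perLayerMean) {
      r <- sub$nFree / sub$nCarrier
      mean(r[is.finite(r)])
    } else nF / nC
    data.frame(stratum = s, nFree = nF, nCarrier = nC, biomass = nF + nC,
               ratio = ratio, infinite = is.infinite(ratio) | (nC == 0 & nF > 0),
               stringsAsFactors = FALSE)
  }))
  boundary <- used$biomass[used$zCorrected >= 0][1]
  attr(out, "boundaryBiomass") <-
    if (is.na(boundary)) 0 else boundary
  out
}

#' Two-way ANOVA of stratum ratios across images and plasmid variants
#'
#' Fixed-effects two-way analysis (factors: stratum, plasmid; no
#' interaction by default, matching a main-effects report) of per-image
#' free:carrier ratios. Observations with non-finite ratios are dropped
#' with a warning. If a factor has a single level the analysis drops to
#' one-way with a warning.
#'
#' @param ratios data.frame with columns `ratio`, `stratum`, `plasmid`
#'   (one row per image x stratum).
#' @param interaction include the stratum:plasmid interaction.
#' @return ANOVA table (data.frame) from [twoWayAnova()].
#' @export
compareStrata <- function(ratios, interaction = FALSE) {
  stopifnot(all(c("ratio", "stratum", "plasmid") %in% names(ratios)))
  ok <- is.finite(ratios$ratio)
  if (!all(ok)) {
    warning(sprintf("dropping %d non-finite ratio(s)", sum(!ok)))
    ratios <- ratios[ok, , drop = FALSE]
  }
  twoWayAnova(ratios$ratio, factor(ratios$stratum), factor(ratios$plasmid),
              names = c("stratum", "plasmid"), interaction = interaction)
}
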