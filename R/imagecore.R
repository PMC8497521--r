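#' 3x3x3 median smoothing of a 3D array
#'
#' Replaces each voxel by the median of its 3x3x3 neighborhood. Borders are
#' handled by edge replication (indices clamped to the array), so every
#' neighborhood contains exactly 27 values and object borders at the stack
#' boundary are not dimmed. The filter suppresses isolated bright voxels
#' (shot noise) while leaving constant regions untouched.
#'
#' @param x numeric 3D array `(z, y, x)`.
#' @return numeric 3D array of the same shape.
#' @examples
#' a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 100
#' max(medianSmooth3D(a))  # isolated voxel removed -> 0
#' @export
medianSmooth3D <- function(x) {
  d <- dim(x)
  if (length(d) != 3L)
    stop("medianSmooth3D() expects a 3D array")
  if (any(d < 1L))
    stop("each axis must have at least one voxel")
  median_filter_3d(as.numeric(x), as.integer(d))
}

## Histogram construction shared by the thresholding criteria: uniform bins
## over the intensity range; values landing exactly on the upper range
## boundary fall in the last bin.
.intensityHistogram <- function(x, nBins) {
  v <- as.vector(x)
  rmin <- min(v); rmax <- max(v)
  if (rmax <= rmin)
    stop("degenerate histogram: image has a single intensity value")
  breaks <- seq(rmin, rmax, length.out = nBins + 1L)
  counts <- tabulate(.bincode(v, breaks, include.lowest = TRUE), nBins)
  list(counts = counts, mids = (breaks[-1L] + breaks[-(nBins + 1L)]) / 2)
}

## Criterion evaluators. Each returns a numeric vector over candidate cuts
## t = 1..(B-1), where cut t separates bins {1..t} from {t+1..B}; invalid
## cuts (an empty class) get -Inf. The chosen cut is the lowest maximizer.
.otsuCriterion <- function(p, mids) {
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  muT <- mu[length(mu)]
  crit <- (muT * omega - mu)^2 / (omega * (1 - omega))
  crit[!is.finite(crit)] <- -Inf
  crit[-length(crit)]
}

.yenCriterion <- function(p, mids) {
  omega <- cumsum(p)
  s1 <- cumsum(p^2)
  s2 <- sum(p^2) - s1
  crit <- -log(pmax(s1 * s2, .Machine$double.xmin)) +
    2 * log(pmax(omega * (1 - omega), .Machine$double.xmin))
  bad <- omega <= 0 | omega >= 1 | s1 <= 0 | s2 <= 0
  crit[bad] <- -Inf
  crit[-length(crit)]
}

## Tsai's moment-preserving threshold: choose the cut whose background mass
## is closest to the fraction p0 that preserves the first three gray-level
## moments under a two-level (bimodal) representation.
.momentsTargetFraction <- function(p, mids) {
  m1 <- sum(p * mids)
  m2 <- sum(p * mids^2)
  m3 <- sum(p * mids^3)
  cd <- m2 - m1^2
  if (cd <= 0)
    stop("degenerate histogram: zero variance")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- (-c1 - sqrt(disc)) / 2
  z1 <- (-c1 + sqrt(disc)) / 2
  if (z1 <= z0) return(0.5)
  (z1 - m1) / (z1 - z0)
}

#' Automatic threshold selection (Otsu, Yen, Moments)
#'
#' Computes a global intensity threshold from the image histogram.
#' `"otsu"` maximizes the between-class variance, `"yen"` maximizes Yen's
#' maximum-correlation (entropic) criterion, and `"moments"` is Tsai's
#' moment-preserving threshold (the cut whose cumulative mass best matches
#' the fraction preserving the first three gray-level moments). Ties are
#' broken toward the lowest candidate cut, making the result deterministic.
#' Foreground is defined downstream as intensity **strictly greater** than
#' the returned threshold, which equals the upper edge of the last
#' background bin, so the histogram classes and the voxel classification
#' agree exactly.
#'
#' @param x numeric array of intensities, or a prebuilt histogram given as
#'   `list(counts =, mids =)` with uniform bin midpoints.
#' @param method `"otsu"`, `"yen"` or `"moments"`.
#' @param nBins number of histogram bins (default 256) when `x` is an array.
#' @return a single numeric threshold; attribute `"cut"` holds the index of
#'   the last background bin.
#' @examples
#' x <- c(rnorm(500, 30, 4), rnorm(500, 160, 10))
#' autoThreshold(x, "otsu")
#' @export
autoThreshold <- function(x, method = c("otsu", "yen", "moments"),
                          nBins = 256L) {
  method <- match.arg(method)
  if (is.list(x)) {
    counts <- x$counts
    mids <- x$mids
    if (length(counts) != length(mids))
      stop("histogram counts and mids must have equal length")
  } else {
    h <- .intensityHistogram(x, nBins)
    counts <- h$counts
    mids <- h$mids
  }
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: need at least two distinct intensity values")
  p <- counts / sum(counts)
  cut <- switch(method,
    otsu = which.max(.otsuCriterion(p, mids)),
    yen  = which.max(.yenCriterion(p, mids)),
    moments = {
      p0 <- .momentsTargetFraction(p, mids)
      omega <- cumsum(p)[-length(p)]
      which.min(abs(omega - p0))
    })
  ## threshold at the boundary between bins `cut` and `cut + 1`
  thr <- (mids[cut] + mids[cut + 1L]) / 2
  attr(thr, "cut") <- cut
  thr
}

#' Segment one channel of a VoxelImage
#'
#' Optionally median-smooths the channel with a 3x3x3 filter, then applies
#' automatic thresholding; voxels with intensity strictly above the
#' threshold become foreground. The algorithm and threshold are recorded in
#' the mask's provenance. Flow-cell stacks are conventionally segmented
#' without smoothing (Yen for the green channel, Moments for the red);
#' bead stacks with smoothing and Otsu for both channels.
#'
#' @param img a [VoxelImage-class].
#' @param channel `"red"` or `"green"`.
#' @param method thresholding method passed to [autoThreshold()].
#' @param smooth apply [medianSmooth3D()] before thresholding.
#' @param nBins histogram bins for threshold selection.
#' @return a [BinaryMask-class].
#' @export
segmentChannel <- function(img, channel = c("green", "red"),
                           method = c("otsu", "yen", "moments"),
                           smooth = FALSE, nBins = 256L) {
  stopifnot(is(img, "VoxelImage"))
  channel <- match.arg(channel)
  method <- match.arg(method)
  a <- channelIntensity(img, channel)
  if (smooth) a <- medianSmooth3D(a)
  thr <- tryCatch(autoThreshold(a, method, nBins = nBins), error = function(e)
    stop(sprintf("thresholding failed for channel '%s': %s",
                 channel, conditionMessage(e)), call. = FALSE))
  BinaryMask(mask = a > as.numeric(thr), channel = channel, method = method,
             threshold = as.numeric(thr), smoothed = smooth)
}

#' Label connected components of a 3D mask
#'
#' Groups foreground voxels into components under 26-connectivity by
#' default: two voxels are adjacent when they differ by at most one step
#' along every axis, i.e. face, edge and corner ("diagonal") neighbors all
#' connect. 18- and 6-connectivity are available for sensitivity analysis.
#' Voxel anisotropy does not alter adjacency; physical units enter only in
#' volume and distance computations. Components are numbered in raster-scan
#' order of their first-encountered voxel.
#'
#' @param mask a [BinaryMask-class] or a logical 3D array.
#' @param connectivity 26 (default), 18 or 6.
#' @return a [LabelMap-class].
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
#' nComponents(labelComponents(m))  # diagonal contact -> one component
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  if (is(mask, "BinaryMask")) mask <- maskArray(mask)
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("mask must be a logical 3D array or a BinaryMask")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  res <- label_components_3d(mask, as.integer(dim(mask)), connectivity)
  new("LabelMap", labels = res$labels, nComponents = as.integer(res$k),
      connectivity = connectivity)
}
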