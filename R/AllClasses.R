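#' VoxelImage: a two-channel 3D confocal stack
#'
#' Container for a dual-label confocal z-stack. The red channel carries the
#' plasmid-encoded mCherry signal (plasmid-carrying cells), the green
#' channel the chromosomal GFP signal (plasmid-free cells). Arrays are
#' indexed `(z, y, x)` and voxel dimensions are physical, in micrometres,
#' ordered `(dz, dy, dx)`; voxels are typically anisotropic (z step larger
#' than the lateral pixel size).
#'
#' @slot red numeric 3D array of red-channel intensities, `(z, y, x)`.
#' @slot green numeric 3D array of green-channel intensities, same shape.
#' @slot voxelSize numeric length-3 vector `(dz, dy, dx)` in micrometres,
#'   all strictly positive.
#'
#' @seealso [VoxelImage()] constructor, [channelIntensity()], [voxelSize()]
#' @exportClass VoxelImage
setClass("VoxelImage",
  representation(red = "array", green = "array", voxelSize = "numeric"))

setValidity("VoxelImage", function(object) {
  msg <- character()
  if (length(dim(object@red)) != 3L || length(dim(object@green)) != 3L)
    msg <- c(msg, "channels must be 3D arrays (z, y, x)")
  else if (!identical(dim(object@red), dim(object@green)))
    msg <- c(msg, "red and green channels must have identical dimensions")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three strictly positive values (dz, dy, dx)")
  if (any(!is.finite(object@red)) || any(!is.finite(object@green)))
    msg <- c(msg, "intensities must be finite")
  else if (min(object@red) < 0 || min(object@green) < 0)
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelImage
#'
#' @param red,green numeric 3D arrays `(z, y, x)` of channel intensities.
#' @param voxelSize numeric `(dz, dy, dx)` voxel dimensions in micrometres.
#' @return A [VoxelImage-class] object.
#' @examples
#' a <- array(0, c(4, 8, 8))
#' img <- VoxelImage(red = a, green = a, voxelSize = c(0.5, 0.2, 0.2))
#' dim(img)
#' @export
VoxelImage <- function(red, green, voxelSize) {
  vs <- as.numeric(voxelSize)
  names(vs) <- c("dz", "dy", "dx")
  new("VoxelImage", red = red, green = green, voxelSize = vs)
}

#' BinaryMask: a segmented channel
#'
#' Foreground mask produced by thresholding one channel of a
#' [VoxelImage-class], together with its provenance (which algorithm, which
#' threshold, whether the channel was median-smoothed first). Foreground is
#' defined as intensity strictly greater than the threshold.
#'
#' @slot mask logical 3D array, `TRUE` = foreground.
#' @slot channel channel label, `"red"` or `"green"`.
#' @slot method thresholding algorithm used (`"otsu"`, `"yen"`, `"moments"`,
#'   or `"manual"`).
#' @slot threshold numeric threshold value applied.
#' @slot smoothed logical, was a 3x3x3 median filter applied first.
#' @seealso [segmentChannel()], [labelComponents()]
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(mask = "array", channel = "character", method = "character",
                 threshold = "numeric", smoothed = "logical"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a logical 3D array")
  if (length(object@channel) != 1L)
    msg <- c(msg, "channel must be a single label")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMask
#'
#' @param mask logical 3D array.
#' @param channel channel label (`"red"` or `"green"`).
#' @param method thresholding method name.
#' @param threshold threshold value.
#' @param smoothed was median smoothing applied before thresholding.
#' @return A [BinaryMask-class] object.
#' @export
BinaryMask <- function(mask, channel = "green", method = "manual",
                       threshold = NA_real_, smoothed = FALSE) {
  new("BinaryMask", mask = mask, channel = channel, method = method,
      threshold = threshold, smoothed = smoothed)
}

#' LabelMap: connected components of a mask
#'
#' Integer labeling of a [BinaryMask-class]: 0 is background and components
#' are numbered `1..K` in raster-scan order of their first-encountered
#' voxel, so the labeling is deterministic.
#'
#' @slot labels integer 3D array of component labels.
#' @slot nComponents number of components `K`.
#' @slot connectivity the voxel adjacency used (6, 18 or 26).
#' @seealso [labelComponents()]
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "array", nComponents = "integer",
                 connectivity = "integer"))

setValidity("LabelMap", function(object) {
  lab <- object@labels
  K <- object@nComponents
  if (!is.integer(lab) || length(dim(lab)) != 3L)
    return("labels must be an integer 3D array")
  u <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (!identical(u, seq_len(K)))
    return("non-background label values must be exactly 1..K")
  TRUE
})
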