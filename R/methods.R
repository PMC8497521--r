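#' @rdname accessors
#' @aliases voxelSize,VoxelImage-method
setMethod("voxelSize", "VoxelImage", function(x) x@voxelSize)

#' @rdname accessors
#' @aliases channelNames,VoxelImage-method
setMethod("channelNames", "VoxelImage", function(x) c("red", "green"))

#' @rdname accessors
#' @aliases channelIntensity,VoxelImage-method
setMethod("channelIntensity", "VoxelImage", function(x, channel) {
  channel <- match.arg(channel, c("red", "green"))
  if (channel == "red") x@red else x@green
})

#' @describeIn VoxelImage dimensions `(z, y, x)` of the stack.
#' @param x a `VoxelImage`.
#' @export
setMethod("dim", "VoxelImage", function(x) dim(x@red))

setMethod("show", "VoxelImage", function(object) {
  d <- dim(object)
  vs <- voxelSize(object)
  cat(sprintf("VoxelImage: %d x %d x %d voxels (z, y, x), 2 channels (red, green)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  voxel size: dz = %g, dy = %g, dx = %g um\n", vs[1], vs[2], vs[3]))
  cat(sprintf("  intensity range: red [%g, %g], green [%g, %g]\n",
              min(object@red), max(object@red),
              min(object@green), max(object@green)))
})

#' @rdname accessors
#' @aliases maskArray,BinaryMask-method
setMethod("maskArray", "BinaryMask", function(x) x@mask)

#' @rdname accessors
#' @aliases maskChannel,BinaryMask-method
setMethod("maskChannel", "BinaryMask", function(x) x@channel)

#' @rdname accessors
#' @aliases maskProvenance,BinaryMask-method
setMethod("maskProvenance", "BinaryMask", function(x)
  list(method = x@method, threshold = x@threshold, smoothed = x@smoothed))

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("BinaryMask (%s channel): %d x %d x %d, %d foreground voxels\n",
              object@channel, d[1], d[2], d[3], sum(object@mask)))
  cat(sprintf("  method = %s, threshold = %g, smoothed = %s\n",
              object@method, object@threshold, object@smoothed))
})

#' @rdname accessors
#' @aliases labelArray,LabelMap-method
setMethod("labelArray", "LabelMap", function(x) x@labels)

#' @rdname accessors
#' @aliases nComponents,LabelMap-method
setMethod("nComponents", "LabelMap", function(x) x@nComponents)

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("LabelMap: %d x %d x %d, %d components (%d-connectivity)\n",
              d[1], d[2], d[3], object@nComponents, object@connectivity))
})
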