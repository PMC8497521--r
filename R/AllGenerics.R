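#' @name accessors
#' @title Accessors for image containers
#' @description Accessor generics for [VoxelImage-class], [BinaryMask-class]
#'   and [LabelMap-class] objects. Slots are never accessed directly by
#'   downstream code.
#' @param x an image container object.
#' @param channel `"red"` (plasmid-carrying) or `"green"` (plasmid-free).
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("channelIntensity",
           function(x, channel) standardGeneric("channelIntensity"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("maskChannel", function(x) standardGeneric("maskChannel"))

#' @rdname accessors
#' @export
setGeneric("maskProvenance", function(x) standardGeneric("maskProvenance"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
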