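#' Write a VoxelImage as multi-page TIFF with a YAML sidecar
#'
#' Pages are written z-interleaved (red then green for each layer) as
#' 16-bit grayscale; intensities above 65535 are clipped. Because baseline
#' TIFF has no standard slot for z spacing, the voxel dimensions, channel
#' order and bit depth are recorded in a YAML sidecar next to the image
#' (same basename, `.yml` extension), which [readStack()] reads back.
#'
#' @param img a [VoxelImage-class].
#' @param path output TIFF path (e.g. `"stack.tif"`).
#' @return invisibly, the sidecar path.
#' @export
writeStack <- function(img, path) {
  stopifnot(is(img, "VoxelImage"))
  d <- dim(img)
  pages <- vector("list", 2L * d[1])
  red <- channelIntensity(img, "red")
  green <- channelIntensity(img, "green")
  for (k in seq_len(d[1])) {
    pages[[2L * k - 1L]] <- pmin(red[k, , ], 65535) / 65535
    pages[[2L * k]] <- pmin(green[k, , ], 65535) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- paste0(tools::file_path_sans_ext(path), ".yml")
  vs <- voxelSize(img)
  yaml::write_yaml(list(
    nLayers = d[1], ny = d[2], nx = d[3],
    channels = c("red", "green"), pageOrder = "z-interleaved",
    bitsPerSample = 16L, scale = 65535,
    voxelSize = list(dz = unname(vs[1]), dy = unname(vs[2]),
                     dx = unname(vs[3]))), side)
  invisible(side)
}

#' Export a segmentation mask as 8-bit multi-page TIFF
#'
#' Foreground voxels are written as 255, background as 0, one page per z
#' layer — convenient for inspecting a segmentation in any image viewer.
#'
#' @param mask a [BinaryMask-class] or logical 3D array.
#' @param path output TIFF path.
#' @return invisibly, `path`.
#' @export
writeMask <- function(mask, path) {
  m <- if (is(mask, "BinaryMask")) maskArray(mask) else mask
  stopifnot(is.logical(m), length(dim(m)) == 3L)
  pages <- lapply(seq_len(dim(m)[1]), function(k) m[k, , ] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [writeStack()]
#'
#' Voxel dimensions are taken from the YAML sidecar when present, else
#' from the `voxelSize` argument; if neither is available the read fails
#' (a stack without physical calibration cannot be quantified).
#'
#' @param path TIFF path.
#' @param voxelSize optional `(dz, dy, dx)` in micrometres, overriding the
#'   sidecar.
#' @return a [VoxelImage-class].
#' @export
readStack <- function(path, voxelSize = NULL) {
  side <- paste0(tools::file_path_sans_ext(path), ".yml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  if (is.null(voxelSize)) {
    if (is.null(meta) || is.null(meta$voxelSize))
      stop("no voxel size available: provide a YAML sidecar or the voxelSize argument")
    voxelSize <- c(meta$voxelSize$dz, meta$voxelSize$dy, meta$voxelSize$dx)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2L != 0L)
    stop("expected an even number of pages (z-interleaved red/green)")
  nz <- length(pages) %/% 2L
  d <- c(nz, nrow(pages[[1]]), ncol(pages[[1]]))
  scale <- if (!is.null(meta$scale)) meta$scale else 65535
  red <- array(0, d); green <- array(0, d)
  for (k in seq_len(nz)) {
    red[k, , ] <- round(pages[[2L * k - 1L]] * scale)
    green[k, , ] <- round(pages[[2L * k]] * scale)
  }
  VoxelImage(red = red, green = green, voxelSize = voxelSize)
}
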