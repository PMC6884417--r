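#' Construct a multi-channel z-stack
#'
#' Container for a confocal acquisition: a non-negative intensity volume of
#' dimension row x column x slice x channel together with the voxel metadata
#' needed downstream (pixel size and slice interval in micrometres, channel
#' names). The FISH channel is expected to be named `"FISH"` and the nuclear
#' counterstain `"DAPI"`.
#'
#' @param voxels numeric array, `dim = c(nrow, ncol, n_slices, n_channels)`,
#'   all values >= 0.
#' @param channel_names character vector, one name per channel.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param slice_interval_um axial slice interval in micrometres.
#' @return an object of class `"zstack"`.
#' @export
zstack <- function(voxels, channel_names, pixel_size_um, slice_interval_um) {
  if (length(dim(voxels)) != 4L)
    .stopf("voxels must be a 4-d array (row, col, slice, channel)")
  if (dim(voxels)[3] < 1L) .stopf("a z-stack needs at least one slice")
  if (dim(voxels)[4] != length(channel_names))
    .stopf("channel_names length (%d) != channel count (%d)",
           length(channel_names), dim(voxels)[4])
  if (min(voxels) < 0) .stopf("voxel intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    .stopf("pixel_size_um must be positive")
  if (!is.numeric(slice_interval_um) || slice_interval_um <= 0)
    .stopf("slice_interval_um must be positive")
  structure(list(voxels = voxels,
                 channel_names = as.character(channel_names),
                 pixel_size_um = pixel_size_um,
                 slice_interval_um = slice_interval_um),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<zstack> %d x %d px, %d slices, channels: %s\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  pixel %.3g um, slice interval %.3g um\n",
              x$pixel_size_um, x$slice_interval_um))
  invisible(x)
}

# internal constructor for a 2-d projection
.projection <- function(pixels, source_slices, span_um, channel,
                        oriented = FALSE, normalization = NULL) {
  structure(list(pixels = pixels, source_slices = source_slices,
                 span_um = span_um, channel = channel, oriented = oriented,
                 normalization = normalization),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("<projection> %d x %d px, channel %s, slices %d..%d (span %.3g um)%s%s\n",
              nrow(x$pixels), ncol(x$pixels), x$channel,
              min(x$source_slices), max(x$source_slices), x$span_um,
              if (x$oriented) ", oriented" else "",
              if (!is.null(x$normalization)) ", normalized" else ""))
  invisible(x)
}

#' Construct a region of interest
#'
#' @param mask logical matrix, TRUE over the region; must be non-empty.
#' @param kind `"blastomere"`, `"whole_embryo"` or `"oocyte"`. Circle shapes
#'   are only meaningful for whole embryos / oocytes, mirroring how regions
#'   are drawn precisely around blastomeres but approximated as circles
#'   around whole specimens.
#' @param label identifier such as `"7a"`.
#' @param shape_spec optional list describing the shape (e.g. circle centre
#'   and radius).
#' @return an object of class `"roi"`.
#' @export
roi <- function(mask, kind = c("blastomere", "whole_embryo", "oocyte"),
                label = "", shape_spec = NULL) {
  kind <- match.arg(kind)
  if (!is.logical(mask) || !is.matrix(mask)) .stopf("mask must be a logical matrix")
  if (!any(mask)) .stopf("ROI mask is empty")
  if (!is.null(shape_spec) && identical(shape_spec$type, "circle") &&
      kind == "blastomere")
    .stopf("circle ROIs are reserved for whole_embryo / oocyte regions")
  structure(list(mask = mask, kind = kind, label = label,
                 shape_spec = shape_spec), class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> kind=%s label=%s area=%d px\n",
              x$kind, x$label, sum(x$mask)))
  invisible(x)
}
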