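#' Equatorial maximum-intensity projection
#'
#' Builds the per-pixel maximum over a window of `n_slices` consecutive
#' slices centred on the equatorial plane of the specimen, for one channel.
#' The equator is located as the slice with the maximal foreground area
#' (Otsu threshold on the FISH + DAPI channel sum; middle slice of a tied
#' run), matching the acquisition of the largest cross-section of each
#' sample. The recorded span is `n_slices * slice_interval_um`.
#'
#' @param stack a [zstack()].
#' @param channel channel name to project (default `"FISH"`).
#' @param n_slices window width (default 10).
#' @return a projection object (`pixels`, `source_slices`, `span_um`,
#'   `channel`, `oriented`, `normalization`).
#' @export
equatorial_projection <- function(stack, channel = "FISH", n_slices = 10L) {
  if (!inherits(stack, "zstack")) .stopf("stack must be a zstack")
  nz <- dim(stack$voxels)[3]
  if (!.is_count(n_slices) || n_slices < 1)
    .stopf("n_slices must be a positive integer")
  if (nz < n_slices)
    .stopf("stack has %d slices, fewer than the %d requested", nz, n_slices)
  ci <- match(channel, stack$channel_names)
  if (is.na(ci)) .stopf("no channel named '%s' (have: %s)", channel,
                        paste(stack$channel_names, collapse = ", "))

  # equator: max foreground area on the channel-summed volume
  total <- array(0, dim = dim(stack$voxels)[1:3])
  for (ch in seq_len(dim(stack$voxels)[4])) {
    x <- stack$voxels[, , , ch, drop = FALSE]
    dim(x) <- dim(total)
    total <- total + x
  }
  thr <- .otsu(total)
  areas <- vapply(seq_len(nz), function(z) sum(total[, , z] > thr), numeric(1))
  tied <- which(areas == max(areas))
  equator <- tied[ceiling(length(tied) / 2)]

  start <- equator - floor(n_slices / 2)
  start <- min(max(start, 1L), nz - n_slices + 1L)
  slices <- seq.int(start, length.out = n_slices)
  proj <- do.call(pmax, lapply(slices, function(z) stack$voxels[, , z, ci]))
  .projection(proj, source_slices = slices,
              span_um = n_slices * stack$slice_interval_um,
              channel = channel)
}

# second-central-moment orientation of a mask (or weighted image), degrees
# from the x-axis, in (-90, 90]; also returns an isotropy measure
.mask_orientation <- function(mask) {
  w <- as.numeric(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  xg <- .xgrid(nr, nc); yg <- .ygrid(nr, nc)
  s <- sum(w)
  xbar <- sum(xg * w) / s; ybar <- sum(yg * w) / s
  mu20 <- sum((xg - xbar)^2 * w) / s
  mu02 <- sum((yg - ybar)^2 * w) / s
  mu11 <- sum((xg - xbar) * (yg - ybar) * w) / s
  ani <- sqrt((mu20 - mu02)^2 + 4 * mu11^2) / (mu20 + mu02)
  list(angle = 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi,
       anisotropy = ani)
}

#' Orient a projection so the specimen's long axis is vertical
#'
#' Rotates the projection (bilinear interpolation) so that the major
#' principal axis of the embryo mask — from the eigenvectors of the mask's
#' second central moments — is parallel to the y-axis of the image frame,
#' the fixed presentation convention for 2-cell embryos. For a degenerate
#' (near circular-symmetric) mask the angle is defined as 0 by tie-break and
#' a warning is emitted.
#'
#' @param projection a projection object.
#' @param embryo_mask an [roi()] (or logical matrix) covering the specimen.
#' @param extra_masks optional named list of logical masks rotated alongside
#'   (e.g. per-blastomere ground-truth masks).
#' @return list with `projection` (rotated, `oriented = TRUE`),
#'   `rotation_angle` in degrees within (-90, 90], `embryo_mask` (rotated)
#'   and `extra_masks` (rotated).
#' @export
orient_long_axis <- function(projection, embryo_mask, extra_masks = list()) {
  if (!inherits(projection, "projection")) .stopf("projection required")
  mask <- if (inherits(embryo_mask, "roi")) embryo_mask$mask else embryo_mask
  if (!any(mask)) .stopf("embryo mask is empty")
  o <- .mask_orientation(mask)
  if (o$anisotropy < 0.02) {
    .warnf("near circular-symmetric mask: orientation undefined, angle set to 0")
    theta <- 0
  } else {
    theta <- .wrap_half(o$angle - 90)
  }
  dims <- dim(projection$pixels)
  rot <- function(m, bilinear = TRUE) {
    if (abs(theta) < 1e-12) return(m)
    r <- EBImage::rotate(m, theta, filter = if (bilinear) "bilinear" else "none",
                         output.dim = dims, bg.col = 0)
    matrix(as.numeric(r), dims[1], dims[2])
  }
  out <- projection
  out$pixels <- rot(projection$pixels)
  out$oriented <- TRUE
  list(projection = out,
       rotation_angle = theta,
       embryo_mask = rot(mask * 1) > 0.5,
       extra_masks = lapply(extra_masks, function(m) rot(m * 1) > 0.5))
}

#' Derive regions of interest from a projection
#'
#' Three modes mirror how regions are defined in practice:
#' \describe{
#'   \item{ground_truth}{passes the generator's per-cell masks through
#'     unchanged (oracle mode for synthetic data).}
#'   \item{segment}{Otsu threshold on the summed FISH + DAPI projections,
#'     hole filling, connected components; touching blastomeres of a 2-cell
#'     embryo are split by watershed on the distance map and exactly two
#'     components are required.}
#'   \item{circle_fit}{one circular region enclosing the whole foreground
#'     (whole-embryo / oocyte convention).}
#' }
#'
#' @param projection oriented FISH projection.
#' @param dapi optional DAPI projection (summed with the FISH projection for
#'   foreground detection).
#' @param mode one of `"ground_truth"`, `"segment"`, `"circle_fit"`.
#' @param truth_masks list of logical masks (required for `ground_truth`),
#'   in the same frame as `projection`.
#' @param geometry `"two_cell"` or `"oocyte"`; controls how many components
#'   `segment` mode must find and the ROI `kind`.
#' @return list of [roi()] objects.
#' @export
derive_rois <- function(projection, dapi = NULL,
                        mode = c("ground_truth", "segment", "circle_fit"),
                        truth_masks = NULL,
                        geometry = c("two_cell", "oocyte")) {
  mode <- match.arg(mode)
  geometry <- match.arg(geometry)
  px <- projection$pixels
  kind_cell <- if (geometry == "oocyte") "oocyte" else "blastomere"

  if (mode == "ground_truth") {
    if (is.null(truth_masks)) .stopf("ground_truth mode needs truth_masks")
    return(lapply(seq_along(truth_masks), function(k)
      roi(truth_masks[[k]], kind = kind_cell, label = letters[k])))
  }

  fg_img <- px + if (!is.null(dapi)) dapi$pixels else 0
  # log intensity makes Otsu separate background from cell body rather than
  # from the (much brighter, much smaller) nucleus / spot cores
  s <- log1p(fg_img)
  fg <- s > .otsu(s)
  if (!any(fg)) .stopf("zero foreground pixels after thresholding")
  fg <- EBImage::closing(fg * 1, EBImage::makeBrush(3, "disc")) > 0
  fg <- EBImage::fillHull(fg * 1) > 0

  if (mode == "circle_fit") {
    nr <- nrow(fg); nc <- ncol(fg)
    xs <- .xgrid(nr, nc)[fg]; ys <- .ygrid(nr, nc)[fg]
    cx <- mean(xs); cy <- mean(ys)
    r <- sqrt(max((xs - cx)^2 + (ys - cy)^2)) + 0.5
    kind <- if (geometry == "oocyte") "oocyte" else "whole_embryo"
    return(list(roi(.disk_mask(nr, nc, cx, cy, r), kind = kind,
                    label = "whole",
                    shape_spec = list(type = "circle",
                                      centre = c(x = cx, y = cy),
                                      radius = r))))
  }

  # segment mode
  lab <- EBImage::bwlabel(fg * 1)
  n_expected <- if (geometry == "two_cell") 2L else 1L
  ncomp <- max(lab)
  if (ncomp < n_expected) {
    # touching blastomeres: split on the distance map
    lab <- EBImage::watershed(EBImage::distmap(fg * 1), tolerance = 1)
    ncomp <- max(lab)
  }
  # drop speckle components (< 1% of the foreground)
  keep <- which(tabulate(lab[lab > 0]) >= 0.01 * sum(fg))
  if (length(keep) != n_expected)
    .stopf("segmentation found %d component(s); expected %d for %s geometry",
           length(keep), n_expected, geometry)
  lab_m <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  masks <- lapply(keep, function(k) lab_m == k)
  # stable order: left to right by centroid x
  cxs <- vapply(masks, function(m) mean(.xgrid(nrow(m), ncol(m))[m]), numeric(1))
  masks <- masks[order(cxs)]
  lapply(seq_along(masks), function(k)
    roi(masks[[k]], kind = kind_cell, label = letters[k]))
}

#' Normalize a batch of projections with shared bounds
#'
#' Applies ONE `(low, high)` intensity pair to every projection in the batch
#' — identical contrast/brightness settings across specimens, the
#' precondition for comparing intensity-weighted statistics between images.
#' If `bounds` is not supplied it is computed as the batch-global 0.1 and
#' 99.9 percentiles. Values are rescaled linearly and clipped to \[0, 1\].
#' A degenerate batch (constant intensity, `low == high`) maps to 0 with a
#' warning.
#'
#' @param projections list of projection objects.
#' @param bounds optional numeric `c(low, high)` with `low < high`.
#' @return list of normalized projections (`normalization` records the
#'   applied bounds).
#' @export
normalize_intensity <- function(projections, bounds = NULL) {
  if (inherits(projections, "projection")) projections <- list(projections)
  if (length(projections) < 1L) .stopf("need at least one projection")
  if (!is.null(bounds)) {
    if (length(bounds) != 2L || bounds[1] >= bounds[2])
      .stopf("bounds must be c(low, high) with low < high")
    low <- bounds[1]; high <- bounds[2]
  } else {
    all_px <- unlist(lapply(projections, function(p) as.numeric(p$pixels)))
    qs <- stats::quantile(all_px, c(0.001, 0.999), names = FALSE)
    low <- qs[1]; high <- qs[2]
    if (low >= high) {
      .warnf("degenerate intensity range in batch; mapping all pixels to 0")
      return(lapply(projections, function(p) {
        p$pixels[] <- 0
        p$normalization <- c(low = low, high = low)
        p
      }))
    }
  }
  lapply(projections, function(p) {
    p$pixels <- pmin(pmax((p$pixels - low) / (high - low), 0), 1)
    p$normalization <- c(low = low, high = high)
    p
  })
}
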