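#' Eccentricity of the intensity distribution within an ROI
#'
#' The core statistic: for a uniform signal the unweighted centroid of the
#' ROI pixels and the intensity-weighted centre of mass coincide, whereas for
#' a non-uniform signal the centre of mass departs from the centroid. The
#' eccentricity E is the Euclidean distance between the two positions — the
#' hypotenuse of the right triangle with legs delta-x and delta-y. Both the
#' centroid and the centre of mass are computed over the ROI mask pixels
#' only; background outside the ROI never contributes.
#'
#' E is reported in pixels (`E_px`) and normalized by the equivalent ROI
#' radius `sqrt(area / pi)` (`E_norm`), which is dimensionless and comparable
#' across ROI sizes.
#'
#' @param projection a projection object, or a plain numeric matrix of pixel
#'   intensities.
#' @param roi an [roi()] whose mask has the same dimensions as the image.
#' @return an object of class `"eccentricity_result"`: `centroid`,
#'   `centre_of_mass`, `delta` (each x, y in 0-based pixel coordinates),
#'   `E_px`, `E_norm`, `roi_label`, `total_intensity`, `roi_area_px`.
#' @examples
#' img <- matrix(1, 3, 3); img[3, 3] <- 10
#' r <- roi(matrix(TRUE, 3, 3), kind = "oocyte", label = "toy")
#' eccentricity(img, r)   # E = sqrt(0.5)
#' @export
eccentricity <- function(projection, roi) {
  px <- if (inherits(projection, "projection")) projection$pixels else projection
  if (!inherits(roi, "roi")) .stopf("roi must be an roi object")
  if (!identical(dim(px), dim(roi$mask)))
    .stopf("ROI mask (%s) does not match image dimensions (%s): ROI exceeds image bounds",
           paste(dim(roi$mask), collapse = "x"), paste(dim(px), collapse = "x"))
  mask <- roi$mask
  w <- px[mask]
  if (any(w < 0)) .stopf("negative intensities inside the ROI")
  total <- sum(w)
  if (total <= 0)
    .stopf("zero total intensity within ROI '%s': eccentricity undefined (distinct from E = 0)",
           roi$label)
  nr <- nrow(px); nc <- ncol(px)
  xs <- .xgrid(nr, nc)[mask]
  ys <- .ygrid(nr, nc)[mask]
  centroid <- c(x = mean(xs), y = mean(ys))
  com <- c(x = sum(w * xs) / total, y = sum(w * ys) / total)
  delta <- com - centroid
  e_px <- sqrt(sum(delta^2))
  area <- sum(mask)
  structure(list(centroid = centroid, centre_of_mass = com,
                 delta = c(dx = unname(delta["x"]), dy = unname(delta["y"])),
                 E_px = e_px, E_norm = e_px / sqrt(area / pi),
                 roi_label = roi$label, total_intensity = total,
                 roi_area_px = area),
            class = "eccentricity_result")
}

#' @export
print.eccentricity_result <- function(x, ...) {
  cat(sprintf("<eccentricity> roi=%s E=%.4f px (E_norm=%.4f)\n", x$roi_label,
              x$E_px, x$E_norm))
  cat(sprintf("  centroid (%.3f, %.3f)  centre of mass (%.3f, %.3f)\n",
              x$centroid["x"], x$centroid["y"],
              x$centre_of_mass["x"], x$centre_of_mass["y"]))
  invisible(x)
}

#' Batch eccentricity over a set of synthetic specimens
#'
#' Runs the full measurement pipeline on each specimen: equatorial
#' maximum-intensity projection of the FISH channel, orientation of 2-cell
#' embryos along their long axis, batch-wide shared intensity normalization,
#' ROI derivation at the requested level, and eccentricity per ROI.
#'
#' @param specimens list; each element a list with `stack` (a [zstack()]),
#'   `truth` (generator ground truth; required for `roi_mode =
#'   "ground_truth"`) and optionally `id`.
#' @param level `"blastomere"` (two polygon ROIs per 2-cell embryo),
#'   `"embryo"` (one circle around the whole embryo) or `"oocyte"`.
#' @param roi_mode ROI derivation mode, see [derive_rois()].
#' @param n_slices projection window width.
#' @param normalize apply batch-global shared-bounds normalization before
#'   measuring (the comparability convention); disable to measure raw
#'   photon-count projections.
#' @param bounds optional explicit normalization bounds.
#' @return `data.frame`, one row per ROI: `specimen`, `roi_label`, `kind`,
#'   `centroid_x`, `centroid_y`, `com_x`, `com_y`, `E_px`, `E_norm`,
#'   `total_intensity`, `area_px`.
#' @export
batch_eccentricity <- function(specimens,
                               level = c("blastomere", "embryo", "oocyte"),
                               roi_mode = c("ground_truth", "segment",
                                            "circle_fit"),
                               n_slices = 10L, normalize = TRUE,
                               bounds = NULL) {
  level <- match.arg(level)
  roi_mode <- match.arg(roi_mode)
  geometry <- if (level == "oocyte") "oocyte" else "two_cell"

  prepped <- lapply(seq_along(specimens), function(i) {
    sp <- specimens[[i]]
    id <- if (!is.null(sp$id)) sp$id else as.character(i)
    res <- tryCatch({
      fish <- equatorial_projection(sp$stack, "FISH", n_slices)
      # the DAPI projection is only consumed by intensity-based ROI modes
      dapi <- if (roi_mode != "ground_truth" &&
                  "DAPI" %in% sp$stack$channel_names)
        equatorial_projection(sp$stack, "DAPI", n_slices) else NULL
      masks <- if (!is.null(sp$truth)) sp$truth$cell_masks else NULL
      if (geometry == "two_cell") {
        embryo_mask <- if (!is.null(masks)) Reduce(`|`, masks) else {
          fg_img <- fish$pixels + if (!is.null(dapi)) dapi$pixels else 0
          fg_img > .otsu(fg_img)
        }
        o <- orient_long_axis(fish, embryo_mask,
                              extra_masks = if (is.null(masks)) list() else masks)
        fish <- o$projection
        if (!is.null(dapi)) {
          od <- orient_long_axis(dapi, embryo_mask)
          dapi <- od$projection
        }
        masks <- if (is.null(masks)) NULL else o$extra_masks
      }
      list(fish = fish, dapi = dapi, masks = masks, id = id)
    }, error = function(e)
      .stopf("specimen '%s': %s", id, conditionMessage(e)))
    res
  })

  if (normalize) {
    normed <- normalize_intensity(lapply(prepped, `[[`, "fish"), bounds)
    for (i in seq_along(prepped)) prepped[[i]]$fish <- normed[[i]]
  }

  rows <- lapply(prepped, function(sp) {
    rois <- tryCatch({
      if (level == "blastomere") {
        derive_rois(sp$fish, sp$dapi, mode = roi_mode,
                    truth_masks = sp$masks, geometry = "two_cell")
      } else if (level == "embryo") {
        derive_rois(sp$fish, sp$dapi, mode = "circle_fit",
                    geometry = "two_cell")
      } else {  # oocyte
        if (roi_mode == "ground_truth")
          derive_rois(sp$fish, sp$dapi, mode = "ground_truth",
                      truth_masks = sp$masks, geometry = "oocyte")
        else derive_rois(sp$fish, sp$dapi, mode = roi_mode,
                         geometry = "oocyte")
      }
    }, error = function(e)
      .stopf("specimen '%s': %s", sp$id, conditionMessage(e)))
    do.call(rbind, lapply(rois, function(r) {
      e <- tryCatch(eccentricity(sp$fish, r), error = function(err)
        .stopf("specimen '%s': %s", sp$id, conditionMessage(err)))
      data.frame(specimen = sp$id, roi_label = r$label, kind = r$kind,
                 centroid_x = e$centroid[["x"]], centroid_y = e$centroid[["y"]],
                 com_x = e$centre_of_mass[["x"]], com_y = e$centre_of_mass[["y"]],
                 E_px = e$E_px, E_norm = e$E_norm,
                 total_intensity = e$total_intensity,
                 area_px = e$roi_area_px)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare eccentricity values between two groups of specimens
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of independent
#' specimen groups: exact when the combined sample size is at most 25 and
#' there are no ties, otherwise the normal approximation with tie and
#' continuity correction. A signed-rank variant for paired designs (e.g.
#' sister blastomeres within an embryo) is available via `paired = TRUE`.
#'
#' @param a,b numeric vectors of E values, each of length >= 3.
#' @param labels group names.
#' @param paired use the signed-rank test for paired observations.
#' @return list of class `"group_comparison"`: `group_labels`, `n_per_group`,
#'   `statistic`, `p_value`, `medians`, `method`.
#' @export
compare_groups <- function(a, b, labels = c("a", "b"), paired = FALSE) {
  if (length(a) < 3 || length(b) < 3)
    .stopf("each group needs n >= 3 (got %d and %d)", length(a), length(b))
  if (paired && length(a) != length(b))
    .stopf("paired comparison needs equal-length groups")
  exact <- !paired && (length(a) + length(b) <= 25) &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                            exact = exact, correct = TRUE))
  structure(list(group_labels = labels,
                 n_per_group = c(length(a), length(b)),
                 statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 medians = c(stats::median(a), stats::median(b)),
                 method = wt$method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d, median %.4g) vs %s (n=%d, median %.4g)\n",
              x$group_labels[1], x$n_per_group[1], x$medians[1],
              x$group_labels[2], x$n_per_group[2], x$medians[2]))
  cat(sprintf("  %s: W = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}
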