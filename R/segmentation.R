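#' Threshold a HU volume by a density window
#'
#' Marks every voxel whose HU value lies inside the closed interval
#' `[hu_low, hu_high]`. A window that excludes all voxels yields a valid
#' all-zero mask, not an error.
#'
#' @param vol an [hu_volume()].
#' @param window a [density_window()] or numeric `c(hu_low, hu_high)`.
#' @return Integer 0/1 array with the same dimensions as `vol$voxels`.
#' @examples
#' vol <- hu_volume(array(c(-50, 300, 1100, 40), c(2, 2, 1)), c(1, 1, 1))
#' sum(threshold_mask(vol, c(500, 2000)))
#' @export
threshold_mask <- function(vol, window) {
  if (!inherits(vol, "hu_volume")) stop("`vol` must be an hu_volume")
  win <- as_density_window(window)
  mask <- (vol$voxels >= win$hu_low) & (vol$voxels <= win$hu_high)
  array(as.integer(mask), dim = dim(vol$voxels))
}

#' Label connected components of a binary 3D mask
#'
#' Grid connectivity: 6 (faces only), 18 (faces and edges) or 26 (faces,
#' edges and corners). Background is 0; components get unique positive labels.
#'
#' @param mask integer/logical 3D array, non-zero = foreground.
#' @param connectivity one of 6, 18, 26.
#' @return List with `labels` (integer array, same dims), `n_components`,
#'   and `sizes` (voxel count per label, in label order).
#' @examples
#' m <- array(0L, c(2, 2, 2)); m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L
#' label_components(m, 6)$n_components   # corner contact only
#' label_components(m, 26)$n_components
#' @export
label_components <- function(mask, connectivity = 26) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  res <- .cc_label3d(as.integer(mask != 0), dim(mask), as.integer(connectivity))
  res$labels <- array(res$labels, dim = dim(mask))
  res
}

#' Measure one labeled stone component
#'
#' Computes the voxel count, volume (voxel count times voxel volume, exact),
#' HU statistics, heterogeneity flag and maximum diameter (largest pairwise
#' Euclidean distance between voxel centers, in mm) of one connected
#' component.
#'
#' A stone is flagged heterogeneous when its within-segment HU range
#' (`hu_max - hu_min`) exceeds `homogeneity_threshold` (default 600 HU).
#'
#' @param labels integer 3D labelmap (as from [label_components()]).
#' @param label positive component label to measure.
#' @param vol the [hu_volume()] the labelmap was derived from.
#' @param homogeneity_threshold HU range above which the segment is flagged
#'   heterogeneous. Default 600.
#' @param compute_diameter compute `max_diameter_mm`? Exact but quadratic in
#'   the number of boundary voxels; set `FALSE` in bulk simulations.
#' @return A one-row data.frame: `label, voxel_count, volume_mm3, hu_mean,
#'   hu_min, hu_max, hu_range, is_heterogeneous, max_diameter_mm`, plus
#'   bounding-box index ranges as an attribute `"bbox"`.
#' @export
measure_segment <- function(labels, label, vol, homogeneity_threshold = 600,
                            compute_diameter = TRUE) {
  if (!inherits(vol, "hu_volume")) stop("`vol` must be an hu_volume")
  label <- as.integer(label)
  in_seg <- which(labels == label)
  if (length(in_seg) == 0L) stop(sprintf("label %d not present in labelmap", label))
  hu <- vol$voxels[in_seg]
  count <- length(in_seg)
  hu_min <- min(hu); hu_max <- max(hu)
  idx <- arrayInd(in_seg, dim(labels))
  bbox <- apply(idx, 2, range)

  max_d <- 0
  if (compute_diameter && count > 1L) {
    b_idx <- .cc_boundary(as.integer(labels), dim(labels), label) + 1L
    coords <- voxel_centers_mm(vol, arrayInd(b_idx, dim(labels)))
    max_d <- .max_pairwise_dist(coords)
  } else if (!compute_diameter) {
    max_d <- NA_real_
  }

  out <- data.frame(
    label = label,
    voxel_count = count,
    volume_mm3 = count * voxel_volume(vol),
    hu_mean = mean(hu),
    hu_min = hu_min,
    hu_max = hu_max,
    hu_range = hu_max - hu_min,
    is_heterogeneous = (hu_max - hu_min) > homogeneity_threshold,
    max_diameter_mm = max_d
  )
  attr(out, "bbox") <- bbox
  out
}

#' Segment kidney stones from a CT volume by density window
#'
#' The full volumetry pipeline: threshold the volume by the HU window, label
#' connected components, drop components smaller than `min_voxels`, and
#' measure each remaining component. Volume is the voxel count times the
#' voxel volume -- no surface meshing or smoothing is involved, so the total
#' is exact with respect to the mask. Deterministic for fixed inputs.
#'
#' @inheritParams threshold_mask
#' @param connectivity grid connectivity for component labeling (6, 18 or
#'   26). Default 26: fragments touching only across oblique voxel corners
#'   stay one object.
#' @param min_voxels drop components with fewer voxels (noise filter);
#'   filtered voxels are excluded from the total. Default 1 (keep all).
#' @param homogeneity_threshold HU range flagging heterogeneity; see
#'   [measure_segment()].
#' @param measure_diameters compute per-segment maximum diameters (exact,
#'   quadratic in boundary size). Default `TRUE`.
#' @return An object of class `stone_segmentation`: list with `segments`
#'   (data.frame sorted by volume descending), `total_volume_mm3`,
#'   `n_segments`, `window`, `connectivity`, `min_voxels`,
#'   `homogeneity_threshold`, `labels` (integer labelmap), `spacing`.
#' @examples
#' vox <- array(-20, c(10, 10, 10))
#' vox[4:6, 4:6, 4:6] <- 1200
#' seg <- segment_stones(hu_volume(vox, c(1, 1, 1)), c(500, 2000))
#' seg$total_volume_mm3   # 27 voxels x 1 mm^3
#' @export
segment_stones <- function(vol, window, connectivity = 26, min_voxels = 1,
                           homogeneity_threshold = 600,
                           measure_diameters = TRUE) {
  win <- as_density_window(window)
  mask <- threshold_mask(vol, win)
  lab <- label_components(mask, connectivity)
  keep <- which(lab$sizes >= min_voxels)

  segs <- lapply(keep, function(l)
    measure_segment(lab$labels, l, vol,
                    homogeneity_threshold = homogeneity_threshold,
                    compute_diameter = measure_diameters))
  segs <- if (length(segs)) do.call(rbind, segs) else
    data.frame(label = integer(), voxel_count = integer(),
               volume_mm3 = numeric(), hu_mean = numeric(),
               hu_min = numeric(), hu_max = numeric(), hu_range = numeric(),
               is_heterogeneous = logical(), max_diameter_mm = numeric())
  segs <- segs[order(-segs$volume_mm3, segs$label), , drop = FALSE]
  rownames(segs) <- NULL

  # zero out filtered components in the returned labelmap
  labels <- lab$labels
  if (length(keep) < lab$n_components)
    labels[!(labels %in% c(0L, keep))] <- 0L

  structure(list(
    segments = segs,
    total_volume_mm3 = sum(segs$volume_mm3),
    n_segments = nrow(segs),
    window = win,
    connectivity = as.integer(connectivity),
    min_voxels = as.integer(min_voxels),
    homogeneity_threshold = homogeneity_threshold,
    labels = labels,
    spacing = vol$spacing
  ), class = "stone_segmentation")
}

#' @export
print.stone_segmentation <- function(x, ...) {
  cat(sprintf("<stone_segmentation> window [%g, %g] HU, connectivity %d\n",
              x$window$hu_low, x$window$hu_high, x$connectivity))
  cat(sprintf("  %d segment(s), total volume %.1f mm^3\n",
              x$n_segments, x$total_volume_mm3))
  if (x$n_segments > 0) {
    s <- head(x$segments, 5)
    for (i in seq_len(nrow(s)))
      cat(sprintf("  #%d: %.1f mm^3 (%d voxels), max diameter %.1f mm, HU %.0f [%.0f-%.0f]%s\n",
                  s$label[i], s$volume_mm3[i], s$voxel_count[i],
                  s$max_diameter_mm[i], s$hu_mean[i], s$hu_min[i], s$hu_max[i],
                  ifelse(s$is_heterogeneous[i], " (heterogeneous)", "")))
    if (x$n_segments > 5) cat(sprintf("  ... and %d more\n", x$n_segments - 5))
  }
  invisible(x)
}

#' @export
summary.stone_segmentation <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
as.data.frame.stone_segmentation <- function(x, ...) x$segments

#' Write a segmentation result to CSV and/or JSON
#'
#' CSV carries the per-segment table (columns `label, voxel_count,
#' volume_mm3, hu_mean, hu_min, hu_max, hu_range, is_heterogeneous,
#' max_diameter_mm`); JSON additionally carries the window and pipeline
#' parameters for audit.
#'
#' @param x a `stone_segmentation`.
#' @param csv,json output paths (either may be `NULL`).
#' @return Invisibly, the list of paths written.
#' @export
write_segmentation <- function(x, csv = NULL, json = NULL) {
  stopifnot(inherits(x, "stone_segmentation"))
  if (!is.null(csv))
    write.csv(x$segments, csv, row.names = FALSE)
  if (!is.null(json)) {
    payload <- list(
      window = list(hu_low = x$window$hu_low, hu_high = x$window$hu_high),
      connectivity = x$connectivity,
      min_voxels = x$min_voxels,
      homogeneity_threshold = x$homogeneity_threshold,
      total_volume_mm3 = x$total_volume_mm3,
      n_segments = x$n_segments,
      segments = x$segments
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(list(csv = csv, json = json))
}
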