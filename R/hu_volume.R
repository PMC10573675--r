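#' CT volume in Hounsfield units
#'
#' Container for a 3D scalar grid of CT attenuation values (Hounsfield units,
#' HU) with physical voxel spacing. This is the substrate every segmentation
#' operation works on. Values are assumed to be calibrated HU (water ~ 0,
#' urinary stones typically 400--1800 HU).
#'
#' Array axes are stored in R's native column-major order; `spacing[i]` is the
#' physical size (mm) of a voxel step along array dimension `i`. Voxel indices
#' are 1-based in R; physical coordinates refer to voxel centers, so voxel
#' `(i, j, k)` sits at `origin + ((i, j, k) - 1) * spacing` mm.
#'
#' @param voxels numeric 3D array of HU values (finite).
#' @param spacing numeric length-3, voxel edge lengths in mm, all > 0.
#' @param origin numeric length-3, physical position (mm) of the center of
#'   voxel (1, 1, 1). Default `c(0, 0, 0)`.
#' @return An object of class `hu_volume`.
#' @examples
#' vol <- hu_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(vol$voxels)
#' @seealso [segment_stones()], [read_hu_nifti()]
#' @export
hu_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (length(voxels) == 0L) stop("`voxels` must be non-empty")
  if (!all(is.finite(voxels))) stop("HU values must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<hu_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f], voxel volume %.4g mm^3\n",
              min(x$voxels), max(x$voxels), prod(x$spacing)))
  invisible(x)
}

#' @export
dim.hu_volume <- function(x) dim(x$voxels)

# mm^3 per voxel
voxel_volume <- function(vol) prod(vol$spacing)

#' Density window (HU interval)
#'
#' The inclusive HU interval the operator chooses so that the thresholded
#' region "visually fits" the stone. This is the single tunable of the
#' density-window volumetry method; the window is closed on both ends, which
#' makes segmented volume exactly monotone in window containment.
#'
#' @param hu_low lower bound (HU).
#' @param hu_high upper bound (HU), must satisfy `hu_low <= hu_high`.
#' @return An object of class `density_window`.
#' @examples
#' density_window(500, 2000)
#' @export
density_window <- function(hu_low, hu_high) {
  hu_low <- as.numeric(hu_low); hu_high <- as.numeric(hu_high)
  if (length(hu_low) != 1L || length(hu_high) != 1L ||
      !is.finite(hu_low) || !is.finite(hu_high))
    stop("window bounds must be single finite numbers")
  if (hu_low > hu_high) stop("`hu_low` must be <= `hu_high`")
  structure(list(hu_low = hu_low, hu_high = hu_high), class = "density_window")
}

#' @export
print.density_window <- function(x, ...) {
  cat(sprintf("<density_window> [%g, %g] HU (inclusive)\n", x$hu_low, x$hu_high))
  invisible(x)
}

as_density_window <- function(win) {
  if (inherits(win, "density_window")) return(win)
  if (is.numeric(win) && length(win) == 2L) return(density_window(win[1], win[2]))
  stop("`window` must be a density_window or a numeric length-2 vector")
}

#' Read a CT volume from a NIfTI-1 file
#'
#' Reads a NIfTI-1 image whose voxel values are assumed to already be in
#' Hounsfield units, and returns it as an [hu_volume()] carrying the file's
#' voxel spacing.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `hu_volume`.
#' @export
read_hu_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) > 3L) arr <- arr[, , , 1, drop = TRUE]
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  hu_volume(arr, spacing = sp)
}

#' Write a volume, mask or labelmap to NIfTI-1
#'
#' @param x an `hu_volume`, or a 3D array (mask/labelmap) with `spacing`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm; taken from `x` when it is an
#'   `hu_volume`.
#' @return `path`, invisibly.
#' @export
write_hu_nifti <- function(x, path, spacing = NULL) {
  if (inherits(x, "hu_volume")) {
    arr <- x$voxels; spacing <- x$spacing
  } else {
    arr <- x
    if (is.null(spacing)) stop("`spacing` required when writing a bare array")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Physical center coordinates (mm) for 1-based voxel index triples (n x 3).
voxel_centers_mm <- function(vol, idx) {
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}
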