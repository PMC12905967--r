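#' @import methods
NULL

.fcStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "fcTarget_error")))
}

#' VoxelGrid: a 3D image lattice with an affine voxel-to-MNI-mm mapping
#'
#' A `VoxelGrid` describes the sampling lattice shared by all volumetric
#' objects in the package: the number of voxels along each axis and the 4x4
#' affine that maps 0-based voxel indices (i, j, k) to MNI millimetre
#' coordinates.
#'
#' @slot shape integer vector of length 3, voxels per axis (all >= 1).
#' @slot affine 4x4 numeric matrix, invertible, mapping homogeneous 0-based
#'   voxel indices to mm.
#'
#' @seealso [voxelGrid()], [mmToVoxel()], [voxelToMm()]
#' @export
setClass("VoxelGrid", representation(shape = "integer", affine = "matrix"))

setValidity("VoxelGrid", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 1L))
    return("shape must be 3 positive integers")
  a <- object@affine
  if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)))
    return("affine must be a 4x4 numeric matrix")
  if (any(!is.finite(a)))
    return("affine must be finite")
  d <- det(a[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100)
    return("affine must be invertible")
  TRUE
})

#' VolumeMask: a boolean region of interest on a VoxelGrid
#'
#' @slot grid a [VoxelGrid-class].
#' @slot member logical vector, one entry per voxel in the grid's linear
#'   (column-major, x-fastest) order.
#' @export
setClass("VolumeMask", representation(grid = "VoxelGrid", member = "logical"))

setValidity("VolumeMask", function(object) {
  if (length(object@member) != prod(object@grid@shape))
    return("member length must equal the voxel count of the grid")
  if (anyNA(object@member)) return("member must not contain NA")
  TRUE
})

#' ScalarVolume: one finite real value per voxel
#'
#' Holds weight maps, connectivity maps written to disk, and electric-field
#' magnitude maps (V/m). `NA` values are permitted only when the object is
#' paired with a mask that excludes them; standalone volumes must be finite.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot values numeric vector, one value per voxel in linear order.
#' @export
setClass("ScalarVolume", representation(grid = "VoxelGrid", values = "numeric"))

setValidity("ScalarVolume", function(object) {
  if (length(object@values) != prod(object@grid@shape))
    return("values length must equal the voxel count of the grid")
  TRUE
})

#' BoldSeries: a 4D BOLD acquisition as a time-by-voxel matrix
#'
#' @slot grid a [VoxelGrid-class].
#' @slot data T x V numeric matrix; column v is the time series of the voxel
#'   with linear index v.
#' @slot tr repetition time in seconds (> 0).
#' @export
setClass("BoldSeries",
         representation(grid = "VoxelGrid", data = "matrix", tr = "numeric"))

setValidity("BoldSeries", function(object) {
  if (nrow(object@data) < 2L) return("need at least 2 frames")
  if (ncol(object@data) != prod(object@grid@shape))
    return("data columns must equal the voxel count of the grid")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    return("tr must be a positive scalar (seconds)")
  if (any(!is.finite(object@data))) return("data must be finite")
  TRUE
})

#' SeedSeries: a single regional time series
#'
#' @slot values numeric vector of per-frame values.
#' @slot label character label ("DLPFC mean", "PGC seedmap", ...).
#' @export
setClass("SeedSeries", representation(values = "numeric", label = "character"))

setValidity("SeedSeries", function(object) {
  if (any(!is.finite(object@values))) return("values must be finite")
  TRUE
})

#' ConnectivityMap: voxelwise seed correlation within a search mask
#'
#' Pearson r per voxel of the search mask; `NA` outside it.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot r numeric vector, one r per voxel (NA outside the search mask).
#' @slot searchMask a [VolumeMask-class] on the same grid.
#' @export
setClass("ConnectivityMap",
         representation(grid = "VoxelGrid", r = "numeric",
                        searchMask = "VolumeMask"))

setValidity("ConnectivityMap", function(object) {
  V <- prod(object@grid@shape)
  if (length(object@r) != V) return("r length must equal the voxel count")
  m <- object@searchMask@member
  if (length(m) != V) return("search mask must live on the same grid")
  if (anyNA(object@r[m])) return("r must be defined on all search-mask voxels")
  if (any(!is.na(object@r[!m]))) return("r must be NA outside the search mask")
  rr <- object@r[m]
  if (any(rr < -1 - 1e-12 | rr > 1 + 1e-12)) return("r must lie in [-1, 1]")
  TRUE
})

#' TargetReport: the selected personalised stimulation target
#'
#' @slot centroid_mm MNI mm centroid of the largest selected cluster.
#' @slot snapped_voxel_mm cluster member voxel nearest the centroid, in mm.
#' @slot cluster_size voxel count of the chosen cluster.
#' @slot cluster_mean_r mean connectivity r over the cluster.
#' @slot peak_voxel_mm mm coordinate of the cluster voxel with maximal r.
#' @slot threshold_r smallest r among all selected (top-fraction) voxels.
#' @slot n_selected number of voxels selected before clustering.
#' @export
setClass("TargetReport",
         representation(centroid_mm = "numeric", snapped_voxel_mm = "numeric",
                        cluster_size = "integer", cluster_mean_r = "numeric",
                        peak_voxel_mm = "numeric", threshold_r = "numeric",
                        n_selected = "integer"))

setValidity("TargetReport", function(object) {
  if (length(object@centroid_mm) != 3L) return("centroid_mm must be length 3")
  if (object@n_selected < object@cluster_size || object@cluster_size < 1L)
    return("need n_selected >= cluster_size >= 1")
  TRUE
})

#' EfieldSummary: electric-field indices over a target region
#'
#' @slot mean_vpm mean field strength over the ROI (V/m).
#' @slot peak_vpm maximal field strength over the ROI (V/m).
#' @slot pct_above_threshold percentage of ROI voxels strictly above threshold.
#' @slot threshold_vpm the threshold used (V/m).
#' @export
setClass("EfieldSummary",
         representation(mean_vpm = "numeric", peak_vpm = "numeric",
                        pct_above_threshold = "numeric",
                        threshold_vpm = "numeric"))

setValidity("EfieldSummary", function(object) {
  if (object@pct_above_threshold < 0 || object@pct_above_threshold > 100)
    return("pct_above_threshold must lie in [0, 100]")
  if (object@peak_vpm < object@mean_vpm - 1e-9)
    return("peak must be >= mean")
  TRUE
})

#' @describeIn TargetReport `$` access to report fields
#' @param x,name object and slot name
#' @export
setMethod("$", "TargetReport", function(x, name) slot(x, name))

#' @describeIn EfieldSummary `$` access to summary fields
#' @param x,name object and slot name
#' @export
setMethod("$", "EfieldSummary", function(x, name) slot(x, name))

setMethod("show", "VoxelGrid", function(object) {
  vs <- voxelSize(object)
  cat(sprintf("VoxelGrid %s, voxel size %s mm\n",
              paste(object@shape, collapse = " x "),
              paste(signif(vs, 4), collapse = " x ")))
})

setMethod("show", "VolumeMask", function(object) {
  cat(sprintf("VolumeMask on %s grid: %d member voxel(s)\n",
              paste(object@grid@shape, collapse = "x"),
              sum(object@member)))
})

setMethod("show", "ScalarVolume", function(object) {
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf("ScalarVolume on %s grid, range [%.4g, %.4g]\n",
              paste(object@grid@shape, collapse = "x"), rng[1], rng[2]))
})

setMethod("show", "BoldSeries", function(object) {
  cat(sprintf("BoldSeries: %d frames x %d voxels, TR = %g s (%s grid)\n",
              nrow(object@data), ncol(object@data), object@tr,
              paste(object@grid@shape, collapse = "x")))
})

setMethod("show", "SeedSeries", function(object) {
  cat(sprintf("SeedSeries '%s': %d frames, sd = %.4g\n",
              object@label, length(object@values), stats::sd(object@values)))
})

setMethod("show", "ConnectivityMap", function(object) {
  rr <- object@r[object@searchMask@member]
  cat(sprintf("ConnectivityMap: %d search voxels, r in [%.3f, %.3f]\n",
              length(rr), min(rr), max(rr)))
})

setMethod("show", "TargetReport", function(object) {
  cat(sprintf(
    paste0("TargetReport\n  centroid (MNI mm): %s\n  snapped voxel: %s\n",
           "  peak voxel: %s\n  cluster: %d of %d selected voxels, ",
           "mean r = %.3f (threshold r = %.3f)\n"),
    paste(round(object@centroid_mm, 2), collapse = ", "),
    paste(round(object@snapped_voxel_mm, 2), collapse = ", "),
    paste(round(object@peak_voxel_mm, 2), collapse = ", "),
    object@cluster_size, object@n_selected,
    object@cluster_mean_r, object@threshold_r))
})

setMethod("show", "EfieldSummary", function(object) {
  cat(sprintf(
    "EfieldSummary: mean %.2f V/m, peak %.2f V/m, %.2f%% above %g V/m\n",
    object@mean_vpm, object@peak_vpm, object@pct_above_threshold,
    object@threshold_vpm))
})
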