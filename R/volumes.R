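#' Construct a VoxelGrid
#'
#' @param shape integer triple, voxels per axis.
#' @param affine 4x4 voxel-index (0-based) to MNI-mm transform.
#' @return a [VoxelGrid-class]
#' @examples
#' g <- voxelGrid(c(10, 10, 10), diag(c(2, 2, 2, 1)))
#' voxelSize(g)
#' @export
voxelGrid <- function(shape, affine) {
  new("VoxelGrid", shape = as.integer(shape), affine = affine)
}

#' Voxel size of a grid in mm
#'
#' Column norms of the 3x3 block of the affine.
#' @param grid a [VoxelGrid-class]
#' @return numeric triple of mm per voxel step along each axis
#' @export
voxelSize <- function(grid) {
  sqrt(colSums(grid@affine[1:3, 1:3]^2))
}

#' Number of voxels in a grid
#' @param grid a [VoxelGrid-class]
#' @export
nVoxels <- function(grid) prod(grid@shape)

#' A regular MNI-box grid
#'
#' Axis-aligned grid covering x in \[-90, 90\], y in \[-126, 90\],
#' z in \[-72, 108\] mm at the requested isotropic spacing, with voxel
#' (0,0,0) at (-90, -126, -72). At 2 mm this matches the shape of the
#' standard 2-mm MNI box (91 x 109 x 91); the 4-mm default used by the
#' phantom simulator is the same box coarsened for desk-scale work.
#'
#' @param voxel_mm isotropic voxel edge in mm (default 2)
#' @return a [VoxelGrid-class]
#' @export
mniGrid <- function(voxel_mm = 2) {
  stopifnot(voxel_mm > 0)
  lo <- c(-90, -126, -72)
  hi <- c(90, 90, 108)
  shape <- floor((hi - lo) / voxel_mm) + 1L
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- lo
  voxelGrid(shape, affine)
}

#' Default coarse phantom grid (4-mm MNI box)
#' @return a [VoxelGrid-class]
#' @export
defaultPhantomGrid <- function() mniGrid(4)

#' Convert MNI mm coordinates to continuous 0-based voxel indices
#'
#' @param grid a [VoxelGrid-class]
#' @param points numeric triple or n x 3 matrix of MNI mm coordinates
#' @return continuous voxel coordinates (same shape as input), 0-based
#' @export
mmToVoxel <- function(grid, points) {
  p <- rbind(t(matrix(points, ncol = 3)), 1)
  v <- solve(grid@affine, p)[1:3, , drop = FALSE]
  if (is.matrix(points)) t(v) else drop(v)
}

#' Convert 0-based voxel indices to MNI mm coordinates
#'
#' @param grid a [VoxelGrid-class]
#' @param ijk integer/numeric triple or n x 3 matrix of 0-based voxel indices
#' @return mm coordinates, same shape as input
#' @export
voxelToMm <- function(grid, ijk) {
  p <- rbind(t(matrix(ijk, ncol = 3)), 1)
  v <- (grid@affine %*% p)[1:3, , drop = FALSE]
  if (is.matrix(ijk)) t(v) else drop(v)
}

# 0-based (i,j,k) of all voxels, V x 3, in linear (x-fastest) order
.gridIjk <- function(grid) {
  s <- grid@shape
  cbind(
    rep_len(0:(s[1] - 1L), prod(s)),
    rep_len(rep(0:(s[2] - 1L), each = s[1]), prod(s)),
    rep(0:(s[3] - 1L), each = s[1] * s[2])
  )
}

# mm coordinates of all voxel centers, V x 3
.gridMm <- function(grid) voxelToMm(grid, .gridIjk(grid))

# 1-based linear index from 0-based ijk rows
.linearIndex <- function(grid, ijk) {
  s <- grid@shape
  ijk[, 1] + s[1] * (ijk[, 2] + s[2] * ijk[, 3]) + 1L
}

#' Read a NIfTI-1 volume
#'
#' 3D images become [ScalarVolume-class]; 4D images become
#' [BoldSeries-class] with T equal to the 4th dimension and TR taken from
#' the NIfTI time pixdim (overridable).
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @param tr repetition time in seconds for 4D images; default uses the
#'   file header, falling back to 1 s when the header has none
#' @return a [ScalarVolume-class] or [BoldSeries-class]
#' @export
readVolume <- function(path, tr = NULL) {
  if (!file.exists(path))
    .fcStop("fcTarget_missing_file", sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    .fcStop("fcTarget_bad_nifti",
                            sprintf("not a readable NIfTI file: %s (%s)",
                                    path, conditionMessage(e))))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (any(!is.finite(aff)) ||
      abs(det(aff[1:3, 1:3])) < .Machine$double.eps * 100)
    .fcStop("fcTarget_bad_affine",
            sprintf("non-finite or singular affine in %s", path))
  arr <- as.array(img)
  d <- dim(arr)
  if (!length(d) %in% c(3L, 4L))
    .fcStop("fcTarget_bad_nifti",
            sprintf("expected a 3D or 4D image, got %dD: %s", length(d), path))
  grid <- voxelGrid(d[1:3], aff)
  if (length(d) == 3L) {
    new("ScalarVolume", grid = grid, values = as.vector(arr))
  } else {
    if (is.null(tr)) {
      pd <- attr(img, "pixdim")
      tr <- if (length(pd) >= 4 && is.finite(pd[4]) && pd[4] > 0) pd[4] else 1
    }
    dat <- t(matrix(arr, prod(d[1:3]), d[4]))
    new("BoldSeries", grid = grid, data = dat, tr = tr)
  }
}

#' Write a volumetric object as NIfTI-1
#'
#' Masks are written as 0/1 integer volumes; the grid affine is written
#' unchanged as both sform and qform.
#'
#' @param x a [ScalarVolume-class], [VolumeMask-class] or [BoldSeries-class]
#' @param path output path (`.nii` or `.nii.gz`)
#' @return `path`, invisibly
#' @export
writeVolume <- function(x, path) {
  grid <- x@grid
  arr <- if (is(x, "VolumeMask")) {
    array(as.integer(x@member), dim = grid@shape)
  } else if (is(x, "ScalarVolume")) {
    array(x@values, dim = grid@shape)
  } else if (is(x, "BoldSeries")) {
    array(t(x@data), dim = c(grid@shape, nrow(x@data)))
  } else .fcStop("fcTarget_bad_input", "unsupported object for writeVolume")
  img <- RNifti::asNifti(arr)
  vs <- voxelSize(grid)
  RNifti::pixdim(img) <- if (is(x, "BoldSeries")) c(vs, x@tr) else vs
  aff <- structure(grid@affine, code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Spherical ROI mask
#'
#' A voxel is a member iff the Euclidean mm distance from its center to
#' `center_mm` is `<= radius_mm` (inclusive boundary). The center need not
#' lie inside the grid; a sphere entirely outside yields an empty mask.
#'
#' @param grid a [VoxelGrid-class]
#' @param center_mm MNI mm triple
#' @param radius_mm radius in mm (> 0)
#' @return a [VolumeMask-class]
#' @export
makeSphereMask <- function(grid, center_mm, radius_mm) {
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    .fcStop("fcTarget_bad_radius", "radius_mm must be > 0")
  mm <- .gridMm(grid)
  d2 <- (mm[, 1] - center_mm[1])^2 + (mm[, 2] - center_mm[2])^2 +
    (mm[, 3] - center_mm[3])^2
  new("VolumeMask", grid = grid, member = d2 <= radius_mm^2)
}

#' Union of masks on a shared grid
#'
#' @param masks a list of [VolumeMask-class] objects on one grid
#' @return a [VolumeMask-class]; member iff member of any input
#' @export
unionMasks <- function(masks) {
  stopifnot(length(masks) >= 1L)
  g <- masks[[1]]@grid
  member <- rep(FALSE, nVoxels(g))
  for (m in masks) {
    if (!identical(m@grid@shape, g@shape) ||
        !isTRUE(all.equal(m@grid@affine, g@affine)))
      .fcStop("fcTarget_grid_mismatch", "masks must share one grid")
    member <- member | m@member
  }
  new("VolumeMask", grid = g, member = member)
}

#' Intersect or subtract masks
#' @param a,b [VolumeMask-class] objects on one grid
#' @return a [VolumeMask-class]
#' @export
intersectMasks <- function(a, b) {
  unionMasks(list(a, b)) # grid check
  new("VolumeMask", grid = a@grid, member = a@member & b@member)
}

#' @rdname intersectMasks
#' @export
subtractMask <- function(a, b) {
  unionMasks(list(a, b))
  new("VolumeMask", grid = a@grid, member = a@member & !b@member)
}

#' MNI centers of the four canonical left-DLPFC stimulation sites
#'
#' BA9, BA46, the "5-cm rule" site, and the Beam F3 group-average site.
#' @return 4 x 3 matrix of MNI mm coordinates
#' @export
dlpfcCenters <- function() {
  m <- rbind(BA9 = c(-36, 39, 43),
             BA46 = c(-44, 40, 29),
             rule_5cm = c(-41, 16, 54),
             beam_F3 = c(-37, 26, 49))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Composite left-DLPFC search mask
#'
#' Union of four 20-mm radius spheres centred at the canonical left-DLPFC
#' stimulation sites ([dlpfcCenters()]), each built separately and merged.
#'
#' @param grid a [VoxelGrid-class] covering the left prefrontal MNI region
#' @param radius_mm sphere radius in mm (default 20)
#' @return a [VolumeMask-class]
#' @export
buildDlpfcMask <- function(grid, radius_mm = 20) {
  ctr <- dlpfcCenters()
  spheres <- lapply(seq_len(nrow(ctr)), function(i)
    makeSphereMask(grid, ctr[i, ], radius_mm))
  m <- unionMasks(spheres)
  if (!any(m@member))
    .fcStop("fcTarget_empty_mask", "grid does not intersect any DLPFC sphere")
  m
}

#' Spherical stand-in for the pregenual cingulate (PGC) seed mask
#'
#' The study's PGC mask is an externally distributed file; when it is not
#' supplied, this configurable sphere (default center (0, 40, 4) mm,
#' radius 6 mm, a pregenual ACC location) is used and reports should flag
#' it as a stand-in.
#'
#' @param grid a [VoxelGrid-class]
#' @param center_mm MNI mm center (default `c(0, 40, 4)`)
#' @param radius_mm radius in mm (default 6)
#' @return a [VolumeMask-class]
#' @export
pgcStandInMask <- function(grid, center_mm = c(0, 40, 4), radius_mm = 6) {
  makeSphereMask(grid, center_mm, radius_mm)
}

#' Read a JSON ROI prescription file
#'
#' Expects a JSON array of objects with fields `center_mm` (length-3),
#' `radius_mm` (scalar) and `label`.
#'
#' @param path path to the JSON file
#' @param grid a [VoxelGrid-class] on which to realise the spheres
#' @return a named list of [VolumeMask-class] objects
#' @export
readRoiPrescriptions <- function(path, grid) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  masks <- lapply(spec, function(s)
    makeSphereMask(grid, unlist(s$center_mm), s$radius_mm))
  names(masks) <- vapply(spec, function(s) s$label, character(1))
  masks
}
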