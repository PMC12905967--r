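#' Discrete-cosine high-pass temporal filter
#'
#' Removes the per-voxel mean and all discrete-cosine components with
#' frequency below `cutoff_hz` by least-squares projection. The DCT basis
#' function k over T frames has frequency k / (2 T tr) Hz; all k with
#' frequency `<= cutoff_hz` are regressed out. Projection is deterministic,
#' idempotent, and well behaved at the series edges for T as short as 100.
#'
#' @param series a [BoldSeries-class]
#' @param cutoff_hz high-pass cutoff in Hz (default 0.01); must be below the
#'   Nyquist frequency 1/(2 tr)
#' @return a filtered [BoldSeries-class] of identical shape
#' @export
highpass <- function(series, cutoff_hz = 0.01) {
  tr <- series@tr
  if (cutoff_hz >= 1 / (2 * tr))
    .fcStop("fcTarget_bad_cutoff",
            sprintf("cutoff %g Hz is not below Nyquist %g Hz",
                    cutoff_hz, 1 / (2 * tr)))
  Tn <- nrow(series@data)
  K <- floor(2 * Tn * tr * cutoff_hz)
  B <- .dctBasis(Tn, K)
  # residual after projecting onto [1, DCT_1..K]; basis is orthogonal
  Bq <- qr.Q(qr(cbind(1, B)))
  out <- series@data - Bq %*% crossprod(Bq, series@data)
  new("BoldSeries", grid = series@grid, data = out, tr = tr)
}

.dctBasis <- function(Tn, K) {
  if (K < 1L) return(matrix(numeric(0), Tn, 0))
  n <- 0:(Tn - 1)
  vapply(seq_len(K), function(k) cos(pi * (n + 0.5) * k / Tn), numeric(Tn))
}

# 1D Gaussian pass in scatter form along the rows of an (n x M) matrix:
# each source row distributes its value over in-bounds target rows
# (column-normalised kernel), so the column totals are conserved exactly,
# also at the boundary
.gaussPass <- function(a, sigma_vox) {
  if (sigma_vox <= 0) return(a)
  n <- nrow(a)
  r <- ceiling(4 * sigma_vox)
  w <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[j[ok], i] <- w[ok] / sum(w[ok])
  }
  K %*% a
}

# smooth a (V x N) matrix of N volumes arranged on grid, along all 3 axes
.smoothVolumes <- function(mat, grid, fwhm_mm) {
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxelSize(grid)
  s <- grid@shape
  N <- ncol(mat)
  arr <- array(mat, dim = c(s, N))
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    a <- .gaussPass(matrix(a, dm[1]), sigma_mm / vs[ax])
    dim(a) <- dm
    arr <- aperm(a, order(perm))
  }
  matrix(arr, prod(s), N)
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable convolution with a Gaussian of `sigma = fwhm / (2 sqrt(2 ln 2))`
#' mm, converted to voxel units per axis from the grid voxel size. The kernel
#' is applied in scatter form (each source voxel distributes its value over
#' in-bounds neighbours), so the per-frame total is conserved exactly, also
#' at the volume boundary. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param x a [BoldSeries-class] (smoothed frame by frame) or
#'   [ScalarVolume-class]
#' @param fwhm_mm full width at half maximum in mm (>= 0; default 4)
#' @return an object of the same class as `x`
#' @export
smoothGaussian <- function(x, fwhm_mm = 4) {
  if (!is.numeric(fwhm_mm) || fwhm_mm < 0)
    .fcStop("fcTarget_bad_fwhm", "fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(x)
  if (is(x, "ScalarVolume")) {
    v <- .smoothVolumes(matrix(x@values, ncol = 1), x@grid, fwhm_mm)
    new("ScalarVolume", grid = x@grid, values = as.vector(v))
  } else if (is(x, "BoldSeries")) {
    sm <- .smoothVolumes(t(x@data), x@grid, fwhm_mm)
    new("BoldSeries", grid = x@grid, data = t(sm), tr = x@tr)
  } else .fcStop("fcTarget_bad_input",
                 "smoothGaussian expects a BoldSeries or ScalarVolume")
}

#' Unweighted mean time series over a mask
#'
#' @param series a [BoldSeries-class]
#' @param mask a non-empty [VolumeMask-class] on the same grid
#' @param label label for the resulting series
#' @return a [SeedSeries-class]
#' @export
meanSeries <- function(series, mask, label = "mean") {
  .checkSameGrid(series@grid, mask@grid)
  idx <- which(mask@member)
  if (length(idx) == 0L)
    .fcStop("fcTarget_empty_mask", "mask has no member voxels")
  new("SeedSeries",
      values = rowMeans(series@data[, idx, drop = FALSE]),
      label = label)
}

#' Seedmap-weighted seed time series
#'
#' The seed series is a weighted spatial average over the voxels of
#' `include` minus `exclude` (typically: gray matter minus the DLPFC search
#' mask), each voxel weighted by its group-average connectivity with the
#' seed region. Weights are used with their sign and the sum is normalised
#' by `sum(abs(w))`, keeping the output scale stable under mixed-sign maps:
#' `out(t) = sum_v w_v x_v(t) / sum_v |w_v|`.
#'
#' @param series a [BoldSeries-class]
#' @param weights a [ScalarVolume-class] of per-voxel weights (same grid)
#' @param include voxels eligible for the average ([VolumeMask-class])
#' @param exclude voxels removed from `include` (optional [VolumeMask-class])
#' @param label label for the resulting series
#' @return a [SeedSeries-class]
#' @export
seedmapSeries <- function(series, weights, include, exclude = NULL,
                          label = "seedmap") {
  .checkSameGrid(series@grid, weights@grid)
  .checkSameGrid(series@grid, include@grid)
  member <- include@member
  if (!is.null(exclude)) {
    .checkSameGrid(series@grid, exclude@grid)
    member <- member & !exclude@member
  }
  idx <- which(member)
  if (length(idx) == 0L)
    .fcStop("fcTarget_empty_mask", "no voxels remain after exclusion")
  w <- weights@values[idx]
  denom <- sum(abs(w))
  if (denom == 0)
    .fcStop("fcTarget_zero_weights",
            "all effective weights are zero in the included region")
  new("SeedSeries",
      values = as.vector(series@data[, idx, drop = FALSE] %*% w) / denom,
      label = label)
}

#' Pearson product-moment correlation of two seed series
#'
#' @param a,b [SeedSeries-class] objects of equal length (>= 3 frames)
#' @return correlation coefficient in \[-1, 1\]
#' @export
pearsonR <- function(a, b) {
  x <- a@values; y <- b@values
  if (length(x) != length(y) || length(x) < 3L)
    .fcStop("fcTarget_bad_input", "series must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .fcStop("fcTarget_zero_variance", "zero-variance input series")
  stats::cor(x, y)
}

#' Export a seed series as two-column TSV
#'
#' Columns `frame_index` (0-based) and `value`.
#' @param series a [SeedSeries-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeSeedSeries <- function(series, path) {
  utils::write.table(
    data.frame(frame_index = seq_along(series@values) - 1L,
               value = series@values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.checkSameGrid <- function(a, b) {
  if (!identical(a@shape, b@shape) || !isTRUE(all.equal(a@affine, b@affine)))
    .fcStop("fcTarget_grid_mismatch", "objects must share one grid")
  invisible(TRUE)
}
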