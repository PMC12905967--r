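#' Voxelwise seed connectivity within a search mask
#'
#' Pearson correlation between every search-mask voxel's time series and the
#' seed series. Voxels with zero temporal variance are assigned r = 0 with a
#' warning rather than an error.
#'
#' @param series a [BoldSeries-class]
#' @param seed a [SeedSeries-class] of matching length
#' @param search a non-empty [VolumeMask-class] on the series grid
#' @return a [ConnectivityMap-class]
#' @export
mapConnectivity <- function(series, seed, search) {
  .checkSameGrid(series@grid, search@grid)
  idx <- which(search@member)
  if (length(idx) == 0L)
    .fcStop("fcTarget_empty_mask", "search mask is empty")
  if (length(seed@values) != nrow(series@data))
    .fcStop("fcTarget_bad_input", "seed length must match frame count")
  s <- seed@values - mean(seed@values)
  sn <- sqrt(sum(s^2))
  if (sn == 0)
    .fcStop("fcTarget_zero_variance", "seed series has zero variance")
  X <- series@data[, idx, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  xn <- sqrt(colSums(Xc^2))
  r <- as.vector(crossprod(Xc, s)) / (xn * sn)
  flat <- xn == 0
  if (any(flat)) {
    warning(sprintf("%d zero-variance voxel(s) assigned r = 0", sum(flat)))
    r[flat] <- 0
  }
  r <- pmin(1, pmax(-1, r))
  rv <- rep(NA_real_, nVoxels(series@grid))
  rv[idx] <- r
  new("ConnectivityMap", grid = series@grid, r = rv, searchMask = search)
}

#' Select the top fraction of connectivity-map voxels
#'
#' Selects `k = ceiling(fraction * N)` voxels of the N search-mask voxels
#' with the largest r (signed). Ties at the cut are broken by larger r and
#' then by lowest linear voxel index, making the selection deterministic.
#'
#' @param map a [ConnectivityMap-class]
#' @param fraction proportion in (0, 1\]; the study prescription is 0.005
#' @return a [VolumeMask-class] of the selected voxels
#' @export
selectTopFraction <- function(map, fraction = 0.005) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    .fcStop("fcTarget_bad_fraction", "fraction must lie in (0, 1]")
  idx <- which(map@searchMask@member)
  if (length(idx) == 0L)
    .fcStop("fcTarget_empty_mask", "connectivity map has an empty search mask")
  r <- map@r[idx]
  k <- as.integer(ceiling(fraction * length(idx)))
  ord <- order(-r, idx)
  sel <- idx[ord[seq_len(k)]]
  member <- rep(FALSE, nVoxels(map@grid))
  member[sel] <- TRUE
  new("VolumeMask", grid = map@grid, member = member)
}

.neighbourOffsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    .fcStop("fcTarget_bad_connectivity", "connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  g <- g[keep, , drop = FALSE]
  # half-space: keep one of each +/- pair
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ,
    drop = FALSE]
}

#' Connected components of a voxel mask
#'
#' Partition of the member voxels into maximal connected sets under
#' face- (6), edge- (18) or vertex-adjacency (26). Components are returned
#' sorted by size descending, size ties broken by lowest member linear index.
#'
#' @param mask a [VolumeMask-class] (may be empty; returns an empty list)
#' @param connectivity 6, 18 or 26 (default 26, the common neuroimaging
#'   convention)
#' @return list of [VolumeMask-class] components
#' @export
connectedComponents <- function(mask, connectivity = 26) {
  offs <- .neighbourOffsets(connectivity)
  grid <- mask@grid
  idx <- which(mask@member)
  M <- length(idx)
  if (M == 0L) return(list())
  vid <- integer(nVoxels(grid))
  vid[idx] <- seq_len(M)
  ijk <- .gridIjk(grid)[idx, , drop = FALSE]
  s <- grid@shape
  edges <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < s[1] & nb[, 2] >= 0 & nb[, 2] < s[2] &
      nb[, 3] >= 0 & nb[, 3] < s[3]
    if (!any(ok)) next
    nlin <- .linearIndex(grid, nb[ok, , drop = FALSE])
    nv <- vid[nlin]
    hit <- nv > 0L
    if (any(hit))
      edges <- c(edges, rbind(which(ok)[hit], nv[hit]))
  }
  g <- igraph::make_empty_graph(n = M, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  comps <- split(idx, memb)
  sizes <- lengths(comps)
  firsts <- vapply(comps, function(x) as.numeric(min(x)), numeric(1))
  comps <- comps[order(-sizes, firsts)]
  lapply(comps, function(ci) {
    member <- rep(FALSE, nVoxels(grid))
    member[ci] <- TRUE
    new("VolumeMask", grid = grid, member = member)
  })
}

#' Locate the personalised stimulation target
#'
#' Thresholds the connectivity map at the top `fraction` of search voxels,
#' clusters the selected voxels, takes the largest contiguous cluster
#' (size ties broken by higher mean r, then lowest linear index), and
#' reports the unweighted centroid of its member voxel MNI coordinates,
#' the member voxel nearest that centroid (ties broken by higher r) and
#' the peak-r voxel.
#'
#' @param map a [ConnectivityMap-class]
#' @param fraction top fraction of search voxels to select (default 0.005)
#' @param connectivity cluster adjacency: 6, 18 or 26 (default 26)
#' @return a [TargetReport-class]
#' @export
locateTarget <- function(map, fraction = 0.005, connectivity = 26) {
  sel <- selectTopFraction(map, fraction)
  comps <- connectedComponents(sel, connectivity)
  meanr <- vapply(comps, function(m) mean(map@r[m@member]), numeric(1))
  sizes <- vapply(comps, function(m) sum(m@member), integer(1))
  firsts <- vapply(comps, function(m) min(which(m@member)), numeric(1))
  best <- comps[[order(-sizes, -meanr, firsts)[1]]]
  midx <- which(best@member)
  mm <- voxelToMm(map@grid, .gridIjk(map@grid)[midx, , drop = FALSE])
  centroid <- colMeans(mm)
  rmem <- map@r[midx]
  d2 <- colSums((t(mm) - centroid)^2)
  snap <- order(d2, -rmem)[1]
  new("TargetReport",
      centroid_mm = unname(centroid),
      snapped_voxel_mm = unname(mm[snap, ]),
      cluster_size = length(midx),
      cluster_mean_r = mean(rmem),
      peak_voxel_mm = unname(mm[which.max(rmem), ]),
      threshold_r = min(map@r[sel@member]),
      n_selected = sum(sel@member))
}

#' Change in target-to-seed functional connectivity across sessions
#'
#' For each session (processed identically: high-pass, then spatial
#' smoothing), correlates the mean series of a sphere at the pre-session
#' target centroid with the seedmap-weighted PGC series, and returns the
#' difference of Fisher-z transformed correlations,
#' `deltaFC = atanh(r_post) - atanh(r_pre)`.
#'
#' @param pre,post [BoldSeries-class] sessions on one grid; the target must
#'   derive from the pre session
#' @param target a [TargetReport-class]
#' @param weights group-average connectivity weight map ([ScalarVolume-class])
#' @param gm gray-matter inclusion mask ([VolumeMask-class])
#' @param exclude mask excluded from the seedmap average (the DLPFC mask)
#' @param sphere_radius_mm radius of the target sphere in mm (default 10)
#' @param highpass_hz temporal high-pass cutoff (default 0.01)
#' @param fwhm_mm spatial smoothing FWHM in mm (default 4)
#' @return list with `delta_fc`, `r_pre`, `r_post`
#' @export
deltaFC <- function(pre, post, target, weights, gm, exclude,
                    sphere_radius_mm = 10, highpass_hz = 0.01, fwhm_mm = 4) {
  .checkSameGrid(pre@grid, post@grid)
  sphere <- makeSphereMask(pre@grid, target@centroid_mm, sphere_radius_mm)
  if (!any(sphere@member))
    .fcStop("fcTarget_empty_mask", "target sphere contains no voxels")
  sessionR <- function(sess) {
    proc <- smoothGaussian(highpass(sess, highpass_hz), fwhm_mm)
    seed <- seedmapSeries(proc, weights, gm, exclude, label = "PGC seedmap")
    pearsonR(meanSeries(proc, sphere, label = "target"), seed)
  }
  r_pre <- sessionR(pre)
  r_post <- sessionR(post)
  list(delta_fc = atanh(r_post) - atanh(r_pre), r_pre = r_pre, r_post = r_post)
}

#' Electric-field summary indices over a target region
#'
#' @param field electric-field magnitude map in V/m ([ScalarVolume-class]),
#'   values >= 0
#' @param roi non-empty [VolumeMask-class] on the field grid
#' @param threshold_vpm suprathreshold cut in V/m (default 150); the
#'   percentage counts voxels strictly above it
#' @return an [EfieldSummary-class]
#' @export
efieldSummary <- function(field, roi, threshold_vpm = 150) {
  .checkSameGrid(field@grid, roi@grid)
  idx <- which(roi@member)
  if (length(idx) == 0L)
    .fcStop("fcTarget_empty_mask", "e-field ROI is empty")
  v <- field@values[idx]
  if (any(v < 0))
    .fcStop("fcTarget_bad_input", "electric-field values must be >= 0")
  new("EfieldSummary",
      mean_vpm = mean(v), peak_vpm = max(v),
      pct_above_threshold = 100 * mean(v > threshold_vpm),
      threshold_vpm = threshold_vpm)
}

#' Export a target report as JSON and/or one-row TSV
#'
#' @param report a [TargetReport-class]
#' @param json_path,tsv_path output paths (either may be `NULL`)
#' @param extra named list echoed into the JSON (configuration, provenance)
#' @return the report, invisibly
#' @export
writeTargetReport <- function(report, json_path = NULL, tsv_path = NULL,
                              extra = list()) {
  row <- data.frame(
    centroid_x = report@centroid_mm[1], centroid_y = report@centroid_mm[2],
    centroid_z = report@centroid_mm[3],
    snapped_x = report@snapped_voxel_mm[1],
    snapped_y = report@snapped_voxel_mm[2],
    snapped_z = report@snapped_voxel_mm[3],
    peak_x = report@peak_voxel_mm[1], peak_y = report@peak_voxel_mm[2],
    peak_z = report@peak_voxel_mm[3],
    cluster_size = report@cluster_size,
    cluster_mean_r = report@cluster_mean_r,
    threshold_r = report@threshold_r, n_selected = report@n_selected)
  if (!is.null(tsv_path))
    utils::write.table(row, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path)) {
    payload <- c(list(
      centroid_mm = report@centroid_mm,
      snapped_voxel_mm = report@snapped_voxel_mm,
      peak_voxel_mm = report@peak_voxel_mm,
      cluster_size = report@cluster_size,
      cluster_mean_r = report@cluster_mean_r,
      threshold_r = report@threshold_r,
      n_selected = report@n_selected), extra)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
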