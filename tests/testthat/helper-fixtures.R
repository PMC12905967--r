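# small axis-aligned grid with voxel (0,0,0) at the origin
smallGrid <- function(n = 8, vox = 2, origin = c(0, 0, 0)) {
  a <- diag(c(rep(vox, 3), 1))
  a[1:3, 4] <- origin
  voxelGrid(rep(n, 3), a)
}

# BoldSeries of iid normal noise on a grid
randomBold <- function(grid, t_frames = 50, tr = 1, seed = 1) {
  set.seed(seed)
  new("BoldSeries", grid = grid,
      data = matrix(rnorm(t_frames * nVoxels(grid)), t_frames), tr = tr)
}

scalarVol <- function(grid, values) {
  new("ScalarVolume", grid = grid, values = values)
}

maskFrom <- function(grid, idx) {
  m <- rep(FALSE, nVoxels(grid))
  m[idx] <- TRUE
  new("VolumeMask", grid = grid, member = m)
}

seedSeries <- function(values, label = "test") {
  new("SeedSeries", values = values, label = label)
}

# coarse MNI box for fast whole-pipeline fixtures
coarsePhantom <- function(seed = 1, ...) {
  makePhantom(phantomSpec(grid = mniGrid(8), seed = seed, ...), post = FALSE)
}

# independent flood-fill connected components (breadth-first search over an
# explicit neighbour check); returns list of sorted member index vectors
floodFillComponents <- function(mask, connectivity) {
  grid <- mask@grid
  s <- grid@shape
  idx <- which(mask@member)
  if (length(idx) == 0) return(list())
  ijk <- cbind((idx - 1) %% s[1],
               ((idx - 1) %/% s[1]) %% s[2],
               (idx - 1) %/% (s[1] * s[2]))
  rownames(ijk) <- idx
  isNb <- function(a, b) {
    d <- abs(a - b)
    if (any(d > 1)) return(FALSE)
    n <- sum(d)
    switch(as.character(connectivity),
           "6" = n == 1, "18" = n >= 1 & sum(d > 0) <= 2 & n <= 2,
           "26" = n >= 1)
  }
  unvisited <- rep(TRUE, length(idx))
  comps <- list()
  while (any(unvisited)) {
    queue <- which(unvisited)[1]
    unvisited[queue] <- FALSE
    comp <- queue
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (j in which(unvisited)) {
        if (isNb(ijk[cur, ], ijk[j, ])) {
          unvisited[j] <- FALSE
          queue <- c(queue, j)
          comp <- c(comp, j)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(idx[comp])
  }
  comps
}
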