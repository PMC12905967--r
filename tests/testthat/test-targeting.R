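test_that("connectivity mapping equals per-voxel correlation with the seed", {
  g <- smallGrid(6)
  b <- randomBold(g, t_frames = 60, seed = 10)
  seed <- seedSeries(b@data[, 100])

  # voxels carrying the seed series itself correlate at 1
  bc <- b
  idx <- c(3, 40, 99)
  bc@data[, idx] <- seed@values
  m <- mapConnectivity(bc, seed, maskFrom(g, idx))
  expect_equal(unname(m@r[idx]), rep(1, 3))

  # elementwise pearsonR oracle on a 10-voxel mask
  set.seed(13)
  sidx <- sample(nVoxels(g), 10)
  m2 <- mapConnectivity(b, seed, maskFrom(g, sidx))
  for (v in sidx)
    expect_equal(m2@r[v], pearsonR(seedSeries(b@data[, v]), seed),
                 tolerance = 1e-12)
  expect_true(all(is.na(m2@r[-sidx])))

  # zero-variance voxel -> r = 0 with a warning
  bz <- b
  bz@data[, sidx[1]] <- 5
  expect_warning(mz <- mapConnectivity(bz, seed, maskFrom(g, sidx)),
                 "zero-variance")
  expect_equal(mz@r[sidx[1]], 0)

  # white-noise null: |r| < 0.2 for at least 99% of voxels at T = 600
  bn <- randomBold(smallGrid(10), t_frames = 600, seed = 11)
  sn <- seedSeries(rnorm(600))
  mn <- mapConnectivity(bn, sn, maskFrom(bn@grid, seq_len(1000)))
  expect_gte(mean(abs(mn@r[1:1000]) < 0.2), 0.99)
})

test_that("top-fraction selection implements the ceiling rule deterministically", {
  g <- smallGrid(10)
  mkMap <- function(idx, r) {
    rv <- rep(NA_real_, nVoxels(g)); rv[idx] <- r
    new("ConnectivityMap", grid = g, r = rv,
        searchMask = maskFrom(g, idx))
  }
  set.seed(12)

  m <- mkMap(1:1000, runif(1000, -1, 1))
  expect_equal(sum(selectTopFraction(m, 0.005)@member), 5L)

  m201 <- mkMap(1:201, runif(201, -1, 1))
  expect_equal(sum(selectTopFraction(m201, 0.005)@member), 2L)

  # full-sort oracle
  sel <- selectTopFraction(m, 0.01)
  k <- ceiling(0.01 * 1000)
  oracle <- sort(order(m@r[1:1000], decreasing = TRUE)[1:k])
  expect_equal(which(sel@member), oracle)

  # deterministic tie handling: ties at the cut resolved by lowest index
  rv <- c(rep(0.9, 3), rep(0.5, 197))
  mt <- mkMap(1:200, rv[order(runif(200))])
  st <- selectTopFraction(mt, 2 / 200)
  top <- which(mt@r == 0.9)
  expect_equal(which(st@member), sort(top)[1:2])

  # rank-only dependence: monotone transform leaves the selection unchanged
  mmono <- mkMap(1:1000, tanh(3 * m@r[1:1000]))
  expect_equal(selectTopFraction(mmono, 0.01)@member,
               selectTopFraction(m, 0.01)@member)

  # k non-decreasing in fraction
  ks <- sapply(c(0.001, 0.01, 0.1, 0.5, 1), function(f)
    sum(selectTopFraction(m, f)@member))
  expect_true(all(diff(ks) >= 0))

  expect_error(selectTopFraction(m, 0), class = "fcTarget_bad_fraction")
  expect_error(selectTopFraction(m, 1.2), class = "fcTarget_bad_fraction")
})

test_that("connected components match a flood-fill oracle and the adjacency semantics", {
  g <- smallGrid(6)

  # face-sharing pair
  a <- maskFrom(g, c(1, 2))
  expect_length(connectedComponents(a, 6), 1)
  expect_equal(sum(connectedComponents(a, 6)[[1]]@member), 2L)

  # corner-sharing pair: split under 6, joined under 26
  crn <- maskFrom(g, c(1, 1 + 1 + 6 + 36))
  expect_length(connectedComponents(crn, 6), 2)
  expect_length(connectedComponents(crn, 26), 1)

  expect_length(connectedComponents(maskFrom(g, integer(0)), 26), 0)
  expect_error(connectedComponents(a, 10),
               class = "fcTarget_bad_connectivity")

  # random masks against the flood-fill oracle, all three adjacencies
  for (s in 1:8) {
    set.seed(100 + s)
    m <- maskFrom(g, sample(nVoxels(g), 40))
    for (conn in c(6, 18, 26)) {
      got <- lapply(connectedComponents(m, conn),
                    function(cm) which(cm@member))
      want <- floodFillComponents(m, conn)
      # same partition irrespective of ordering
      expect_setequal(lapply(got, sort), want)
      # ordering contract: size descending, ties by lowest member index
      sizes <- lengths(got)
      expect_true(all(diff(sizes) <= 0))
      # 26-components are unions of 6-components
      if (conn == 26) {
        got6 <- lapply(connectedComponents(m, 6),
                       function(cm) which(cm@member))
        for (c6 in got6) {
          host <- Filter(function(c26) all(c6 %in% c26), got)
          expect_length(host, 1)
        }
      }
    }
  }
})

test_that("target localisation reports centroid, snapped and peak voxels", {
  g <- smallGrid(10, 2, origin = c(-50, 30, 30))
  mkMap <- function(idx, r) {
    rv <- rep(NA_real_, nVoxels(g)); rv[idx] <- r
    new("ConnectivityMap", grid = g, r = rv, searchMask = maskFrom(g, idx))
  }

  # singleton cluster: all three coordinates coincide
  m1 <- mkMap(1:200, c(0.99, runif(199, 0, 0.5)))
  t1 <- locateTarget(m1, fraction = 1 / 200)
  expect_equal(t1@cluster_size, 1L)
  expect_equal(t1@centroid_mm, t1@snapped_voxel_mm)
  expect_equal(t1@centroid_mm, t1@peak_voxel_mm)
  expect_equal(t1@centroid_mm, voxelToMm(g, c(0, 0, 0)))

  # two-voxel cluster along x: centroid at the midpoint
  idx <- c(1, 2)
  m2 <- mkMap(1:200, replace(runif(200, 0, 0.3), idx, c(0.9, 0.8)))
  t2 <- locateTarget(m2, fraction = 2 / 200)
  expect_equal(t2@cluster_size, 2L)
  p1 <- voxelToMm(g, c(0, 0, 0)); p2 <- voxelToMm(g, c(1, 0, 0))
  expect_equal(t2@centroid_mm, (p1 + p2) / 2)
  expect_equal(t2@peak_voxel_mm, p1) # higher r
  expect_true(t2@snapped_voxel_mm[1] %in% c(p1[1], p2[1]))
  expect_equal(t2@n_selected, 2L)
  expect_equal(t2@threshold_r, 0.8)

  # invariance under strictly monotone transforms of the map
  m3 <- mkMap(1:500, runif(500, -1, 1))
  m3t <- mkMap(1:500, tanh(2 * m3@r[1:500]))
  t3 <- locateTarget(m3, 0.02)
  t3t <- locateTarget(m3t, 0.02)
  expect_equal(t3@centroid_mm, t3t@centroid_mm)
  expect_equal(t3@cluster_size, t3t@cluster_size)
})

test_that("deltaFC is zero for identical sessions and matches the Fisher-z form", {
  g <- smallGrid(5)
  b <- randomBold(g, t_frames = 100, seed = 20)
  all <- maskFrom(g, seq_len(nVoxels(g)))
  w <- numeric(nVoxels(g)); w[60] <- 1
  tgt <- new("TargetReport", centroid_mm = voxelToMm(g, c(1, 1, 1)),
             snapped_voxel_mm = voxelToMm(g, c(1, 1, 1)),
             cluster_size = 1L, cluster_mean_r = 0.9,
             peak_voxel_mm = voxelToMm(g, c(1, 1, 1)),
             threshold_r = 0.9, n_selected = 1L)

  same <- deltaFC(b, b, tgt, scalarVol(g, w), all, NULL,
                  sphere_radius_mm = 1, fwhm_mm = 0)
  expect_equal(same$delta_fc, 0)
  expect_equal(same$r_pre, same$r_post)

  # engineered correlations: r_pre = 0, r_post = 0.5 -> atanh(0.5)
  Tn <- 100
  sphereVox <- 1 + 5 * (1 + 5 * 1) + 1 # voxel (1,1,1)
  set.seed(21)
  sref <- as.vector(scale(rnorm(Tn)))
  orth <- as.vector(scale(residuals(lm(rnorm(Tn) ~ sref))))
  half <- as.vector(scale(0.5 * sref + sqrt(1 - 0.25) * orth))
  expect_equal(cor(half, sref), 0.5, tolerance = 1e-12)
  pre <- b; pre@data[, sphereVox] <- orth; pre@data[, 60] <- sref
  post <- b; post@data[, sphereVox] <- half; post@data[, 60] <- sref
  got <- deltaFC(pre, post, tgt, scalarVol(g, w), all, NULL,
                 sphere_radius_mm = 1, highpass_hz = 0.004, fwhm_mm = 0)
  expect_equal(got$delta_fc, atanh(0.5), tolerance = 1e-6)

  # doubled planted coupling increases deltaFC on the phantom
  sp <- phantomSpec(grid = mniGrid(8), coupling_gain = 0.5, seed = 30)
  ph <- makePhantom(sp, post_gain_mult = 2)
  tg <- targetFromPhantom(ph)
  d <- deltaFC(ph$pre, ph$post, tg$target, ph$group_weights,
               ph$gm_mask, ph$dlpfc_mask)
  expect_gt(d$delta_fc, 0)
})

test_that("e-field summaries report mean, peak and strict suprathreshold fraction", {
  g <- smallGrid(6)
  roi <- maskFrom(g, 1:40)

  uni <- efieldSummary(scalarVol(g, rep(200, nVoxels(g))), roi, 150)
  expect_equal(uni$mean_vpm, 200)
  expect_equal(uni$peak_vpm, 200)
  expect_equal(uni$pct_above_threshold, 100)

  low <- efieldSummary(scalarVol(g, rep(100, nVoxels(g))), roi, 150)
  expect_equal(low$pct_above_threshold, 0)

  v <- rep(0, nVoxels(g)); v[1:20] <- 160; v[21:40] <- 140
  two <- efieldSummary(scalarVol(g, v), roi, 150)
  expect_equal(two$pct_above_threshold, 50)
  expect_equal(two$mean_vpm, 150)
  expect_equal(two$peak_vpm, 160)

  # boundary value is not "above threshold"
  v[1:40] <- 150
  expect_equal(efieldSummary(scalarVol(g, v), roi, 150)$pct_above_threshold, 0)

  expect_error(efieldSummary(scalarVol(g, v), maskFrom(g, integer(0))),
               class = "fcTarget_empty_mask")
  v[2] <- -1
  expect_error(efieldSummary(scalarVol(g, v), roi),
               class = "fcTarget_bad_input")
})

test_that("target reports export to JSON and TSV", {
  tgt <- new("TargetReport", centroid_mm = c(-40, 32, 40),
             snapped_voxel_mm = c(-40, 32, 40), cluster_size = 3L,
             cluster_mean_r = 0.8, peak_voxel_mm = c(-38, 32, 40),
             threshold_r = 0.7, n_selected = 5L)
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".tsv")
  writeTargetReport(tgt, fj, ft, extra = list(pgc_mask = "stand-in"))
  j <- jsonlite::fromJSON(fj)
  expect_equal(j$centroid_mm, c(-40, 32, 40))
  expect_equal(j$pgc_mask, "stand-in")
  d <- read.delim(ft)
  expect_equal(d$cluster_size, 3L)
  expect_equal(d$centroid_x, -40)
})
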