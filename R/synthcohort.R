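# run expr with a local RNG state seeded from `seed`, restoring the caller's
# stream afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# band-limited latent time course: temporally smoothed white noise,
# standardised to mean 0, sd 1
.latentCourse <- function(Tn, smooth_frames = 3) {
  x <- stats::rnorm(Tn + 6 * smooth_frames)
  k <- stats::dnorm(seq(-3 * smooth_frames, 3 * smooth_frames),
                    sd = smooth_frames)
  y <- stats::filter(x, k / sum(k), sides = 2)
  y <- y[!is.na(y)][seq_len(Tn)]
  as.vector(scale(y))
}

#' Specification of a synthetic BOLD phantom
#'
#' Describes a resting-state phantom with a pregenual-cingulate (PGC) seed
#' region and one planted DLPFC voxel cluster coupled to the same latent
#' time course, embedded in voxelwise Gaussian noise plus a spatially
#' smooth, temporally white noise field (the residual spatially correlated
#' noise expected after upstream denoising). The defaults are the package's desk-scale surrogate for a
#' 600-frame 2-mm acquisition: the coarse 4-mm MNI box, 200 frames, TR 1 s.
#'
#' @param grid a [VoxelGrid-class] (default [defaultPhantomGrid()])
#' @param t_frames frames per session (>= 100; default 200)
#' @param tr repetition time in seconds (default 1)
#' @param hotspot_center_mm MNI center of the planted cluster; must lie
#'   inside the composite DLPFC mask (default `c(-40, 32, 40)`)
#' @param hotspot_radius_mm radius of the planted cluster (default 8)
#' @param coupling_gain amplitude of the latent course in hotspot voxels,
#'   in units of `noise_sd` (default 1)
#' @param noise_sd per-voxel Gaussian noise SD (default 1)
#' @param smooth_confound_fwhm_mm spatial FWHM of the smooth noise field
#'   (default 8)
#' @param confound_amp SD of the smooth noise field (default 0.3)
#' @param seed integer RNG seed
#' @return a validated list of class `PhantomSpec`
#' @export
phantomSpec <- function(grid = defaultPhantomGrid(), t_frames = 200L, tr = 1,
                        hotspot_center_mm = c(-40, 32, 40),
                        hotspot_radius_mm = 8, coupling_gain = 1,
                        noise_sd = 1, smooth_confound_fwhm_mm = 8,
                        confound_amp = 0.3, seed = 1L) {
  if (t_frames < 100L)
    .fcStop("fcTarget_bad_spec", "t_frames must be >= 100")
  if (noise_sd <= 0 || coupling_gain < 0)
    .fcStop("fcTarget_bad_spec",
            "need noise_sd > 0 and coupling_gain >= 0")
  dl <- buildDlpfcMask(grid)
  ctr_vox <- round(mmToVoxel(grid, hotspot_center_mm))
  if (any(ctr_vox < 0) || any(ctr_vox >= grid@shape))
    .fcStop("fcTarget_bad_spec", "hotspot center lies outside the grid")
  ctr_lin <- .linearIndex(grid, matrix(ctr_vox, 1))
  if (!dl@member[ctr_lin])
    .fcStop("fcTarget_bad_spec",
            "hotspot center must lie inside the DLPFC search mask")
  structure(list(grid = grid, t_frames = as.integer(t_frames), tr = tr,
                 hotspot_center_mm = hotspot_center_mm,
                 hotspot_radius_mm = hotspot_radius_mm,
                 coupling_gain = coupling_gain, noise_sd = noise_sd,
                 smooth_confound_fwhm_mm = smooth_confound_fwhm_mm,
                 confound_amp = confound_amp, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a two-session BOLD phantom with a planted coupled cluster
#'
#' Builds, reproducibly from `spec$seed`: a latent band-limited time course
#' `s(t)`; a PGC stand-in whose voxels carry `s + noise`; a planted hotspot
#' inside the DLPFC search mask carrying `coupling_gain * s + noise`; all
#' other voxels carrying noise plus a spatially smooth confound; a
#' group-average connectivity weight map (smoothed indicator of the coupled
#' voxels, peaked at the PGC); and a second session generated by the same
#' recipe with fresh noise and the hotspot gain multiplied by
#' `post_gain_mult`.
#'
#' @param spec a [phantomSpec()] object
#' @param post_gain_mult hotspot coupling-gain multiplier for the post
#'   session (default 1)
#' @param post generate the post session? Set `FALSE` when only the
#'   targeting session is needed (default `TRUE`)
#' @return list with elements `pre`, `post` ([BoldSeries-class], `NULL`
#'   when `post = FALSE`), `pgc_mask`, `gm_mask`, `dlpfc_mask`
#'   ([VolumeMask-class]), `group_weights` ([ScalarVolume-class]),
#'   `hotspot_mask`, and `spec`
#' @export
makePhantom <- function(spec, post_gain_mult = 1, post = TRUE) {
  stopifnot(inherits(spec, "PhantomSpec"))
  grid <- spec$grid
  V <- nVoxels(grid)
  pgc <- pgcStandInMask(grid)
  dlpfc <- buildDlpfcMask(grid)
  gm <- unionMasks(list(makeSphereMask(grid, c(0, -20, 10), 80), dlpfc, pgc))
  hotspot <- intersectMasks(
    makeSphereMask(grid, spec$hotspot_center_mm, spec$hotspot_radius_mm),
    dlpfc)
  coupled <- unionMasks(list(pgc, hotspot))
  wraw <- smoothGaussian(
    new("ScalarVolume", grid = grid, values = as.numeric(coupled@member)), 8)
  weights <- new("ScalarVolume", grid = grid,
                 values = wraw@values / max(wraw@values))

  session <- function(gain) {
    s <- .latentCourse(spec$t_frames)
    dat <- matrix(stats::rnorm(spec$t_frames * V, sd = spec$noise_sd),
                  spec$t_frames, V)
    dat[, pgc@member] <- dat[, pgc@member] + s
    if (any(hotspot@member))
      dat[, hotspot@member] <- dat[, hotspot@member] + gain * s
    if (spec$confound_amp > 0) {
      # spatially smooth, temporally white noise field: residual spatially
      # correlated noise surviving upstream denoising
      sm <- .smoothVolumes(matrix(stats::rnorm(V * spec$t_frames), V),
                           grid, spec$smooth_confound_fwhm_mm)
      dat <- dat + (spec$confound_amp / stats::sd(sm)) * t(sm)
    }
    new("BoldSeries", grid = grid, data = dat, tr = spec$tr)
  }

  .withSeed(spec$seed, {
    pre <- session(spec$coupling_gain)
    post_s <- if (post) session(spec$coupling_gain * post_gain_mult) else NULL
    list(pre = pre, post = post_s, pgc_mask = pgc, gm_mask = gm,
         dlpfc_mask = dlpfc, group_weights = weights,
         hotspot_mask = hotspot, spec = spec)
  })
}

#' Specification of a synthetic clinical cohort
#'
#' Marginals emulate a small open-label migraine rTMS trial: about 21
#' patients, baseline ~10 headache days/month (bounded 3-30), a responder
#' subgroup with substantially larger proportional reduction in headache
#' days, and a connectivity-change score (`dfc`) elevated in responders by
#' `dfc_effect` standard deviations.
#'
#' @param n_patients cohort size (default 21)
#' @param baseline_days_mean,baseline_days_sd truncated-normal parameters of
#'   baseline monthly headache days (defaults 10.2 and 7.1, bounds 3-30)
#' @param responder_prob latent responder probability (default 11/21)
#' @param responder_reduction_mean,responder_reduction_sd proportional
#'   reduction in the responder class (defaults 0.55, 0.15)
#' @param nonresponder_reduction_mean,nonresponder_reduction_sd proportional
#'   reduction in the non-responder class (defaults 0.10, 0.12)
#' @param timepoint_jitter_sd extra per-timepoint SD on the reduction
#'   (default 0.03)
#' @param dfc_effect standardised responder/non-responder separation of the
#'   connectivity change (default 1.1)
#' @param dfc_sd within-class SD of the connectivity change (default 0.2)
#' @param dfc_nonresponder_mean non-responder mean connectivity change
#'   (default -0.05)
#' @param intensity_mean,intensity_sd baseline 0-10 headache intensity
#'   (defaults 5.7, 1.5; truncated to 3-9 as in the trial's entry criteria)
#' @param intensity_drop responder intensity drop at later timepoints
#'   (default 2.5 points)
#' @param psqi_mean,psqi_sd PSQI sleep score, unaffected by treatment
#'   (defaults 7.7, 3)
#' @param seed integer RNG seed
#' @return a validated list of class `CohortSpec`
#' @export
cohortSpec <- function(n_patients = 21L, baseline_days_mean = 10.2,
                       baseline_days_sd = 7.1, responder_prob = 11 / 21,
                       responder_reduction_mean = 0.55,
                       responder_reduction_sd = 0.15,
                       nonresponder_reduction_mean = 0.10,
                       nonresponder_reduction_sd = 0.12,
                       timepoint_jitter_sd = 0.03,
                       dfc_effect = 1.1, dfc_sd = 0.2,
                       dfc_nonresponder_mean = -0.05,
                       intensity_mean = 5.7, intensity_sd = 1.5,
                       intensity_drop = 2.5,
                       psqi_mean = 7.7, psqi_sd = 3, seed = 1L) {
  if (responder_prob < 0 || responder_prob > 1)
    .fcStop("fcTarget_bad_spec", "responder_prob must lie in [0, 1]")
  if (n_patients < 1L)
    .fcStop("fcTarget_bad_spec", "n_patients must be >= 1")
  structure(as.list(environment()), class = "CohortSpec")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] < lo | out[todo] > hi]
  }
  out
}

#' Generate a synthetic clinical cohort table
#'
#' Per patient: baseline headache days from a truncated normal on \[3, 30\];
#' a latent responder flag; Post and Follow-up headache days equal to
#' `baseline * (1 - reduction)` with the reduction drawn per class (plus a
#' small per-timepoint jitter) and clipped so that days stay within
#' \[0, 31\]; connectivity change (`dfc`) drawn with the class separation
#' `dfc_effect * dfc_sd`; 0-10 intensity and 0-21 PSQI integer scales; and a
#' 3-category PGIC derived from the realised reduction at each timepoint
#' (> 15% improvement, < -5% worsening, otherwise no change). Day counts
#' are rounded to whole diary days. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohortSpec()] object
#' @return a `data.frame` with one row per patient and columns
#'   `patient_id`, `responder_latent`, `days_baseline/post/followup`,
#'   `intensity_baseline/post/followup`, `psqi_baseline/post/followup`,
#'   `pgic_post`, `pgic_followup`, `dfc`
#' @export
makeCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  n <- spec$n_patients
  .withSeed(spec$seed, {
    base <- .rtruncnorm(n, spec$baseline_days_mean, spec$baseline_days_sd,
                        3, 30)
    base <- round(base)
    resp <- stats::runif(n) < spec$responder_prob
    redMean <- ifelse(resp, spec$responder_reduction_mean,
                      spec$nonresponder_reduction_mean)
    redSd <- ifelse(resp, spec$responder_reduction_sd,
                    spec$nonresponder_reduction_sd)
    latentRed <- stats::rnorm(n, redMean, redSd)
    clipRed <- function(red) pmin(1, pmax(1 - 31 / base, red))
    redPost <- clipRed(latentRed + stats::rnorm(n, 0, spec$timepoint_jitter_sd))
    redFu <- clipRed(latentRed + stats::rnorm(n, 0, spec$timepoint_jitter_sd))
    daysPost <- round(base * (1 - redPost))
    daysFu <- round(base * (1 - redFu))
    pgic <- function(red)
      ifelse(red > 0.15, "improvement",
             ifelse(red < -0.05, "worsening", "no_change"))
    dfc <- stats::rnorm(n, spec$dfc_nonresponder_mean +
                          ifelse(resp, spec$dfc_effect * spec$dfc_sd, 0),
                        spec$dfc_sd)
    int0 <- round(.rtruncnorm(n, spec$intensity_mean, spec$intensity_sd, 3, 9))
    intLater <- function() {
      drop <- ifelse(resp, spec$intensity_drop, 0.5) + stats::rnorm(n, 0, 0.8)
      pmin(10, pmax(0, round(int0 - drop)))
    }
    psqi <- function() pmin(21, pmax(0, round(
      stats::rnorm(n, spec$psqi_mean, spec$psqi_sd))))
    data.frame(
      patient_id = sprintf("P%02d", seq_len(n)),
      responder_latent = resp,
      days_baseline = base, days_post = daysPost, days_followup = daysFu,
      intensity_baseline = int0, intensity_post = intLater(),
      intensity_followup = intLater(),
      psqi_baseline = psqi(), psqi_post = psqi(), psqi_followup = psqi(),
      pgic_post = pgic(redPost), pgic_followup = pgic(redFu),
      dfc = dfc,
      stringsAsFactors = FALSE)
  })
}

#' Write / read a cohort table as TSV
#'
#' @param cohort a cohort `data.frame` from [makeCohort()]
#' @param path TSV path
#' @return `path` (write) or the cohort `data.frame` (read)
#' @export
writeCohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
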