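#' rTMS protocol arithmetic
#'
#' Pulses per session equal `frequency_hz * train_s * n_trains`; session
#' duration is `n_trains * train_s + (n_trains - 1) * intertrain_s` seconds,
#' reported both raw (minutes) and rounded up to whole minutes. The study
#' protocol (10 Hz, 5-s trains, 25-s intervals, 36 trains) gives 1800
#' pulses in 18 minutes.
#'
#' @param frequency_hz stimulation frequency in Hz
#' @param train_s train duration in seconds
#' @param intertrain_s inter-train interval in seconds
#' @param n_trains number of trains per session
#' @return list with `pulses_per_session`, `session_minutes` (raw) and
#'   `session_minutes_rounded` (ceiling)
#' @examples
#' protocolTotals(10, 5, 25, 36)
#' @export
protocolTotals <- function(frequency_hz = 10, train_s = 5, intertrain_s = 25,
                           n_trains = 36) {
  stopifnot(frequency_hz > 0, train_s > 0, intertrain_s >= 0, n_trains >= 1)
  sec <- n_trains * train_s + (n_trains - 1) * intertrain_s
  list(pulses_per_session = frequency_hz * train_s * n_trains,
       session_minutes = sec / 60,
       session_minutes_rounded = ceiling(sec / 60))
}

#' Classify a patient as treatment responder
#'
#' Responder: at least a 30% reduction in monthly headache days relative to
#' baseline (boundary inclusive).
#'
#' @param baseline,later headache days/month at baseline and at the later
#'   timepoint; baseline must be > 0
#' @param threshold proportional-reduction cut (default 0.30)
#' @return logical, vectorised over inputs
#' @export
classifyResponder <- function(baseline, later, threshold = 0.30) {
  if (any(baseline <= 0))
    .fcStop("fcTarget_bad_input", "baseline headache days must be > 0")
  (baseline - later) / baseline >= threshold
}

#' Responder rate of a cohort at a timepoint
#'
#' @param cohort a cohort `data.frame` (see [makeCohort()])
#' @param timepoint `"post"` or `"followup"`
#' @param threshold proportional-reduction cut (default 0.30)
#' @return list with `n_responders`, `n_total`, `rate_pct` (2 dp)
#' @export
responseRate <- function(cohort, timepoint = c("post", "followup"),
                         threshold = 0.30) {
  timepoint <- match.arg(timepoint)
  if (nrow(cohort) == 0L)
    .fcStop("fcTarget_bad_input", "cohort is empty")
  later <- cohort[[paste0("days_", timepoint)]]
  resp <- classifyResponder(cohort$days_baseline, later, threshold)
  list(n_responders = sum(resp), n_total = length(resp),
       rate_pct = round(100 * mean(resp), 2))
}

.pairedFromSummary <- function(mean_diff, sd_diff, n, n_comparisons,
                               alpha = 0.05) {
  se <- sd_diff / sqrt(n)
  df <- n - 1
  if (sd_diff == 0) {
    return(list(mean_diff = mean_diff, sd_diff = 0, n = n, df = df,
                t_stat = if (mean_diff == 0) 0 else Inf * sign(mean_diff),
                p_adjusted = if (mean_diff == 0) 1 else 0,
                ci_low = mean_diff, ci_high = mean_diff,
                cohen_d = if (mean_diff == 0) 0 else Inf * sign(mean_diff),
                degenerate = TRUE, n_comparisons = n_comparisons))
  }
  tstat <- mean_diff / se
  p <- min(1, n_comparisons * 2 * stats::pt(-abs(tstat), df))
  tcrit <- stats::qt(1 - alpha / (2 * n_comparisons), df)
  list(mean_diff = mean_diff, sd_diff = sd_diff, n = n, df = df,
       t_stat = tstat, p_adjusted = p,
       ci_low = mean_diff - tcrit * se, ci_high = mean_diff + tcrit * se,
       cohen_d = mean_diff / sd_diff, degenerate = FALSE,
       n_comparisons = n_comparisons)
}

#' Bonferroni-corrected paired comparison with paired Cohen's d
#'
#' Paired t statistic on the differences `a - b`, a Dunn-Bonferroni
#' simultaneous 95% confidence interval
#' (`mean +/- qt(1 - alpha/(2 m), n - 1) * sd/sqrt(n)` with `m`
#' comparisons), the Bonferroni-adjusted two-sided p-value, and the paired
#' effect size `d = mean(diff) / sd(diff)`.
#'
#' @param a,b equal-length per-patient vectors (the difference analysed is
#'   `a - b`, e.g. Baseline minus Follow-up)
#' @param n_comparisons number of comparisons in the family (default 3:
#'   the three pairwise contrasts of a three-timepoint design)
#' @param alpha family significance level (default 0.05)
#' @return a list of class `PairwiseResult`; see
#'   [pairedBonferroniSummary()] for the fields
#' @export
pairedBonferroni <- function(a, b, n_comparisons = 3, alpha = 0.05) {
  if (length(a) != length(b) || length(a) < 3L)
    .fcStop("fcTarget_bad_input", "need equal-length vectors, n >= 3")
  if (n_comparisons < 1)
    .fcStop("fcTarget_bad_input", "n_comparisons must be >= 1")
  d <- a - b
  out <- .pairedFromSummary(mean(d), stats::sd(d), length(d), n_comparisons,
                            alpha)
  class(out) <- "PairwiseResult"
  out
}

#' Paired comparison from printed summary statistics
#'
#' Same computation as [pairedBonferroni()], entered from a reported mean
#' difference, SD of the differences, and n, so that published summary
#' tables can be checked directly.
#'
#' @param mean_diff mean of the paired differences
#' @param sd_diff sample SD (n - 1) of the paired differences
#' @param n number of pairs
#' @param n_comparisons comparisons in the family (default 3)
#' @param alpha family significance level (default 0.05)
#' @return list of class `PairwiseResult` with `mean_diff`, `sd_diff`, `n`,
#'   `df`, `t_stat`, `p_adjusted`, `ci_low`, `ci_high`, `cohen_d`,
#'   `degenerate`
#' @export
pairedBonferroniSummary <- function(mean_diff, sd_diff, n, n_comparisons = 3,
                                    alpha = 0.05) {
  out <- .pairedFromSummary(mean_diff, sd_diff, n, n_comparisons, alpha)
  class(out) <- "PairwiseResult"
  out
}

#' One-way repeated-measures ANOVA (sphericity assumed)
#'
#' Univariate within-subject ANOVA on an n x k matrix of one measure at k
#' timepoints: `df_effect = k - 1`, `df_error = (k - 1)(n - 1)`. Fitted via
#' `stats::aov` with an `Error(subject)` stratum.
#'
#' @param values n x k numeric matrix, no missing cells
#' @return list with `F`, `df_effect`, `df_error`, `p`
#' @export
rmAnova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values))
    .fcStop("fcTarget_bad_input", "missing cells are not supported")
  n <- nrow(values); k <- ncol(values)
  if (n < 3L || k < 2L)
    .fcStop("fcTarget_bad_input", "need n >= 3 subjects and k >= 2 timepoints")
  d <- data.frame(y = as.vector(values),
                  subject = factor(rep(seq_len(n), k)),
                  time = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ time + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  msE <- tab["Residuals", "Mean Sq"]
  msT <- tab["time", "Mean Sq"]
  dfe <- tab["time", "Df"]; dfr <- tab["Residuals", "Df"]
  if (!is.finite(msE) || msE <= .Machine$double.eps * max(msT, 1)) {
    Fv <- if (msT <= .Machine$double.eps) 0 else Inf
    return(list(F = Fv, df_effect = dfe, df_error = dfr,
                p = if (is.infinite(Fv)) 0 else 1))
  }
  Fv <- msT / msE
  list(F = Fv, df_effect = dfe, df_error = dfr,
       p = stats::pf(Fv, dfe, dfr, lower.tail = FALSE))
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H across k independent groups, with
#' `eta_squared = (H - k + 1) / (N - k)`.
#'
#' @param groups list of numeric samples (k >= 2 groups)
#' @return list with `H`, `df`, `p`, `eta_squared`, `k`, `N`
#' @export
kruskalWallisEta2 <- function(groups) {
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (k < 2L || N < k + 2L)
    .fcStop("fcTarget_bad_input", "need k >= 2 groups and N >= k + 2")
  if (length(unique(x)) == 1L) {
    warning("all observations identical; H undefined, reported as 0")
    return(list(H = 0, df = k - 1, p = 1, eta_squared = etaSquaredFromH(0, k, N),
                k = k, N = N))
  }
  g <- factor(rep(seq_len(k), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  list(H = H, df = unname(kt$parameter), p = kt$p.value,
       eta_squared = etaSquaredFromH(H, k, N), k = k, N = N)
}

#' Eta-squared from a Kruskal-Wallis H statistic
#'
#' `eta^2 = (H - k + 1) / (N - k)` for k groups and N total observations.
#'
#' @param H Kruskal-Wallis statistic
#' @param k number of groups
#' @param N total observations
#' @return eta-squared
#' @export
etaSquaredFromH <- function(H, k, N) (H - k + 1) / (N - k)

#' Chi-square goodness-of-fit for 3-category PGIC counts
#'
#' Tests the observed (improvement, no change, worsening) counts against
#' uniform expected counts; df = 2.
#'
#' @param counts numeric vector of 3 category counts
#' @return list with `chi2`, `df`, `p`, `expected`
#' @export
pgicChisquare <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3L || sum(counts) <= 0)
    .fcStop("fcTarget_bad_input", "need 3 category counts with positive total")
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = unname(ct$expected))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); the p-value is
#' exact for untied small samples and asymptotic otherwise.
#'
#' @param x,y equal-length numeric vectors (n >= 4)
#' @return list with `rho`, `p`, `n`
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4L)
    .fcStop("fcTarget_bad_input", "need equal-length vectors, n >= 4")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    .fcStop("fcTarget_zero_variance", "constant input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Full outcome analysis of a cohort table
#'
#' Runs the trial's outcome battery on a cohort: RM-ANOVA on headache days;
#' Bonferroni-corrected paired comparisons (Baseline vs Post and Baseline
#' vs Follow-up, family of 3); responder rates; Kruskal-Wallis with
#' eta-squared for intensity and PSQI across the three timepoints (treated
#' as independent groups, so N = 3 n); PGIC chi-square at Post and
#' Follow-up; and the Spearman correlation between the PGIC category at
#' Post (1 = improvement, 2 = no change, 3 = worsening) and the realised
#' reduction rate in headache days.
#'
#' @param cohort a cohort `data.frame` (see [makeCohort()])
#' @param responder_threshold proportional-reduction cut (default 0.30)
#' @return nested list of results
#' @export
analyzeCohort <- function(cohort, responder_threshold = 0.30) {
  days <- as.matrix(cohort[, c("days_baseline", "days_post",
                               "days_followup")])
  pgicCounts <- function(col) {
    lev <- c("improvement", "no_change", "worsening")
    as.numeric(table(factor(cohort[[col]], levels = lev)))
  }
  redPost <- (cohort$days_baseline - cohort$days_post) / cohort$days_baseline
  pgicNum <- match(cohort$pgic_post,
                   c("improvement", "no_change", "worsening"))
  list(
    n = nrow(cohort),
    anova_days = rmAnova(days),
    pairwise_post = pairedBonferroni(cohort$days_baseline, cohort$days_post,
                                     n_comparisons = 3),
    pairwise_followup = pairedBonferroni(cohort$days_baseline,
                                         cohort$days_followup,
                                         n_comparisons = 3),
    response_post = responseRate(cohort, "post", responder_threshold),
    response_followup = responseRate(cohort, "followup", responder_threshold),
    kw_intensity = kruskalWallisEta2(list(cohort$intensity_baseline,
                                          cohort$intensity_post,
                                          cohort$intensity_followup)),
    kw_psqi = kruskalWallisEta2(list(cohort$psqi_baseline, cohort$psqi_post,
                                     cohort$psqi_followup)),
    pgic_post = pgicChisquare(pgicCounts("pgic_post")),
    pgic_followup = pgicChisquare(pgicCounts("pgic_followup")),
    spearman_pgic_reduction = spearmanRho(pgicNum, redPost))
}
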