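test_that("protocol arithmetic reproduces the session totals", {
  p <- protocolTotals(10, 5, 25, 36)
  expect_equal(p$pulses_per_session, 1800)
  expect_equal(p$session_minutes, (36 * 5 + 35 * 25) / 60) # 17.9167
  expect_equal(p$session_minutes_rounded, 18)

  expect_equal(protocolTotals(1, 1, 0, 1)$pulses_per_session, 1)
  expect_equal(protocolTotals(1, 1, 0, 1)$session_minutes, 1 / 60)
})

test_that("the 30% responder rule is boundary-inclusive", {
  expect_true(classifyResponder(10, 7))    # exactly 30%
  expect_false(classifyResponder(10, 7.1)) # just below
  expect_false(classifyResponder(10, 12))  # worsening
  expect_equal(classifyResponder(c(10, 20), c(7, 18)), c(TRUE, FALSE))
  expect_error(classifyResponder(0, 5), class = "fcTarget_bad_input")
})

test_that("response rates report the rounded percentage", {
  co <- data.frame(days_baseline = rep(10, 21),
                   days_post = c(rep(7, 11), rep(9, 10)),
                   days_followup = rep(10, 21))
  rr <- responseRate(co, "post")
  expect_equal(rr$n_responders, 11L)
  expect_equal(rr$rate_pct, 52.38)
  expect_equal(responseRate(co, "followup")$rate_pct, 0)
  co$days_followup <- 1
  expect_equal(responseRate(co, "followup")$rate_pct, 100)
  expect_error(responseRate(co[0, ], "post"), class = "fcTarget_bad_input")
})

test_that("paired comparisons reproduce the published effect sizes and CIs", {
  fu <- pairedBonferroniSummary(4.42, 5.48, 21, n_comparisons = 3)
  expect_equal(round(fu$cohen_d, 2), 0.81)
  expect_lt(abs(fu$ci_low - 1.30), 0.01)
  expect_lt(abs(fu$ci_high - 7.54), 0.01)

  po <- pairedBonferroniSummary(3.18, 5.46, 21, n_comparisons = 3)
  expect_equal(round(po$cohen_d, 2), 0.58)
  expect_lt(abs(po$ci_low - 0.07), 0.01)
  expect_lt(abs(po$ci_high - 6.29), 0.01)
})

test_that("paired test obeys its definitional identities and null behaviour", {
  set.seed(30)
  a <- rnorm(21, 10, 3)
  d <- rnorm(21, 0, 2)
  b <- a - d
  r <- pairedBonferroni(a, b, n_comparisons = 3)
  expect_equal(r$mean_diff, mean(d))
  expect_equal(r$sd_diff, sd(d))
  expect_equal(r$cohen_d, mean(d) / sd(d))
  expect_equal(r$t_stat, mean(d) / (sd(d) / sqrt(21)))
  # against the base paired t-test (unadjusted)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(r$t_stat, unname(tt$statistic))
  expect_equal(r$p_adjusted, min(1, 3 * tt$p.value))
  expect_true(r$ci_low <= r$mean_diff && r$mean_diff <= r$ci_high)

  # null case: zero mean difference -> t = 0, CI symmetric about 0
  dz <- d - mean(d)
  rz <- pairedBonferroni(a, a - dz, n_comparisons = 3)
  expect_equal(rz$t_stat, 0)
  expect_equal(rz$ci_low, -rz$ci_high)

  # CI width is non-decreasing in the number of comparisons
  widths <- sapply(1:6, function(m)
    with(pairedBonferroni(a, b, n_comparisons = m), ci_high - ci_low))
  expect_true(all(diff(widths) >= 0))

  # d invariant under common rescaling
  r2 <- pairedBonferroni(3 * a, 3 * b, n_comparisons = 3)
  expect_equal(r2$cohen_d, r$cohen_d, tolerance = 1e-12)

  # degenerate zero-SD differences are flagged
  rdeg <- pairedBonferroni(a, a - 2, n_comparisons = 3)
  expect_true(rdeg$degenerate)
  expect_true(is.infinite(rdeg$cohen_d))

  expect_error(pairedBonferroni(1:2, 1:2), class = "fcTarget_bad_input")
})

test_that("repeated-measures ANOVA matches a hand sums-of-squares oracle", {
  set.seed(31)
  y <- matrix(rnorm(24, 10, 2), 8, 3)
  got <- rmAnova(y)

  # independent decomposition: subject-centred two-way SS
  n <- 8; k <- 3
  grand <- mean(y)
  ssTime <- n * sum((colMeans(y) - grand)^2)
  ssSubj <- k * sum((rowMeans(y) - grand)^2)
  ssTot <- sum((y - grand)^2)
  ssErr <- ssTot - ssTime - ssSubj
  For <- (ssTime / (k - 1)) / (ssErr / ((k - 1) * (n - 1)))
  expect_equal(got$F, For, tolerance = 1e-10)
  expect_equal(got$df_effect, 2)
  expect_equal(got$df_error, 14)
  expect_equal(got$p, pf(For, 2, 14, lower.tail = FALSE), tolerance = 1e-10)

  # three identical columns -> no time effect
  same <- matrix(rep(rnorm(8), 3), 8, 3)
  expect_equal(rmAnova(same)$F, 0)

  # degenerate error term -> infinite F
  sub <- rnorm(8)
  deg <- cbind(sub + 10, sub + 7, sub + 6)
  expect_true(is.infinite(rmAnova(deg)$F))

  expect_error(rmAnova(matrix(c(1, NA, 3, 4, 5, 6), 2)),
               class = "fcTarget_bad_input")
})

test_that("Kruskal-Wallis eta squared reproduces the published effect sizes", {
  expect_equal(round(etaSquaredFromH(29.65, 3, 63), 3), 0.461)
  expect_equal(round(etaSquaredFromH(2.747, 3, 63), 3), 0.012)

  # tie-corrected H against a hand-computed oracle on fixed data with ties
  g1 <- c(1, 2, 2, 3); g2 <- c(2, 3, 4, 4); g3 <- c(4, 5, 5, 6)
  x <- c(g1, g2, g3); grp <- rep(1:3, each = 4)
  r <- rank(x); N <- 12
  Hraw <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, function(z) length(z) * mean(z)^2)) - 3 * (N + 1)
  ties <- table(x)
  Hor <- Hraw / (1 - sum(ties^3 - ties) / (N^3 - N))
  got <- kruskalWallisEta2(list(g1, g2, g3))
  expect_equal(got$H, Hor, tolerance = 1e-10)
  expect_equal(got$eta_squared, (Hor - 2) / 9, tolerance = 1e-10)

  expect_warning(z <- kruskalWallisEta2(list(c(1, 1), c(1, 1), c(1, 1))),
                 "identical")
  expect_equal(z$H, 0)
  expect_error(kruskalWallisEta2(list(1:3)), class = "fcTarget_bad_input")
})

test_that("PGIC chi-square is the uniform goodness-of-fit test", {
  expect_equal(pgicChisquare(c(7, 7, 7))$chi2, 0)
  g <- pgicChisquare(c(10, 8, 3))
  expect_equal(g$chi2, 26 / 7, tolerance = 1e-12)
  expect_equal(g$df, 2)
  ext <- pgicChisquare(c(21, 0, 0))
  expect_equal(ext$chi2, (14^2 + 7^2 + 7^2) / 7) # 42
  expect_error(pgicChisquare(c(0, 0, 0)), class = "fcTarget_bad_input")
})

test_that("Spearman correlation uses mid-ranks and matches a rank oracle", {
  x <- 1:8
  expect_equal(spearmanRho(x, 2 * x + 3)$rho, 1)
  expect_equal(spearmanRho(x, rev(x))$rho, -1)

  # tied 6-point example: rank then Pearson by hand
  a <- c(1, 2, 2, 4, 5, 5)
  b <- c(3, 3, 1, 6, 6, 2)
  ra <- rank(a); rb <- rank(b)
  oracle <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  expect_equal(spearmanRho(a, b)$rho, oracle, tolerance = 1e-12)

  expect_error(spearmanRho(rep(1, 6), 1:6),
               class = "fcTarget_zero_variance")
})

test_that("the cohort analysis battery runs end to end on a synthetic cohort", {
  co <- makeCohort(cohortSpec(seed = 12))
  res <- analyzeCohort(co)
  expect_equal(res$n, 21)
  expect_true(res$anova_days$F > 0)
  expect_equal(res$anova_days$df_effect, 2)
  expect_equal(res$anova_days$df_error, 40)
  expect_equal(res$kw_intensity$N, 63)
  expect_equal(res$kw_intensity$eta_squared,
               (res$kw_intensity$H - 2) / 60, tolerance = 1e-12)
  expect_equal(res$response_post$n_total, 21)
  expect_equal(res$pgic_post$df, 2)
  expect_true(abs(res$spearman_pgic_reduction$rho) <= 1)
  # the generator plants a real treatment effect: Follow-up improvement
  expect_gt(res$pairwise_followup$mean_diff, 0)
})
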