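# Statistical layer: exact signed-rank distribution, effect sizes,
# equivalence testing, and the coupling analyses.

test_that("wilcoxon_exact agrees with brute-force enumeration", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    d <- rnorm(n)
    got <- wilcoxon_exact(rep(0, n), d)
    expect_equal(got$p_exact, enum_signed_rank_p(d), tolerance = 1e-12)
  }
  # with ties (the DP is exact for mid-ranks too)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE) / 2
    got <- wilcoxon_exact(rep(0, n), d)
    expect_equal(got$p_exact, enum_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("zeros are dropped and degenerate pairings rejected", {
  pre <- c(1, 2, 3, 4, 5)
  post <- c(1, 3, 4, 5, 6)  # one zero difference
  got <- wilcoxon_exact(pre, post)
  expect_equal(got$n, 4)
  expect_equal(got$W, 0)
  expect_error(wilcoxon_exact(pre, pre), "degenerate")
})

test_that("the SMD is paired Cohen's d_z with a percentile bootstrap CI", {
  set.seed(12)
  pre <- rnorm(10)
  post <- pre + rnorm(10, 1, 0.5)
  d <- post - pre
  es <- smd_bootstrap(pre, post, B = 2000, seed = 4)
  expect_equal(es$smd, mean(d) / sd(d))
  expect_lte(es$ci[1], es$smd)
  expect_gte(es$ci[2], es$smd)
  # saturated differences: large SMD, CI excludes zero
  sat <- smd_bootstrap(rep(0, 8), c(1, 1, 1, 1, 1, 1, 1, 1.001) ,
                       B = 500, seed = 1)
  expect_gt(sat$ci[1], 0)
  expect_error(smd_bootstrap(1:5, 1:5 + 2), "zero variance")
  # seeded: reproducible
  expect_identical(smd_bootstrap(pre, post, B = 500, seed = 9)$ci,
                   smd_bootstrap(pre, post, B = 500, seed = 9)$ci)
})

test_that("TOST behaves exactly at the null, the bound, and far outside", {
  set.seed(77)
  pre <- rnorm(10)
  # identical pairs: decisive equivalence
  expect_lt(tost_equivalence(pre, pre)$p_max, 1e-6)
  # mean difference exactly on the bound: p_max = 0.5 (t statistic 0);
  # symmetric jitter keeps the difference variance non-degenerate
  jit <- rep(c(-1e-3, 1e-3), 5)
  on_bound <- tost_equivalence(pre, pre + 0.3 * sd(pre) + jit)
  expect_equal(on_bound$p_max, 0.5, tolerance = 1e-3)
  # one full SD shift: clearly non-equivalent
  shifted <- tost_equivalence(pre, pre + sd(pre))
  expect_gt(shifted$p_max, 0.9)
  expect_false(shifted$equivalent)
  # monotone in |mean difference| at fixed variance
  set.seed(78)
  noise <- rnorm(10, 0, 0.2)
  p_at <- vapply(c(0, 0.2, 0.4, 0.8), function(sh) {
    tost_equivalence(pre, pre + noise + sh * sd(pre))$p_max
  }, numeric(1))
  expect_true(all(diff(p_at) > 0))
  expect_error(tost_equivalence(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("correlation handles monotone, constant and bootstrap cases", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(zscore_and_correlate(x, -x^3, "spearman", B = 200,
                                    seed = 1)$rho, -1)
  expect_error(zscore_and_correlate(rep(1, 5), rnorm(5), "pearson"),
               "constant")
  set.seed(55)
  xx <- rnorm(40)
  yy <- -0.373 * xx + rnorm(40, 0, 0.94)
  res <- zscore_and_correlate(xx, yy, "pearson", B = 1000, seed = 2)
  expect_true(res$ci[1] <= res$rho && res$rho <= res$ci[2])
  expect_equal(res$n, 40)
})

test_that("regression recovers slope, R2 shape and task terms", {
  # replicate-average recovery of a standardized slope of -0.373
  set.seed(66)
  slopes <- r2s <- numeric(40)
  for (r in 1:40) {
    beta <- rnorm(40)
    # slope -0.373 on unit-variance x with noise SD 0.925 gives R^2 =
    # 0.373^2 / (0.373^2 + 0.925^2) ~ 0.14
    speed <- -0.373 * beta + rnorm(40, 0, 0.925)
    fit <- regression_with_task(scale(beta)[, 1], scale(speed)[, 1],
                                rep("baseline", 40))
    slopes[r] <- fit$beta_coef
    r2s[r] <- fit$r2
  }
  expect_equal(mean(slopes), -0.373, tolerance = 0.05)
  # E[R^2] at n = 40 exceeds the population 0.14 by about (1 - rho^2)/n
  expect_lt(abs(mean(r2s) - (0.14 + 0.86 / 40)), 0.03)
  # single task level reduces to the simple regression
  fit1 <- regression_with_task(rnorm(20), rnorm(20), rep("a", 20))
  expect_true(is.na(fit1$p_task))
  # a strong task-specific slope is detected by the interaction test
  beta <- rnorm(60)
  task <- rep(c("pre", "post"), each = 30)
  speed <- ifelse(task == "pre", 1.5 * beta, -1.5 * beta) +
    rnorm(60, 0, 0.3)
  fit2 <- regression_with_task(beta, speed, task)
  expect_lt(fit2$p_interaction, 0.001)
})

test_that("change scores use the stated sign conventions", {
  # participant improves: beta drops (positive delta beta), speed rises
  beta_pre <- c(1.0, 1.1, 0.9, 1.2)
  beta_post <- c(0.8, 0.9, 0.85, 1.0)
  speed_pre <- c(1, 1, 1, 1)
  speed_post <- c(1.4, 1.3, 1.1, 1.5)
  res <- change_score_analysis(beta_pre, beta_post, speed_pre, speed_post,
                               B = 200, seed = 1)
  expect_true(all(res$delta_beta > 0))
  expect_true(all(res$delta_speed > 0))
  # delta speed strictly increasing in delta beta gives rho = 1
  db <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  res2 <- change_score_analysis(1 + db, rep(1, 5), rep(1, 5), 1 + 2 * db,
                                B = 200, seed = 1)
  expect_equal(res2$rho, 1)
  expect_error(change_score_analysis(1:2, 1:2, 1:2, 1:2), "3 participants")
})

test_that("analysis sets mirror the prespecified cohort splits", {
  coh <- gen_paired_cohort(10, 0.9, seed = 17)
  dat <- data.frame(participant = coh$participant, pre = coh$pre,
                    post = coh$post)
  tab <- analysis_sets(dat, non_responders = c("P01", "P09"), B = 300,
                       seed = 1)
  expect_equal(tab$analysis_set,
               c("all", "responders", "excl_P01", "excl_P09"))
  expect_equal(tab$n, c(10, 8, 9, 9))
  # empty non-responder set: only the full-cohort row
  tab0 <- analysis_sets(dat, non_responders = character(0), B = 300,
                        seed = 1)
  expect_equal(nrow(tab0), 1)
  # a set smaller than 3 is skipped with a warning
  expect_warning(
    analysis_sets(dat[1:4, ], non_responders = c("P01", "P02"), B = 100,
                  seed = 1),
    "fewer than 3")
})

test_that("a single dominant subject is flagged by leave-one-out", {
  # nine near-null alternating differences plus one huge driver (P10)
  d <- c(0.05, -0.04, 0.03, -0.05, 0.04, -0.03, 0.05, -0.04, 0.03, 5)
  dat <- data.frame(participant = sprintf("P%02d", 1:10), pre = 0,
                    post = d)
  tab <- analysis_sets(dat, non_responders = "P10", B = 300, seed = 2)
  smd_all <- tab$smd[tab$analysis_set == "all"]
  smd_excl <- tab$smd[tab$analysis_set == "excl_P10"]
  expect_gt(smd_all, 2 * smd_excl)
})
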