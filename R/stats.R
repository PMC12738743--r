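# Statistical layer for small paired neurofeedback cohorts: exact Wilcoxon
# signed-rank tests (two-sided, zeros dropped, mid-ranks for ties),
# bootstrapped paired standardized mean differences (Cohen's d_z,
# percentile CIs), TOST equivalence against +/- 0.3 SD of the pre values,
# z-scored correlation/regression, and change-score coupling. No
# multiple-testing correction is applied; every metric is reported raw.

# Null distribution of the positive rank sum T+ for given positive ranks
# (mid-ranks allowed). Works on doubled ranks so tied half-ranks stay
# integer; returns counts over 0..sum(2*ranks). Exact for any tie pattern:
# the dynamic program enumerates all 2^n sign assignments implicitly.
signed_rank_null_counts <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  g <- numeric(total + 1)
  g[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), g[seq_len(total + 1 - r)])
    g <- g + shifted
  }
  g
}

# Exact lower tail P(T+ <= w) for the given ranks.
signed_rank_cdf <- function(w, ranks) {
  g <- signed_rank_null_counts(ranks)
  k <- floor(round(2 * w, 6)) + 1
  k <- max(0, min(k, length(g)))
  if (k == 0) return(0)
  sum(g[seq_len(k)]) / 2^length(ranks)
}

#' Exact two-sided p-value of the signed-rank statistic
#'
#' For `n` untied pairs and observed statistic `W` (the smaller of the
#' positive and negative rank sums), returns the exact two-sided p-value
#' `min(1, 2 * P(T+ <= W))` under the symmetric null.
#'
#' @param W observed statistic (min of positive/negative rank sums)
#' @param n number of non-zero paired differences
#' @return exact two-sided p-value
#' @examples
#' wilcoxon_exact_p(0, 10)  # 2 / 1024
#' @export
wilcoxon_exact_p <- function(W, n) {
  stopifnot(W >= 0, n >= 1)
  min(1, 2 * signed_rank_cdf(W, seq_len(n)))
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Differences are `post - pre`; zero differences are dropped (reducing the
#' effective n), absolute differences are ranked with mid-ranks for ties,
#' and the two-sided p-value is computed from the exact null distribution
#' of the rank sum (a dynamic program over sign assignments, exact also
#' under ties).
#'
#' @param pre,post paired measurement vectors of equal length
#' @return list with `W` (min rank sum), `p_exact`, `n` (effective), and
#'   the positive/negative rank sums
#' @examples
#' wilcoxon_exact(1:10, 1:10 + 1)  # all positive: W = 0, p = 0.002
#' @export
wilcoxon_exact <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  d <- d[d != 0]
  if (length(d) == 0) stop("degenerate pairing: all differences are zero")
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  p <- min(1, 2 * signed_rank_cdf(W, r))
  list(W = W, p_exact = p, n = length(d), w_pos = w_pos, w_neg = w_neg)
}

#' Paired standardized mean difference with bootstrap CI
#'
#' Cohen's d_z: mean of the paired differences divided by their standard
#' deviation, with a seeded percentile bootstrap (pairs resampled with
#' replacement) for the 95 percent confidence interval.
#'
#' @param pre,post paired measurement vectors (n >= 3)
#' @param B number of bootstrap resamples
#' @param seed integer seed for the resampling
#' @param conf confidence level
#' @return list with `smd`, `ci` (percentile interval), `n`, `B`
#' @export
smd_bootstrap <- function(pre, post, B = 5000, seed = 1, conf = 0.95) {
  stopifnot(length(pre) == length(post))
  n <- length(pre)
  if (n < 3) stop("need at least 3 pairs")
  d <- post - pre
  s <- stats::sd(d)
  if (s == 0) stop("zero variance of the paired differences")
  smd <- mean(d) / s
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), B, n)
    dm <- matrix(d[idx], B, n)
    m <- rowMeans(dm)
    # guard against tiny negative values from catastrophic cancellation in
    # degenerate resamples (all pairs identical)
    v <- pmax((rowSums(dm^2) - n * m^2) / (n - 1), 0)
    m / sqrt(v)
  })
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  list(smd = smd, ci = ci, n = n, B = B)
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t-tests against the equivalence bounds
#' `+/- sesoi_factor * sd(pre)` (smallest effect size of interest).
#' Equivalence is declared when the larger of the two one-sided p-values
#' falls below `alpha`.
#'
#' @param pre,post paired measurement vectors (n >= 3)
#' @param sesoi_factor bound as a multiple of the SD of the pre values
#' @param alpha significance level for the equivalence decision
#' @return list with `p_max`, `p_lower`, `p_upper`, `bound`, `equivalent`
#' @export
tost_equivalence <- function(pre, post, sesoi_factor = 0.3, alpha = 0.05) {
  stopifnot(length(pre) == length(post))
  n <- length(pre)
  if (n < 3) stop("need at least 3 pairs")
  s_pre <- stats::sd(pre)
  if (s_pre == 0) stop("zero variance of the pre values")
  delta <- sesoi_factor * s_pre
  d <- post - pre
  se <- stats::sd(d) / sqrt(n)
  if (se == 0) {
    inside <- abs(mean(d)) < delta
    p_lower <- p_upper <- if (inside) 0 else 1
  } else {
    p_lower <- stats::pt((mean(d) + delta) / se, n - 1, lower.tail = FALSE)
    p_upper <- stats::pt((mean(d) - delta) / se, n - 1)
  }
  p_max <- max(p_lower, p_upper)
  list(p_max = p_max, p_lower = p_lower, p_upper = p_upper, bound = delta,
       n = n, equivalent = p_max < alpha)
}

#' Correlation of z-scored series with bootstrap CI
#'
#' Z-scores both inputs, computes Pearson's r or Spearman's rho with its
#' asymptotic p-value, and attaches a seeded percentile bootstrap CI over
#' paired resampling.
#'
#' @param x,y numeric vectors of equal length (n >= 3)
#' @param method `"pearson"` or `"spearman"`
#' @param B number of bootstrap resamples
#' @param seed integer seed
#' @param conf confidence level
#' @return object of class `coupling_result`: list with `rho`, `ci`, `p`,
#'   `n`, `method`
#' @export
zscore_and_correlate <- function(x, y, method = c("pearson", "spearman"),
                                 B = 5000, seed = 1, conf = 0.95) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  zx <- (x - mean(x)) / stats::sd(x)
  zy <- (y - mean(y)) / stats::sd(y)
  ct <- suppressWarnings(stats::cor.test(zx, zy, method = method,
                                         exact = FALSE))
  boots <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(zx[i]) == 0 || stats::sd(zy[i]) == 0) return(NA_real_)
      stats::cor(zx[i], zy[i], method = method)
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  structure(list(rho = unname(ct$estimate), ci = ci, p = ct$p.value,
                 n = n, method = method),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("%s correlation: rho = %.3f, 95%% CI [%.3f, %.3f], p = %.4g, n = %d\n",
              x$method, x$rho, x$ci[1], x$ci[2], x$p, x$n))
  invisible(x)
}

#' Beta-behavior regression with task as a factor
#'
#' Ordinary least squares of the movement metric on beta-power, then
#' augmented with the task phase as a categorical factor and with
#' beta x task interactions; nested models are compared by F-tests.
#'
#' @param beta z-scored (or raw) beta-power values
#' @param speed movement-metric values
#' @param task_labels task phase per observation (e.g. baseline, pre, post)
#' @return list with `r2`, `f_stat`, `df`, `beta_coef`, `beta_ci`,
#'   `p_beta`, `p_task`, `p_interaction`, and the fitted base model
#' @export
regression_with_task <- function(beta, speed, task_labels) {
  stopifnot(length(beta) == length(speed),
            length(task_labels) == length(beta))
  task <- factor(task_labels)
  dat <- data.frame(beta = beta, speed = speed, task = task)
  base <- stats::lm(speed ~ beta, data = dat)
  sm <- summary(base)
  if (qr(stats::model.matrix(base))$rank < 2) stop("rank-deficient design")
  out <- list(
    r2 = sm$r.squared,
    f_stat = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2:3]),
    beta_coef = unname(stats::coef(base)["beta"]),
    beta_ci = unname(stats::confint(base)["beta", ]),
    p_beta = sm$coefficients["beta", 4],
    p_task = NA_real_, p_interaction = NA_real_,
    model = base)
  if (nlevels(task) >= 2) {
    m_task <- stats::lm(speed ~ beta + task, data = dat)
    m_int <- stats::lm(speed ~ beta * task, data = dat)
    out$p_task <- stats::anova(base, m_task)[2, "Pr(>F)"]
    out$p_interaction <- stats::anova(m_task, m_int)[2, "Pr(>F)"]
  }
  out
}

#' Change-score coupling between beta reduction and speed gain
#'
#' Per-participant change scores `Delta beta = beta_pre - beta_post`
#' (larger = greater beta reduction) and
#' `Delta speed = speed_post - speed_pre` (larger = speed gain), correlated
#' with Spearman's rho and a seeded 5000-resample bootstrap CI.
#'
#' @param beta_pre,beta_post per-participant median beta-power (pre/post
#'   neurofeedback)
#' @param speed_pre,speed_post per-participant movement speed (pre/post)
#' @param B number of bootstrap resamples
#' @param seed integer seed
#' @return a `coupling_result` with the change scores attached
#' @export
change_score_analysis <- function(beta_pre, beta_post, speed_pre,
                                  speed_post, B = 5000, seed = 1) {
  n <- length(beta_pre)
  stopifnot(length(beta_post) == n, length(speed_pre) == n,
            length(speed_post) == n)
  if (n < 3) stop("need at least 3 participants")
  d_beta <- beta_pre - beta_post
  d_speed <- speed_post - speed_pre
  res <- zscore_and_correlate(d_beta, d_speed, method = "spearman",
                              B = B, seed = seed)
  res$delta_beta <- d_beta
  res$delta_speed <- d_speed
  res
}

#' Paired tests across the prespecified analysis sets
#'
#' Runs the exact Wilcoxon test and the bootstrapped SMD on the full
#' cohort, on responders only, and on leave-one-out sets excluding each
#' non-responder separately. Sets smaller than 3 pairs are skipped with a
#' warning.
#'
#' @param data data.frame with columns `participant`, `pre`, `post`
#' @param non_responders character vector of non-responder ids
#' @param B bootstrap resamples for the SMD CI
#' @param seed integer seed
#' @return data.frame with one row per analysis set: `analysis_set`, `n`,
#'   `W`, `p_exact`, `smd`, `smd_ci_low`, `smd_ci_high`
#' @export
analysis_sets <- function(data, non_responders = character(0), B = 5000,
                          seed = 1) {
  stopifnot(all(c("participant", "pre", "post") %in% names(data)))
  sets <- list(all = data$participant)
  if (length(non_responders)) {
    sets$responders <- setdiff(data$participant, non_responders)
    for (id in non_responders) {
      sets[[paste0("excl_", id)]] <- setdiff(data$participant, id)
    }
  }
  rows <- list()
  for (nm in names(sets)) {
    sel <- data$participant %in% sets[[nm]]
    if (sum(sel) < 3) {
      warning("analysis set '", nm, "' has fewer than 3 pairs; skipped")
      next
    }
    wt <- wilcoxon_exact(data$pre[sel], data$post[sel])
    es <- smd_bootstrap(data$pre[sel], data$post[sel], B = B, seed = seed)
    rows[[nm]] <- data.frame(analysis_set = nm, n = sum(sel), W = wt$W,
                             p_exact = wt$p_exact, smd = es$smd,
                             smd_ci_low = es$ci[1], smd_ci_high = es$ci[2])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
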