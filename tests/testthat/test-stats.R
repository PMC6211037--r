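# Summary-based reconstructions, exact nonparametric tests, assumption checks.

test_that("group summaries derive sd and variance consistently", {
  g <- group_summary(10, 2, 9)
  expect_equal(g$sd, 6)
  expect_equal(g$variance, 36)
  x <- sample_with_moments(12, 5, 2, seed = 3)
  s <- summarize_sample(x)
  expect_equal(s$mean, 5)
  expect_equal(s$sd, 2)
})

test_that("summary ANOVA equals the raw-data ANOVA and degenerates to F = 0", {
  specs <- list(c(12, 10, 3), c(8, 15, 2.5), c(9, 6, 4))
  raw <- lapply(seq_along(specs), function(i) {
    sample_with_moments(specs[[i]][2], specs[[i]][1], specs[[i]][3], seed = i)
  })
  groups <- lapply(raw, summarize_sample)
  ours <- anova_from_summary(groups)

  df <- data.frame(y = unlist(raw),
                   g = factor(rep(seq_along(raw), lengths(raw))))
  ref <- anova(lm(y ~ g, df))
  expect_equal(ours$value, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(ours$df, ref$Df)
  expect_equal(ours$p, ref$`Pr(>F)`[1], tolerance = 1e-10)

  same <- list(group_summary(5, 1, 4), group_summary(5, 2, 6))
  expect_equal(anova_from_summary(same)$value, 0)
  expect_error(anova_from_summary(list(group_summary(1, 1, 1),
                                       group_summary(2, 1, 5))), "n >= 2")
})

test_that("summary t tests match t.test on matching raw data, and F = t^2 for two groups", {
  x <- sample_with_moments(11, 20, 4, seed = 1)
  y <- sample_with_moments(15, 17, 6, seed = 2)
  a <- summarize_sample(x)
  b <- summarize_sample(y)

  pooled <- t_from_summary(a, b, "pooled")
  ref_p <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$value, unname(ref_p$statistic), tolerance = 1e-10)
  expect_equal(pooled$df, unname(ref_p$parameter))

  welch <- t_from_summary(a, b, "welch")
  ref_w <- t.test(x, y)
  expect_equal(welch$value, unname(ref_w$statistic), tolerance = 1e-10)
  expect_equal(welch$df, unname(ref_w$parameter), tolerance = 1e-10)

  expect_equal(anova_from_summary(list(a, b))$value, pooled$value^2,
               tolerance = 1e-10)
  expect_equal(t_from_summary(a, a)$value, 0)
})

test_that("the exact signed-rank p equals full enumeration of sign assignments", {
  for (n in c(4, 6, 9)) {
    d <- withr::with_seed(n, stats::rnorm(n) + 0.4)
    v_obs <- sum(rank(abs(d))[d > 0])
    r <- rank(abs(d))
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    v_all <- signs %*% r
    p_enum <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
    ours <- wilcoxon_signed_rank_exact(differences = d)
    expect_equal(ours$value, v_obs)
    expect_equal(ours$p, p_enum)
  }
})

test_that("the signed-rank null distribution is symmetric and matches psignrank", {
  for (n in c(5, 8, 12)) {
    null <- signed_rank_null(n)
    expect_equal(sum(null), 1)
    expect_equal(null, rev(null))  # p(V) = p(n(n+1)/2 - V)
    v <- 0:(n * (n + 1) / 2)
    expect_equal(cumsum(null), stats::psignrank(v, n), tolerance = 1e-12)
  }
})

test_that("signed-rank edge handling: zeros dropped, all-zero rejected, large-n approximation", {
  expect_warning(r <- wilcoxon_signed_rank_exact(differences = c(0, 1, 2, -0.5, 3)),
                 "zero difference")
  expect_equal(r$n_pairs, 4L)
  expect_error(suppressWarnings(wilcoxon_signed_rank_exact(differences = c(0, 0))),
               "all differences")
  approx <- wilcoxon_signed_rank_exact(V = 100, n = 30)
  expect_match(approx$method, "approximation")
  expect_true(approx$p > 0 && approx$p < 1)
})

test_that("rank-sum W uses the Mann-Whitney convention and exact p matches enumeration", {
  x <- 1:4
  y <- 5:9  # complete separation
  r <- wilcoxon_rank_sum(x, y)
  expect_equal(r$value, 0)
  expect_equal(r$p, 2 / choose(9, 4))

  # enumeration oracle on small arbitrary data
  x <- c(1.2, 3.4, 2.2)
  y <- c(0.5, 4.1, 2.9, 5.5)
  ours <- wilcoxon_rank_sum(x, y)
  all_ranks <- rank(c(x, y))
  u_obs <- sum(all_ranks[1:3]) - 3 * 4 / 2
  combos <- utils::combn(7, 3)
  u_all <- apply(combos, 2, function(i) sum(all_ranks[i])) - 3 * 4 / 2
  p_enum <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(ours$value, u_obs)
  expect_equal(ours$p, p_enum)

  same <- wilcoxon_rank_sum(1, 1)
  expect_equal(same$p, 1)
})

test_that("Kruskal-Wallis wraps the rank test and is invariant to monotone transforms", {
  g <- withr::with_seed(2, lapply(1:3, function(i) stats::rnorm(6, i / 2)))
  ours <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(ours$value, unname(ref$statistic))
  expect_equal(kruskal_wallis(lapply(g, exp))$value, ours$value)
  expect_equal(kruskal_wallis(list(1:5, 1:5))$value, 0)
})

test_that("Levene test matches the ANOVA on absolute mean deviations and calibrates near 5%", {
  vals <- withr::with_seed(4, stats::rnorm(30))
  grp <- rep(letters[1:3], each = 10)
  ours <- levene_test(vals, grp)
  centred <- abs(vals - ave(vals, grp))
  ref <- anova(lm(centred ~ factor(grp)))
  expect_equal(ours$value, ref$`F value`[1])

  # type-I calibration under equal variances (F approximation is
  # asymptotic, so calibrate at a moderate group size)
  grp30 <- rep(letters[1:3], each = 30)
  rejections <- withr::with_seed(99, {
    mean(replicate(800, {
      v <- stats::rnorm(90)
      levene_test(v, grp30)$p < 0.05
    }))
  })
  expect_lt(abs(rejections - 0.05), 0.025)
})

test_that("Shapiro wrapper rejects degenerate samples; outlier rule flags a z = 5 point", {
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  x <- withr::with_seed(1, stats::rnorm(30))
  x[30] <- mean(x[1:29]) + 5 * sd(x[1:29])
  flags <- outlier_flags(x)
  expect_equal(which(flags), 30L)
  checks <- assumption_checks(x, rep(c("a", "b"), 15))
  expect_named(checks, c("shapiro", "levene", "outliers"))
})

test_that("Bonferroni multiplies and clips", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(c(0.2, 0.04), 1), c(0.2, 0.04))
  expect_equal(bonferroni(0.02, 4), p.adjust(rep(0.02, 4), "bonferroni")[1])
})

test_that("Pearson correlation reproduces the t transform of r", {
  x <- withr::with_seed(7, stats::rnorm(36))
  y <- 0.7 * x + withr::with_seed(8, stats::rnorm(36, sd = 0.7))
  r <- pearson_correlation(x, y)
  expect_equal(r$value, r$r * sqrt((36 - 2) / (1 - r$r^2)), tolerance = 1e-10)
  expect_equal(r$df, 34)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_error(pearson_correlation(x, rep(1, 36)), "zero variance")
})

test_that("type-I error of the pooled summary t is near 5% under the null", {
  rejections <- withr::with_seed(123, {
    mean(replicate(2000, {
      a <- summarize_sample(stats::rnorm(10))
      b <- summarize_sample(stats::rnorm(12))
      t_from_summary(a, b, "pooled")$p < 0.05
    }))
  })
  expect_lt(abs(rejections - 0.05), 0.015)
})
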