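# Fisher LDA: criterion, directions, classification, biplot, MANOVA.

three_class_data <- function(seed = 1, n = c(9, 20, 6), sep = 4) {
  withr::with_seed(seed, {
    cls <- rep(c("A", "B", "C"), n)
    mu <- list(A = c(0, 0, 0), B = c(sep, 0, sep / 2), C = c(0, sep, sep))
    X <- t(vapply(cls, function(g) mu[[g]] + stats::rnorm(3), numeric(3)))
    df <- as.data.frame(X)
    names(df) <- c("f1", "f2", "f3")
    df$lineage <- cls
    df
  })
}

test_that("the fitted direction maximizes the Fisher criterion in the univariate two-class case", {
  x1 <- sample_with_moments(10, 0, 1, seed = 1)
  x2 <- sample_with_moments(12, 3, 1.5, seed = 2)
  df <- data.frame(f = c(x1, x2), lineage = rep(c("A", "B"), c(10, 12)))
  m <- fit_lda(df, "f", "lineage", standardize = FALSE)
  s <- lda_scores(m, df)
  crit_scores <- fisher_criterion(s[df$lineage == "A"], s[df$lineage == "B"])
  crit_direct <- fisher_criterion(x1, x2)
  expect_equal(crit_scores, crit_direct, tolerance = 1e-10)
  expect_equal(fisher_criterion(x1, x2),
               (mean(x1) - mean(x2))^2 / (var(x1) + var(x2)))
})

test_that("the two-class multivariate direction is parallel to W^-1 (mu1 - mu2)", {
  df <- three_class_data(seed = 3)
  df2 <- df[df$lineage != "C", ]
  m <- fit_lda(df2, c("f1", "f2", "f3"), "lineage", standardize = FALSE)
  X <- as.matrix(df2[, 1:3])
  cl <- factor(df2$lineage)
  mu <- rowsum(X, cl) / as.vector(table(cl))
  W <- crossprod(X - mu[cl, ])
  dir_ref <- solve(W, mu[1, ] - mu[2, ])
  cosine <- sum(dir_ref * m$scaling[, 1]) /
    sqrt(sum(dir_ref^2) * sum(m$scaling[, 1]^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-8)
})

test_that("with standardization, feature rescaling changes neither scores (up to sign) nor confusion", {
  df <- three_class_data(seed = 5)
  m1 <- fit_lda(df, c("f1", "f2", "f3"), "lineage")
  df_scaled <- df
  df_scaled$f2 <- df_scaled$f2 * 1000
  m2 <- fit_lda(df_scaled, c("f1", "f2", "f3"), "lineage")
  s1 <- lda_scores(m1, df)
  s2 <- lda_scores(m2, df_scaled)
  for (j in 1:2) {
    expect_equal(abs(s1[, j]), abs(s2[, j]), tolerance = 1e-6)
  }
  expect_equal(as.vector(lda_classify(m1, df)$confusion),
               as.vector(lda_classify(m2, df_scaled)$confusion))
})

test_that("three classes and three features give two directions with trace shares summing to one", {
  df <- three_class_data(seed = 6)
  m <- fit_lda(df, c("f1", "f2", "f3"), "lineage")
  expect_equal(ncol(m$scaling), 2L)
  expect_equal(sum(m$proportion_of_trace), 1)
  expect_true(all(diff(m$eigenvalues) <= 1e-9))
  expect_gte(m$means["A", ] %*% m$scaling[, 1], 0)  # sign convention
})

test_that("class-identical data is flagged degenerate", {
  df <- three_class_data(seed = 8, sep = 0)
  df$lineage <- rep(c("A", "B"), length.out = nrow(df))
  m <- fit_lda(df, c("f1", "f2", "f3"), "lineage")
  expect_lt(m$eigenvalues[1], 0.6)  # no real separation
  # identical class distributions: between-scatter is exactly zero
  same <- data.frame(f1 = rep(c(1, 2, 3, 4), 2),
                     lineage = rep(c("A", "B"), each = 4))
  msame <- fit_lda(same, "f1", "lineage", standardize = FALSE)
  expect_true(msame$degenerate)
  expect_true(all(is.na(msame$proportion_of_trace)))
})

test_that("classification agrees with MASS::lda and a class-mean point goes to its class", {
  skip_if_not_installed("MASS")
  df <- three_class_data(seed = 9)
  m <- fit_lda(df, c("f1", "f2", "f3"), "lineage", standardize = FALSE)
  ours <- lda_classify(m, df)
  ref <- MASS::lda(lineage ~ f1 + f2 + f3, df)
  ref_pred <- stats::predict(ref, df)
  expect_equal(as.character(ours$assigned), as.character(ref_pred$class))
  # proportions of trace agree
  expect_equal(m$proportion_of_trace, unname(ref$svd^2 / sum(ref$svd^2)),
               tolerance = 1e-8)

  centre_row <- df[1, ]
  centre_row[1, 1:3] <- colMeans(df[df$lineage == "B", 1:3])
  centre_row$lineage <- NULL
  expect_equal(as.character(lda_classify(m, centre_row)$assigned), "B")
})

test_that("biplot data is internally consistent with classification", {
  df <- three_class_data(seed = 10)
  m <- fit_lda(df, c("f1", "f2", "f3"), "lineage")
  bp <- biplot_data(m, df)
  expect_equal(dim(bp$scores), c(nrow(df), 2L))
  expect_equal(dim(bp$loadings), c(3L, 2L))
  # ellipse centres are the class score means
  for (g in names(bp$ellipses)) {
    expect_equal(bp$ellipses[[g]]$centre,
                 colMeans(bp$scores[df$lineage == g, , drop = FALSE]))
  }
  # nearest-centroid reassignment from exported scores matches classify
  centroids <- m$means %*% m$scaling
  near <- apply(bp$scores, 1, function(s) {
    m$classes[which.min(colSums((t(centroids[, 1:2]) - s)^2))]
  })
  cls <- lda_classify(m, df)
  agree <- mean(near == as.character(cls$assigned))
  expect_gt(agree, 0.9)  # priors can flip only borderline points
})

test_that("feature mismatch and tiny classes are rejected", {
  df <- three_class_data(seed = 11)
  m <- fit_lda(df, c("f1", "f2", "f3"), "lineage")
  expect_error(lda_scores(m, df[, c("f1", "f2")]), "missing feature")
  bad <- df[c(1, 10, 11, 12), ]
  expect_error(fit_lda(bad, c("f1", "f2"), "lineage"), "n >= 2")
})

test_that("MANOVA statistics match the reference implementation and the 1-D identity", {
  df <- three_class_data(seed = 12)
  mt <- manova_tests(df[, 1:3], df$lineage)
  ref <- summary(stats::manova(as.matrix(df[, 1:3]) ~ factor(df$lineage)),
                 test = "Wilks")
  expect_equal(mt$wilks$value, ref$stats[1, "Wilks"], tolerance = 1e-8)
  ref_p <- summary(stats::manova(as.matrix(df[, 1:3]) ~ factor(df$lineage)),
                   test = "Pillai")
  expect_equal(mt$pillai$value, ref_p$stats[1, "Pillai"], tolerance = 1e-8)
  expect_equal(mt$pillai$p, ref_p$stats[1, "Pr(>F)"], tolerance = 1e-6)

  # one discriminant dimension: Pillai = 1 - Lambda
  df2 <- df[df$lineage != "C", ]
  mt2 <- manova_tests(df2[, 1:3], df2$lineage)
  expect_equal(mt2$pillai$value, 1 - mt2$wilks$value, tolerance = 1e-10)
})

test_that("Pillai tends to zero for identically distributed groups", {
  df <- withr::with_seed(13, data.frame(
    f1 = stats::rnorm(300), f2 = stats::rnorm(300),
    g = rep(c("A", "B"), 150)))
  mt <- manova_tests(df[, 1:2], df$g)
  expect_lt(mt$pillai$value, 0.05)
})

test_that("pairwise Pillai post-hocs cover all lineage pairs and separate well-separated groups", {
  df <- three_class_data(seed = 14)
  ph <- manova_posthoc(df[, 1:3], df$lineage)
  expect_equal(nrow(ph), 3L)
  expect_true(all(ph$p_adjusted >= ph$p))
  expect_true(all(ph$p_adjusted < 0.05))
})
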