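## MANOVA on the multivariate duet features: Wilks' Lambda and the Pillai
## trace from the eigenvalues of W^-1 B (within- and between-group SSCP),
## with the standard F approximations; pairwise Pillai tests serve as the
## post-hoc comparisons.

#' MANOVA tests (Wilks and Pillai)
#'
#' @param features Numeric matrix or data frame (n x p) of responses.
#' @param groups Grouping factor (>= 2 levels, total n > p + k).
#' @return List with `wilks` and `pillai` test results and the
#'   eigenvalues of `W^-1 B`.  For one discriminant dimension
#'   (`min(p, k-1) == 1`), `Pillai == 1 - Lambda`.
#' @export
manova_tests <- function(features, groups) {
  X <- as.matrix(features)
  groups <- factor(groups)
  k <- nlevels(groups)
  p <- ncol(X)
  N <- nrow(X)
  stopifnot(k >= 2L, length(groups) == N)
  if (N <= p + k) stop("too few observations for a p-variate MANOVA", call. = FALSE)
  sc <- .scatter_matrices(X, groups)
  Winv <- tryCatch(solve(sc$W), error = function(e) {
    stop("singular within-group scatter matrix", call. = FALSE)
  })
  lam <- Re(eigen(Winv %*% sc$B, only.values = TRUE)$values)
  lam <- pmax(lam, 0)
  s <- min(p, k - 1)

  wilks <- prod(1 / (1 + lam))
  # Rao's F approximation
  t_ <- if (p^2 + (k - 1)^2 - 5 > 0) {
    sqrt((p^2 * (k - 1)^2 - 4) / (p^2 + (k - 1)^2 - 5))
  } else 1
  df1_w <- p * (k - 1)
  df2_w <- t_ * ((N - 1) - (p + k) / 2) - (p * (k - 1) - 2) / 2
  lw <- wilks^(1 / t_)
  f_w <- (1 - lw) / lw * df2_w / df1_w

  pillai <- sum(lam / (1 + lam))
  m <- (abs(p - k + 1) - 1) / 2
  nn <- (N - k - p - 1) / 2
  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * nn + s + 1)
  f_p <- (2 * nn + s + 1) / (2 * m + s + 1) * pillai / (s - pillai)

  list(
    wilks = test_result("Wilks Lambda", wilks, c(df1_w, df2_w),
                        pf(f_w, df1_w, df2_w, lower.tail = FALSE),
                        "MANOVA (Rao's F for Wilks)",
                        extra = list(F = f_w)),
    pillai = test_result("Pillai trace", pillai, c(df1_p, df2_p),
                         pf(f_p, df1_p, df2_p, lower.tail = FALSE),
                         "MANOVA (Pillai trace)",
                         extra = list(F = f_p)),
    eigenvalues = sort(lam, decreasing = TRUE)[seq_len(s)]
  )
}

.scatter_matrices <- function(X, groups) {
  mu <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X))
  B <- matrix(0, ncol(X), ncol(X))
  for (g in levels(groups)) {
    Xg <- X[groups == g, , drop = FALSE]
    mg <- colMeans(Xg)
    W <- W + crossprod(sweep(Xg, 2L, mg))
    B <- B + nrow(Xg) * tcrossprod(mg - mu)
  }
  list(W = W, B = B)
}

#' Pairwise Pillai post-hoc comparisons
#'
#' Runs a two-group MANOVA (Pillai trace) for every pair of group levels,
#' with Bonferroni-adjusted p-values.
#'
#' @param features Numeric matrix or data frame (n x p).
#' @param groups Grouping factor.
#' @return Data frame with one row per pair: `pillai`, `F`, `p`,
#'   `p_adjusted`.
#' @export
manova_posthoc <- function(features, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    sel <- groups %in% pairs[, j]
    mt <- manova_tests(as.matrix(features)[sel, , drop = FALSE],
                       droplevels(groups[sel]))
    data.frame(group1 = pairs[1L, j], group2 = pairs[2L, j],
               pillai = mt$pillai$value, F = mt$pillai$F,
               p = mt$pillai$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bonferroni(out$p, nrow(out))
  out
}
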