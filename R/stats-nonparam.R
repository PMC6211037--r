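## Nonparametric tests and distributional assumption checks.
##
## The signed-rank null distribution is built exactly by convolution over
## the rank generating function (each rank contributes factor
## (1 + z^r) / 2), which equals full enumeration of the 2^n sign
## assignments; with all n differences sharing one sign (V = 0) the exact
## two-sided p is 2 / 2^n.

#' Exact signed-rank null distribution by convolution
#'
#' @param n Number of non-zero paired differences.
#' @return Numeric vector `d` where `d[v + 1] = P(V = v)` under the null,
#'   `v = 0, ..., n(n+1)/2`.
#' @export
signed_rank_null <- function(n) {
  stopifnot(n >= 1)
  d <- 1
  for (r in seq_len(n)) {
    new <- c(d, numeric(r))
    new[(r + 1):length(new)] <- new[(r + 1):length(new)] + d
    d <- new / 2
  }
  d
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Exact p-values are computed from the convolution null distribution for
#' `n <= exact_max`; a normal approximation with continuity correction is
#' used above.  Zero differences are dropped with a warning; ties among
#' `|differences|` receive midranks (the exact distribution then treats
#' ranks as if distinct, the standard convention).
#'
#' Either supply the raw paired `differences`, or the statistic `V` with
#' the number of pairs `n`.
#'
#' @param differences Paired differences (zeros dropped).
#' @param V Signed-rank statistic (sum of ranks of positive differences).
#' @param n Number of non-zero pairs, required with `V`.
#' @param exact_max Largest `n` for which the exact distribution is used.
#' @return A test result with statistic `"V"`.
#' @export
#' @examples
#' wilcoxon_signed_rank_exact(V = 0, n = 8)$p  # 2/256
wilcoxon_signed_rank_exact <- function(differences = NULL, V = NULL, n = NULL,
                                       exact_max = 25L) {
  if (is.null(V)) {
    stopifnot(!is.null(differences))
    d <- differences[differences != 0]
    if (length(d) < length(differences)) {
      warning(length(differences) - length(d), " zero difference(s) dropped",
              call. = FALSE)
    }
    if (!length(d)) stop("all differences are zero", call. = FALSE)
    n <- length(d)
    V <- sum(rank(abs(d))[d > 0])
  } else {
    stopifnot(!is.null(n), n >= 1)
  }
  vmax <- n * (n + 1) / 2
  if (n <= exact_max) {
    null <- signed_rank_null(n)
    lo <- sum(null[seq_len(floor(V) + 1L)])          # P(V <= v)
    hi <- sum(null[(ceiling(V) + 1L):length(null)])  # P(V >= v)
    p <- min(1, 2 * min(lo, hi))
    method <- "Exact Wilcoxon signed-rank (convolution null)"
  } else {
    mu <- vmax / 2
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (V - mu - sign(V - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "Wilcoxon signed-rank (normal approximation, continuity corrected)"
  }
  test_result("V", V, n, p, method, extra = list(n_pairs = n))
}

#' Wilcoxon rank-sum test
#'
#' Wraps [stats::wilcox.test()].  The reported `W` is the Mann-Whitney
#' statistic (rank sum of `x` minus its minimum `n1(n1+1)/2`), so complete
#' separation with all `x` below all `y` gives `W = 0`.
#'
#' @param x,y Non-empty numeric samples.
#' @param exact_threshold Use the exact distribution when both samples are
#'   at most this size and there are no ties.
#' @return A test result with statistic `"W"`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 50L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (max(c(x, y)) == min(c(x, y))) {  # fully tied data: no evidence either way
    return(test_result("W", length(x) * length(y) / 2,
                       c(length(x), length(y)), 1,
                       "Wilcoxon rank-sum (degenerate: all values tied)"))
  }
  exact <- length(x) <= exact_threshold && length(y) <= exact_threshold &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  test_result("W", unname(wt$statistic), c(length(x), length(y)), wt$p.value,
              paste0("Wilcoxon rank-sum (",
                     if (exact) "exact" else "normal approximation", ")"))
}

#' Kruskal-Wallis rank-sum test
#'
#' Wraps [stats::kruskal.test()] (chi-squared statistic with tie
#' correction, df `k - 1`).
#'
#' @param groups List of numeric samples (>= 2 groups).
#' @return A test result with statistic `"chi-squared"`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L)
  kt <- kruskal.test(groups)
  test_result("chi-squared", unname(kt$statistic), unname(kt$parameter),
              kt$p.value, "Kruskal-Wallis rank-sum")
}

#' Levene test for homogeneity of variance (mean-centred)
#'
#' Classical Levene: one-way ANOVA on the absolute deviations from the
#' group means.
#'
#' @param values Numeric vector.
#' @param group Grouping factor (>= 2 levels).
#' @return A test result with statistic `"F"`.
#' @export
levene_test <- function(values, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2L, length(values) == length(group))
  centred <- abs(values - ave(values, group))
  fit <- anova(lm(centred ~ group))
  test_result("F", fit$`F value`[1L], fit$Df, fit$`Pr(>F)`[1L],
              "Levene test (mean-centred)")
}

#' Shapiro-Wilk normality test
#'
#' Wraps [stats::shapiro.test()]; errors on constant samples (zero
#' variance) and on `n < 3`.
#'
#' @param x Numeric sample, `3 <= n <= 5000`.
#' @return A test result with statistic `"W"`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L) stop("Shapiro-Wilk needs n >= 3", call. = FALSE)
  if (sd(x) == 0) stop("Shapiro-Wilk undefined for a constant sample", call. = FALSE)
  st <- shapiro.test(x)
  test_result("W", unname(st$statistic), length(x), st$p.value, "Shapiro-Wilk")
}

#' Outlier flags on standardized values (boxplot 1.5 IQR rule)
#'
#' Standardizes the sample to z-scores and flags points outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the standardized values.
#'
#' @param x Numeric sample.
#' @return Logical vector of flags.
#' @export
outlier_flags <- function(x) {
  z <- as.vector(scale(x))
  q <- quantile(z, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  z < q[1L] - 1.5 * iqr | z > q[2L] + 1.5 * iqr
}

#' Bundle of distributional assumption checks
#'
#' Shapiro-Wilk per group (groups too small or constant are reported as
#' `NULL`), mean-centred Levene across groups, and outlier flags on the
#' pooled standardized values.
#'
#' @param values Numeric vector.
#' @param group Grouping factor.
#' @return List with `shapiro` (per-group test results), `levene`, and
#'   `outliers` (logical flags).
#' @export
assumption_checks <- function(values, group) {
  group <- factor(group)
  list(
    shapiro = lapply(split(values, group), function(v) {
      if (length(v) < 3L || sd(v) == 0) NULL else shapiro_wilk(v)
    }),
    levene = levene_test(values, group),
    outliers = outlier_flags(values)
  )
}
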