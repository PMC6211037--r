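## Reconstruction of test statistics from printed (mean, SEM, n) summaries.
##
## Published comparative results are typically printed as mean +/- SEM with
## a group size; with the group variance recovered as s^2 = n * SEM^2 the
## classical one-way ANOVA and two-sample t statistics are exact functions
## of the summaries, so printed F and t values can be reproduced without
## the raw data.

#' Group summary (mean, SEM, n)
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Group size (>= 1).
#' @param label Optional group label.
#' @return A `group_summary` with derived `sd = sem * sqrt(n)` and
#'   `variance = n * sem^2`.
#' @export
group_summary <- function(mean, sem, n, label = NULL) {
  stopifnot(n >= 1, sem >= 0)
  structure(
    list(mean = mean, sem = sem, n = as.integer(n),
         sd = sem * sqrt(n), variance = n * sem^2, label = label),
    class = "group_summary"
  )
}

#' Summarize a raw sample into a group summary
#' @param x Numeric sample.
#' @param label Optional label.
#' @return A [group_summary()].
#' @export
summarize_sample <- function(x, label = NULL) {
  group_summary(mean(x), sd(x) / sqrt(length(x)), length(x), label)
}

## Uniform container for test results.
test_result <- function(statistic, value, df, p, method, extra = NULL) {
  structure(
    c(list(statistic = statistic, value = value, df = df, p = p,
           method = method), extra),
    class = "titiduet_test"
  )
}

#' @export
print.titiduet_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s: %s = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, x$value, dfs, x$p))
  invisible(x)
}

#' One-way ANOVA from group summaries
#'
#' `F = MS_between / MS_within` with df `(k - 1, sum(n) - k)`, group
#' variances reconstructed as `n * sem^2`.  Equals the ANOVA on any raw
#' data having exactly those means and variances.
#'
#' @param groups List of [group_summary()] objects (>= 2 groups, each
#'   `n >= 2`).
#' @return A test result with statistic `"F"`.
#' @export
#' @examples
#' anova_from_summary(list(
#'   group_summary(1186.3, 26.2, 11),
#'   group_summary(992.0, 17.00, 15),
#'   group_summary(667.5, 15.73, 6)))
anova_from_summary <- function(groups) {
  stopifnot(length(groups) >= 2L)
  for (g in groups) {
    stopifnot(inherits(g, "group_summary"))
    if (g$n < 2L) stop("each group needs n >= 2", call. = FALSE)
  }
  n <- vapply(groups, `[[`, 0L, "n")
  m <- vapply(groups, `[[`, 0, "mean")
  v <- vapply(groups, `[[`, 0, "variance")
  k <- length(groups)
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * v)
  f <- (ss_between / (k - 1)) / (ss_within / (N - k))
  test_result("F", f, c(k - 1, N - k),
              pf(f, k - 1, N - k, lower.tail = FALSE),
              "One-way ANOVA from (mean, SEM, n) summaries")
}

#' Two-sample t test from group summaries
#'
#' @param a,b [group_summary()] objects with `n >= 2`.
#' @param kind `"pooled"` (classical Student, df `n1 + n2 - 2`) or
#'   `"welch"` (Welch statistic, Welch-Satterthwaite df).
#' @return A test result with statistic `"t"`.  If both variances are zero
#'   with unequal means, the statistic is `Inf` (sentinel).
#' @export
t_from_summary <- function(a, b, kind = c("pooled", "welch")) {
  kind <- match.arg(kind)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"),
            a$n >= 2L, b$n >= 2L)
  d <- a$mean - b$mean
  if (kind == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$variance + (b$n - 1) * b$variance) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$variance / a$n
    vb <- b$variance / b$n
    se <- sqrt(va + vb)
    df <- if (se > 0) {
      (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    } else NA_real_
  }
  t <- if (se == 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / se
  p <- if (is.finite(t)) 2 * pt(abs(t), df, lower.tail = FALSE) else 0
  test_result("t", t, df, p,
              paste0(if (kind == "pooled") "Student" else "Welch",
                     " two-sample t from summaries"))
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for each p-value.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Pearson correlation test
#'
#' Wraps [stats::cor.test()] and reports `r`, `t = r * sqrt((n-2)/(1-r^2))`
#' and `df = n - 2`; used to screen predictors for multicollinearity.
#'
#' @param x,y Numeric vectors (`n >= 3`).
#' @return A test result with statistic `"t"` and extra field `r`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  test_result("t", unname(ct$statistic), unname(ct$parameter), ct$p.value,
              "Pearson product-moment correlation",
              extra = list(r = unname(ct$estimate)))
}
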