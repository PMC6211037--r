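## Gaussian random-intercept mixed model, fitted by REML with the single
## variance ratio lambda = sigma_u^2 / sigma_e^2 profiled out.
##
## Repeated measurements (one per sequence or phrase) within a duet are
## correlated, so the duet ("song") enters as a random intercept while
## species is the fixed categorical effect.  With V_g = I + lambda * J for
## each duet g, Woodbury gives V_g^{-1} = I - (lambda / (1 + lambda n_g)) J
## and log|V_g| = log(1 + lambda n_g); all GLS quantities reduce to
## per-duet sums, and the profiled REML criterion is one-dimensional in
## log(lambda).  The fixed factor is tested with a Wald chi-squared
## analysis of deviance.

#' Fit a random-intercept linear mixed model by REML
#'
#' @param value Numeric response (one entry per measurement).
#' @param duet Grouping id of the random intercept (the duet / song).
#' @param species Fixed categorical effect.
#' @return An `lmm_fit`: fixed-effect estimates with covariance, the
#'   random-intercept variance and SD, residual variance, the profiled
#'   `lambda`, and the Wald chi-squared analysis of deviance for the fixed
#'   factor (`wald_chisq`, `wald_df`, `wald_p`).
#' @export
lmm_random_intercept <- function(value, duet, species) {
  duet <- factor(duet)
  species <- factor(species)
  stopifnot(length(value) == length(duet), length(value) == length(species))
  if (nlevels(duet) < 2L) stop("need measurements from at least two duets", call. = FALSE)
  X <- stats::model.matrix(~species)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design", call. = FALSE)
  y <- value
  N <- length(y)
  p <- ncol(X)
  idx <- split(seq_len(N), duet)
  ng <- lengths(idx)

  gls_parts <- function(lambda) {
    A <- matrix(0, p, p)
    cvec <- numeric(p)
    yy <- 0
    logdetV <- 0
    for (g in seq_along(idx)) {
      i <- idx[[g]]
      Xg <- X[i, , drop = FALSE]
      yg <- y[i]
      w <- lambda / (1 + lambda * ng[g])
      sx <- colSums(Xg)
      sy <- sum(yg)
      A <- A + crossprod(Xg) - w * tcrossprod(sx)
      cvec <- cvec + crossprod(Xg, yg) - w * sx * sy
      yy <- yy + sum(yg^2) - w * sy^2
      logdetV <- logdetV + log1p(lambda * ng[g])
    }
    b <- solve(A, cvec)
    rss <- max(yy - sum(b * cvec), .Machine$double.eps)
    list(A = A, b = b, rss = rss, logdetV = logdetV)
  }

  reml_crit <- function(loglambda) {
    gp <- gls_parts(exp(loglambda))
    gp$logdetV + determinant(gp$A, logarithm = TRUE)$modulus +
      (N - p) * log(gp$rss)
  }

  opt <- optimize(reml_crit, interval = c(-15, 15))
  lambda <- exp(opt$minimum)
  # boundary preference: when a pure fixed-effects model fits as well
  # (e.g. one measurement per duet leaves lambda unidentified), take
  # the zero-variance solution
  if (reml_crit(-30) <= opt$objective + 1e-6) lambda <- exp(-30)
  gp <- gls_parts(lambda)
  sigma_e2 <- gp$rss / (N - p)
  sigma_u2 <- lambda * sigma_e2
  vcov_b <- sigma_e2 * solve(gp$A)
  b <- drop(gp$b)
  names(b) <- colnames(X)

  sel <- setdiff(seq_len(p), 1L)  # species contrasts (drop intercept)
  chisq <- if (length(sel)) {
    drop(t(b[sel]) %*% solve(vcov_b[sel, sel, drop = FALSE], b[sel]))
  } else 0
  df <- length(sel)
  structure(
    list(coefficients = b, vcov = vcov_b,
         random_intercept_variance = sigma_u2,
         random_intercept_sd = sqrt(sigma_u2),
         residual_variance = sigma_e2, lambda = lambda,
         wald_chisq = chisq, wald_df = df,
         wald_p = pchisq(chisq, df, lower.tail = FALSE),
         n_obs = N, n_duets = nlevels(duet)),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> %d obs in %d duets\n  random intercept: var %.4g (SD %.4g); residual var %.4g\n  Wald chi-squared = %.4g, df = %d, p = %.4g\n",
    x$n_obs, x$n_duets, x$random_intercept_variance, x$random_intercept_sd,
    x$residual_variance, x$wald_chisq, x$wald_df, x$wald_p))
  invisible(x)
}
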